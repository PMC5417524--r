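fake_calls <- function(starts, dvs, kind, id = "q") {
  data.frame(source_id = rep(id, length(starts)), start = as.integer(starts),
             boundary_kind = rep(kind, length(starts)),
             decision_value = dvs, model_tag = rep("rf", length(starts)),
             stringsAsFactors = FALSE)
}

test_that("the sliding window visits L - s + 1 positions", {
  bundle <- fixture_bundle()
  win15 <- substr(fixture_corpus()$residues[1], 1, 15)
  calls <- scan_sites(win15, bundle$rf_init, bundle$pwm_init,
                      bundle$scale_table, "initiation", threshold = 0)
  expect_equal(attr(calls, "n_windows"), 1L)
  expect_equal(nrow(calls), 1L)

  seq100 <- substr(fixture_corpus()$residues[1], 1, 100)
  calls <- scan_sites(seq100, bundle$rf_init, bundle$pwm_init,
                      bundle$scale_table, "initiation", threshold = 0)
  expect_equal(attr(calls, "n_windows"), 86L)
  expect_equal(nrow(calls), 86L)
  expect_true(all(calls$decision_value >= 0 & calls$decision_value <= 1))

  expect_warning(short <- scan_sites("MGQT", bundle$rf_init, bundle$pwm_init,
                                     bundle$scale_table, "initiation"),
                 "shorter")
  expect_equal(nrow(short), 0L)
})

test_that("windows with non-standard residues are skipped and counted", {
  bundle <- fixture_bundle()
  res <- paste0(substr(fixture_corpus()$residues[1], 1, 40), "X",
                substr(fixture_corpus()$residues[1], 42, 80))
  calls <- scan_sites(res, bundle$rf_init, bundle$pwm_init,
                      bundle$scale_table, "initiation", threshold = 0)
  expect_equal(attr(calls, "n_skipped"), 15L)  # every window covering the X
  expect_equal(nrow(calls), attr(calls, "n_windows") - 15L)
})

test_that("the top-scoring initiation call sits on the planted start", {
  bundle <- fixture_bundle()
  strong <- generate_corpus(corpus_spec(5, conservation = 1, seed = 77))
  for (i in seq_len(nrow(strong))) {
    calls <- scan_sites(strong$residues[i], bundle$rf_init, bundle$pwm_init,
                        bundle$scale_table, "initiation", threshold = 0,
                        id = strong$id[i])
    expect_equal(calls$start[which.max(calls$decision_value)],
                 strong$ma_start[i])
  }
})

test_that("pair enumeration applies inclusive 88/127 length bounds", {
  init <- fake_calls(10, 0.9, "initiation")
  # term call at window start t implies ma_end = t + 14
  term_for_end <- function(ends) fake_calls(ends - 14L, 0.8, "termination")

  pairs <- enumerate_pairs(init, term_for_end(109L))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$ma_length, 100L)
  expect_equal(pairs$ma_start, 10L)
  expect_equal(pairs$ma_end, 109L)

  lens <- function(ends) enumerate_pairs(init, term_for_end(ends))$ma_length
  expect_equal(lens(10L + 88L - 1L), 88L)     # lower bound accepted
  expect_equal(lens(10L + 127L - 1L), 127L)   # upper bound accepted
  expect_length(lens(10L + 87L - 1L), 0L)     # 87 rejected
  expect_length(lens(10L + 128L - 1L), 0L)    # 128 rejected

  expect_equal(nrow(enumerate_pairs(init[0, ], term_for_end(109L))), 0L)
})

test_that("pair enumeration matches exhaustive brute force", {
  set.seed(55)
  for (rep in 1:5) {
    L <- 300L
    init <- fake_calls(sort(sample(L - 14L, 12)), runif(12), "initiation")
    term <- fake_calls(sort(sample(L - 14L, 12)), runif(12), "termination")
    pairs <- enumerate_pairs(init, term)
    brute <- list()
    for (i in seq_len(nrow(init))) {
      for (t in seq_len(nrow(term))) {
        len <- (term$start[t] + 14L) - init$start[i] + 1L
        if (len >= 88L && len <= 127L) {
          brute[[length(brute) + 1L]] <- c(init$start[i], term$start[t] + 14L)
        }
      }
    }
    expect_equal(nrow(pairs), length(brute))
    if (length(brute) > 0) {
      got <- mapply(paste, pairs$ma_start, pairs$ma_end)
      want <- vapply(brute, function(b) paste(b[1], b[2]), "")
      expect_setequal(got, want)
    }
  }
})

test_that("final selection takes the max-product survivor with tie-breaks", {
  base <- data.frame(source_id = "q", ma_start = c(10L, 30L),
                     ma_end = c(109L, 129L), ma_length = c(100L, 100L),
                     rf_init_dv = 0.9, rf_term_dv = 0.9,
                     stringsAsFactors = FALSE)
  # 0.95 * 0.9 = 0.855 beats 0.9 * 0.8 = 0.72
  base$wsvm_init_dv <- c(0.9, 0.95)
  base$wsvm_term_dv <- c(0.8, 0.9)
  pick <- select_final(base)
  expect_equal(pick$ma_start, 30L)
  expect_equal(pick$product_score, 0.855)

  # veto: pairs failing either WSVM threshold are discarded
  base$wsvm_init_dv <- c(0.9, 0.4)
  base$wsvm_term_dv <- c(0.8, 0.9)
  pick <- select_final(base)
  expect_equal(pick$ma_start, 10L)
  base$wsvm_init_dv <- c(0.4, 0.4)
  expect_null(select_final(base))

  # exact product ties break toward the smaller ma_start, then ma_end
  base$wsvm_init_dv <- c(0.9, 0.9)
  base$wsvm_term_dv <- c(0.8, 0.8)
  pick <- select_final(base)
  expect_equal(pick$ma_start, 10L)
  # order of the input rows does not matter
  pick_rev <- select_final(base[2:1, ])
  expect_equal(pick_rev$ma_start, 10L)
})

test_that("end-to-end prediction recovers planted boundaries exactly", {
  bundle <- fixture_bundle()
  held <- generate_corpus(corpus_spec(6, conservation = 0.95, seed = 123))
  n_hit <- 0L
  for (i in seq_len(nrow(held))) {
    pred <- predict_ma(held$residues[i], bundle, id = held$id[i])
    if (!is.null(pred) && pred$ma_start == held$ma_start[i] &&
        pred$ma_end == held$ma_end[i]) {
      n_hit <- n_hit + 1L
      expect_equal(pred$ma_length, held$ma_end[i] - held$ma_start[i] + 1L)
    }
  }
  expect_gte(n_hit, 5L)
})

test_that("prediction abstains on sequences that cannot host an MA", {
  bundle <- fixture_bundle()
  expect_null(predict_ma(strrep("A", 80), bundle))  # below min MA length

  set.seed(71)
  null_seq <- paste(sample(AA_ALPHABET, 400, replace = TRUE), collapse = "")
  expect_null(predict_ma(null_seq, bundle))
})

test_that("at most one prediction per sequence, length within bounds", {
  bundle <- fixture_bundle()
  held <- generate_corpus(corpus_spec(10, conservation = 0.9, seed = 301))
  preds <- predict_corpus(held, bundle)
  expect_lte(nrow(preds), nrow(held))
  expect_false(any(duplicated(preds$source_id)))
  expect_true(all(preds$ma_length >= 88L & preds$ma_length <= 127L))
  expect_true(all(preds$product_score >= 0 & preds$product_score <= 1))
})

test_that("six-frame DNA scanning agrees with direct protein scanning", {
  bundle <- fixture_bundle()
  held <- generate_corpus(corpus_spec(2, conservation = 1, seed = 42))
  prot <- held$residues[1]
  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
             H = "CAT", I = "ATT", K = "AAA", L = "TTG", M = "ATG", N = "AAT",
             P = "CCT", Q = "CAA", R = "CGT", S = "AGT", T = "ACT", V = "GTT",
             W = "TGG", Y = "TAT")
  dna <- paste(codon[strsplit(prot, "")[[1]]], collapse = "")

  direct <- predict_ma(prot, bundle)
  viaDNA <- translate_and_scan(dna, bundle, frames = 1)
  expect_equal(nrow(viaDNA), 1L)
  expect_equal(viaDNA$prot_start, direct$ma_start)
  expect_equal(viaDNA$prot_end, direct$ma_end)
  expect_equal(viaDNA$dna_start, 3L * (direct$ma_start - 1L) + 1L)
  expect_equal(viaDNA$dna_end, 3L * direct$ma_end)

  # reverse-complemented input: same call on the minus strand, coordinates
  # on the input as given
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  viaRC <- translate_and_scan(rc, bundle, frames = 6)
  expect_equal(nrow(viaRC), 1L)
  expect_equal(viaRC$strand, "-")
  expect_equal(viaRC$prot_start, direct$ma_start)
  expect_equal(viaRC$dna_end, nchar(dna) - viaDNA$dna_start + 1L)

  # all-stop DNA yields nothing
  expect_equal(nrow(translate_and_scan(strrep("TAA", 200), bundle, frames = 6)),
               0L)
  expect_error(translate_and_scan("ACGTQQ", bundle), "IUPAC")
})
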