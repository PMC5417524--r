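test_that("FASTA reading handles single records, case, and flags", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MGQT"), path)
  corpus <- read_fasta(path)
  expect_equal(corpus$id, "s1")
  expect_equal(corpus$residues, "MGQT")
  expect_false(corpus$nonstandard)
  expect_true(is.na(corpus$ma_start))

  writeLines(c(">s1", "mgxt"), path)
  corpus <- read_fasta(path)
  expect_equal(corpus$residues, "MGXT")  # uppercased, X retained
  expect_true(corpus$nonstandard)
})

test_that("FASTA round-trip preserves arbitrary valid records", {
  set.seed(31)
  n <- 12L
  corpus <- data.frame(
    id = paste0("rec", seq_len(n)),
    residues = vapply(sample(20:400, n), function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), ""),
    ma_start = NA_integer_, ma_end = NA_integer_, nonstandard = FALSE,
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(corpus, path)
  back <- read_fasta(path)
  expect_identical(back$id, corpus$id)
  expect_identical(back$residues, corpus$residues)
})

test_that("duplicate ids and empty files are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MG", ">a", "MG"), path)
  expect_error(read_fasta(path), "duplicate.*a")
  writeLines(character(), path)
  expect_error(read_fasta(path))
})

test_that("annotations attach with exact coordinates and init-only support", {
  fasta <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(s1 = paste(rep("ACDEFGHIKLMNPQRSTVWY", 10), collapse = ""),
            s2 = paste(rep("MGQTVTTPLSLTLGH", 10), collapse = ""))
  writeLines(c(">s1", seqs[1], ">s2", seqs[2]), fasta)
  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tma_start\tma_end", "s1\t10\t109", "s2\t10\t"), ann)
  corpus <- read_annotations(ann, read_fasta(fasta))
  expect_equal(corpus$ma_start, c(10L, 10L))
  expect_equal(corpus$ma_end, c(109L, NA_integer_))
  expect_equal(corpus$ma_end[1] - corpus$ma_start[1] + 1L, 100L)

  # init-only record usable for initiation training only
  expect_equal(nrow(positive_windows(corpus, "initiation")), 2L)
  expect_equal(nrow(positive_windows(corpus, "termination")), 1L)
})

test_that("annotation coordinates match independently hand-sliced windows", {
  # three fixtures with known content at the boundaries
  res <- c(
    paste0("XXXX", "MABCDEFGHIJKLYY", strrep("Q", 100)),
    paste0(strrep("S", 20), "WINDWATTWENTYWR", strrep("T", 100)),
    paste0("M", strrep("A", 118)))
  res <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "A", res)  # sanitize letters
  fasta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">f1", res[1], ">f2", res[2], ">f3", res[3]), fasta)
  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tma_start\tma_end", "f1\t5\t104", "f2\t21\t120", "f3\t1\t100"),
             ann)
  corpus <- read_annotations(ann, read_fasta(fasta))
  pos <- positive_windows(corpus, "initiation")
  for (i in 1:3) {
    expect_identical(pos$window[i],
                     substr(corpus$residues[i], corpus$ma_start[i],
                            corpus$ma_start[i] + 14L))
  }
})

test_that("annotation errors: unknown id, inverted interval, 0-based input", {
  fasta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", strrep("M", 200)), fasta)
  corpus <- read_fasta(fasta)
  ann <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("id\tma_start\tma_end", "ghost\t10\t109"), ann)
  expect_error(read_annotations(ann, corpus), "ghost")

  writeLines(c("id\tma_start\tma_end", "s1\t109\t10"), ann)
  expect_error(read_annotations(ann, corpus), "ma_start > ma_end")

  writeLines(c("id\tma_start\tma_end", "s1\t0\t99"), ann)
  expect_error(read_annotations(ann, corpus), "1-based")

  # off-range MA length warns but keeps the record
  writeLines(c("id\tma_start\tma_end", "s1\t1\t50"), ann)
  expect_warning(out <- read_annotations(ann, corpus), "outside")
  expect_equal(out$ma_end[1], 50L)
})

test_that("scale tables are validated to 10 x 20", {
  tab <- fixture_scale_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(scale = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_scale_table(path)
  expect_identical(unname(m), unname(tab))
  expect_identical(colnames(m), AA_ALPHABET)

  utils::write.table(df[1:9, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_scale_table(path), "10")

  utils::write.table(df[, setdiff(names(df), "W")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_scale_table(path), "W")
})

test_that("shipped default scale table loads and is standardized", {
  m <- default_scale_table()
  expect_equal(dim(m), c(10L, 20L))
  expect_equal(unname(rowMeans(m)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(m, 1, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("bundle persistence round-trips bit-identical decision values", {
  bundle <- fixture_bundle()
  seq1 <- fixture_corpus()$residues[1]
  before <- predict_ma(seq1, bundle, id = "rt")
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, path)
  reloaded <- load_bundle(path)
  after <- predict_ma(seq1, reloaded, id = "rt")
  expect_identical(before, after)

  scan_before <- scan_sites(seq1, bundle$rf_init, bundle$pwm_init,
                            bundle$scale_table, "initiation", threshold = 0)
  scan_after <- scan_sites(seq1, reloaded$rf_init, reloaded$pwm_init,
                           reloaded$scale_table, "initiation", threshold = 0)
  expect_identical(scan_before$decision_value, scan_after$decision_value)
})

test_that("bundle persistence refuses incomplete or unreadable input", {
  bundle <- fixture_bundle()
  broken <- bundle
  broken$wsvm_term <- NULL
  path <- withr::local_tempfile(fileext = ".rds")
  expect_error(save_bundle(broken, path), "wsvm_term")

  writeLines("not a bundle", path)
  expect_error(load_bundle(path))

  wrong <- bundle
  wrong$format_version <- "0.0"
  saveRDS(wrong, path)
  expect_error(load_bundle(path), "version")
})
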