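#' Scan a sequence for candidate boundary sites
#'
#' Slides a 15-residue window over the sequence (step 1), featurizes every
#' window against the bundle's PWM for the given boundary kind, and returns
#' the windows whose decision value reaches `threshold`.  Windows containing
#' non-standard residues are skipped and counted (attribute `n_skipped`).
#' A window start of `w` (1-based) implies boundary coordinates
#' `ma_start = w` for initiation calls and `ma_end = w + 14` for termination
#' calls, because a positive termination window ends at the termination
#' site.
#'
#' @param residues Amino-acid sequence (single string).
#' @param clf Trained `ma_classifier` for this boundary kind.
#' @param pwm The matching `ma_pwm` (positives-only PWM of this boundary
#'   kind).
#' @param scale_table 10 x 20 physicochemical table.
#' @param boundary_kind `"initiation"` or `"termination"`.
#' @param threshold Minimum decision value to report (default 0.5); set to 0
#'   to keep every window.
#' @param id Sequence identifier carried into the calls.
#' @return Data frame of site calls: `source_id`, `start` (1-based window
#'   start), `boundary_kind`, `decision_value`, `model_tag`.  Empty (with a
#'   warning) for sequences shorter than the window.
#' @export
scan_sites <- function(residues, clf, pwm, scale_table,
                       boundary_kind = c("initiation", "termination"),
                       threshold = 0.5, id = "seq") {
  boundary_kind <- match.arg(boundary_kind)
  s <- ncol(pwm$scores)
  empty <- data.frame(source_id = character(), start = integer(),
                      boundary_kind = character(), decision_value = numeric(),
                      model_tag = character(), stringsAsFactors = FALSE)
  if (nchar(residues) < s) {
    warning("sequence '", id, "' shorter than the ", s, "-residue window")
    return(empty)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- aa_index(chars)
  starts <- seq_len(length(idx) - s + 1L)
  widx <- matrix(idx[outer(starts, 0:(s - 1L), "+")],
                 nrow = length(starts), ncol = s)
  valid <- rowSums(is.na(widx)) == 0L
  n_skipped <- sum(!valid)
  if (!any(valid)) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  X <- featurize_index_matrix(widx[valid, , drop = FALSE], pwm, scale_table)
  dv <- decision_value(clf, X)
  keep <- dv >= threshold
  n_keep <- sum(keep)
  out <- data.frame(source_id = rep(id, n_keep),
                    start = starts[valid][keep],
                    boundary_kind = rep(boundary_kind, n_keep),
                    decision_value = dv[keep],
                    model_tag = rep(clf$algorithm, n_keep),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_windows") <- length(starts)
  out
}

#' Enumerate length-admissible boundary pairs
#'
#' Crosses every initiation call with every termination call of the same
#' sequence and keeps pairs whose implied MA length lies within
#' `[min_len, max_len]` inclusive.  An initiation call at window start `i`
#' implies `ma_start = i`; a termination call at window start `t` implies
#' `ma_end = t + 14` (the window ends at the termination site), so the
#' implied length is `ma_end - ma_start + 1`.
#'
#' @param init_calls,term_calls Site-call data frames from [scan_sites()].
#' @param min_len,max_len Inclusive MA length bounds (defaults 88 and 127).
#' @param s Window length (default 15).
#' @return Data frame of candidate pairs: `source_id`, `ma_start`, `ma_end`,
#'   `ma_length`, `rf_init_dv`, `rf_term_dv` (the candidate-model decision
#'   values).
#' @export
enumerate_pairs <- function(init_calls, term_calls, min_len = 88L,
                            max_len = 127L, s = 15L) {
  empty <- data.frame(source_id = character(), ma_start = integer(),
                      ma_end = integer(), ma_length = integer(),
                      rf_init_dv = numeric(), rf_term_dv = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(init_calls) == 0L || nrow(term_calls) == 0L) return(empty)
  stopifnot(all(init_calls$source_id == term_calls$source_id[1L]))
  g <- expand.grid(i = seq_len(nrow(init_calls)), t = seq_len(nrow(term_calls)))
  ma_start <- init_calls$start[g$i]
  ma_end <- term_calls$start[g$t] + s - 1L
  len <- ma_end - ma_start + 1L
  keep <- len >= min_len & len <= max_len
  data.frame(source_id = init_calls$source_id[g$i][keep],
             ma_start = as.integer(ma_start[keep]),
             ma_end = as.integer(ma_end[keep]),
             ma_length = as.integer(len[keep]),
             rf_init_dv = init_calls$decision_value[g$i][keep],
             rf_term_dv = term_calls$decision_value[g$t][keep],
             stringsAsFactors = FALSE)
}

#' Select the final MA prediction by WSVM veto and maximum product
#'
#' Re-scores the boundary windows of every candidate pair with the
#' weighted-SVM models; a pair survives only if both its initiation and
#' termination windows are also called positive by the WSVMs
#' (`decision value >= threshold`).  Among survivors the pair with the
#' largest product of the two WSVM decision values wins; ties break toward
#' the smaller `ma_start`, then the smaller `ma_end`.
#'
#' @param pairs Candidate pairs from [enumerate_pairs()] (one sequence).
#' @param residues The sequence the pairs come from.
#' @param bundle Trained `ma_bundle` (supplies `wsvm_init`, `wsvm_term`,
#'   PWMs and scale table).
#' @param threshold WSVM veto threshold (default 0.5).
#'
#' @details If `pairs` already carries `wsvm_init_dv` / `wsvm_term_dv`
#' columns they are used as-is and `residues` / `bundle` are not consulted,
#' which makes the veto-and-argmax rule testable in isolation.
#'
#' @return One-row data frame (`source_id`, `ma_start`, `ma_end`,
#'   `ma_length`, `rf_init_dv`, `rf_term_dv`, `wsvm_init_dv`,
#'   `wsvm_term_dv`, `product_score`) or `NULL` when every pair is vetoed.
#' @export
select_final <- function(pairs, residues, bundle, threshold = 0.5) {
  if (nrow(pairs) == 0L) return(NULL)
  if (!all(c("wsvm_init_dv", "wsvm_term_dv") %in% names(pairs))) {
    s <- bundle$window_length
    init_starts <- sort(unique(pairs$ma_start))
    term_starts <- sort(unique(pairs$ma_end - s + 1L))
    win <- function(starts) substr(rep(residues, length(starts)), starts, starts + s - 1L)
    init_dv <- decision_value(bundle$wsvm_init,
                              featurize_windows(win(init_starts), bundle$pwm_init,
                                                bundle$scale_table))
    term_dv <- decision_value(bundle$wsvm_term,
                              featurize_windows(win(term_starts), bundle$pwm_term,
                                                bundle$scale_table))
    pairs$wsvm_init_dv <- init_dv[match(pairs$ma_start, init_starts)]
    pairs$wsvm_term_dv <- term_dv[match(pairs$ma_end - s + 1L, term_starts)]
  }
  pairs$product_score <- pairs$wsvm_init_dv * pairs$wsvm_term_dv
  ok <- pairs$wsvm_init_dv >= threshold & pairs$wsvm_term_dv >= threshold
  surv <- pairs[ok, , drop = FALSE]
  if (nrow(surv) == 0L) return(NULL)
  surv <- surv[order(-surv$product_score, surv$ma_start, surv$ma_end), , drop = FALSE]
  out <- surv[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the matrix-protein interval of one protein sequence
#'
#' End-to-end composition: random-forest scans for initiation and
#' termination candidates, length-constrained pair enumeration, then the
#' WSVM veto + maximum-product selection.  Deterministic given the bundle.
#' At most one prediction is returned per sequence; `NULL` means no
#' admissible, veto-surviving pair exists (the expected outcome on
#' sequences without an MA).
#'
#' @param residues Amino-acid sequence.
#' @param bundle Trained `ma_bundle`.
#' @param id Sequence identifier.
#' @param rf_threshold,wsvm_threshold Decision-value thresholds (default 0.5).
#' @return One-row prediction data frame (see [select_final()]) or `NULL`.
#' @export
predict_ma <- function(residues, bundle, id = "seq", rf_threshold = 0.5,
                       wsvm_threshold = 0.5) {
  stopifnot(inherits(bundle, "ma_bundle"))
  if (nchar(residues) < bundle$min_ma_len) return(NULL)
  init <- scan_sites(residues, bundle$rf_init, bundle$pwm_init,
                     bundle$scale_table, "initiation",
                     threshold = rf_threshold, id = id)
  if (nrow(init) == 0L) return(NULL)
  term <- scan_sites(residues, bundle$rf_term, bundle$pwm_term,
                     bundle$scale_table, "termination",
                     threshold = rf_threshold, id = id)
  pairs <- enumerate_pairs(init, term, min_len = bundle$min_ma_len,
                           max_len = bundle$max_ma_len,
                           s = bundle$window_length)
  select_final(pairs, residues, bundle, threshold = wsvm_threshold)
}

#' Predict MA intervals for every sequence of a corpus
#'
#' @param corpus Corpus data frame (annotations, if any, are ignored).
#' @param bundle Trained `ma_bundle`.
#' @param progress_every Log a progress message every this many sequences
#'   (0 disables).
#' @inheritParams predict_ma
#' @return Data frame of predictions, zero rows when nothing is found.
#' @export
predict_corpus <- function(corpus, bundle, rf_threshold = 0.5,
                           wsvm_threshold = 0.5, progress_every = 0L) {
  preds <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    preds[[i]] <- predict_ma(corpus$residues[i], bundle, id = corpus$id[i],
                             rf_threshold = rf_threshold,
                             wsvm_threshold = wsvm_threshold)
    if (progress_every > 0L && i %% progress_every == 0L) {
      message("scanned ", i, "/", nrow(corpus), " sequences")
    }
  }
  preds <- preds[!vapply(preds, is.null, logical(1))]
  if (length(preds) == 0L) {
    return(data.frame(source_id = character(), ma_start = integer(),
                      ma_end = integer(), ma_length = integer(),
                      rf_init_dv = numeric(), rf_term_dv = numeric(),
                      wsvm_init_dv = numeric(), wsvm_term_dv = numeric(),
                      product_score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  out
}

#' Six-frame translate a DNA sequence and scan for MA predictions
#'
#' Translates the requested reading frames with the standard genetic code,
#' splits each translation at stop codons, scans every resulting segment
#' independently, and reports predictions with frame, strand, protein-space
#' coordinates (within the segment) and DNA-space coordinates on the input
#' sequence as given (for minus-strand hits, the coordinates of the region
#' whose reverse complement encodes the protein; `dna_start < dna_end`
#' always).
#'
#' @param dna_sequence DNA string over the IUPAC alphabet (ambiguity codes
#'   translate to `X` and the affected windows are skipped).
#' @param bundle Trained `ma_bundle`.
#' @param frames 1 (forward frame 1), 3 (forward frames) or 6 (both
#'   strands).
#' @param id Sequence identifier.
#' @inheritParams predict_ma
#' @return Data frame of predictions with `frame`, `strand`, `prot_start`,
#'   `prot_end`, `dna_start`, `dna_end` columns added; zero rows when
#'   nothing is found.
#' @export
translate_and_scan <- function(dna_sequence, bundle, frames = 6L, id = "seq",
                               rf_threshold = 0.5, wsvm_threshold = 0.5) {
  stopifnot(frames %in% c(1L, 3L, 6L))
  dna_sequence <- toupper(dna_sequence)
  if (grepl("[^ACGTNRYSWKMBDHV]", dna_sequence)) {
    stop("non-IUPAC letter(s) in DNA input")
  }
  dna <- Biostrings::DNAString(dna_sequence)
  L <- length(dna)
  strands <- if (frames == 6L) c("+", "-") else "+"
  frame_set <- if (frames == 1L) 1L else 1:3
  rows <- list()
  for (strand in strands) {
    seq_use <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    for (f in frame_set) {
      n_codon <- (L - f + 1L) %/% 3L
      if (n_codon < 1L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(seq_use, f, f + 3L * n_codon - 1L),
        if.fuzzy.codon = "X")))
      # split at stop codons; track each segment's offset in the frame
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      offset <- 0L
      for (seg in segs) {
        seg_start_aa <- offset + 1L         # 1-based aa position in frame
        offset <- offset + nchar(seg) + 1L  # skip the stop
        if (nchar(seg) < bundle$min_ma_len) next
        pred <- predict_ma(seg, bundle, id = id,
                           rf_threshold = rf_threshold,
                           wsvm_threshold = wsvm_threshold)
        if (is.null(pred)) next
        aa_start <- seg_start_aa + pred$ma_start - 1L  # frame aa coords
        aa_end <- seg_start_aa + pred$ma_end - 1L
        nt_start <- f + 3L * (aa_start - 1L)           # coords on seq_use
        nt_end <- f + 3L * aa_end - 1L
        if (strand == "-") {
          tmp <- L - nt_end + 1L
          nt_end <- L - nt_start + 1L
          nt_start <- tmp
        }
        pred$frame <- f
        pred$strand <- strand
        pred$prot_start <- pred$ma_start
        pred$prot_end <- pred$ma_end
        pred$dna_start <- as.integer(nt_start)
        pred$dna_end <- as.integer(nt_end)
        rows[[length(rows) + 1L]] <- pred
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(source_id = character(), ma_start = integer(),
                      ma_end = integer(), ma_length = integer(),
                      rf_init_dv = numeric(), rf_term_dv = numeric(),
                      wsvm_init_dv = numeric(), wsvm_term_dv = numeric(),
                      product_score = numeric(), frame = integer(),
                      strand = character(), prot_start = integer(),
                      prot_end = integer(), dna_start = integer(),
                      dna_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write predictions as TSV
#'
#' @param predictions Prediction data frame from [predict_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write predictions as GFF3
#'
#' Emits one `matrix_protein` feature per prediction, with the product of
#' the WSVM decision values as the score column.
#'
#' @param predictions Prediction data frame.
#' @param path Output path.
#' @param coordinates `"protein"` (use `ma_start`/`ma_end`) or `"dna"` (use
#'   `dna_start`/`dna_end` from [translate_and_scan()]).
#' @return `path`, invisibly.
#' @export
write_predictions_gff3 <- function(predictions, path,
                                   coordinates = c("protein", "dna")) {
  coordinates <- match.arg(coordinates)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(predictions) == 0L) return(invisible(path))
  start <- if (coordinates == "dna") predictions$dna_start else predictions$ma_start
  end <- if (coordinates == "dna") predictions$dna_end else predictions$ma_end
  strand <- if ("strand" %in% names(predictions)) predictions$strand else "+"
  lines <- paste(predictions$source_id, "mascan", "matrix_protein",
                 start, end, sprintf("%.4f", predictions$product_score),
                 strand, ".",
                 paste0("ID=", predictions$source_id, ":MA:", start, "-", end),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
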