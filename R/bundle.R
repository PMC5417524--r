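#' Train a complete MA-prediction model bundle
#'
#' Builds the initiation and termination training sets (positives plus
#' `neg_ratio` seeded negatives each), the two positives-only PWMs, and
#' trains the four classifiers the boundary-pairing rule needs: random
#' forests as the high-sensitivity candidate callers and weighted SVMs as
#' the high-specificity veto models, for both boundary kinds.
#'
#' @param corpus Annotated corpus data frame.
#' @param scale_table 10 x 20 physicochemical table.
#' @param seed Integer master seed; all sampling and training seeds derive
#'   from it and are recorded in the bundle metadata.
#' @param neg_ratio Negatives per positive (default 5).
#' @param s Window length (default 15).
#' @param min_ma_len,max_ma_len Admissible MA length range (defaults 88,
#'   127).
#' @param pseudocount PPM smoothing (default 1).
#' @param rf_params,wsvm_params Optional hyperparameter overrides, each a
#'   list with `initiation` / `termination` entries.
#' @return An `ma_bundle` object (see [save_bundle()]).
#' @export
train_model_bundle <- function(corpus, scale_table = default_scale_table(),
                               seed = 1L, neg_ratio = 5L, s = 15L,
                               min_ma_len = 88L, max_ma_len = 127L,
                               pseudocount = 1, rf_params = NULL,
                               wsvm_params = NULL) {
  stopifnot(min_ma_len <= max_ma_len)
  kinds <- c("initiation", "termination")
  sets <- list()
  models <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    ts <- build_training_set(corpus, kind, ratio = neg_ratio,
                             seed = seed + i, s = s,
                             scale_table = scale_table,
                             pseudocount = pseudocount)
    sets[[kind]] <- ts
    models[[paste0("rf_", kind)]] <-
      train_classifier("rf", ts$X, ts$y, params = rf_params[[kind]],
                       seed = seed + 10L + i, boundary_kind = kind)
    models[[paste0("wsvm_", kind)]] <-
      train_classifier("wsvm", ts$X, ts$y, params = wsvm_params[[kind]],
                       seed = seed + 20L + i, boundary_kind = kind)
  }
  structure(list(
    format_version = BUNDLE_FORMAT_VERSION,
    window_length = as.integer(s),
    min_ma_len = as.integer(min_ma_len),
    max_ma_len = as.integer(max_ma_len),
    pwm_init = sets$initiation$pwm,
    pwm_term = sets$termination$pwm,
    scale_table = scale_table,
    rf_init = models$rf_initiation,
    rf_term = models$rf_termination,
    wsvm_init = models$wsvm_initiation,
    wsvm_term = models$wsvm_termination,
    metadata = list(
      seed = seed,
      neg_ratio = neg_ratio,
      n_init_pos = sum(sets$initiation$y == 1L),
      n_term_pos = sum(sets$termination$y == 1L),
      dataset_digest = corpus_digest(corpus),
      trained = format(Sys.time(), tz = "UTC"))),
    class = "ma_bundle")
}

# md5 of the corpus content, for provenance tracking in bundle metadata
#' @keywords internal
corpus_digest <- function(corpus) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(corpus$id, corpus$residues,
                   corpus$ma_start, corpus$ma_end, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.ma_bundle <- function(x, ...) {
  cat("mascan model bundle (format ", x$format_version, ")\n",
      "  window length: ", x$window_length,
      ", MA length range: [", x$min_ma_len, ", ", x$max_ma_len, "]\n",
      "  trained on ", x$metadata$n_init_pos, " initiation / ",
      x$metadata$n_term_pos, " termination positives (1:",
      x$metadata$neg_ratio, " negatives), seed ", x$metadata$seed, "\n",
      sep = "")
  invisible(x)
}
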