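#' Extract positive boundary windows from an annotated corpus
#'
#' A positive initiation window is the `s` residues starting at `ma_start`;
#' a positive termination window is the `s` residues ending at `ma_end`
#' (1-based inclusive).  Sequences lacking the relevant boundary are
#' silently not used (e.g. initiation-only records contribute nothing to the
#' termination set); sequences whose boundary lies closer than `s` residues
#' to the relevant edge are skipped with a warning.
#'
#' @param corpus Annotated corpus data frame (see [read_annotations()]).
#' @param boundary_kind `"initiation"` or `"termination"`.
#' @param s Window length (default 15).
#' @return Data frame of window samples: `window`, `label` (`"positive"`),
#'   `boundary_kind`, `source_id`, `start` (1-based window start in the
#'   source sequence).  The number of edge-skipped sequences is attached as
#'   attribute `n_skipped`.
#' @export
positive_windows <- function(corpus, boundary_kind = c("initiation", "termination"),
                             s = 15L) {
  boundary_kind <- match.arg(boundary_kind)
  has <- if (boundary_kind == "initiation") !is.na(corpus$ma_start) else !is.na(corpus$ma_end)
  sub <- corpus[has, , drop = FALSE]
  len <- nchar(sub$residues)
  start <- if (boundary_kind == "initiation") sub$ma_start else sub$ma_end - s + 1L
  ok <- start >= 1L & (start + s - 1L) <= len
  if (any(!ok)) {
    warning(sum(!ok), " sequence(s) skipped: ", boundary_kind,
            " boundary closer than ", s, " residues to the sequence edge")
  }
  sub <- sub[ok, , drop = FALSE]
  start <- start[ok]
  out <- data.frame(window = substr(sub$residues, start, start + s - 1L),
                    label = rep("positive", nrow(sub)),
                    boundary_kind = rep(boundary_kind, nrow(sub)),
                    source_id = sub$id,
                    start = as.integer(start),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Sample negative boundary windows
#'
#' The negative pool contains every `s`-residue window of every training
#' sequence whose start position is not a positive window start for the
#' given boundary kind in that sequence (regions without an MA, or
#' overlapping an MA without sharing its boundary).  Windows containing
#' non-standard residues, and windows closer than `min_distance` to a
#' positive start, are excluded.  Sampling is uniform without replacement
#' across the pooled corpus, seeded for reproducibility.
#'
#' @param corpus Annotated corpus data frame.
#' @param positives Positive window data frame from [positive_windows()].
#' @param ratio Negatives per positive (default 5).
#' @param seed Integer RNG seed.
#' @param min_distance Minimum |start difference| from any positive start
#'   (default 0: hard negatives adjacent to the true site are allowed).
#' @param s Window length.
#' @return Data frame in the same layout as [positive_windows()] with
#'   `label = "negative"`.
#' @export
negative_windows <- function(corpus, positives, ratio = 5L, seed = 1L,
                             min_distance = 0L, s = 15L) {
  stopifnot(ratio >= 1L)
  boundary_kind <- unique(positives$boundary_kind)
  stopifnot(length(boundary_kind) == 1L)
  pool <- vector("list", nrow(corpus))
  nonstd <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  for (i in seq_len(nrow(corpus))) {
    len <- nchar(corpus$residues[i])
    if (len < s) next
    starts <- seq_len(len - s + 1L)
    pos_starts <- positives$start[positives$source_id == corpus$id[i]]
    if (length(pos_starts) > 0L) {
      d <- vapply(starts, function(x) min(abs(x - pos_starts)), numeric(1))
      starts <- starts[d > min_distance]
    }
    if (length(starts) == 0L) next
    win <- substr(rep(corpus$residues[i], length(starts)), starts, starts + s - 1L)
    keep <- !grepl(nonstd, win)
    pool[[i]] <- data.frame(window = win[keep], source_id = corpus$id[i],
                            start = starts[keep], stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool) || nrow(pool) == 0L) stop("negative pool is empty")
  n_wanted <- ratio * nrow(positives)
  if (nrow(pool) < n_wanted) {
    warning("negative pool (", nrow(pool), ") smaller than requested ",
            n_wanted, "; returning the whole pool")
    n_wanted <- nrow(pool)
  }
  set.seed(seed)
  take <- sample.int(nrow(pool), n_wanted, replace = FALSE)
  out <- pool[take, , drop = FALSE]
  rownames(out) <- NULL
  data.frame(window = out$window,
             label = "negative",
             boundary_kind = boundary_kind,
             source_id = out$source_id,
             start = as.integer(out$start),
             stringsAsFactors = FALSE)
}

#' Build a boundary-kind training set
#'
#' Composes the sampling and feature modules: extracts positives, builds the
#' PWM from the positive windows only, samples `ratio` negatives per
#' positive, and featurizes everything into a numeric matrix.
#'
#' @inheritParams positive_windows
#' @inheritParams negative_windows
#' @param scale_table 10 x 20 physicochemical table (default:
#'   [default_scale_table()]).
#' @param pseudocount PPM smoothing constant (default 1).
#' @return List with `X` (n x 165 feature matrix), `y` (0/1 integer vector,
#'   1 = positive), `pwm` (the positives-only `ma_pwm`), and `samples` (the
#'   combined window data frame).
#' @export
build_training_set <- function(corpus, boundary_kind = c("initiation", "termination"),
                               ratio = 5L, seed = 1L, s = 15L,
                               scale_table = default_scale_table(),
                               pseudocount = 1, min_distance = 0L) {
  boundary_kind <- match.arg(boundary_kind)
  pos <- positive_windows(corpus, boundary_kind, s)
  if (nrow(pos) == 0L) stop("no positive ", boundary_kind, " windows in corpus")
  neg <- negative_windows(corpus, pos, ratio = ratio, seed = seed,
                          min_distance = min_distance, s = s)
  pwm <- build_pwm(pos$window, s = s, pseudocount = pseudocount)
  samples <- rbind(pos, neg)
  X <- featurize_windows(samples$window, pwm, scale_table)
  bad <- rowSums(is.na(X)) > 0L
  if (any(bad)) {
    warning(sum(bad), " training window(s) with non-standard residues dropped")
    X <- X[!bad, , drop = FALSE]
    samples <- samples[!bad, , drop = FALSE]
  }
  list(X = X,
       y = as.integer(samples$label == "positive"),
       pwm = pwm,
       samples = samples)
}

#' Dump a training set for audit
#'
#' @param training_set List from [build_training_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_training_set <- function(training_set, path) {
  utils::write.table(training_set$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
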