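#' The 20-letter standard amino-acid alphabet
#'
#' Fixed ordering used by every matrix in the package: PFM/PWM rows and
#' scale-table columns are always in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
aa_index <- function(chars) match(chars, AA_ALPHABET)

# windows -> n x s integer matrix of alphabet indices (NA for non-standard)
#' @keywords internal
window_index_matrix <- function(windows, s = 15L) {
  if (length(windows) == 0L) stop("no windows supplied")
  nch <- nchar(windows)
  if (any(nch != s)) {
    stop("all windows must have length ", s, "; offending lengths: ",
         paste(unique(nch[nch != s]), collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), ncol = s, byrow = TRUE)
  matrix(aa_index(chars), nrow = length(windows), ncol = s)
}

#' Build a position frequency matrix from aligned windows
#'
#' Counts the occurrences of each of the 20 amino acids at each of the `s`
#' positions of a set of equal-length windows.  Windows containing
#' non-standard residues (B, J, O, U, X, Z, `*`, ...) are rejected with a
#' warning rather than silently imputed.
#'
#' @param windows Character vector of `s`-residue strings.
#' @param s Window length (default 15).
#' @return An object of class `ma_pfm`: a list with `counts` (20 x `s`
#'   integer matrix, rows in [AA_ALPHABET] order), `n_sequences`, and
#'   `window_length`.
#' @export
build_pfm <- function(windows, s = 15L) {
  idx <- window_index_matrix(windows, s)
  bad <- rowSums(is.na(idx)) > 0L
  if (any(bad)) {
    warning(sum(bad), " window(s) with non-standard residues dropped from PFM")
    idx <- idx[!bad, , drop = FALSE]
  }
  if (nrow(idx) == 0L) stop("no usable windows (all contained non-standard residues)")
  counts <- vapply(seq_len(s), function(j) tabulate(idx[, j], nbins = 20L),
                   integer(20L))
  dimnames(counts) <- list(AA_ALPHABET, paste0("p", seq_len(s)))
  structure(list(counts = counts, n_sequences = nrow(idx), window_length = s),
            class = "ma_pfm")
}

#' Convert a position frequency matrix to a position probability matrix
#'
#' Each cell is `(count + pseudocount) / (N + 20 * pseudocount)`.  With
#' `pseudocount = 0` this is the plain relative frequency; the default
#' Laplace pseudocount of 1 keeps every cell strictly positive so the
#' log-likelihood transform stays finite.
#'
#' @param pfm An `ma_pfm` object.
#' @param pseudocount Non-negative additive smoothing constant.
#' @return 20 x `s` numeric matrix; every column sums to 1.
#' @export
pfm_to_ppm <- function(pfm, pseudocount = 1) {
  stopifnot(inherits(pfm, "ma_pfm"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pfm$n_sequences <= 0L) stop("PFM built from zero sequences")
  (pfm$counts + pseudocount) / (pfm$n_sequences + 20 * pseudocount)
}

#' Log-likelihood transform of a position probability matrix
#'
#' Scores are natural logarithms of the ratio between each probability and a
#' uniform background (`b = 1/20 = 0.05` for amino acids): a residue observed
#' at exactly the background rate scores 0, an invariant residue scores
#' `log(20)`.  Zero probabilities (possible only with `pseudocount = 0`
#' upstream) map to a finite `floor` score instead of `-Inf`.
#'
#' @param ppm 20 x `s` probability matrix from [pfm_to_ppm()].
#' @param background Background probability per residue (default 0.05).
#' @param floor Score assigned to zero-probability cells (default -10).
#' @param pseudocount Recorded provenance of the PPM smoothing (metadata only).
#' @return An `ma_pwm` object: list with `scores` (20 x `s`), `background`,
#'   `floor`, `pseudocount` and `log_base = "natural"`.
#' @export
ppm_to_pwm <- function(ppm, background = 0.05, floor = -10, pseudocount = NA_real_) {
  if (background <= 0) stop("background must be > 0")
  stopifnot(is.matrix(ppm), nrow(ppm) == 20L)
  scores <- log(ppm / background)
  scores[ppm == 0] <- floor
  structure(list(scores = scores, background = background, floor = floor,
                 pseudocount = pseudocount, log_base = "natural"),
            class = "ma_pwm")
}

#' Build a position weight matrix directly from positive windows
#'
#' Convenience composition of [build_pfm()], [pfm_to_ppm()] and
#' [ppm_to_pwm()].
#'
#' @inheritParams build_pfm
#' @inheritParams pfm_to_ppm
#' @inheritParams ppm_to_pwm
#' @return An `ma_pwm` object.
#' @export
build_pwm <- function(windows, s = 15L, pseudocount = 1, background = 0.05,
                      floor = -10) {
  ppm <- pfm_to_ppm(build_pfm(windows, s), pseudocount)
  ppm_to_pwm(ppm, background = background, floor = floor,
             pseudocount = pseudocount)
}

#' @export
print.ma_pwm <- function(x, ...) {
  cat("Position weight matrix: 20 x", ncol(x$scores),
      "(natural log, background", x$background, ")\n")
  invisible(x)
}

#' Position features of a single window
#'
#' Looks up each residue's PWM score at its position, producing the
#' 15-dimensional positional component of the hybrid feature vector.
#'
#' @param window Single `s`-residue string over the standard alphabet.
#' @param pwm An `ma_pwm` object.
#' @return Numeric vector of length `s`.
#' @export
position_features <- function(window, pwm) {
  stopifnot(inherits(pwm, "ma_pwm"))
  s <- ncol(pwm$scores)
  idx <- window_index_matrix(window, s)[1L, ]
  if (anyNA(idx)) {
    j <- which(is.na(idx))[1L]
    stop("non-standard residue '", substr(window, j, j), "' at position ", j)
  }
  unname(pwm$scores[cbind(idx, seq_len(s))])
}

#' Physicochemical features of a single window
#'
#' Maps the window through each of the 10 property scales, flattened
#' scale-major: entries 1..15 are scale 1 at positions 1..15, entries 16..30
#' scale 2, and so on.
#'
#' @param window Single `s`-residue string.
#' @param scale_table 10 x 20 numeric matrix (see [read_scale_table()]).
#' @return Numeric vector of length `10 * s` (150 for the default window).
#' @export
physicochemical_features <- function(window, scale_table) {
  validate_scale_table(scale_table)
  s <- nchar(window)
  idx <- window_index_matrix(window, s)[1L, ]
  if (anyNA(idx)) {
    j <- which(is.na(idx))[1L]
    stop("residue '", substr(window, j, j), "' at position ", j,
         " is absent from the scale table")
  }
  as.vector(t(scale_table[, idx, drop = FALSE]))
}

#' Hybrid 165-dimensional feature vector of a window
#'
#' Concatenates [position_features()] (15 values) and
#' [physicochemical_features()] (150 values) in that fixed layout.
#'
#' @inheritParams position_features
#' @inheritParams physicochemical_features
#' @return Numeric vector of length `(1 + 10) * s` = 165.
#' @export
featurize <- function(window, pwm, scale_table) {
  c(position_features(window, pwm),
    physicochemical_features(window, scale_table))
}

#' Featurize many windows at once
#'
#' Vectorized version of [featurize()] used by training-set construction and
#' the sliding-window scanner.  Rows with non-standard residues are returned
#' as `NA` rows; callers decide whether to drop or fail.
#'
#' @param windows Character vector of equal-length windows.
#' @param pwm An `ma_pwm`.
#' @param scale_table 10 x 20 scale matrix.
#' @return Numeric matrix, one row per window, `(1 + 10) * s` columns.
#' @export
featurize_windows <- function(windows, pwm, scale_table) {
  stopifnot(inherits(pwm, "ma_pwm"))
  validate_scale_table(scale_table)
  s <- ncol(pwm$scores)
  idx <- window_index_matrix(windows, s)
  featurize_index_matrix(idx, pwm, scale_table)
}

# core vectorized featurizer over an n x s matrix of alphabet indices
#' @keywords internal
featurize_index_matrix <- function(idx, pwm, scale_table) {
  n <- nrow(idx)
  s <- ncol(idx)
  out <- matrix(NA_real_, nrow = n, ncol = (1L + nrow(scale_table)) * s)
  pos <- matrix(NA_real_, nrow = n, ncol = s)
  for (j in seq_len(s)) pos[, j] <- pwm$scores[cbind(idx[, j], j)]
  out[, seq_len(s)] <- pos
  for (i in seq_len(nrow(scale_table))) {
    vals <- scale_table[i, ]
    block <- matrix(vals[idx], nrow = n, ncol = s)
    out[, s + (i - 1L) * s + seq_len(s)] <- block
  }
  colnames(out) <- c(paste0("pwm_p", seq_len(s)),
                     as.vector(t(outer(rownames(scale_table),
                                       paste0("_p", seq_len(s)), paste0))))
  out
}
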