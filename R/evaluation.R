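#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred Binary 0/1 vectors (1 = positive).
#' @return Named integer vector with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L))
}

#' Classification metrics for imbalanced boundary prediction
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, overall accuracy `ACC`, Matthews correlation
#' coefficient `MCC` (defined as 0 when its denominator vanishes), and the
#' geometric mean `G_mean = sqrt(Sn * Sp)` — the headline metric under class
#' imbalance: a degenerate all-negative classifier scores `ACC` near 1 but
#' `G_mean` exactly 0.
#'
#' @param counts Named vector with `TP`, `FN`, `TN`, `FP` (see
#'   [confusion_counts()]), all non-negative, with at least one positive and
#'   one negative sample.
#' @return Named numeric vector `Sn`, `Sp`, `ACC`, `MCC`, `G_mean`.
#' @export
boundary_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FN <- as.numeric(counts[["FN"]])
  TN <- as.numeric(counts[["TN"]]); FP <- as.numeric(counts[["FP"]])
  if (any(c(TP, FN, TN, FP) < 0)) stop("confusion counts must be non-negative")
  if (TP + FN == 0) stop("no positive samples: Sn undefined")
  if (TN + FP == 0) stop("no negative samples: Sp undefined")
  Sn <- TP / (TP + FN)
  Sp <- TN / (TN + FP)
  ACC <- (TP + TN) / (TP + TN + FN + FP)
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  c(Sn = Sn, Sp = Sp, ACC = ACC, MCC = MCC, G_mean = sqrt(Sn * Sp))
}

#' Stratified k-fold cross-validation of a boundary classifier
#'
#' Samples are shuffled within class and dealt into `k` folds so every fold
#' keeps the 1:`ratio` class balance.  Per-fold confusion counts are pooled
#' before metrics are computed (`pooling = "pooled"`, the default) or
#' per-fold metrics are averaged (`pooling = "average"`).  With
#' `reruns > 1` the whole procedure repeats on independent shufflings and
#' the report carries the mean and standard deviation across reruns.
#'
#' @param X,y Training data (0/1 labels).
#' @param algorithm `"wsvm"`, `"welm"` or `"rf"`.
#' @param params Hyperparameters forwarded to [train_classifier()].
#' @param k Number of folds (default 5; 10 also standard).
#' @param reruns Independent repetitions (default 1).
#' @param seed Integer seed.
#' @param pooling `"pooled"` or `"average"`.
#' @param boundary_kind Forwarded for default hyperparameters.
#' @return List with `metrics` (mean across reruns), `sd` (across reruns),
#'   `per_rerun` (matrix), `counts` (pooled confusion counts of the first
#'   rerun), plus `k`, `reruns`, `pooling` metadata.
#' @export
kfold_cv <- function(X, y, algorithm, params = NULL, k = 5L, reruns = 1L,
                     seed = 1L, pooling = c("pooled", "average"),
                     boundary_kind = "initiation") {
  pooling <- match.arg(pooling)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(y)) stop("k exceeds the number of samples")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (min(n_pos, n_neg) < 2L) {
    stop("smallest class (", min(n_pos, n_neg), ") too small for ", k,
         "-fold cross-validation")
  }
  # beyond k = min class size (e.g. the jack-knife limit k = n) some folds
  # hold out a single class; per-fold metrics are then undefined, so only
  # pooled counts are allowed
  if (min(n_pos, n_neg) < k && pooling == "average") {
    stop("smallest class (", min(n_pos, n_neg), ") has fewer samples than k = ",
         k, "; per-fold averaging undefined (use pooling = \"pooled\")")
  }
  per_rerun <- matrix(NA_real_, nrow = reruns, ncol = 5L,
                      dimnames = list(NULL, c("Sn", "Sp", "ACC", "MCC", "G_mean")))
  first_counts <- NULL
  for (r in seq_len(reruns)) {
    rerun_seed <- seed + 7919L * (r - 1L)
    set.seed(rerun_seed)
    # cyclic dealing over the shuffled classes: folds get equal sizes and
    # each class is spread as evenly as integer arithmetic allows
    ord <- c(sample(which(y == 1L)), sample(which(y == 0L)))
    folds <- integer(length(y))
    folds[ord] <- rep_len(seq_len(k), length(y))
    fold_counts <- matrix(0L, nrow = k, ncol = 4L,
                          dimnames = list(NULL, c("TP", "FN", "TN", "FP")))
    for (f in seq_len(k)) {
      hold <- folds == f
      clf <- train_classifier(algorithm, X[!hold, , drop = FALSE], y[!hold],
                              params = params, seed = rerun_seed + f,
                              boundary_kind = boundary_kind)
      dv <- decision_value(clf, X[hold, , drop = FALSE])
      fold_counts[f, ] <- confusion_counts(y[hold], dv >= 0.5)
    }
    pooled <- colSums(fold_counts)
    if (r == 1L) first_counts <- pooled
    per_rerun[r, ] <- if (pooling == "pooled") {
      boundary_metrics(pooled)
    } else {
      rowMeans(apply(fold_counts, 1L, boundary_metrics))
    }
  }
  list(metrics = colMeans(per_rerun),
       sd = apply(per_rerun, 2L, stats::sd),
       per_rerun = per_rerun,
       counts = first_counts,
       k = k, reruns = reruns, pooling = pooling)
}

#' Exact boundary accuracy of the full pipeline on annotated sequences
#'
#' Runs [predict_ma()] on every sequence that has both boundaries annotated
#' and counts a sequence as exact only when the predicted (start, end) pair
#' equals the annotation.  Per-sequence signed deviations are reported per
#' boundary; a sequence with no prediction counts as not exact with `NA`
#' deviations.
#'
#' @param corpus Annotated corpus (both boundaries required per sequence).
#' @param bundle Trained `ma_bundle`.
#' @return List with `n_exact`, `n_total`, `fraction`, and `deviations`
#'   (data frame: `id`, `true_start`, `true_end`, `pred_start`, `pred_end`,
#'   `init_dev`, `term_dev`, `exact`, `predicted`).
#' @export
exact_boundary_accuracy <- function(corpus, bundle) {
  sub <- corpus[!is.na(corpus$ma_start) & !is.na(corpus$ma_end), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no sequences with both boundaries annotated")
  rows <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    pred <- predict_ma(sub$residues[i], bundle, id = sub$id[i])
    if (is.null(pred)) {
      rows[[i]] <- data.frame(id = sub$id[i],
                              true_start = sub$ma_start[i], true_end = sub$ma_end[i],
                              pred_start = NA_integer_, pred_end = NA_integer_,
                              init_dev = NA_integer_, term_dev = NA_integer_,
                              exact = FALSE, predicted = FALSE,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(id = sub$id[i],
                              true_start = sub$ma_start[i], true_end = sub$ma_end[i],
                              pred_start = pred$ma_start, pred_end = pred$ma_end,
                              init_dev = pred$ma_start - sub$ma_start[i],
                              term_dev = pred$ma_end - sub$ma_end[i],
                              exact = pred$ma_start == sub$ma_start[i] &&
                                pred$ma_end == sub$ma_end[i],
                              predicted = TRUE,
                              stringsAsFactors = FALSE)
    }
  }
  dev <- do.call(rbind, rows)
  list(n_exact = sum(dev$exact), n_total = nrow(dev),
       fraction = sum(dev$exact) / nrow(dev), deviations = dev)
}

#' Cross-validation report over algorithms and boundary kinds
#'
#' Convenience wrapper producing one row per (boundary kind, algorithm)
#' combination with the five standard metrics, the shape of a model
#' comparison table.
#'
#' @param corpus Annotated corpus.
#' @param algorithms Character vector of algorithms to compare.
#' @param boundary_kinds Character vector of boundary kinds.
#' @param k,reruns,seed,ratio,scale_table Forwarded to the harness.
#' @return Data frame with columns `boundary_kind`, `algorithm`, `Sn`, `Sp`,
#'   `ACC`, `MCC`, `G_mean`, `k`, `reruns`.
#' @export
cv_report <- function(corpus, algorithms = c("wsvm", "welm", "rf"),
                      boundary_kinds = c("initiation", "termination"),
                      k = 5L, reruns = 1L, seed = 1L, ratio = 5L,
                      scale_table = default_scale_table()) {
  rows <- list()
  for (kind in boundary_kinds) {
    ts <- build_training_set(corpus, kind, ratio = ratio, seed = seed,
                             scale_table = scale_table)
    for (alg in algorithms) {
      cv <- kfold_cv(ts$X, ts$y, alg, k = k, reruns = reruns, seed = seed,
                     boundary_kind = kind)
      rows[[length(rows) + 1L]] <-
        data.frame(boundary_kind = kind, algorithm = alg,
                   t(cv$metrics), k = k, reruns = reruns,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
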