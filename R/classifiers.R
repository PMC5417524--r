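#' Default hyperparameters per algorithm and boundary kind
#'
#' Reads the shipped configuration table
#' (`inst/extdata/default_hyperparams.tsv`), the grid-search optima used as
#' package defaults: WSVM `cost`/`gamma` 0.1895/0.0625 (initiation) and
#' 0.5743/0.1895 (termination); WELM 2000 hidden neurons / C = 9300
#' (initiation) and 1600 / 5100 (termination); random forest 160 trees /
#' mtry 80 (initiation) and 140 / 50 (termination).
#'
#' @param algorithm `"wsvm"`, `"welm"` or `"rf"`.
#' @param boundary_kind `"initiation"` or `"termination"`.
#' @return Named list of hyperparameter values.
#' @export
default_hyperparams <- function(algorithm = c("wsvm", "welm", "rf"),
                                boundary_kind = c("initiation", "termination")) {
  algorithm <- match.arg(algorithm)
  boundary_kind <- match.arg(boundary_kind)
  path <- system.file("extdata", "default_hyperparams.tsv", package = "mascan",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sub <- tab[tab$algorithm == algorithm & tab$boundary_kind == boundary_kind, ]
  as.list(stats::setNames(sub$value, sub$parameter))
}

#' Train a boundary-window classifier
#'
#' Uniform entry point for the three imbalance-aware binary classifiers.
#' `wsvm` is an RBF-kernel support vector machine (libsvm via e1071) with
#' per-class weights inversely proportional to class frequency and a
#' Platt-calibrated decision value; `welm` is a weighted extreme learning
#' machine solved in closed form; `rf` is a random forest whose decision
#' value is the fraction of trees voting positive.
#'
#' @param algorithm `"wsvm"`, `"welm"` or `"rf"`.
#' @param X Numeric feature matrix (n x p; p = 165 for the full feature
#'   space).
#' @param y Binary labels: 0/1 vector (1 = positive) or a logical vector.
#' @param params Named list of hyperparameters; missing entries fall back to
#'   [default_hyperparams()] for the given `boundary_kind`.
#' @param seed Integer seed driving the random forest bootstrap, the WELM
#'   input layer and the WSVM calibration folds.
#' @param boundary_kind Used only to pick default hyperparameters.
#' @return An `ma_classifier` object.
#' @export
train_classifier <- function(algorithm = c("wsvm", "welm", "rf"), X, y,
                             params = NULL, seed = 1L,
                             boundary_kind = c("initiation", "termination")) {
  algorithm <- match.arg(algorithm)
  boundary_kind <- match.arg(boundary_kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  defaults <- default_hyperparams(algorithm, boundary_kind)
  params <- utils::modifyList(defaults, as.list(params %||% list()))
  fit <- switch(algorithm,
                wsvm = train_wsvm(X, y, params, seed),
                welm = train_welm(X, y,
                                  L = params$n_hidden, C = params$C,
                                  weight_scheme = params$weight_scheme %||% "W1",
                                  seed = seed),
                rf = train_rf(X, y, params, seed))
  fit$params <- params
  fit$seed <- seed
  fit$dim <- ncol(X)
  fit
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
train_rf <- function(X, y, params, seed) {
  mtry <- min(as.integer(params$mtry), ncol(X))
  set.seed(seed)
  model <- randomForest::randomForest(
    x = X, y = factor(y, levels = c(0L, 1L), labels = c("neg", "pos")),
    ntree = as.integer(params$n_trees), mtry = mtry)
  structure(list(algorithm = "rf", model = model), class = "ma_classifier")
}

#' @keywords internal
train_wsvm <- function(X, y, params, seed) {
  yf <- factor(y, levels = c(0L, 1L), labels = c("neg", "pos"))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  weights <- c(neg = 1, pos = n_neg / n_pos)
  # libsvm practice: min-max scale every feature to [0,1] (stored and
  # reapplied at prediction time) so the RBF kernel width is comparable
  # across features and data sets
  mins <- apply(X, 2L, min)
  ranges <- apply(X, 2L, max) - mins
  ranges[ranges == 0] <- 1
  X <- sweep(sweep(X, 2L, mins, "-"), 2L, ranges, "/")
  fit_svm <- function(Xs, ys) {
    e1071::svm(x = Xs, y = ys, kernel = "radial",
               cost = params$cost, gamma = params$gamma,
               class.weights = weights, scale = FALSE)
  }
  model <- fit_svm(X, yf)
  # Platt calibration on cross-validated margins: margins of held-out points
  # reflect generalization, so the calibrated probability is honest for new
  # windows rather than for memorized training points.
  k <- min(5L, n_pos, n_neg)
  margins <- rep(NA_real_, length(y))
  if (k >= 2L) {
    set.seed(seed)
    folds <- integer(length(y))
    folds[y == 1L] <- sample(rep_len(seq_len(k), n_pos))
    folds[y == 0L] <- sample(rep_len(seq_len(k), n_neg))
    for (f in seq_len(k)) {
      hold <- folds == f
      sub <- fit_svm(X[!hold, , drop = FALSE], yf[!hold])
      margins[hold] <- svm_margin(sub, X[hold, , drop = FALSE])
    }
  } else {
    margins <- svm_margin(model, X)
  }
  platt <- suppressWarnings(
    stats::glm(y ~ m, family = stats::binomial(),
               data = data.frame(y = y, m = margins)))
  structure(list(algorithm = "wsvm", model = model,
                 platt = stats::coef(platt),
                 scaling = list(mins = mins, ranges = ranges)),
            class = "ma_classifier")
}

# signed SVM margin, positive = "pos" class
#' @keywords internal
svm_margin <- function(model, X) {
  pred <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sign <- if (strsplit(colnames(dv)[1L], "/")[[1]][1L] == "pos") 1 else -1
  sign * as.numeric(dv[, 1L])
}

#' Train a weighted extreme learning machine
#'
#' Single hidden layer with random input weights and biases uniform in
#' [-1, 1] (seeded) and sigmoid activation.  Output weights are solved in
#' closed form, `beta = (I/C + H' S H)^{-1} H' S t`, with a diagonal sample
#' weight matrix `S`: under the default `"W1"` scheme every sample of class
#' `c` gets weight `1 / n_c`, so both classes carry equal total weight
#' regardless of imbalance; `"W2"` down-weights the majority class to
#' `0.618 / n_c`.  Targets are coded -1/+1 and the decision value is the
#' logistic squash of the network output.
#'
#' @param X Feature matrix (n x p).
#' @param y 0/1 labels.
#' @param L Number of hidden neurons.
#' @param C Regularization constant (> 0).
#' @param weight_scheme `"W1"` (default) or `"W2"`.
#' @param seed Integer seed for the random input layer.
#' @return An `ma_classifier`.
#' @export
train_welm <- function(X, y, L, C, weight_scheme = c("W1", "W2"), seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  X <- as.matrix(X)
  y <- as.integer(y)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (C <= 0) stop("C must be > 0")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  p <- ncol(X)
  set.seed(seed)
  W <- matrix(stats::runif(p * L, -1, 1), nrow = p, ncol = L)
  b <- stats::runif(L, -1, 1)
  H <- stats::plogis(sweep(X %*% W, 2L, b, "+"))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  w <- ifelse(y == 1L, 1 / n_pos, 1 / n_neg)
  if (weight_scheme == "W2") {
    maj <- if (n_neg >= n_pos) 0L else 1L
    w[y == maj] <- 0.618 / if (maj == 0L) n_neg else n_pos
  }
  t_target <- ifelse(y == 1L, 1, -1)
  A <- diag(L) / C + crossprod(H, w * H)
  beta <- solve(A, crossprod(H, w * t_target))
  structure(list(algorithm = "welm", model = list(W = W, b = b, beta = beta),
                 weight_scheme = weight_scheme),
            class = "ma_classifier")
}

#' Decision values of a trained classifier
#'
#' Returns a score in [0, 1] per row of `X`: the larger the value, the more
#' likely the window is a true boundary window.  For the random forest this
#' is the fraction of trees voting positive; for the WSVM a Platt-calibrated
#' probability; for the WELM the logistic squash of the network margin.  The
#' predicted label convention everywhere in the package is
#' `decision_value >= 0.5`.
#'
#' @param clf An `ma_classifier`.
#' @param X Feature matrix (or a single feature vector).
#' @return Numeric vector in [0, 1], one value per row.
#' @export
decision_value <- function(clf, X) {
  stopifnot(inherits(clf, "ma_classifier"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (!is.null(clf$dim) && ncol(X) != clf$dim) {
    stop("feature dimension mismatch: classifier expects ", clf$dim,
         ", got ", ncol(X))
  }
  switch(clf$algorithm,
         rf = {
           votes <- stats::predict(clf$model, X, type = "vote", norm.votes = TRUE)
           unname(votes[, "pos"])
         },
         wsvm = {
           X <- sweep(sweep(X, 2L, clf$scaling$mins, "-"),
                      2L, clf$scaling$ranges, "/")
           m <- svm_margin(clf$model, X)
           unname(stats::plogis(clf$platt[1L] + clf$platt[2L] * m))
         },
         welm = {
           H <- stats::plogis(sweep(X %*% clf$model$W, 2L, clf$model$b, "+"))
           unname(stats::plogis(as.numeric(H %*% clf$model$beta)))
         },
         stop("unknown algorithm: ", clf$algorithm))
}

#' @export
print.ma_classifier <- function(x, ...) {
  cat("mascan classifier:", x$algorithm,
      if (!is.null(x$dim)) paste0("(", x$dim, " features)"), "\n")
  invisible(x)
}

#' Grid search over hyperparameters by repeated cross-validated G-mean
#'
#' For every grid point, runs `reruns` independent `k`-fold
#' cross-validations and averages the pooled G-mean.  Ties are broken toward
#' smaller parameter values (grid sorted ascending on every column, first
#' maximum wins).
#'
#' @param algorithm `"wsvm"`, `"welm"` or `"rf"`.
#' @param X,y Training data.
#' @param grid Data frame, one column per hyperparameter, one row per
#'   candidate.
#' @param k Folds (default 5).
#' @param reruns Independent CV repetitions averaged per point (default 10).
#' @param seed Integer seed.
#' @return List with `best` (named list of winning hyperparameters) and
#'   `table` (the grid with `mean_gmean` and `sd_gmean` columns).
#' @export
grid_search <- function(algorithm, X, y, grid, k = 5L, reruns = 10L, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  means <- numeric(nrow(grid))
  sds <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cv <- kfold_cv(X, y, algorithm, params = as.list(grid[i, , drop = FALSE]),
                   k = k, reruns = reruns, seed = seed)
    means[i] <- cv$metrics["G_mean"]
    sds[i] <- if (reruns > 1L) cv$sd["G_mean"] else NA_real_
  }
  best_i <- which.max(means)
  out <- grid
  out$mean_gmean <- means
  out$sd_gmean <- sds
  list(best = as.list(grid[best_i, , drop = FALSE]), table = out)
}

#' Default hyperparameter grids centered on the shipped optima
#'
#' Step sizes follow the tuning protocol shipped with the package: 0.0001
#' for the SVM cost and kernel width, 50 for the ELM hidden-layer size and
#' regularization, and 5 for the forest size and `mtry`.  Because exhaustive
#' grids at those step sizes are enormous, `span` controls how many steps
#' around the default optimum are generated.
#'
#' @param algorithm `"wsvm"`, `"welm"` or `"rf"`.
#' @param boundary_kind `"initiation"` or `"termination"`.
#' @param span Number of steps on each side of the optimum (default 2).
#' @return Data frame grid for [grid_search()].
#' @export
default_grid <- function(algorithm, boundary_kind = "initiation", span = 2L) {
  opt <- default_hyperparams(algorithm, boundary_kind)
  steps <- switch(algorithm,
                  wsvm = c(cost = 1e-4, gamma = 1e-4),
                  welm = c(n_hidden = 50, C = 50),
                  rf = c(n_trees = 5, mtry = 5))
  vals <- lapply(names(steps), function(p) {
    v <- unlist(opt[p]) + steps[p] * (-span:span)
    v[v > 0]
  })
  names(vals) <- names(steps)
  expand.grid(vals)
}
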