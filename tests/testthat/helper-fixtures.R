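# Shared fixtures, built in code so correctness never depends on shipped data.

# deterministic 10 x 20 scale table with varied integer values
fixture_scale_table <- function() {
  m <- outer(1:10, 1:20, function(i, j) ((i * 7 + j * 3) %% 11) - 5)
  dimnames(m) <- list(paste0("s", 1:10), AA_ALPHABET)
  storage.mode(m) <- "double"
  m
}

# constant-valued table (every scale identically `value`)
constant_scale_table <- function(value = 1) {
  m <- matrix(value, nrow = 10, ncol = 20,
              dimnames = list(paste0("s", 1:10), AA_ALPHABET))
  m
}

random_windows <- function(n, s = 15L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(AA_ALPHABET, s, replace = TRUE), collapse = ""),
         "")
}

# linearly separable 165-dim toy set: two informative dimensions, the rest
# low-variance noise
toy_separable <- function(n = 20L, seed = 42L, imbalance = FALSE) {
  set.seed(seed)
  y <- if (imbalance) rep(c(1L, 0L), c(n %/% 6, n - n %/% 6)) else
    rep(c(0L, 1L), each = n %/% 2)
  X <- matrix(stats::rnorm(length(y) * 165, sd = 0.1), length(y), 165)
  X[, 1] <- ifelse(y == 1L, 3, -3) + stats::rnorm(length(y), sd = 0.1)
  X[, 2] <- ifelse(y == 1L, -2, 2) + stats::rnorm(length(y), sd = 0.1)
  list(X = X, y = y)
}

toy_params <- function(algorithm) {
  switch(algorithm,
         wsvm = list(cost = 10, gamma = 0.05),
         welm = list(n_hidden = 50, C = 100),
         rf = list(n_trees = 100, mtry = 20))
}

# one small trained bundle shared across test files (expensive to train)
.fixture_cache <- new.env(parent = emptyenv())

fixture_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <-
      generate_corpus(corpus_spec(40, conservation = 0.95, seed = 7))
  }
  .fixture_cache$corpus
}

fixture_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <-
      suppressWarnings(train_model_bundle(fixture_corpus(), seed = 3))
  }
  .fixture_cache$bundle
}
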