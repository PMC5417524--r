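# Fixed 15-residue consensus motifs planted at the two MA boundaries of
# every synthetic sequence.  Arbitrary but constant, so the PWM implied by
# the generator is analytically known.
MOTIF_INIT_CONSENSUS <- "MGQTVTTPLSLTLDH"
MOTIF_TERM_CONSENSUS <- "WVKQCFRCGKEGHFA"

#' Specification of a synthetic gag-like corpus
#'
#' Bundles the generator parameters with validation.  Sequence lengths and
#' MA lengths are drawn uniformly from their ranges; the MA interval is
#' placed uniformly within the sequence; the 15 residues at each boundary
#' follow a consensus-with-noise motif model: each position emits the
#' consensus residue with probability `conservation`, otherwise a uniform
#' residue from the 20-letter alphabet.  All other residues come from the
#' background distribution.
#'
#' @param n_sequences Number of sequences.
#' @param seq_len Length-2 integer range of sequence lengths (default
#'   c(300, 700)).
#' @param ma_len Length-2 integer range of MA lengths (default c(88, 127),
#'   the canonical range).
#' @param conservation Per-position consensus probability in [0, 1]
#'   (default 0.9).
#' @param background Length-20 probability vector over [AA_ALPHABET]
#'   (default uniform).
#' @param motif_init,motif_term 15-residue consensus strings.
#' @param seed Integer seed.
#' @return A validated `ma_corpus_spec` list.
#' @export
corpus_spec <- function(n_sequences, seq_len = c(300L, 700L),
                        ma_len = c(88L, 127L), conservation = 0.9,
                        background = rep(1 / 20, 20),
                        motif_init = MOTIF_INIT_CONSENSUS,
                        motif_term = MOTIF_TERM_CONSENSUS, seed = 1L) {
  stopifnot(n_sequences >= 0L, length(seq_len) == 2L, length(ma_len) == 2L,
            seq_len[1] <= seq_len[2], ma_len[1] <= ma_len[2])
  if (conservation < 0 || conservation > 1) {
    stop("conservation must be within [0, 1]")
  }
  if (length(background) != 20L || any(background < 0)) {
    stop("background must be 20 non-negative probabilities")
  }
  stopifnot(nchar(motif_init) == 15L, nchar(motif_term) == 15L)
  if (seq_len[1] < ma_len[2]) {
    stop("minimum sequence length (", seq_len[1],
         ") too small to host an MA of up to ", ma_len[2], " residues")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_len = as.integer(seq_len), ma_len = as.integer(ma_len),
                 conservation = conservation,
                 background = background / sum(background),
                 motif_init = motif_init, motif_term = motif_term,
                 seed = as.integer(seed)),
            class = "ma_corpus_spec")
}

#' Generate a synthetic annotated gag-like corpus
#'
#' Every sequence carries exactly one MA interval with both boundaries
#' annotated; the 15 residues starting at `ma_start` and the 15 residues
#' ending at `ma_end` are drawn from the two conserved boundary motifs.
#' Fully reproducible under the spec's seed.
#'
#' @param spec An `ma_corpus_spec` from [corpus_spec()].
#' @return Annotated corpus data frame in the [read_fasta()] layout.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "ma_corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_sequences
  out <- data.frame(id = sprintf("synth%04d", seq_len(n)),
                    residues = character(n),
                    ma_start = integer(n), ma_end = integer(n),
                    nonstandard = rep(FALSE, n), stringsAsFactors = FALSE)
  init_cons <- strsplit(spec$motif_init, "")[[1]]
  term_cons <- strsplit(spec$motif_term, "")[[1]]
  for (i in seq_len(n)) {
    L <- sample(spec$seq_len[1]:spec$seq_len[2], 1L)
    ma_len <- sample(spec$ma_len[1]:spec$ma_len[2], 1L)
    ma_start <- sample.int(L - ma_len + 1L, 1L)
    ma_end <- ma_start + ma_len - 1L
    chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = spec$background)
    chars[ma_start:(ma_start + 14L)] <-
      emit_motif(init_cons, spec$conservation)
    chars[(ma_end - 14L):ma_end] <-
      emit_motif(term_cons, spec$conservation)
    out$residues[i] <- paste(chars, collapse = "")
    out$ma_start[i] <- ma_start
    out$ma_end[i] <- ma_end
  }
  out
}

#' @keywords internal
emit_motif <- function(consensus, conservation) {
  use_cons <- stats::runif(length(consensus)) < conservation
  chars <- sample(AA_ALPHABET, length(consensus), replace = TRUE)
  chars[use_cons] <- consensus[use_cons]
  chars
}

#' Generate a background-only null corpus
#'
#' Sequences with no planted motif and no MA annotation, for measuring the
#' false-positive rate of the full pipeline.
#'
#' @param spec An `ma_corpus_spec`; only the length range, background and
#'   seed are used.
#' @return Corpus data frame with `ma_start` / `ma_end` all `NA`.
#' @export
generate_null_corpus <- function(spec) {
  stopifnot(inherits(spec, "ma_corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_sequences
  out <- data.frame(id = sprintf("null%04d", seq_len(n)),
                    residues = character(n),
                    ma_start = rep(NA_integer_, n), ma_end = rep(NA_integer_, n),
                    nonstandard = rep(FALSE, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- sample(spec$seq_len[1]:spec$seq_len[2], 1L)
    out$residues[i] <- paste(sample(AA_ALPHABET, L, replace = TRUE,
                                    prob = spec$background), collapse = "")
  }
  out
}
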