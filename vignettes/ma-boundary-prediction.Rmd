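---
title: "Predicting matrix-protein boundaries in gag: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting matrix-protein boundaries in gag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the divide-and-conquer model

The matrix protein (MA) is the N-terminal product of the retroviral `gag`
polyprotein. Its length in annotated endogenous-retrovirus (ERV) records
varies between 88 and 127 residues, which rules out any classifier over a
fixed-dimension representation of the whole protein. `mascan` therefore
splits the task into two *fixed-length* classification problems — is this
15-residue window the start of an MA? is it the end? — and recombines the
two answer sets under the length constraint. The working assumptions are:

* the residues immediately at each MA boundary are conserved enough to
  support window classification (gag processing sites are, within a genus);
* each gag contains at most one canonical MA, so a single best boundary
  pair per sequence is the correct output granularity;
* the admissible MA length range is known a priori (88–127 residues,
  configurable via `min_ma_len` / `max_ma_len`).

Non-canonical MAs (e.g. HERV-L-like gags) violate the first assumption and
are out of scope.

## Feature space

Every 15-residue window maps to 165 = (1 + 10) × 15 features.

**Position features (15).** A position frequency matrix is counted over the
positive windows only, converted to probabilities, and log-ratio-transformed
against the uniform background $b_k = 1/20$:
$M^{PWM}_{k,j} = \log\!\big(M^{PPM}_{k,j} / b_k\big)$. Feature $j$ of a
window is the PWM score of its residue at position $j$. Natural logarithm is
used and recorded in the `ma_pwm` object (`log_base = "natural"`); any fixed
base only rescales features monotonically, so the choice cannot affect
tree-based models and affects kernel models only through the kernel width.

**Physicochemical features (150).** Ten per-residue property scales — four
electronic (net side-chain charge, isoelectric point, polarity,
polarizability), two steric (residue volume in Å³, bulkiness), two
hydrophobic (Kyte–Doolittle hydropathy, consensus hydrophobicity) and two
hydrogen-bond (side-chain donor and acceptor counts) — are applied
position-wise and flattened scale-major. The shipped default table
(`inst/extdata/aa_scales_default.tsv`) assembles published scales matching
those property classes; `default_scale_table()` standardizes each scale to
mean 0 / sd 1 across the 20 amino acids so that volume (tens of Å³) cannot
dominate charge (±1) in kernel distances. Any 10 × 20 table with the same
schema can be substituted (`read_scale_table()`), and the test suite uses
synthetic fixture tables throughout, so package correctness is independent
of the default table's provenance.

## Numerical choices

* **Zero-probability PWM cells.** With few positives, most of the 20 × 15
  cells are unobserved and the log-ratio is $-\infty$. The default is a
  Laplace pseudocount ($\alpha = 1$) at the probability stage; a strict
  mode ($\alpha = 0$) with a finite score floor of −10 is available. Both
  choices keep every feature finite, which the classifiers require.
* **WSVM decision values.** Raw SVM margins are unbounded; the contract
  requires a score in [0, 1]. Margins are calibrated with a logistic
  (Platt) fit on *cross-validated* margins (internal 5-fold split of the
  training set, seeded): calibrating on resubstitution margins would
  produce overconfident probabilities for training-like windows and useless
  ones for new windows.
* **WSVM feature scaling.** Inside the SVM wrapper each feature is min-max
  scaled to [0, 1] (parameters stored in the model and reapplied at
  prediction). This is the standard libsvm preprocessing; without it the
  RBF kernel at practical values of $\gamma$ collapses on 165-dimensional
  inputs (all off-diagonal kernel entries ≈ 0) and the model cannot rank
  unseen windows. Tree ensembles and the ELM operate on the unscaled
  features.
* **Class weighting.** WSVM: per-class weights inversely proportional to
  class frequency (the 1:5 design gives the positive class weight 5). WELM:
  the `"W1"` scheme (every sample weighted $1/n_{class}$, equal total class
  weight) by default; `"W2"` (0.618 on the majority class) is available.
* **WELM internals.** Single hidden layer, input weights and biases uniform
  in [−1, 1] (seeded), sigmoid activation, output weights in closed form
  $\beta = (I/C + H^{\mathsf T} S H)^{-1} H^{\mathsf T} S t$ with targets
  ±1; the decision value is the logistic squash of the network output.
* **MCC convention.** When the MCC denominator vanishes (a degenerate
  confusion table) the statistic is defined as 0, keeping grid search total.
* **Cross-validation folds.** Folds are stratified by cyclic dealing over
  the independently shuffled classes: fold sizes are equal, the class ratio
  is preserved to integer precision, and the jack-knife limit $k = n$
  still partitions correctly. Per-fold confusion counts are pooled before
  metrics are computed (`pooling = "pooled"`); averaging per-fold metrics is
  available but undefined beyond $k$ = smallest class size.
* **Thresholds and tie-breaks.** Site calls and the WSVM veto use decision
  value ≥ 0.5 (majority vote for the forest); both thresholds are exposed.
  Equal product scores in the final selection break toward the smaller
  `ma_start`, then the smaller `ma_end` — the selection is therefore
  invariant to the order in which candidate pairs are enumerated.

## Coordinates

External files (FASTA annotation tables, predictions, GFF3) use 1-based
inclusive coordinates, as biologists write them, and the same convention is
kept internally: a window starting at position $w$ covers residues
$w \ldots w+14$; a positive termination window *ends* at `ma_end`, so a
termination call at window start $w$ implies `ma_end` $= w + 14$. Keeping a
single 1-based convention (rather than a 0-based internal layer) matches R
indexing and removes a conversion boundary where off-by-one errors breed;
the slicing contracts are pinned by fixture tests.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `s` (window length) | 15 residues | boundary window seen by all classifiers |
| `neg_ratio` | 5 | negatives sampled per positive |
| `min_ma_len`, `max_ma_len` | 88, 127 residues | admissible MA length (inclusive) |
| `pseudocount` | 1 | PPM smoothing |
| WSVM `cost`, `gamma` | 0.1895 / 0.0625 (init), 0.5743 / 0.1895 (term) | RBF SVM hyperparameters |
| WELM `n_hidden`, `C` | 2000 / 9300 (init), 1600 / 5100 (term) | hidden neurons, regularization |
| RF `n_trees`, `mtry` | 160 / 80 (init), 140 / 50 (term) | forest size, features per split |
| `rf_threshold`, `wsvm_threshold` | 0.5 | call and veto thresholds |

The per-boundary-kind optima ship as a config table
(`inst/extdata/default_hyperparams.tsv`) read by `default_hyperparams()`;
`grid_search()` re-tunes any algorithm by mean G-mean over repeated
stratified CV, with ties broken toward smaller parameter values. The
documented step sizes (0.0001 for `cost`/`gamma`, 50 for the ELM
parameters, 5 for the forest parameters) are encoded in `default_grid()`,
which spans a window of steps around the shipped optimum rather than an
exhaustive range.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces gag-like sequences (uniform lengths 300–700
residues) each carrying exactly one MA of uniform length 88–127, with two
fixed 15-residue consensus motifs planted at the boundaries under a
consensus-with-noise model: each motif position emits the consensus residue
with probability `conservation` (default 0.9), otherwise a uniform residue.
The background is i.i.d. uniform over the 20 amino acids.
`generate_null_corpus()` drops the MA and the motifs. This is the simplest
generator whose implied PWM is analytically known (at `conservation = 1`
the positive-window PPM has exactly one unit cell per column, which the
tests exploit).

Real gag corpora differ in ways the generator deliberately ignores:
phylogenetic correlation between sequences (training and test windows can
be near-duplicates), compositional bias, indels and frameshifts, and
boundary motifs whose information content varies by position. Passing the
synthetic-recovery tests therefore demonstrates that the pipeline is
implemented correctly and can recover boundaries whose conservation is
comparable to the planted regime — it does not certify the reported
cross-validation numbers on any particular curated corpus.

Problem sizes in the shipped experiments were chosen to make the recovery
question statistically meaningful while staying at desk scale: 150 training
sequences (900 windows per boundary kind after 1:5 negative sampling), 50
held-out sequences for exact-boundary recovery, and a 100-sequence null
corpus for the false-positive count; the conservation sweep in the test
suite uses smaller corpora (30 training / 12 held-out per level).

## Open design decisions

* **Negative pool.** Negatives are drawn uniformly *pooled across the
  corpus* from all windows whose start is not a positive start for that
  boundary kind; no minimum distance from the true site is imposed
  (`min_distance = 0`), so hard negatives one residue away from a boundary
  are allowed. A per-sequence quota and a distance knob exist but are not
  the default.
* **DNA input.** The scanning protocol for coding-region DNA is six-frame
  translation with stop-codon segmentation; each segment is scanned
  independently and hits are mapped back to input-sequence nucleotide
  coordinates (minus-strand hits report the region whose reverse complement
  encodes the protein). Protein input is the reference path.
* **Model persistence.** Bundles are saved with `saveRDS()` plus an
  explicit `format_version`; loading a bundle reproduces bit-identical
  decision values, and saving refuses a bundle missing any of the four
  classifiers or either PWM.

## Known limitations

* One prediction per sequence by design; tandem or nested MAs are not
  reported.
* Windows containing non-standard residues (B, J, O, U, X, Z, stops) are
  skipped during scanning and rejected during training; a boundary inside
  such a window cannot be found.
* The WELM is provided for model comparison; the shipped pairing rule uses
  only the forest (candidate) and WSVM (veto) models.
* Decision-value calibration is logistic and monotone; the *ranking* of
  candidate pairs is robust, but the absolute probabilities inherit the
  usual Platt-scaling approximation error.
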