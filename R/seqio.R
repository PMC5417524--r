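#' Read a protein FASTA file into an annotated corpus
#'
#' Returns one row per record with empty MA annotation columns; coordinates
#' are attached later by [read_annotations()].  Residues are uppercased.
#' Records containing letters outside the 20-letter standard alphabet
#' (B, J, O, U, X, Z, `*`, ...) are retained but flagged in the
#' `nonstandard` column.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `residues`, `ma_start`, `ma_end`
#'   (integer, `NA` when unannotated) and `nonstandard` (logical).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  res <- toupper(as.character(set))
  data.frame(id = ids,
             residues = unname(res),
             ma_start = NA_integer_,
             ma_end = NA_integer_,
             nonstandard = grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), res),
             stringsAsFactors = FALSE)
}

#' Write a corpus to FASTA
#'
#' @param corpus Data frame with `id` and `residues` columns.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(corpus, path, width = 70L) {
  stopifnot(is.data.frame(corpus), all(c("id", "residues") %in% names(corpus)))
  set <- Biostrings::AAStringSet(stats::setNames(corpus$residues, corpus$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Attach MA boundary annotations to a corpus
#'
#' Reads a tab-separated table with header columns `id`, `ma_start`,
#' `ma_end`.  Coordinates are 1-based inclusive; an empty `ma_end` cell
#' marks a record annotated with an initiation site only.  Every table row
#' must match a FASTA record.  An annotated MA length outside the canonical
#' 88-127 range triggers a warning, never a drop: the record is kept as-is.
#'
#' @param path Path to the TSV annotation table.
#' @param corpus Corpus data frame from [read_fasta()].
#' @param min_ma_len,max_ma_len Range used for the length warning.
#' @return The corpus with `ma_start` / `ma_end` filled for annotated rows.
#' @export
read_annotations <- function(path, corpus, min_ma_len = 88L, max_ma_len = 127L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = c(id = "character"))
  need <- c("id", "ma_start", "ma_end")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  missing_ids <- setdiff(tab$id, corpus$id)
  if (length(missing_ids) > 0L) {
    stop("annotated id(s) absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  }
  if (anyNA(tab$ma_start)) stop("ma_start is required for every annotated row")
  if (any(tab$ma_start < 1L)) {
    stop("coordinates are 1-based: ma_start must be >= 1")
  }
  row <- match(tab$id, corpus$id)
  len <- nchar(corpus$residues[row])
  if (any(!is.na(tab$ma_end) & tab$ma_start > tab$ma_end)) {
    stop("ma_start > ma_end for id(s): ",
         paste(tab$id[!is.na(tab$ma_end) & tab$ma_start > tab$ma_end],
               collapse = ", "))
  }
  if (any(!is.na(tab$ma_end) & tab$ma_end > len)) {
    stop("ma_end beyond sequence length for id(s): ",
         paste(tab$id[!is.na(tab$ma_end) & tab$ma_end > len], collapse = ", "))
  }
  if (any(tab$ma_start > len)) {
    stop("ma_start beyond sequence length for id(s): ",
         paste(tab$id[tab$ma_start > len], collapse = ", "))
  }
  ma_len <- tab$ma_end - tab$ma_start + 1L
  off <- !is.na(ma_len) & (ma_len < min_ma_len | ma_len > max_ma_len)
  if (any(off)) {
    warning("annotated MA length outside [", min_ma_len, ", ", max_ma_len,
            "] for id(s): ", paste(tab$id[off], collapse = ", "),
            " (kept as-is)")
  }
  corpus$ma_start[row] <- as.integer(tab$ma_start)
  corpus$ma_end[row] <- as.integer(tab$ma_end)
  corpus
}

#' Write the annotation table of a corpus
#'
#' @param corpus Corpus data frame.
#' @param path Output TSV path; `NA` coordinates become empty cells.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(corpus, path) {
  ann <- corpus[!is.na(corpus$ma_start), c("id", "ma_start", "ma_end")]
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @keywords internal
validate_scale_table <- function(scale_table) {
  if (!is.matrix(scale_table) || !is.numeric(scale_table)) {
    stop("scale table must be a numeric matrix")
  }
  if (nrow(scale_table) != 10L) {
    stop("scale table must have exactly 10 scales (rows), got ",
         nrow(scale_table), "; expected 10 x 20")
  }
  if (ncol(scale_table) != 20L || !identical(colnames(scale_table), AA_ALPHABET)) {
    missing <- setdiff(AA_ALPHABET, colnames(scale_table))
    stop("scale table must have one column per standard amino acid",
         if (length(missing) > 0L) paste0(" (missing: ",
                                          paste(missing, collapse = ", "), ")"),
         "; expected 10 x 20")
  }
  if (anyNA(scale_table)) stop("scale table contains missing values")
  invisible(scale_table)
}

#' Read a 10-scale physicochemical property table
#'
#' Expects a TSV with a `scale` column naming each of the 10 property scales
#' and one numeric column per standard amino acid (any column order).
#' Columns are reordered to the fixed [AA_ALPHABET] order.
#'
#' @param path Path to the TSV table.
#' @return 10 x 20 numeric matrix, rownames = scale names, colnames =
#'   [AA_ALPHABET].
#' @export
read_scale_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"scale" %in% names(tab)) stop("scale table needs a 'scale' column")
  m <- as.matrix(tab[, setdiff(names(tab), "scale"), drop = FALSE])
  rownames(m) <- tab$scale
  if (!all(AA_ALPHABET %in% colnames(m))) {
    stop("scale table missing column(s) for: ",
         paste(setdiff(AA_ALPHABET, colnames(m)), collapse = ", "),
         "; expected 10 x 20")
  }
  m <- m[, AA_ALPHABET, drop = FALSE]
  storage.mode(m) <- "double"
  validate_scale_table(m)
  m
}

#' The default physicochemical scale table
#'
#' Ten published per-residue property scales covering the four property
#' classes the feature space requires: four electronic (net charge,
#' isoelectric point, polarity, polarizability), two steric (residue volume,
#' bulkiness), two hydrophobic (Kyte-Doolittle hydropathy, Eisenberg
#' consensus hydrophobicity) and two hydrogen-bond (side-chain donor and
#' acceptor counts).  Each scale is standardized to mean 0 / sd 1 across the
#' 20 amino acids so no single property dominates kernel distances.
#'
#' @param standardize Standardize each scale across the 20 residues
#'   (default `TRUE`).
#' @return 10 x 20 numeric matrix.
#' @export
default_scale_table <- function(standardize = TRUE) {
  path <- system.file("extdata", "aa_scales_default.tsv", package = "mascan",
                      mustWork = TRUE)
  m <- read_scale_table(path)
  if (standardize) {
    m <- t(scale(t(m)))
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

BUNDLE_FORMAT_VERSION <- "1.0"

#' Persist a trained model bundle
#'
#' Refuses to write an incomplete bundle: the boundary-pairing rule needs
#' both random-forest and both weighted-SVM models plus both PWMs and the
#' scale table.  Reloading a saved bundle reproduces bit-identical decision
#' values on any input window.
#'
#' @param bundle An `ma_bundle` from [train_model_bundle()].
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "ma_bundle"))
  required <- c("pwm_init", "pwm_term", "scale_table",
                "rf_init", "rf_term", "wsvm_init", "wsvm_term")
  missing <- required[vapply(required, function(f) is.null(bundle[[f]]), logical(1))]
  if (length(missing) > 0L) {
    stop("refusing to save incomplete bundle; missing: ",
         paste(missing, collapse = ", "))
  }
  if (bundle$min_ma_len > bundle$max_ma_len) stop("min_ma_len > max_ma_len")
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model bundle saved by [save_bundle()]
#'
#' @param path Path to the saved bundle.
#' @return An `ma_bundle` object.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bundle <- tryCatch(readRDS(path),
                     error = function(e) stop("cannot read bundle (truncated or not a bundle): ",
                                              conditionMessage(e)))
  if (!inherits(bundle, "ma_bundle")) stop("not a mascan model bundle: ", path)
  if (!identical(bundle$format_version, BUNDLE_FORMAT_VERSION)) {
    stop("bundle format version mismatch: file has '",
         bundle$format_version, "', this package reads '",
         BUNDLE_FORMAT_VERSION, "'")
  }
  bundle
}
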