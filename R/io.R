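#' Extract a centered sequence window around a phosphosite
#'
#' Returns the `width` amino acids centered on `position` in
#' `protein_sequence`. Positions beyond either terminus are padded with
#' `'_'`, following the MaxQuant sequence-window convention, so the window
#' always has exactly `width` characters with the phosphorylated residue at
#' the center.
#'
#' @param protein_sequence Single amino-acid string.
#' @param position Integer vector of 1-based residue indices.
#' @param width Odd window width (default 13).
#' @return Character vector of windows, one per position.
#' @examples
#' extract_window("MKKS", 1)          # "______MKKS___"
#' extract_window("MKRRRSSTPLE", 6)   # center is the 6th residue
#' @export
extract_window <- function(protein_sequence, position, width = 13L) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  if (width %% 2L == 0L) abort("`width` must be odd.")
  n <- nchar(protein_sequence)
  if (any(position < 1L | position > n)) {
    abort(sprintf("`position` out of range 1..%d.", n))
  }
  flank <- (width - 1L) %/% 2L
  pad <- strrep("_", flank)
  padded <- paste0(pad, protein_sequence, pad)
  substr(rep(padded, length(position)), position, position + width - 1L)
}

# Column families holding log2 ratios in a site table.
ratio_column_regex <- "^(ins|mk|ly)_[0-9]+$|^tc[0-9]+_[0-9]+$"

required_site_columns <- c(
  "site_id", "protein_id", "position", "residue",
  "localization_prob", "multiplicity", "sequence_window"
)

#' Read a phosphosite quantification table
#'
#' Reads a tab-separated site table in the layout written by
#' [write_site_table()]: one row per phosphosite with identity columns
#' (`site_id`, `protein_id`, `gene_name`, `position`, `residue`,
#' `localization_prob`, `multiplicity`, `sequence_window`), per-replicate
#' inhibitor-screen ratio columns `ins_*`, `mk_*`, `ly_*`
#' (insulin/basal, insulin+Akt-inhibitor/basal, insulin+PI3K-mTOR-inhibitor/
#' basal) and time-course columns `tc<timepoint>_<replicate>`.
#'
#' Ratios are stored internally as log2 values; `ratio_scale = "linear"`
#' declares that the file holds raw (linear) ratios, which are
#' log2-transformed on read. Missing quantification is encoded as an empty
#' cell / `NA`, never as 0. Rows flagged in optional `reverse` or
#' `contaminant` columns (any non-empty value) are excluded; the exclusion
#' count is attached as attribute `"n_excluded"` and reported.
#'
#' @param path Path to a TSV file.
#' @param ratio_scale Either `"log2"` (default) or `"linear"`.
#' @return A tibble of site records.
#' @export
read_site_table <- function(path, ratio_scale = c("log2", "linear")) {
  ratio_scale <- match.arg(ratio_scale)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sites <- readr::read_tsv(path, show_col_types = FALSE,
                           na = c("", "NA", "NaN"))
  missing_cols <- setdiff(required_site_columns, names(sites))
  if (length(missing_cols) > 0) {
    abort(sprintf("Site table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(sites)
  if (nrow(probs) > 0) {
    warn(sprintf("%d cell(s) failed to parse and were set to NA.",
                 nrow(probs)))
  }
  n_excluded <- 0L
  for (flag in c("reverse", "contaminant")) {
    if (flag %in% names(sites)) {
      bad <- !is.na(sites[[flag]]) & sites[[flag]] != ""
      n_excluded <- n_excluded + sum(bad)
      sites <- sites[!bad, , drop = FALSE]
      sites[[flag]] <- NULL
    }
  }
  if (n_excluded > 0) {
    message(sprintf("Excluded %d reverse/contaminant-flagged row(s).",
                    n_excluded))
  }
  ratio_cols <- grep(ratio_column_regex, names(sites), value = TRUE)
  if (ratio_scale == "linear") {
    if (any(purrr::map_lgl(sites[ratio_cols],
                           ~ any(.x <= 0, na.rm = TRUE)))) {
      abort("Linear ratios must be positive to be log2-transformed.")
    }
    sites <- mutate(sites, across(all_of(ratio_cols), log2))
  }
  bad_res <- !sites$residue %in% c("S", "T", "Y")
  if (any(bad_res)) {
    abort(sprintf("%d row(s) have residue outside {S, T, Y}.", sum(bad_res)))
  }
  attr(sites, "n_excluded") <- n_excluded
  sites
}

#' Write a phosphosite table to TSV
#'
#' @param sites Tibble of site records (as from [simulate_phosphoproteome()]
#'   or [read_site_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into a named character vector of amino-acid
#' sequences. The identifier is the first whitespace-delimited token of each
#' header; duplicate identifiers and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, `protein_id -> sequence`.
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA identifier(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(aa)
  if (any(nchar(seqs) == 0)) abort("FASTA contains an empty sequence.")
  setNames(seqs, ids)
}

#' Write and read kinase-substrate prediction tables
#'
#' `write_predictions()` emits one row per site and kinase with the
#' normalized ensemble score, delta score, Pareto front and rank;
#' `read_predictions()` reads such a table back.
#'
#' @param predictions Tibble with columns `site_id`, `kinase`, `score`,
#'   `delta`, `front`, `rank` (additional columns are preserved).
#' @param path TSV path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, path) {
  needed <- c("site_id", "kinase", "score", "delta", "front", "rank")
  missing_cols <- setdiff(needed, names(predictions))
  if (length(missing_cols) > 0) {
    abort(sprintf("Prediction table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(predictions, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
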