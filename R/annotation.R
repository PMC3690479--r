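#' Count observable tryptic peptides of a protein
#'
#' In-silico fully tryptic digest (cleavage C-terminal to K or R, except
#' before proline, no missed cleavages), counting fragments whose length
#' falls within the observable range. This is the denominator of the iBAQ
#' abundance estimate.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param min_len,max_len Observable peptide length range, default 7-30.
#' @return Integer vector of peptide counts (0 for empty sequences).
#' @export
count_tryptic_peptides <- function(sequence, min_len = 7L, max_len = 30L) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0) return(0L)
    frags <- strsplit(s, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
    sum(nchar(frags) >= min_len & nchar(frags) <= max_len)
  }, integer(1), USE.NAMES = FALSE)
}

#' Rank proteins by iBAQ abundance and assign quartiles
#'
#' Computes iBAQ (summed peptide intensity divided by the number of
#' theoretically observable tryptic peptides), ranks proteins by descending
#' iBAQ (rank 1 = most abundant, ties broken deterministically by
#' `protein_id`) and splits the ranking into four equal-count quartiles
#' Q1 (most abundant) to Q4.
#'
#' @param proteins Tibble with `protein_id`, `summed_intensity` and either
#'   `theoretical_peptides` or a `sequence` column (digested with
#'   [count_tryptic_peptides()]).
#' @return The input with `ibaq`, `rank` and `quartile` columns, ordered by
#'   rank.
#' @export
rank_quartiles <- function(proteins) {
  if (nrow(proteins) < 4) abort("Need at least 4 proteins.")
  if (!"theoretical_peptides" %in% names(proteins)) {
    if (!"sequence" %in% names(proteins)) {
      abort("Need `theoretical_peptides` or `sequence`.")
    }
    proteins <- mutate(proteins,
      theoretical_peptides = count_tryptic_peptides(.data$sequence))
  }
  if (any(proteins$theoretical_peptides < 1)) {
    abort("`theoretical_peptides` must be >= 1 for ranking.")
  }
  n <- nrow(proteins)
  proteins |>
    mutate(ibaq = .data$summed_intensity / .data$theoretical_peptides) |>
    arrange(desc(.data$ibaq), .data$protein_id) |>
    mutate(rank = row_number(),
           quartile = paste0("Q", ceiling(4 * .data$rank / n)))
}

#' Fisher's exact enrichment of a term in a foreground set
#'
#' Two-sided Fisher's exact test on the 2x2 table of term membership
#' against foreground membership within the background universe. The odds
#' ratio is the sample cross-product ratio (`Inf` when a zero cell makes
#' the association maximal).
#'
#' @param term_members Ids annotated with the term.
#' @param foreground Ids of the set tested for enrichment (must be a
#'   subset of `background`).
#' @param background The background universe of ids.
#' @return One-row tibble: the four table counts, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(term_members, foreground, background) {
  foreground <- unique(foreground)
  background <- unique(background)
  term_members <- unique(term_members)
  if (length(foreground) == 0) abort("Empty foreground.")
  if (length(setdiff(foreground, background)) > 0) {
    abort("`foreground` must be a subset of `background`.")
  }
  term_members <- intersect(term_members, background)
  rest <- setdiff(background, foreground)
  a <- length(intersect(term_members, foreground))
  b <- length(foreground) - a
  c <- length(intersect(term_members, rest))
  d <- length(rest) - c
  p <- fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble(in_term_fg = a, out_term_fg = b, in_term_bg = c, out_term_bg = d,
         odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up false-discovery-rate control; a test is flagged when
#' its adjusted p value falls below `alpha`.
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @param alpha FDR level, default 0.02.
#' @return Tibble: `p_value`, `adjusted`, `significant`.
#' @export
bh_fdr <- function(pvals, alpha = 0.02) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1].")
  }
  adj <- p.adjust(pvals, method = "BH")
  tibble(p_value = pvals, adjusted = adj, significant = adj < alpha)
}

#' Term-enrichment table with FDR control
#'
#' Runs [fisher_enrichment()] for every term and applies
#' Benjamini-Hochberg control across terms.
#'
#' @param terms Tibble with `term_id` and `protein_id` (one row per
#'   membership).
#' @param foreground,background Id sets as in [fisher_enrichment()].
#' @param fdr FDR level, default 0.02.
#' @return Tibble, one row per term, ordered by p value.
#' @export
enrich_terms <- function(terms, foreground, background, fdr = 0.02) {
  stopifnot(all(c("term_id", "protein_id") %in% names(terms)))
  res <- terms |>
    group_by(.data$term_id) |>
    group_modify(~ fisher_enrichment(.x$protein_id, foreground,
                                     background)) |>
    ungroup()
  adj <- bh_fdr(res$p_value, alpha = fdr)
  res |>
    mutate(adjusted = adj$adjusted, significant = adj$significant) |>
    arrange(.data$p_value)
}

#' Rank-shift test of phosphoprotein abundance
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) comparing the abundance ranks of phosphoproteins against
#' the remaining proteins, detecting a systematic shift such as relative
#' enrichment of low-abundance proteins among phosphoproteins.
#'
#' @param abundance Output of [rank_quartiles()] (needs `protein_id` and
#'   `rank`).
#' @param phospho_ids Protein ids observed with phosphorylation.
#' @return One-row tibble: group sizes, rank-sum statistic `W` (for the
#'   phosphoprotein group) and `p_value`.
#' @export
rank_shift_test <- function(abundance, phospho_ids) {
  in_phos <- abundance$protein_id %in% phospho_ids
  if (!any(in_phos) || all(in_phos)) {
    abort("Both groups must be non-empty.")
  }
  ht <- wilcox.test(abundance$rank[in_phos], abundance$rank[!in_phos],
                    exact = FALSE, correct = TRUE)
  tibble(n_phospho = sum(in_phos), n_other = sum(!in_phos),
         W = unname(ht$statistic), p_value = ht$p.value)
}
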