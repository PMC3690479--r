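#' Localization class of a phosphosite
#'
#' Maps localization probabilities to the standard four confidence classes:
#' class I (> 0.75), class II (0.75 to > 0.5), class III (0.5 to > 0.25) and
#' class IV (<= 0.25). Class I sites are the confidently localized sites
#' used by downstream filters.
#'
#' @param prob Numeric vector of localization probabilities in \[0, 1\].
#' @return Character vector with values `"I"`, `"II"`, `"III"`, `"IV"`.
#' @examples
#' localization_class(c(0.96, 0.75, 0.25))
#' @export
localization_class <- function(prob) {
  if (any(!is.finite(prob)) || any(prob < 0 | prob > 1)) {
    abort("`prob` must lie in [0, 1].")
  }
  dplyr::case_when(
    prob > 0.75 ~ "I",
    prob > 0.5  ~ "II",
    prob > 0.25 ~ "III",
    TRUE        ~ "IV"
  )
}

#' Regulation threshold from the median absolute deviation
#'
#' Computes `multiplier` times the raw median absolute deviation of log2
#' ratios, the global cutoff used to call insulin regulation. The raw MAD
#' (no normal-consistency constant) is used by default; set
#' `consistency = 1.4826` for the normal-consistent estimator.
#'
#' @param values Numeric vector of log2 ratios (at least 3 finite values).
#' @param multiplier MAD multiplier, default 2.5.
#' @param consistency Scale constant applied to the MAD, default 1.
#' @return The threshold, a single non-negative number.
#' @export
mad_threshold <- function(values, multiplier = 2.5, consistency = 1) {
  if (multiplier <= 0) abort("`multiplier` must be positive.")
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("Need at least 3 finite values.")
  m <- median(abs(values - median(values))) * consistency
  if (m == 0) warn("All values identical: MAD threshold is 0.")
  multiplier * m
}

med_across <- function(sites, prefix) {
  cols <- grep(sprintf("^%s_[0-9]+$", prefix), names(sites), value = TRUE)
  if (length(cols) == 0) abort(sprintf("No `%s_*` replicate columns.", prefix))
  apply(as.matrix(sites[cols]), 1L, median, na.rm = TRUE)
}

#' Call the direction of insulin regulation
#'
#' Computes each site's median insulin/basal log2 ratio over replicates and
#' calls it up- or down-regulated when the median strictly exceeds a global
#' threshold (by default 2.5 raw MADs of the full distribution of insulin
#' log2 ratios, pooling every replicate measurement of every quantified
#' site). Sites with no quantified insulin replicate are
#' reported with `quantified = FALSE` and direction `NA`, distinct from an
#' unregulated `"none"` call.
#'
#' @param sites Site tibble with `ins_*` replicate columns.
#' @param threshold Optional fixed threshold; when `NULL` it is computed
#'   from the data by [mad_threshold()].
#' @param mad_multiplier MAD multiplier used when `threshold` is `NULL`.
#' @return Tibble with `site_id`, `insulin_log2_median`, `quantified`,
#'   `direction`; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
call_regulation <- function(sites, threshold = NULL, mad_multiplier = 2.5) {
  ins_med <- med_across(sites, "ins")
  quantified <- is.finite(ins_med)
  if (is.null(threshold)) {
    ins_cols <- grep("^ins_[0-9]+$", names(sites), value = TRUE)
    ins_all <- unlist(sites[ins_cols], use.names = FALSE)
    threshold <- mad_threshold(ins_all, mad_multiplier)
  }
  if (threshold < 0) abort("`threshold` must be non-negative.")
  direction <- dplyr::case_when(
    !quantified                ~ NA_character_,
    ins_med > threshold        ~ "up",
    ins_med < -threshold       ~ "down",
    TRUE                       ~ "none"
  )
  out <- tibble(site_id = sites$site_id,
                insulin_log2_median = ifelse(quantified, ins_med, NA_real_),
                quantified = quantified,
                direction = direction)
  attr(out, "threshold") <- threshold
  out
}

#' Fraction of the insulin response reversed by an inhibitor
#'
#' `1 - inhibitor_log2 / insulin_log2`: the proportion of the
#' insulin-induced log2 change abolished in the inhibitor arm. 1 is full
#' reversal, 0 no reversal; the formula is sign-symmetric, so it applies
#' unchanged to down-regulated sites. Undefined (NA) when the insulin
#' response is zero.
#'
#' @param insulin_log2,inhibitor_log2 Numeric vectors of log2 ratios
#'   (typically replicate medians).
#' @return Numeric vector of reversal fractions.
#' @examples
#' reversal_fraction(2, c(0, 2, 1))  # 1.0, 0.0, 0.5
#' @export
reversal_fraction <- function(insulin_log2, inhibitor_log2) {
  ifelse(insulin_log2 == 0, NA_real_, 1 - inhibitor_log2 / insulin_log2)
}

#' Classify PI3K/mTOR and Akt dependence of insulin-regulated sites
#'
#' Applies the cross-screen analysis: sites are filtered to the requested
#' localization class, to quantification in at least one replicate of each
#' screen arm (insulin, Akt inhibitor, PI3K/mTOR inhibitor), and optionally
#' to a consistent response direction across insulin replicates. Regulation
#' direction is called by [call_regulation()] with a global MAD threshold
#' computed on all quantified sites (before filtering). A regulated site is
#' PI3K/mTOR-dependent when the PI3K/mTOR inhibitor reverses its insulin
#' response by more than `reversal_threshold` (default > 40%), and
#' Akt-dependent when it is PI3K-dependent and the Akt inhibitor also
#' reverses it by more than the threshold.
#'
#' @param sites Site tibble with `ins_*`, `mk_*`, `ly_*` replicate columns
#'   and `localization_prob`.
#' @param mad_multiplier MAD multiplier for the regulation threshold.
#' @param reversal_threshold Reversal fraction above which a site is called
#'   inhibitor-dependent; default 0.40.
#' @param min_localization_class Most permissive localization class
#'   retained (`"I"` keeps only class I).
#' @param require_same_direction Require every quantified insulin replicate
#'   to agree in sign with the median response (robustness filter mirroring
#'   the requirement of same-direction regulation in both screens).
#' @param threshold Optional fixed regulation threshold (overrides the MAD
#'   computation).
#' @return Tibble with one row per site: `site_id`, `direction`,
#'   `insulin_log2_median`, `reversal_ly`, `reversal_mk`,
#'   `pi3k_dependent`, `akt_dependent`, `passed_filters`. Attributes
#'   `"threshold"` and `"summary"` (see [dependence_summary()]).
#' @export
classify_dependence <- function(sites,
                                mad_multiplier = 2.5,
                                reversal_threshold = 0.40,
                                min_localization_class = "I",
                                require_same_direction = TRUE,
                                threshold = NULL) {
  if (reversal_threshold <= 0 || reversal_threshold >= 1) {
    abort("`reversal_threshold` must lie in (0, 1).")
  }
  calls <- call_regulation(sites, threshold = threshold,
                           mad_multiplier = mad_multiplier)
  thr <- attr(calls, "threshold")
  ins_med <- calls$insulin_log2_median
  mk_med <- med_across(sites, "mk")
  ly_med <- med_across(sites, "ly")

  classes <- c("I", "II", "III", "IV")
  keep_classes <- classes[seq_len(match(min_localization_class, classes))]
  class_ok <- localization_class(sites$localization_prob) %in% keep_classes
  arm_ok <- calls$quantified & is.finite(mk_med) & is.finite(ly_med)

  dir_ok <- rep(TRUE, nrow(sites))
  if (require_same_direction) {
    ins_cols <- grep("^ins_[0-9]+$", names(sites), value = TRUE)
    ins_mat <- as.matrix(sites[ins_cols])
    agree <- sign(ins_mat) == sign(ins_med)[row(ins_mat)]
    dir_ok <- apply(agree | is.na(ins_mat), 1L, all) &
      !is.na(ins_med) & ins_med != 0
  }
  passed <- class_ok & arm_ok & dir_ok
  if (!any(passed)) abort("No sites pass the cross-screen filters.")

  rev_ly <- reversal_fraction(ins_med, ly_med)
  rev_mk <- reversal_fraction(ins_med, mk_med)
  regulated <- !is.na(calls$direction) & calls$direction != "none"
  pi3k <- passed & regulated & !is.na(rev_ly) & rev_ly > reversal_threshold
  akt <- pi3k & !is.na(rev_mk) & rev_mk > reversal_threshold

  out <- tibble(
    site_id = sites$site_id,
    direction = calls$direction,
    insulin_log2_median = ins_med,
    reversal_ly = rev_ly,
    reversal_mk = rev_mk,
    pi3k_dependent = pi3k,
    akt_dependent = akt,
    passed_filters = passed
  )
  attr(out, "threshold") <- thr
  attr(out, "summary") <- dependence_summary(out)
  out
}

#' Summarize pathway-dependence fractions
#'
#' Reports, among sites passing the cross-screen filters, the fraction of
#' insulin-regulated sites blocked by the PI3K/mTOR inhibitor and the
#' fraction of those PI3K-dependent sites additionally blocked by the Akt
#' inhibitor.
#'
#' @param calls Output of [classify_dependence()].
#' @return One-row tibble with counts and the two fractions.
#' @export
dependence_summary <- function(calls) {
  reg <- calls$passed_filters & !is.na(calls$direction) &
    calls$direction != "none"
  n_reg <- sum(reg)
  n_pi3k <- sum(calls$pi3k_dependent)
  n_akt <- sum(calls$akt_dependent)
  tibble(
    n_filtered = sum(calls$passed_filters),
    n_regulated = n_reg,
    n_pi3k_dependent = n_pi3k,
    n_akt_dependent = n_akt,
    frac_pi3k = if (n_reg > 0) n_pi3k / n_reg else NA_real_,
    frac_akt_among_pi3k = if (n_pi3k > 0) n_akt / n_pi3k else NA_real_
  )
}

#' Residue distribution of phosphosites
#'
#' Fractions of phosphoserine, phosphothreonine and phosphotyrosine among
#' the supplied records (conventionally filtered to class I first).
#'
#' @param sites Site tibble with a `residue` column.
#' @return Tibble with `residue`, `n` and `fraction` (fractions sum to 1).
#' @export
residue_distribution <- function(sites) {
  if (nrow(sites) == 0) abort("No sites supplied.")
  sites |>
    count(residue = factor(.data$residue, levels = c("S", "T", "Y")),
          .drop = FALSE) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    as_tibble()
}
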