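window_letter_counts <- function(windows, width) {
  mat <- matrix(0L, nrow = width, ncol = 20, dimnames = list(NULL, AA20))
  chars <- matrix(unlist(strsplit(windows, "")), ncol = width, byrow = TRUE)
  bad <- !(chars %in% c(AA20, "_"))
  if (any(bad)) {
    abort(sprintf("Unknown letter(s) in windows: %s",
                  paste(unique(chars[bad]), collapse = ", ")))
  }
  for (i in seq_len(width)) {
    tab <- table(factor(chars[, i], levels = AA20))
    mat[i, ] <- as.integer(tab)
  }
  mat
}

#' Build a position-specific scoring matrix from substrate windows
#'
#' Computes per-position amino-acid frequencies from 13-residue sequence
#' windows (the `'_'` padding character is excluded from counts), adds a
#' pseudocount, and converts to log2 odds against background frequencies.
#' The default background is uniform over the 20 amino acids; in practice
#' pass the letter frequencies of the full (non-regulated) site cohort via
#' `background`, or compute them with [background_freqs()].
#'
#' @param windows Character vector of equal-width (default 13) windows,
#'   at least 5.
#' @param background Named 20-vector of background frequencies (summing to
#'   1), or `NULL` for uniform.
#' @param pseudocount Additive pseudocount per letter, default 0.5.
#' @return An object of class `"pssm"`: `log_odds` and `freqs` (width x 20
#'   matrices), `background`, `pseudocount`, `n` (source window count),
#'   `width`.
#' @export
build_pssm <- function(windows, background = NULL, pseudocount = 0.5) {
  if (length(windows) < 5) abort("Need at least 5 windows.")
  widths <- unique(nchar(windows))
  if (length(widths) != 1) abort("Windows have inconsistent widths.")
  width <- widths
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA20)
  }
  background <- background[AA20]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be a named frequency vector over the 20 AAs.")
  }
  counts <- window_letter_counts(windows, width)
  freqs <- (counts + pseudocount) /
    (rowSums(counts) + 20 * pseudocount)
  log_odds <- log2(sweep(freqs, 2, background, "/"))
  structure(list(log_odds = log_odds, freqs = freqs,
                 background = background, pseudocount = pseudocount,
                 n = length(windows), width = width),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d, built from %d windows (pseudocount %g)\n",
              x$width, x$n, x$pseudocount))
  invisible(x)
}

#' Background amino-acid frequencies of a window set
#'
#' Pooled letter frequencies across all positions of the supplied windows,
#' excluding the `'_'` padding character.
#'
#' @param windows Character vector of sequence windows.
#' @return Named frequency vector over the 20 amino acids.
#' @export
background_freqs <- function(windows) {
  chars <- unlist(strsplit(windows, ""))
  chars <- chars[chars != "_"]
  tab <- table(factor(chars, levels = AA20))
  as.vector(tab / sum(tab)) |> setNames(AA20)
}

#' Score sequence windows against a PSSM
#'
#' Sums the per-position log2 odds over the flanking positions of each
#' window. The center position is skipped (it is conditioned on being
#' S/T/Y) and `'_'` padding positions contribute 0, so an all-padding flank
#' scores 0. Higher scores are more motif-like.
#'
#' @param pssm A [build_pssm()] object.
#' @param windows Character vector of windows of the PSSM's width.
#' @return Numeric vector of scores.
#' @export
score_window <- function(pssm, windows) {
  stopifnot(inherits(pssm, "pssm"))
  if (any(nchar(windows) != pssm$width)) {
    abort(sprintf("Windows must have width %d.", pssm$width))
  }
  center <- (pssm$width + 1L) %/% 2L
  chars <- matrix(unlist(strsplit(windows, "")), ncol = pssm$width,
                  byrow = TRUE)
  bad <- !(chars %in% c(AA20, "_"))
  if (any(bad)) {
    abort(sprintf("Unknown letter(s) in windows: %s",
                  paste(unique(chars[bad]), collapse = ", ")))
  }
  scores <- numeric(length(windows))
  for (i in setdiff(seq_len(pssm$width), center)) {
    idx <- match(chars[, i], AA20)
    contrib <- ifelse(is.na(idx), 0, pssm$log_odds[i, ][idx])
    scores <- scores + contrib
  }
  scores
}

#' Percent-difference motif enrichment between window sets
#'
#' For every (position, residue) cell, computes the difference in percent
#' occurrence between foreground and background windows
#' (`100 * (p_fg - p_bg)`, iceLogo-style percent difference) and tests it
#' with a two-sided pooled two-proportion z-test with continuity
#' correction. `'_'` padding is excluded from the per-position
#' denominators.
#'
#' @param foreground,background Character vectors of equal-width windows.
#' @param alpha Significance threshold, default 0.01.
#' @return Tibble with `position` (offset from the center, -6..6 for width
#'   13), `residue`, `pct_fg`, `pct_bg`, `percent_difference`, `p_value`,
#'   `significant`.
#' @export
percent_difference_enrichment <- function(foreground, background,
                                          alpha = 0.01) {
  if (length(foreground) == 0 || length(background) == 0) {
    abort("Both window sets must be non-empty.")
  }
  widths <- unique(nchar(c(foreground, background)))
  if (length(widths) != 1) abort("Windows have inconsistent widths.")
  width <- widths
  center <- (width + 1L) %/% 2L
  cf <- window_letter_counts(foreground, width)
  cb <- window_letter_counts(background, width)
  nf <- rowSums(cf)
  nb <- rowSums(cb)
  out <- vector("list", width)
  for (i in seq_len(width)) {
    p1 <- cf[i, ] / nf[i]
    p2 <- cb[i, ] / nb[i]
    pooled <- (cf[i, ] + cb[i, ]) / (nf[i] + nb[i])
    se <- sqrt(pooled * (1 - pooled) * (1 / nf[i] + 1 / nb[i]))
    cc <- 0.5 * (1 / nf[i] + 1 / nb[i])  # continuity correction
    z <- ifelse(se == 0, 0,
                sign(p1 - p2) * pmax(abs(p1 - p2) - cc, 0) / se)
    p <- 2 * pnorm(-abs(z))
    out[[i]] <- tibble(position = i - center, residue = AA20,
                       pct_fg = unname(100 * p1),
                       pct_bg = unname(100 * p2),
                       percent_difference = unname(100 * (p1 - p2)),
                       p_value = unname(p),
                       significant = unname(p < alpha))
  }
  bind_rows(out)
}

#' Heatmap of percent-difference motif enrichment
#'
#' @param enrichment Output of [percent_difference_enrichment()].
#' @param significant_only Mark only significant cells with a dot.
#' @return A ggplot object: position x residue heatmap of percent
#'   differences.
#' @export
plot_motif_enrichment <- function(enrichment, significant_only = TRUE) {
  p <- ggplot(enrichment,
              aes(x = .data$position, y = .data$residue,
                  fill = .data$percent_difference)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick") +
    labs(x = "position relative to phosphosite", y = "residue",
         fill = "% difference")
  if (significant_only) {
    p <- p + geom_point(data = filter(enrichment, .data$significant),
                        size = 0.8)
  }
  p
}
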