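#' Configuration for the synthetic phosphoproteome generator
#'
#' Builds the parameter list consumed by [simulate_phosphoproteome()]. The
#' defaults emulate the composition of the insulin-stimulated adipocyte
#' phosphoproteome: roughly 15% of sites respond to insulin, about two
#' thirds of responders increase, a little over half of responders are
#' blocked by PI3K/mTOR inhibition and about two thirds of those are
#' additionally Akt-dependent; residues are 87.8% serine, 11.4% threonine
#' and 0.8% tyrosine, and 63% of sites are confidently localized (class I).
#'
#' @param n_sites Number of phosphosites to simulate.
#' @param frac_regulated Fraction of sites responding to insulin.
#' @param frac_up Fraction of regulated sites that increase.
#' @param frac_pi3k Fraction of regulated sites that are PI3K/mTOR-dependent.
#' @param frac_akt_among_pi3k Fraction of PI3K-dependent sites that are also
#'   Akt-dependent (Akt acts downstream of PI3K, so Akt dependence implies
#'   PI3K dependence).
#' @param residue_freqs Named probabilities for S/T/Y center residues.
#' @param frac_class1 Fraction of sites with localization probability > 0.75.
#' @param archetype_mix_up Named probabilities over temporal archetypes for
#'   up-regulated sites: `fast_sustained` (Akt-like, plateau by 1 min),
#'   `transient` (peak at 1-2 min, decayed by 60 min) and `slow_ramp`
#'   (mTORC1-like, plateau between 10 and 60 min).
#' @param replicate_noise_sd Per-replicate Gaussian noise, log2 units.
#' @param missing_rate Probability that any single replicate measurement is
#'   missing (missing completely at random).
#' @param n_replicates Biological replicates per condition.
#' @param timepoints_min Stimulation timepoints in minutes.
#' @param effect_mean,effect_sd,effect_min Log2 effect-size distribution for
#'   regulated sites: Normal(`effect_mean`, `effect_sd`) truncated at
#'   `effect_min`.
#' @return A list of class `"phos_sim_config"`.
#' @export
sim_config <- function(n_sites = 20000L,
                       frac_regulated = 0.15,
                       frac_up = 0.667,
                       frac_pi3k = 0.55,
                       frac_akt_among_pi3k = 0.67,
                       residue_freqs = c(S = 0.878, T = 0.114, Y = 0.008),
                       frac_class1 = 0.63,
                       archetype_mix_up = c(fast_sustained = 0.5,
                                            transient = 0.3,
                                            slow_ramp = 0.2),
                       replicate_noise_sd = 0.25,
                       missing_rate = 0.1,
                       n_replicates = 3L,
                       timepoints_min = PHOS_TIMEPOINTS,
                       effect_mean = 1.5,
                       effect_sd = 0.5,
                       effect_min = 1.0) {
  cfg <- list(n_sites = as.integer(n_sites), frac_regulated = frac_regulated,
              frac_up = frac_up, frac_pi3k = frac_pi3k,
              frac_akt_among_pi3k = frac_akt_among_pi3k,
              residue_freqs = residue_freqs, frac_class1 = frac_class1,
              archetype_mix_up = archetype_mix_up,
              replicate_noise_sd = replicate_noise_sd,
              missing_rate = missing_rate,
              n_replicates = as.integer(n_replicates),
              timepoints_min = timepoints_min,
              effect_mean = effect_mean, effect_sd = effect_sd,
              effect_min = effect_min)
  nums <- unlist(cfg[!names(cfg) %in% "n_sites"])
  if (any(!is.finite(nums))) abort("Config values must be finite.")
  fracs <- c(frac_regulated, frac_up, frac_pi3k, frac_akt_among_pi3k,
             frac_class1, missing_rate, residue_freqs, archetype_mix_up)
  if (any(fracs < 0 | fracs > 1)) abort("Fractions must lie in [0, 1].")
  if (abs(sum(residue_freqs) - 1) > 1e-8) {
    abort("`residue_freqs` must sum to 1.")
  }
  if (abs(sum(archetype_mix_up) - 1) > 1e-8) {
    abort("`archetype_mix_up` must sum to 1.")
  }
  if (replicate_noise_sd < 0 || effect_sd < 0) {
    abort("Standard deviations must be non-negative.")
  }
  structure(cfg, class = "phos_sim_config")
}

#' Noiseless temporal template for an archetype
#'
#' Pure function giving the log2-ratio template curve of a temporal
#' archetype at the requested timepoints, scaled by the site's log2 effect
#' size. `fast_sustained` reaches >= 95% of its plateau by 1 min;
#' `slow_ramp` plateaus between 10 and 60 min; `transient` peaks at 1.5 min
#' and has returned to under 25% of peak by 60 min; `decreased` is the
#' negative mirror of `fast_sustained`; `flat` is identically zero. All
#' templates are zero at t = 0 (basal reference).
#'
#' @param archetype One of `"fast_sustained"`, `"slow_ramp"`, `"transient"`,
#'   `"decreased"`, `"flat"`.
#' @param effect Log2 effect size (plateau or peak height).
#' @param timepoints_min Timepoints in minutes.
#' @return Numeric vector of log2 ratios.
#' @export
archetype_template <- function(archetype, effect,
                               timepoints_min = PHOS_TIMEPOINTS) {
  t <- timepoints_min
  switch(archetype,
    fast_sustained = effect * (1 - exp(-t / 0.25)),
    slow_ramp      = effect * (1 - exp(-t / 12)),
    transient      = effect * (t / 1.5) * exp(1 - t / 1.5),
    decreased      = -effect * (1 - exp(-t / 0.25)),
    flat           = rep(0, length(t)),
    abort(sprintf("Unknown archetype: %s", archetype))
  )
}

# Column-frequency model for 13-mer windows: a 13 x 20 matrix of letter
# probabilities per position (center row is replaced by the site residue at
# draw time). Kinase models enrich the field's hallmark positions: Akt
# (RxRxxS/T): Arg at -5 and -3; PKA: Arg at -3 and -2; mTORC1: Pro at +1.
window_model <- function(kinase = c("background", "Akt", "mTORC1", "PKA"),
                         enrich_prob = 0.8, width = 13L) {
  kinase <- match.arg(kinase)
  center <- (width + 1L) %/% 2L
  m <- matrix(1 / 20, nrow = width, ncol = 20,
              dimnames = list(NULL, AA20))
  enrich <- function(m, offset, letter) {
    i <- center + offset
    m[i, ] <- (1 - enrich_prob) / 19
    m[i, letter] <- enrich_prob
    m
  }
  if (kinase == "Akt")    m <- enrich(enrich(m, -5L, "R"), -3L, "R")
  if (kinase == "PKA")    m <- enrich(enrich(m, -3L, "R"), -2L, "R")
  if (kinase == "mTORC1") m <- enrich(m, +1L, "P")
  m
}

#' Sample sequence windows from a column-frequency model
#'
#' Draws 13-character windows column-wise from a positional letter-frequency
#' model, fixing the center at the phosphorylated residue. Used by the
#' simulator to plant kinase-motif windows (via [window_model()]) and
#' background windows.
#'
#' @param model A width x 20 positional frequency matrix, as from
#'   [window_model()].
#' @param residue Center residue, one of `"S"`, `"T"`, `"Y"`; recycled.
#' @param n Number of windows to draw (defaults to `length(residue)`).
#' @return Character vector of windows.
#' @export
sample_window <- function(model, residue, n = length(residue)) {
  if (!all(residue %in% c("S", "T", "Y"))) {
    abort("`residue` must be one of S, T, Y.")
  }
  residue <- rep_len(residue, n)
  width <- nrow(model)
  center <- (width + 1L) %/% 2L
  cols <- matrix("", nrow = n, ncol = width)
  for (i in seq_len(width)) {
    cols[, i] <- if (i == center) residue else
      sample(AA20, n, replace = TRUE, prob = model[i, ])
  }
  apply(cols, 1L, paste0, collapse = "")
}

truncated_normal <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  lo <- pnorm(lower, mean, sd)
  stats::qnorm(runif(n, lo, 1), mean, sd)
}

#' Simulate the two insulin phosphoproteomics screens with ground truth
#'
#' Generates a phosphosite table emulating (i) a two-inhibitor SILAC screen
#' (insulin, insulin + Akt inhibitor, insulin + PI3K/mTOR inhibitor, each as
#' log2 ratio versus basal, with replicates) and (ii) a nine-point insulin
#' time course, together with the planted ground-truth labels.
#'
#' Regulated sites receive a truncated-normal log2 effect size and a
#' temporal archetype realized as a noiseless template curve
#' ([archetype_template()]) plus per-replicate Gaussian noise; basal (t = 0)
#' log2 ratios are 0 by construction before noise. In the inhibitor screen
#' the insulin arm carries the full signed effect; Akt-dependent sites are
#' reversed in both inhibitor arms by a fraction drawn from Uniform(0.6, 1),
#' PI3K-only sites in the PI3K/mTOR arm only, and independent sites are
#' essentially unreversed (Uniform(-0.1, 0.2)). Windows of kinase-assigned
#' sites are sampled from that kinase's motif model, others from the
#' background model. Missingness is applied per replicate per condition,
#' completely at random.
#'
#' Planted kinases follow the pathway structure: Akt substrates are
#' fast-sustained and Akt-dependent; mTORC1 substrates are slow-ramp and
#' PI3K- (but not Akt-) dependent; PKA substrates are PI3K-independent
#' increases.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list of class `"phos_sim"` with elements `sites` (tibble, one
#'   row per site), `truth` (tibble of planted labels) and `config`.
#' @export
simulate_phosphoproteome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "phos_sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_sites
  tp <- config$timepoints_min
  n_rep <- config$n_replicates
  noise <- config$replicate_noise_sd

  residue <- sample(names(config$residue_freqs), n, replace = TRUE,
                    prob = config$residue_freqs)
  class1 <- runif(n) < config$frac_class1
  localization_prob <- ifelse(class1, runif(n, 0.7501, 1), runif(n, 0, 0.75))
  multiplicity <- sample(1:3, n, replace = TRUE, prob = c(0.72, 0.23, 0.05))

  regulated <- runif(n) < config$frac_regulated
  up <- regulated & runif(n) < config$frac_up
  direction <- ifelse(!regulated, "none", ifelse(up, "up", "down"))
  pi3k_dependent <- regulated & runif(n) < config$frac_pi3k
  akt_dependent <- pi3k_dependent & runif(n) < config$frac_akt_among_pi3k

  archetype <- rep("flat", n)
  archetype[direction == "down"] <- "decreased"
  n_up <- sum(up)
  if (n_up > 0) {
    archetype[up] <- sample(names(config$archetype_mix_up), n_up,
                            replace = TRUE, prob = config$archetype_mix_up)
  }

  true_kinase <- rep("none", n)
  true_kinase[up & akt_dependent & archetype == "fast_sustained"] <- "Akt"
  true_kinase[up & pi3k_dependent & !akt_dependent &
                archetype == "slow_ramp"] <- "mTORC1"
  true_kinase[up & !pi3k_dependent &
                archetype %in% c("fast_sustained", "transient")] <- "PKA"

  effect <- truncated_normal(n, config$effect_mean, config$effect_sd,
                             config$effect_min)
  effect[!regulated] <- 0
  signed_effect <- effect * ifelse(direction == "down", -1, 1)

  # sequence windows: kinase motif models for planted substrates
  window <- character(n)
  bg_model <- window_model("background")
  for (k in c("Akt", "mTORC1", "PKA")) {
    idx <- true_kinase == k
    if (any(idx)) {
      window[idx] <- sample_window(window_model(k), residue[idx])
    }
  }
  idx <- true_kinase == "none"
  if (any(idx)) window[idx] <- sample_window(bg_model, residue[idx])

  # protein / position bookkeeping (positions arbitrary; ids opaque)
  n_prot <- max(1L, round(n / 6.5))
  protein_id <- sprintf("P%05d", sample.int(n_prot, n, replace = TRUE))
  gene_name <- sub("^P", "Gene", protein_id)
  position <- sample.int(1000L, n, replace = TRUE)
  site_id <- sprintf("site%06d", seq_len(n))

  noisy <- function(true_vals) {
    m <- matrix(rep(true_vals, n_rep), nrow = n) +
      matrix(rnorm(n * n_rep, 0, noise), nrow = n)
    m[matrix(runif(n * n_rep) < config$missing_rate, nrow = n)] <- NA_real_
    m
  }

  # inhibitor screen: insulin arm carries the full effect; reversal fraction
  # r shrinks the residual inhibitor-arm response to (1 - r) * insulin.
  r_ly <- ifelse(pi3k_dependent, runif(n, 0.6, 1.0), runif(n, -0.1, 0.2))
  r_mk <- ifelse(akt_dependent, runif(n, 0.6, 1.0), runif(n, -0.1, 0.2))
  ins_mat <- noisy(signed_effect)
  ly_mat <- noisy(signed_effect * (1 - r_ly))
  mk_mat <- noisy(signed_effect * (1 - r_mk))

  # time course: template curves per archetype, realized per replicate
  templ <- matrix(0, nrow = n, ncol = length(tp))
  for (a in c("fast_sustained", "slow_ramp", "transient", "decreased")) {
    idx <- archetype == a
    if (any(idx)) {
      templ[idx, ] <- outer(effect[idx], rep(1, length(tp))) *
        matrix(rep(archetype_template(a, 1, tp), each = sum(idx)),
               nrow = sum(idx))
    }
  }
  tc_cols <- list()
  for (j in seq_along(tp)) {
    m <- noisy(templ[, j])
    for (r in seq_len(n_rep)) {
      tc_cols[[sprintf("tc%d_%d", j, r)]] <- m[, r]
    }
  }

  rep_cols <- function(m, prefix) {
    setNames(lapply(seq_len(n_rep), function(r) m[, r]),
             sprintf("%s_%d", prefix, seq_len(n_rep)))
  }

  sites <- tibble(
    site_id = site_id, protein_id = protein_id, gene_name = gene_name,
    position = position, residue = residue,
    localization_prob = localization_prob, multiplicity = multiplicity,
    sequence_window = window,
    !!!rep_cols(ins_mat, "ins"), !!!rep_cols(mk_mat, "mk"),
    !!!rep_cols(ly_mat, "ly"), !!!tc_cols
  )

  truth <- tibble(
    site_id = site_id, regulated = regulated, direction = direction,
    archetype = archetype, true_kinase = true_kinase,
    pi3k_dependent = pi3k_dependent, akt_dependent = akt_dependent,
    window_source = ifelse(true_kinase == "none", "background",
                           "kinase-PSSM"),
    effect_size = signed_effect,
    reversal_ly = r_ly, reversal_mk = r_mk
  )

  structure(list(sites = sites, truth = truth, config = config, seed = seed),
            class = "phos_sim")
}

#' @export
print.phos_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic phosphoproteome: %d sites (%d regulated), seed %d\n",
    nrow(x$sites), sum(x$truth$regulated), x$seed))
  invisible(x)
}
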