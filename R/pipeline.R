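#' Run the full analysis pipeline on simulated screens
#'
#' End-to-end orchestration: simulate the two screens
#' ([simulate_phosphoproteome()]), call regulation and inhibitor dependence
#' ([classify_dependence()]), cluster the regulated time courses
#' ([cluster_profiles()]), compute motif enrichment of up-regulated class I
#' windows against the non-regulated background
#' ([percent_difference_enrichment()]), train the per-kinase SVM ensembles
#' on planted substrates and Pareto-rank predictions
#' ([rank_kinase_predictions()]), and test the top-ranked Akt predictions
#' for enrichment of planted Akt substrates ([fisher_enrichment()]).
#'
#' All stage outputs are written as TSV under `out_dir`, together with a
#' `manifest.json` recording the seed, the effective configuration, stage
#' summaries and md5 checksums of every output file. No timestamps are
#' recorded, so two runs with the same seed produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Generator configuration, see [sim_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_clusters,m Fuzzy c-means parameters.
#' @param n_members Ensemble size per kinase classifier.
#' @param n_train_positives Planted substrates sampled per kinase as the
#'   curated training set.
#' @param top_n Size of the top-ranked set used in the final enrichment
#'   check.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(out_dir, config = sim_config(n_sites = 2000L),
                         seed = 1L, n_clusters = 18L, m = 2,
                         n_members = 10L, n_train_positives = 50L,
                         top_n = 50L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  path <- function(f) file.path(out_dir, f)

  # stage 1: simulate
  sim <- simulate_phosphoproteome(config, seed = seed)
  write_site_table(sim$sites, path("sites.tsv"))
  readr::write_tsv(sim$truth, path("truth.tsv"))

  # stage 2: regulation + dependence
  calls <- classify_dependence(sim$sites)
  readr::write_tsv(calls, path("regulation_calls.tsv"))
  dep_summary <- attr(calls, "summary")

  # stage 3: temporal clustering of regulated sites
  regulated_ids <- calls$site_id[!is.na(calls$direction) &
                                   calls$direction != "none"]
  reg_sites <- filter(sim$sites, .data$site_id %in% regulated_ids)
  clusters <- cluster_profiles(reg_sites, centers = n_clusters, m = m,
                               seed = seed + 1L)
  readr::write_tsv(clusters, path("clusters.tsv"))

  # stage 4: motif enrichment, up-regulated class I vs non-regulated
  class1 <- localization_class(sim$sites$localization_prob) == "I"
  up_ids <- calls$site_id[!is.na(calls$direction) & calls$direction == "up"]
  fg <- sim$sites$sequence_window[class1 & sim$sites$site_id %in% up_ids]
  bg <- sim$sites$sequence_window[!sim$sites$site_id %in% regulated_ids]
  motif_tbl <- percent_difference_enrichment(fg, bg, alpha = 0.01)
  readr::write_tsv(motif_tbl, path("motif_enrichment.tsv"))

  # stage 5: kinase-substrate prediction (kinases with enough planted
  # substrates to act as a curated positive set)
  set.seed(seed + 2L)
  # at most half of the planted substrates act as the "curated" training
  # set; the rest stay unlabeled so recovery can be assessed
  positives <- lapply(setNames(PHOS_KINASES, PHOS_KINASES), function(k) {
    ids <- sim$truth$site_id[sim$truth$true_kinase == k]
    sample(ids, min(n_train_positives, ceiling(length(ids) / 2)))
  })
  trainable <- vapply(positives, length, integer(1)) >= 10L
  if (!all(trainable)) {
    warn(sprintf("Too few planted substrates to train: %s",
                 paste(PHOS_KINASES[!trainable], collapse = ", ")))
  }
  if (sum(trainable) < 2) {
    abort("Need at least 2 trainable kinases for delta scores.")
  }
  positives <- positives[trainable]
  kinases <- names(positives)
  bg_freqs <- background_freqs(sim$sites$sequence_window)
  pssms <- lapply(positives, function(ids) {
    build_pssm(sim$sites$sequence_window[sim$sites$site_id %in% ids],
               background = bg_freqs)
  })
  features <- assemble_features(sim$sites, pssms)
  neg_pool <- candidate_negatives(sim$sites, positives)
  neg_pool <- intersect(neg_pool, features$site_id)
  classifiers <- lapply(setNames(kinases, kinases), function(k) {
    train_kinase_ensemble(features, intersect(positives[[k]],
                                              features$site_id),
                          kinase = k, negative_ids = neg_pool,
                          n_members = n_members, seed = seed + 3L)
  })
  predictions <- rank_kinase_predictions(features, classifiers)
  write_predictions(predictions, path("predictions.tsv"))

  # stage 6: enrichment of planted Akt substrates in the top predictions
  train_ids <- unlist(positives, use.names = FALSE)
  top_akt <- predictions |>
    filter(.data$kinase == "Akt", !.data$site_id %in% train_ids) |>
    slice_min(.data$rank, n = top_n)
  akt_truth <- sim$truth$site_id[sim$truth$true_kinase == "Akt"]
  universe <- setdiff(features$site_id, unlist(positives))
  akt_enrichment <- fisher_enrichment(intersect(akt_truth, universe),
                                      top_akt$site_id, universe)

  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_sites = nrow(sim$sites),
    regulation = as.list(dep_summary),
    mad_threshold = attr(calls, "threshold"),
    n_clustered = nrow(clusters),
    cluster_shape_fractions = as.list(
      prop.table(table(clusters$shape))),
    n_significant_motif_cells = sum(motif_tbl$significant),
    top_akt_enrichment = as.list(akt_enrichment)
  )
  files <- c("sites.tsv", "truth.tsv", "regulation_calls.tsv",
             "clusters.tsv", "motif_enrichment.tsv", "predictions.tsv")
  manifest$checksums <- as.list(setNames(
    unname(tools::md5sum(vapply(files, path, character(1)))), files))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Scatter plot of inhibitor reversal versus insulin response
#'
#' @param calls Output of [classify_dependence()].
#' @return A ggplot object: insulin log2 median against PI3K/mTOR-arm
#'   reversal fraction, colored by dependence class.
#' @export
plot_dependence <- function(calls) {
  d <- calls |>
    filter(.data$passed_filters, !is.na(.data$direction),
           .data$direction != "none") |>
    mutate(class = case_when(
      .data$akt_dependent ~ "Akt-dependent",
      .data$pi3k_dependent ~ "PI3K/mTOR-dependent",
      TRUE ~ "independent"))
  ggplot(d, aes(x = .data$insulin_log2_median, y = .data$reversal_ly,
                colour = .data$class)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = 0.4, linetype = 2) +
    labs(x = "insulin log2 ratio (median)",
         y = "reversal fraction (PI3K/mTOR inhibitor)",
         colour = NULL)
}
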