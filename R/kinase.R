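#' Assemble the kinase-prediction feature table
#'
#' Builds, for every site with a usable time course, the feature vector
#' used by the SVM ensembles, in a fixed documented layout: the 9 scaled
#' timepoint values; the area under the scaled curve (1); the quadratic fit
#' coefficients (3, highest order first); the mean log2 fold ratio across
#' timepoints (1); the inhibitor-screen replicate medians for the insulin,
#' Akt-inhibitor and PI3K/mTOR-inhibitor arms (3); and one PSSM score per
#' trained kinase (K). Total length 17 + K. Sites missing more than
#' `max_missing` timepoints are excluded (count attached as attribute
#' `"n_excluded"`); missing inhibitor medians are imputed as 0 (no
#' response).
#'
#' @param sites Site tibble (time-course + inhibitor columns +
#'   `sequence_window`).
#' @param pssms Named list of [build_pssm()] objects, one per kinase.
#' @param timepoints_min Timepoints in minutes.
#' @param max_missing Missing-timepoint tolerance.
#' @return Tibble: `site_id` followed by the numeric feature columns
#'   `sc_1..sc_9`, `auc`, `poly_2`, `poly_1`, `poly_0`, `mean_log2`,
#'   `ins_med`, `mk_med`, `ly_med`, `pssm_<kinase>`.
#' @export
assemble_features <- function(sites, pssms,
                              timepoints_min = PHOS_TIMEPOINTS,
                              max_missing = 3L) {
  stopifnot(is.list(pssms), !is.null(names(pssms)))
  scaled <- scale_profiles(sites, timepoints_min, max_missing)
  keep <- match(scaled$site_id, sites$site_id)
  sites <- sites[keep, , drop = FALSE]
  sc_mat <- as.matrix(scaled[sprintf("sc_%d", seq_along(timepoints_min))])

  n_tp <- length(timepoints_min)
  med_tc <- sapply(seq_len(n_tp), function(j) {
    cols <- grep(sprintf("^tc%d_[0-9]+$", j), names(sites), value = TRUE)
    apply(as.matrix(sites[cols]), 1L, median, na.rm = TRUE)
  })
  if (nrow(sites) == 1L) med_tc <- matrix(med_tc, nrow = 1L)

  auc <- apply(sc_mat, 1L, compute_auc, timepoints_min = timepoints_min)
  poly <- t(apply(sc_mat, 1L, fit_poly2, timepoints_min = timepoints_min))

  impute0 <- function(x) ifelse(is.finite(x), x, 0)
  out <- tibble(
    site_id = scaled$site_id,
    as_tibble(sc_mat),
    auc = auc,
    poly_2 = poly[, 1], poly_1 = poly[, 2], poly_0 = poly[, 3],
    mean_log2 = rowMeans(med_tc, na.rm = TRUE),
    ins_med = impute0(med_across(sites, "ins")),
    mk_med = impute0(med_across(sites, "mk")),
    ly_med = impute0(med_across(sites, "ly"))
  )
  for (k in names(pssms)) {
    out[[paste0("pssm_", k)]] <- score_window(pssms[[k]],
                                              sites$sequence_window)
  }
  attr(out, "n_excluded") <- attr(scaled, "n_excluded")
  out
}

feature_matrix <- function(features) {
  as.matrix(features[setdiff(names(features), "site_id")])
}

#' Candidate negative pool for classifier training
#'
#' Site ids usable as negative examples for a kinase: everything not in any
#' positive set and not within `min_gap` residues of a positive site on the
#' same protein (window-overlap leakage guard).
#'
#' @param sites Site tibble with `protein_id` and `position`.
#' @param positive_ids Character vector (or list of vectors) of positive
#'   site ids.
#' @param min_gap Minimum residue distance to any positive on the same
#'   protein, default 13.
#' @return Character vector of site ids.
#' @export
candidate_negatives <- function(sites, positive_ids, min_gap = 13L) {
  positive_ids <- unique(unlist(positive_ids))
  pos <- filter(sites, .data$site_id %in% positive_ids)
  pool <- filter(sites, !.data$site_id %in% positive_ids)
  near <- pool |>
    inner_join(select(pos, "protein_id", pos_position = "position"),
               by = "protein_id", relationship = "many-to-many") |>
    filter(abs(.data$position - .data$pos_position) < min_gap) |>
    pull("site_id") |>
    unique()
  setdiff(pool$site_id, near)
}

#' Train an SVM ensemble for one kinase
#'
#' Fits `n_members` radial-basis-kernel SVMs, each on all positive examples
#' against an independently subsampled negative set (without replacement,
#' `neg_ratio` negatives per positive). Features are standardized with
#' location/scale estimated from the training pool; ensemble training is
#' deterministic given `seed`.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param positive_ids Site ids of curated substrates of this kinase (at
#'   least 10, all present in `features`).
#' @param kinase Kinase name.
#' @param negative_ids Pool to subsample negatives from; defaults to all
#'   non-positive sites in `features` (use [candidate_negatives()] to guard
#'   against window overlap).
#' @param n_members Ensemble size, default 25.
#' @param neg_ratio Negatives per positive in each member, default 5.
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` uses
#'   1 / n_features.
#' @param seed Integer seed.
#' @return Object of class `"kinase_ensemble"`.
#' @export
train_kinase_ensemble <- function(features, positive_ids, kinase = "kinase",
                                  negative_ids = NULL, n_members = 25L,
                                  neg_ratio = 5, cost = 1, gamma = NULL,
                                  seed = 1L) {
  missing_pos <- setdiff(positive_ids, features$site_id)
  if (length(missing_pos) > 0) {
    abort(sprintf("Positive id(s) absent from feature table: %s",
                  paste(head(missing_pos, 5), collapse = ", ")))
  }
  if (length(positive_ids) < 10) abort("Need at least 10 positives.")
  if (is.null(negative_ids)) {
    negative_ids <- setdiff(features$site_id, positive_ids)
  }
  negative_ids <- setdiff(negative_ids, positive_ids)
  n_neg <- round(length(positive_ids) * neg_ratio)
  if (length(negative_ids) < n_neg) {
    abort("Negative pool too small for the requested neg_ratio.")
  }
  x <- feature_matrix(features)
  rownames(x) <- features$site_id
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  pool_x <- x[c(positive_ids,
                intersect(features$site_id, negative_ids)), , drop = FALSE]
  center <- colMeans(pool_x)
  scale_ <- apply(pool_x, 2, sd)
  scale_[scale_ == 0] <- 1

  set.seed(as.integer(seed))
  members <- vector("list", n_members)
  for (e in seq_len(n_members)) {
    neg_e <- sample(negative_ids, n_neg)
    xs <- scale(x[c(positive_ids, neg_e), , drop = FALSE],
                center = center, scale = scale_)
    y <- factor(rep(c("pos", "neg"), c(length(positive_ids), n_neg)),
                levels = c("pos", "neg"))
    fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    dv <- attr(predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])
    members[[e]] <- list(fit = fit, flip = flip)
  }
  structure(list(kinase = kinase, members = members, center = center,
                 scale = scale_, feature_names = colnames(x),
                 positive_ids = positive_ids, cost = cost, gamma = gamma,
                 neg_ratio = neg_ratio, seed = seed),
            class = "kinase_ensemble")
}

#' @export
print.kinase_ensemble <- function(x, ...) {
  cat(sprintf(
    "SVM ensemble for %s: %d members, %d positives, %d features\n",
    x$kinase, length(x$members), length(x$positive_ids),
    length(x$feature_names)))
  invisible(x)
}

ensemble_decision <- function(object, features) {
  x <- feature_matrix(features)
  if (!identical(colnames(x), object$feature_names)) {
    abort("Feature layout does not match the trained ensemble.")
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  dv <- vapply(object$members, function(m) {
    d <- attr(predict(m$fit, xs, decision.values = TRUE),
              "decision.values")[, 1]
    if (m$flip) -d else d
  }, numeric(nrow(xs)))
  if (nrow(xs) == 1L) dv <- matrix(dv, nrow = 1L)
  unname(rowMeans(dv))
}

#' Normalized ensemble prediction scores
#'
#' Mean decision value over the ensemble members, min-max normalized to
#' \[0, 1\] over the scored set. A single scored site has no range and
#' returns 0.5 with a warning.
#'
#' @param object A `kinase_ensemble`.
#' @param features Feature tibble with the training layout.
#' @return Tibble: `site_id`, `raw_score` (mean decision value), `score`
#'   (normalized).
#' @export
predict_scores <- function(object, features) {
  raw <- ensemble_decision(object, features)
  rng <- range(raw)
  if (diff(rng) == 0) {
    warn("Degenerate normalization: fewer than 2 distinct scores.")
    score <- rep(0.5, length(raw))
  } else {
    score <- (raw - rng[1]) / diff(rng)
  }
  tibble(site_id = features$site_id, raw_score = raw, score = score)
}

#' @rdname predict_scores
#' @param newdata Feature tibble (alias of `features`).
#' @param ... Unused.
#' @export
predict.kinase_ensemble <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' Delta scores across kinases
#'
#' For each site and kinase, the normalized score minus the site's best
#' score among the other kinases: positive deltas mark sites scored
#' distinctly highest by that kinase.
#'
#' @param scores Numeric matrix or data frame, sites x kinases (at least
#'   2 kinase columns; an optional `site_id` column is carried through).
#' @return Same shape as the input with deltas in place of scores.
#' @export
delta_scores <- function(scores) {
  id <- NULL
  if (is.data.frame(scores) && "site_id" %in% names(scores)) {
    id <- scores$site_id
    scores <- scores[setdiff(names(scores), "site_id")]
  }
  m <- as.matrix(scores)
  if (ncol(m) < 2) abort("Need scores for at least 2 kinases.")
  delta <- m
  for (k in seq_len(ncol(m))) {
    delta[, k] <- m[, k] - apply(m[, -k, drop = FALSE], 1L, max)
  }
  if (is.null(id)) return(delta)
  bind_cols(tibble(site_id = id), as_tibble(delta))
}

#' Pareto ranking over (score, delta)
#'
#' Non-dominated sorting maximizing both coordinates: front 1 contains the
#' points dominated by no other (dominance: at least as large on both
#' coordinates and strictly larger on at least one); later fronts are
#' defined recursively on the remainder. Within a front, ranks are
#' assigned by descending score, ties broken stably by input order.
#'
#' @param score,delta Numeric vectors of equal length.
#' @return Tibble: `front` (integer, 1 = non-dominated) and `rank`
#'   (1 = best), aligned with the input order.
#' @export
pareto_rank <- function(score, delta) {
  stopifnot(length(score) == length(delta),
            all(is.finite(score)), all(is.finite(delta)))
  n <- length(score)
  front <- integer(n)
  remaining <- seq_len(n)
  f <- 0L
  # score-descending sweep: within an equal-score group only the points at
  # the group's maximal delta can be non-dominated, and only if that delta
  # strictly exceeds the best delta among all strictly better scores
  while (length(remaining) > 0) {
    f <- f + 1L
    nd <- logical(length(remaining))
    groups <- split(seq_along(remaining),
                    factor(-score[remaining],
                           levels = sort(unique(-score[remaining]))))
    best_prev <- -Inf
    for (g in groups) {
      gmax <- max(delta[remaining[g]])
      if (gmax > best_prev) nd[g[delta[remaining[g]] == gmax]] <- TRUE
      best_prev <- max(best_prev, gmax)
    }
    front[remaining[nd]] <- f
    remaining <- remaining[!nd]
  }
  ord_all <- order(front, -score, seq_len(n))
  rank <- integer(n)
  rank[ord_all] <- seq_len(n)
  tibble(front = front, rank = rank)
}

#' Score, delta-score and Pareto-rank sites for all kinases
#'
#' Runs [predict_scores()] for each trained ensemble, computes delta scores
#' across kinases, and Pareto-ranks sites per kinase over (score, delta).
#' Sites in a kinase's positive training set are flagged, not removed.
#'
#' @param features Feature tibble.
#' @param classifiers Named list of `kinase_ensemble` objects.
#' @return Long tibble: `site_id`, `kinase`, `score`, `delta`, `front`,
#'   `rank`, `is_known_substrate`.
#' @export
rank_kinase_predictions <- function(features, classifiers) {
  stopifnot(length(classifiers) >= 2)
  kin <- names(classifiers)
  score_tbl <- tibble(site_id = features$site_id)
  for (k in kin) {
    score_tbl[[k]] <- predict_scores(classifiers[[k]], features)$score
  }
  delta_tbl <- delta_scores(score_tbl)
  out <- purrr::map_dfr(kin, function(k) {
    pr <- pareto_rank(score_tbl[[k]], delta_tbl[[k]])
    tibble(site_id = score_tbl$site_id, kinase = k,
           score = score_tbl[[k]], delta = delta_tbl[[k]],
           front = pr$front, rank = pr$rank,
           is_known_substrate =
             score_tbl$site_id %in% classifiers[[k]]$positive_ids)
  })
  arrange(out, .data$kinase, .data$rank)
}

auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated sensitivity, specificity and AUROC
#'
#' Stratified k-fold cross-validation of the ensemble classifier: each fold
#' is scored by an ensemble trained on the remaining folds, sensitivity and
#' specificity are evaluated at the 0.5 normalized-score operating point,
#' and the AUROC is computed from the pooled held-out scores. Proportion
#' confidence intervals are Wilson intervals; the AUROC interval uses the
#' Hanley-McNeil standard error.
#'
#' @param features Feature tibble.
#' @param positive_ids,negative_ids Site ids of the two classes.
#' @param folds Number of folds, default 5 (every fold needs >= 2
#'   positives).
#' @param seed Integer seed for fold assignment and ensemble training.
#' @param ... Passed to [train_kinase_ensemble()] (e.g. `n_members`).
#' @return One-row tibble: `sensitivity`, `specificity`, `auroc` with lower
#'   and upper 95% bounds, plus counts.
#' @export
evaluate_cv <- function(features, positive_ids, negative_ids, folds = 5L,
                        seed = 1L, ...) {
  n_pos <- length(positive_ids)
  if (n_pos < 2 * folds) {
    abort("Too few positives: each fold needs at least 2.")
  }
  set.seed(as.integer(seed))
  fold_pos <- sample(rep_len(seq_len(folds), n_pos))
  fold_neg <- sample(rep_len(seq_len(folds), length(negative_ids)))
  held_scores <- numeric(0)
  held_labels <- logical(0)
  for (f in seq_len(folds)) {
    train_pos <- positive_ids[fold_pos != f]
    train_neg <- negative_ids[fold_neg != f]
    test_ids <- c(positive_ids[fold_pos == f], negative_ids[fold_neg == f])
    fit <- train_kinase_ensemble(
      filter(features, !.data$site_id %in% test_ids),
      train_pos, negative_ids = train_neg, seed = seed + f, ...)
    sc <- predict_scores(fit, filter(features,
                                     .data$site_id %in% test_ids))
    held_scores <- c(held_scores, sc$score)
    held_labels <- c(held_labels, sc$site_id %in% positive_ids)
  }
  tp <- sum(held_scores >= 0.5 & held_labels)
  fn <- sum(held_scores < 0.5 & held_labels)
  tn <- sum(held_scores < 0.5 & !held_labels)
  fp <- sum(held_scores >= 0.5 & !held_labels)
  wilson <- function(k, n) {
    ci <- stats::prop.test(k, n, correct = FALSE)$conf.int
    c(ci[1], ci[2])
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  auc <- auroc(held_scores, held_labels)
  n1 <- sum(held_labels); n0 <- sum(!held_labels)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se_auc <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci_s <- wilson(tp, tp + fn); ci_p <- wilson(tn, tn + fp)
  tibble(
    n_pos = n1, n_neg = n0, folds = folds,
    sensitivity = sens, sensitivity_low = ci_s[1],
    sensitivity_high = ci_s[2],
    specificity = spec, specificity_low = ci_p[1],
    specificity_high = ci_p[2],
    auroc = auc,
    auroc_low = max(0, auc - 1.96 * se_auc),
    auroc_high = min(1, auc + 1.96 * se_auc)
  )
}
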