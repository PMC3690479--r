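tp <- phos_timepoints()

sim_features <- function(n = 1500, seed = 30) {
  sim <- cached_sim(n, seed = seed)
  bg <- background_freqs(sim$sites$sequence_window)
  pssms <- lapply(
    stats::setNames(c("Akt", "PKA"), c("Akt", "PKA")),
    function(k) {
      ids <- sim$truth$site_id[sim$truth$true_kinase == k]
      build_pssm(sim$sites$sequence_window[sim$sites$site_id %in% ids],
                 background = bg)
    })
  list(sim = sim, pssms = pssms,
       features = assemble_features(sim$sites, pssms))
}

test_that("feature vectors equal a hand-assembled concatenation", {
  env <- sim_features()
  sim <- env$sim
  feats <- env$features
  id <- feats$site_id[5]
  row <- feats[feats$site_id == id, ]
  site <- sim$sites[sim$sites$site_id == id, ]
  # layout: 9 scaled + auc + 3 poly + mean log2 + 3 inhibitor + K pssm
  expect_identical(names(feats),
                   c("site_id", sprintf("sc_%d", 1:9), "auc",
                     "poly_2", "poly_1", "poly_0", "mean_log2",
                     "ins_med", "mk_med", "ly_med", "pssm_Akt",
                     "pssm_PKA"))
  med <- vapply(1:9, function(j) {
    median(unlist(site[sprintf("tc%d_%d", j, 1:3)]), na.rm = TRUE)
  }, numeric(1))
  sc <- as.numeric(scale_profile(med, tp))
  expect_equal(as.numeric(row[sprintf("sc_%d", 1:9)]), sc)
  expect_equal(row$auc, compute_auc(sc, tp))
  expect_equal(as.numeric(row[c("poly_2", "poly_1", "poly_0")]),
               unname(fit_poly2(sc, tp)))
  expect_equal(row$mean_log2, mean(med, na.rm = TRUE))
  expect_equal(row$ins_med,
               median(unlist(site[sprintf("ins_%d", 1:3)]), na.rm = TRUE))
  expect_equal(row$pssm_Akt,
               score_window(env$pssms$Akt, site$sequence_window))
})

test_that("a flat noiseless profile yields the degenerate conventions", {
  sim <- simulate_phosphoproteome(
    sim_config(n_sites = 30, frac_regulated = 0, replicate_noise_sd = 0,
               missing_rate = 0), seed = 1)
  pssms <- list(Akt = build_pssm(sim$sites$sequence_window[1:10]),
                PKA = build_pssm(sim$sites$sequence_window[11:20]))
  feats <- assemble_features(sim$sites, pssms)
  expect_equal(as.numeric(feats$sc_1), rep(0.5, 30))
  expect_equal(feats$auc, rep(0.5, 30))
})

test_that("permuting input sites permutes feature rows identically", {
  env <- sim_features(400, seed = 31)
  perm <- sample(nrow(env$sim$sites))
  f2 <- assemble_features(env$sim$sites[perm, ], env$pssms)
  f1 <- env$features
  expect_equal(f2[order(match(f2$site_id, f1$site_id)), ], f1,
               ignore_attr = TRUE)
})

test_that("delta scores subtract the best competing kinase", {
  m <- matrix(c(0.9, 0.2, 0.1), nrow = 1,
              dimnames = list(NULL, c("Akt", "mTORC1", "PKA")))
  expect_equal(as.numeric(delta_scores(m)), c(0.7, -0.7, -0.8))
  eq <- matrix(0.4, nrow = 3, ncol = 3)
  expect_true(all(delta_scores(eq) == 0))
  two <- matrix(runif(10), ncol = 2)
  d <- delta_scores(two)
  expect_equal(d[, 1], -d[, 2])
})

test_that("Pareto fronts match the brute-force dominance oracle", {
  expect_equal(pareto_rank(c(1, 0), c(1, 0))$front, c(1L, 2L))
  expect_equal(pareto_rank(c(0.9, 0.1), c(0.1, 0.9))$front, c(1L, 1L))
  set.seed(32)
  score <- round(runif(200), 2)  # rounding forces ties
  delta <- round(runif(200, -1, 1), 2)
  pr <- pareto_rank(score, delta)
  expect_identical(pr$front, pareto_brute_force(score, delta))
  # front 1 contains the maximum-score point
  expect_true(all(pr$front[score == max(score)] == 1 |
                    delta[score == max(score)] <
                      max(delta[score == max(score)])))
  expect_equal(pr$front[which.max(score + 1e-9 * delta)], 1L)
  # ranks: a permutation, ordered by front then descending score
  expect_setequal(pr$rank, 1:200)
  ord <- order(pr$rank)
  expect_true(all(diff(pr$front[ord]) >= 0))
})

test_that("ensemble training recovers planted substrates (held-out AUROC)", {
  env <- sim_features(2500, seed = 33)
  sim <- env$sim
  akt_ids <- sim$truth$site_id[sim$truth$true_kinase == "Akt"]
  akt_ids <- intersect(akt_ids, env$features$site_id)
  neg_pool <- candidate_negatives(sim$sites, akt_ids)
  neg_pool <- intersect(neg_pool,
                        sim$truth$site_id[sim$truth$true_kinase == "none"])
  neg_pool <- intersect(neg_pool, env$features$site_id)
  set.seed(33)
  train_pos <- sample(akt_ids, floor(length(akt_ids) / 2))
  test_pos <- setdiff(akt_ids, train_pos)
  test_neg <- sample(setdiff(neg_pool, train_pos), 400)
  fit <- train_kinase_ensemble(
    dplyr::filter(env$features,
                  !.data$site_id %in% c(test_pos, test_neg)),
    train_pos, kinase = "Akt",
    negative_ids = setdiff(neg_pool, c(test_pos, test_neg)),
    n_members = 10, seed = 1)
  held <- dplyr::filter(env$features,
                        .data$site_id %in% c(test_pos, test_neg))
  sc <- predict_scores(fit, held)
  labels <- sc$site_id %in% test_pos
  r <- rank(sc$score)
  auroc <- (sum(r[labels]) - sum(labels) * (sum(labels) + 1) / 2) /
    (sum(labels) * sum(!labels))
  expect_gte(auroc, 0.9)
})

test_that("an ensemble of one member equals a direct single SVM fit", {
  env <- sim_features(800, seed = 34)
  feats <- env$features
  pos <- head(feats$site_id, 15)
  negs <- setdiff(feats$site_id, pos)
  fit1 <- train_kinase_ensemble(feats, pos, negative_ids = negs,
                                n_members = 1, seed = 7)
  fit2 <- train_kinase_ensemble(feats, pos, negative_ids = negs,
                                n_members = 1, seed = 7)
  expect_equal(predict_scores(fit1, feats), predict_scores(fit2, feats))
  # direct oracle: replicate the standardization and sampling by hand
  x <- as.matrix(feats[setdiff(names(feats), "site_id")])
  rownames(x) <- feats$site_id
  pool <- x[c(pos, negs), ]
  ctr <- colMeans(pool); scl <- apply(pool, 2, sd); scl[scl == 0] <- 1
  set.seed(7)
  neg_s <- sample(negs, round(15 * 5))
  xs <- scale(x[c(pos, neg_s), ], center = ctr, scale = scl)
  y <- factor(rep(c("pos", "neg"), c(15, 75)), levels = c("pos", "neg"))
  ref <- e1071::svm(xs, y, kernel = "radial", cost = 1,
                    gamma = 1 / ncol(x), scale = FALSE)
  dv <- attr(predict(ref, scale(x, center = ctr, scale = scl),
                     decision.values = TRUE), "decision.values")[, 1]
  if (mean(dv[feats$site_id %in% pos]) < mean(dv)) dv <- -dv
  expect_equal(cor(predict_scores(fit1, feats)$raw_score, dv), 1,
               tolerance = 1e-8)
})

test_that("shuffled labels give chance-level held-out AUROC", {
  env <- sim_features(2000, seed = 35)
  feats <- env$features
  set.seed(35)
  fake_pos <- sample(feats$site_id, 200)
  fake_neg <- setdiff(feats$site_id, fake_pos)
  cv <- evaluate_cv(feats, fake_pos, fake_neg, folds = 5, seed = 1,
                    n_members = 5)
  expect_gt(cv$auroc, 0.45)
  expect_lt(cv$auroc, 0.55)
})

test_that("normalized scores obey the min-max law and degenerate rule", {
  env <- sim_features(400, seed = 31)
  feats <- env$features
  pos <- head(feats$site_id, 12)
  fit <- train_kinase_ensemble(feats, pos, n_members = 3, seed = 2)
  sc <- predict_scores(fit, feats)
  expect_equal(min(sc$score), 0)
  expect_equal(max(sc$score), 1)
  expect_equal(sc$score[which.max(sc$raw_score)], 1)
  expect_warning(one <- predict_scores(fit, feats[3, ]), "Degenerate")
  expect_equal(one$score, 0.5)
  # determinism under a fixed seed, invariance to site order
  fit_b <- train_kinase_ensemble(feats, pos, n_members = 3, seed = 2)
  expect_equal(predict_scores(fit_b, feats), sc)
  perm <- sample(nrow(feats))
  sc_p <- predict_scores(fit, feats[perm, ])
  expect_equal(sc_p$raw_score, sc$raw_score[perm])
  expect_error(train_kinase_ensemble(feats, c(pos, "nope"), seed = 1),
               "absent")
})

test_that("cross-validated metrics match a hand confusion matrix", {
  env <- sim_features(2500, seed = 33)
  sim <- env$sim
  akt_ids <- intersect(sim$truth$site_id[sim$truth$true_kinase == "Akt"],
                       env$features$site_id)
  none_ids <- intersect(sim$truth$site_id[sim$truth$true_kinase == "none"],
                        env$features$site_id)
  set.seed(2)
  cv <- evaluate_cv(env$features, akt_ids, sample(none_ids, 300),
                    folds = 5, seed = 3, n_members = 5)
  expect_gte(cv$auroc, 0.9)
  expect_true(cv$sensitivity >= 0 && cv$sensitivity <= 1)
  expect_true(cv$specificity_low <= cv$specificity &&
                cv$specificity <= cv$specificity_high)
})

test_that("top-ranked Akt predictions have Akt-like temporal profiles", {
  env <- sim_features(2500, seed = 33)
  sim <- env$sim
  feats <- env$features
  akt_ids <- intersect(sim$truth$site_id[sim$truth$true_kinase == "Akt"],
                       feats$site_id)
  pka_ids <- intersect(sim$truth$site_id[sim$truth$true_kinase == "PKA"],
                       feats$site_id)
  cls <- list(
    Akt = train_kinase_ensemble(feats, akt_ids, kinase = "Akt",
                                n_members = 5, seed = 4),
    PKA = train_kinase_ensemble(feats, pka_ids, kinase = "PKA",
                                n_members = 5, seed = 4))
  pred <- rank_kinase_predictions(feats, cls)
  top50 <- pred[pred$kinase == "Akt" & pred$rank <= 50, ]
  prof <- as.matrix(feats[match(top50$site_id, feats$site_id),
                          sprintf("sc_%d", 1:9)])
  mean_prof <- colMeans(prof)
  # mean scaled profile reaches >= 90% of its plateau by 1 min
  expect_gte(mean_prof[tp == 1], 0.9 * max(mean_prof))
  expect_true(all(pred$front >= 1))
  expect_true(all(pred$delta >= -1 & pred$delta <= 1))
})
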