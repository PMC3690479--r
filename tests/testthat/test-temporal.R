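tp <- phos_timepoints()

test_that("profile scaling maps to [0,1] and is affine invariant", {
  expect_equal(as.numeric(scale_profile(c(0, 1, 2), c(0, 1, 2))),
               c(0, 0.5, 1))
  const <- scale_profile(rep(3, 9), tp)
  expect_equal(as.numeric(const), rep(0.5, 9))
  expect_true(attr(const, "degenerate"))
  x <- rnorm(9)
  expect_equal(as.numeric(scale_profile(2.7 * x + 1.3, tp)),
               as.numeric(scale_profile(x, tp)))
  expect_error(scale_profile(c(1, rep(NA, 8)), tp), "at least 2")
})

test_that("missing timepoints are interpolated on the time axis", {
  x <- archetype_template("slow_ramp", 2, tp)
  x_miss <- x
  x_miss[c(3, 9)] <- NA   # interior point + endpoint
  s <- scale_profile(x_miss, tp)
  # interior: linear interpolation between neighbours in minutes
  expected3 <- x[2] + (x[4] - x[2]) * (tp[3] - tp[2]) / (tp[4] - tp[2])
  full <- x
  full[3] <- expected3
  full[9] <- x[8]         # endpoint takes nearest observed value
  expect_equal(as.numeric(s),
               (full - min(full)) / (max(full) - min(full)))
})

test_that("AUC is the hand trapezoid on normalized time", {
  expect_equal(compute_auc(rep(1, 9), tp), 1)
  expect_equal(compute_auc(rep(0, 9), tp), 0)
  # step profile: 0 through 1 min, 1 afterwards
  step <- as.numeric(tp > 1)
  # hand trapezoid over minutes/60: ramp 1->2 min contributes (1/60)/2,
  # plateau 2->60 min contributes 58/60
  expect_equal(compute_auc(step, tp), (1 / 60) / 2 + 58 / 60)
})

test_that("quadratic fits recover coefficients and match normal equations", {
  tn <- tp / max(tp)
  y <- 2 * tn^2 - 0.7 * tn + 0.3
  expect_equal(fit_poly2(y, tp),
               c(poly_2 = 2, poly_1 = -0.7, poly_0 = 0.3),
               tolerance = 1e-9)
  expect_equal(fit_poly2(rep(0.5, 9), tp),
               c(poly_2 = 0, poly_1 = 0, poly_0 = 0.5))
  set.seed(3)
  yn <- y + rnorm(9, 0, 0.1)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, tn, tn^2)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(unname(fit_poly2(yn, tp)), rev(as.numeric(beta)),
               tolerance = 1e-8)
})

test_that("fuzzy c-means separates well-separated groups perfectly", {
  set.seed(10)
  g1 <- matrix(rnorm(50 * 9, 0, 0.05), ncol = 9)
  g2 <- matrix(rnorm(50 * 9, 5, 0.05), ncol = 9)
  fit <- fuzzy_cmeans(rbind(g1, g2), centers = 2, seed = 1)
  lab <- fit$cluster
  expect_true(all(lab[1:50] == lab[1]) && all(lab[51:100] == lab[51]) &&
                lab[1] != lab[51])
})

test_that("memberships are row-normalized and the objective non-increasing", {
  set.seed(11)
  x <- matrix(rnorm(120 * 9), ncol = 9)
  fit <- fuzzy_cmeans(x, centers = 5, m = 2, seed = 2)
  expect_equal(rowSums(fit$membership), rep(1, 120))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("a profile coinciding with a centroid takes membership 1", {
  x <- rbind(matrix(rep(c(0, 1), each = 20), ncol = 2, byrow = FALSE))
  # duplicate identical profiles: 20 at (0,1)-ish patterns
  x <- rbind(matrix(0, 10, 3), matrix(5, 10, 3))
  fit <- fuzzy_cmeans(x, centers = 2, seed = 3, tol = 1e-12,
                      max_iter = 500)
  expect_equal(sort(unname(apply(fit$membership, 1, max)))[1], 1,
               tolerance = 1e-6)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  set.seed(12)
  g1 <- matrix(rnorm(40 * 9, 0, 0.2), ncol = 9)
  g2 <- matrix(rnorm(40 * 9, 3, 0.2), ncol = 9)
  x <- rbind(g1, g2)
  fit <- fuzzy_cmeans(x, centers = 2, m = 2, seed = 4, tol = 1e-10)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 300)
  # centroids agree up to cluster relabeling
  d <- as.matrix(dist(rbind(fit$centroids, ref$centers)))[1:2, 3:4]
  perm <- if (d[1, 1] + d[2, 2] <= d[1, 2] + d[2, 1]) c(1, 2) else c(2, 1)
  expect_lt(max(abs(fit$centroids - ref$centers[perm, ])), 1e-3)
})

test_that("clustering is invariant to row permutation on separable data", {
  set.seed(13)
  x <- rbind(matrix(rnorm(30 * 9, 0, 0.1), ncol = 9),
             matrix(rnorm(30 * 9, 4, 0.1), ncol = 9))
  perm <- sample(60)
  f1 <- fuzzy_cmeans(x, centers = 2, seed = 5)
  f2 <- fuzzy_cmeans(x[perm, ], centers = 2, seed = 6)
  part1 <- f1$cluster
  part2 <- integer(60)
  part2[perm] <- f2$cluster
  agreement <- max(mean(part1 == part2), mean(part1 == 3 - part2))
  expect_equal(agreement, 1)
})

test_that("shape labeling classifies the archetype templates correctly", {
  mk_scaled <- function(a) {
    v <- archetype_template(a, 1.5, tp)
    as.numeric(scale_profile(v, tp))
  }
  cents <- rbind(mk_scaled("fast_sustained"), mk_scaled("slow_ramp"),
                 mk_scaled("transient"), mk_scaled("decreased"))
  expect_identical(label_cluster_shapes(cents, tp),
                   c("sustained_increase", "sustained_increase",
                     "transient", "decreased"))
})

test_that("noisy planted archetypes are labeled correctly in clusters", {
  sim <- cached_sim(3000, seed = 5, frac_regulated = 1)
  cl <- cluster_profiles(sim$sites, centers = 12, m = 2, seed = 5)
  tr <- sim$truth[match(cl$site_id, sim$truth$site_id), ]
  expected <- dplyr::case_when(
    tr$archetype %in% c("fast_sustained", "slow_ramp") ~
      "sustained_increase",
    tr$archetype == "transient" ~ "transient",
    tr$archetype == "decreased" ~ "decreased",
    TRUE ~ "other")
  expect_gte(mean(cl$shape == expected), 0.95)
})

test_that("tidy, glance and autoplot summarize a fit", {
  set.seed(14)
  fit <- fuzzy_cmeans(matrix(rnorm(40 * 9), ncol = 9), centers = 3,
                      seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 9)
  expect_equal(td$value[td$cluster == 2],
               unname(fit$centroids[2, ]))
  gl <- glance(fit)
  expect_equal(gl$clusters, 3)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
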