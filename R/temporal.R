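#' Min-max scale a time-course profile
#'
#' Scales a nine-point log2 ratio profile to \[0, 1\] as
#' `(x - min) / (max - min)`. Missing timepoints are first linearly
#' interpolated on the (real, minutes) time axis; a missing endpoint takes
#' the nearest observed value. A constant profile has no dynamic range and
#' maps to all 0.5, flagged via attribute `"degenerate"`. Scaling is
#' invariant to positive affine transforms of the input.
#'
#' @param log2_ratios Numeric vector, one value per timepoint (NA allowed,
#'   at least 2 observed).
#' @param timepoints_min Timepoints in minutes.
#' @return Scaled numeric vector, attribute `"degenerate"` logical.
#' @export
scale_profile <- function(log2_ratios, timepoints_min = PHOS_TIMEPOINTS) {
  stopifnot(length(log2_ratios) == length(timepoints_min))
  obs <- is.finite(log2_ratios)
  if (sum(obs) < 2) abort("Need at least 2 observed timepoints.")
  x <- log2_ratios
  if (!all(obs)) {
    x <- approx(timepoints_min[obs], log2_ratios[obs],
                xout = timepoints_min, rule = 2)$y
  }
  rng <- range(x)
  if (diff(rng) == 0) {
    return(structure(rep(0.5, length(x)), degenerate = TRUE))
  }
  structure((x - rng[1]) / diff(rng), degenerate = FALSE)
}

#' Area under a scaled time-course profile
#'
#' Trapezoidal integral of the scaled profile over the time axis normalized
#' to \[0, 1\] (minutes divided by the final timepoint, 60 min), so the
#' result lies in \[0, 1\]: 1 for an immediately saturating profile, near 0
#' for a late ramp.
#'
#' @param scaled Complete scaled profile in \[0, 1\].
#' @param timepoints_min Timepoints in minutes.
#' @return A single number in \[0, 1\].
#' @export
compute_auc <- function(scaled, timepoints_min = PHOS_TIMEPOINTS) {
  stopifnot(length(scaled) == length(timepoints_min), all(is.finite(scaled)))
  tn <- timepoints_min / max(timepoints_min)
  pracma::trapz(tn, scaled)
}

#' Quadratic fit to a scaled time-course profile
#'
#' Least-squares quadratic in normalized time (minutes / 60). Coefficients
#' are returned highest order first: `(quadratic, linear, constant)`, so a
#' constant profile at 0.5 yields `(0, 0, 0.5)`.
#'
#' @param scaled Complete scaled profile.
#' @param timepoints_min Timepoints in minutes.
#' @return Named numeric vector `c(poly_2, poly_1, poly_0)`.
#' @export
fit_poly2 <- function(scaled, timepoints_min = PHOS_TIMEPOINTS) {
  stopifnot(length(scaled) == length(timepoints_min), all(is.finite(scaled)))
  tn <- timepoints_min / max(timepoints_min)
  fit <- lm(scaled ~ tn + I(tn^2))
  co <- coef(fit)
  co[is.na(co)] <- 0
  setNames(rev(unname(co)), c("poly_2", "poly_1", "poly_0"))
}

#' Per-site scaled time-course profiles
#'
#' Collapses replicate time-course columns (`tc<j>_<r>`) to per-timepoint
#' medians, excludes sites with more than `max_missing` of the nine
#' timepoints entirely missing, interpolates the remainder and min-max
#' scales each profile ([scale_profile()]).
#'
#' @param sites Site tibble with `tc*_*` columns.
#' @param timepoints_min Timepoints in minutes.
#' @param max_missing Maximum number of fully missing timepoints tolerated
#'   (default 3).
#' @return Tibble: `site_id`, scaled columns `sc_1` .. `sc_9`, `degenerate`.
#'   The number of excluded sites is attached as attribute `"n_excluded"`.
#' @export
scale_profiles <- function(sites, timepoints_min = PHOS_TIMEPOINTS,
                           max_missing = 3L) {
  n_tp <- length(timepoints_min)
  med <- sapply(seq_len(n_tp), function(j) {
    cols <- grep(sprintf("^tc%d_[0-9]+$", j), names(sites), value = TRUE)
    if (length(cols) == 0) abort(sprintf("No `tc%d_*` columns.", j))
    apply(as.matrix(sites[cols]), 1L, median, na.rm = TRUE)
  })
  if (nrow(sites) == 1L) med <- matrix(med, nrow = 1L)
  n_missing <- rowSums(!is.finite(med))
  keep <- n_missing <= max_missing & (n_tp - n_missing) >= 2
  scaled <- matrix(NA_real_, nrow = sum(keep), ncol = n_tp,
                   dimnames = list(NULL, sprintf("sc_%d", seq_len(n_tp))))
  degenerate <- logical(sum(keep))
  for (i in seq_len(sum(keep))) {
    s <- scale_profile(med[which(keep)[i], ], timepoints_min)
    scaled[i, ] <- s
    degenerate[i] <- attr(s, "degenerate")
  }
  out <- bind_cols(tibble(site_id = sites$site_id[keep]),
                   as_tibble(scaled), tibble(degenerate = degenerate))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Soft clustering by the standard Bezdek alternating updates: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` from squared Euclidean
#' distances, centroids as membership^m-weighted means, iterated until the
#' largest centroid change falls below `tol` or `max_iter` is reached.
#' Memberships are initialized at random (rows normalized to sum to 1), so
#' results are deterministic given `seed`. A profile coinciding exactly
#' with a centroid receives membership 1 there (shared equally among
#' coinciding centroids).
#'
#' @param x Numeric matrix, one row per profile (or a tibble whose `sc_*`
#'   columns are used, e.g. from [scale_profiles()]).
#' @param centers Number of clusters `c` (default 18).
#' @param m Fuzzifier, > 1 (default 2).
#' @param max_iter,tol Convergence controls.
#' @param seed Seed for the random membership initialization.
#' @return An object of class `"fcm_fit"`: `centroids` (c x p),
#'   `membership` (n x c), `cluster` (hard assignment by maximal
#'   membership), `objective` (value of `sum u^m d^2` after each
#'   iteration), `iterations`, `m`.
#' @export
fuzzy_cmeans <- function(x, centers = 18L, m = 2, max_iter = 300L,
                         tol = 1e-6, seed = 1L) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[grep("^sc_[0-9]+$", names(x), value = TRUE)])
  }
  n <- nrow(x)
  if (m <= 1) abort("Fuzzifier `m` must exceed 1.")
  if (n < centers) abort("Need at least as many profiles as clusters.")
  set.seed(as.integer(seed))
  u <- matrix(runif(n * centers), nrow = n)
  u <- u / rowSums(u)
  objective <- numeric(0)
  centroids <- matrix(0, nrow = centers, ncol = ncol(x))
  for (iter in seq_len(max_iter)) {
    um <- u^m
    new_centroids <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, centers)) +
      outer(rep(1, n), rowSums(new_centroids^2)) -
      2 * x %*% t(new_centroids)
    d2[d2 < 0] <- 0
    zero <- d2 < .Machine$double.eps
    inv <- (1 / pmax(d2, .Machine$double.eps))^(1 / (m - 1))
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    objective <- c(objective, sum(u^m * d2))
    delta <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (delta < tol) break
  }
  structure(list(centroids = centroids, membership = u,
                 cluster = max.col(u, ties.method = "first"),
                 objective = objective, iterations = iter, m = m,
                 tol = tol, seed = seed),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means fit: %d profiles, %d clusters, m = %g, %d iteration(s)\n",
    nrow(x$membership), nrow(x$centroids), x$m, x$iterations))
  invisible(x)
}

#' Tidy a fuzzy c-means fit
#'
#' @param x An `fcm_fit` object.
#' @param ... Unused.
#' @return Long tibble: `cluster`, `timepoint` (index), `value` (centroid
#'   coordinate).
#' @method tidy fcm_fit
#' @export
tidy.fcm_fit <- function(x, ...) {
  tibble(
    cluster = rep(seq_len(nrow(x$centroids)), ncol(x$centroids)),
    timepoint = rep(seq_len(ncol(x$centroids)),
                    each = nrow(x$centroids)),
    value = as.vector(x$centroids)
  ) |> arrange(.data$cluster, .data$timepoint)
}

#' @rdname tidy.fcm_fit
#' @method glance fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(n = nrow(x$membership), clusters = nrow(x$centroids), m = x$m,
         iterations = x$iterations,
         objective = x$objective[length(x$objective)])
}

#' Plot fuzzy c-means centroid curves
#'
#' @param object An `fcm_fit` object.
#' @param timepoints_min Timepoints in minutes for the x axis.
#' @param ... Unused.
#' @return A ggplot object: one panel per cluster, centroid trajectory on
#'   the scaled \[0, 1\] axis against log-scaled time.
#' @method autoplot fcm_fit
#' @export
autoplot.fcm_fit <- function(object, timepoints_min = PHOS_TIMEPOINTS, ...) {
  td <- tidy.fcm_fit(object) |>
    mutate(minutes = timepoints_min[.data$timepoint],
           shape = label_cluster_shapes(object$centroids,
                                        timepoints_min)[.data$cluster])
  ggplot(td, aes(x = .data$minutes + 0.1, y = .data$value,
                 colour = .data$shape)) +
    geom_line() +
    facet_wrap(~cluster) +
    scale_x_log10() +
    labs(x = "time (min, log scale, offset 0.1)", y = "scaled log2 ratio",
         colour = "shape")
}

#' Label cluster centroids by temporal shape
#'
#' Classifies each centroid curve (on the scaled \[0, 1\] axis) as
#' `"decreased"` (final value more than 0.3 below the initial value),
#' `"sustained_increase"` (final value at least 60% of the maximum, and the
#' post-1-min maximum at least 0.3 above the initial value), `"transient"`
#' (maximum before 5 min and final value at most 40% of the maximum) or
#' `"other"`. The decreased rule is evaluated first so that monotone
#' decreases (whose scaled maximum sits at t = 0) are not mistaken for
#' transients.
#'
#' @param centroids Matrix of centroid profiles (rows), or an `fcm_fit`.
#' @param timepoints_min Timepoints in minutes.
#' @return Character vector of shape labels, one per centroid.
#' @export
label_cluster_shapes <- function(centroids,
                                 timepoints_min = PHOS_TIMEPOINTS) {
  if (inherits(centroids, "fcm_fit")) centroids <- centroids$centroids
  apply(centroids, 1L, function(v) {
    first <- v[1]
    final <- v[length(v)]
    vmax <- max(v)
    t_max <- timepoints_min[which.max(v)]
    late_max <- max(v[timepoints_min >= 1])
    if (final < first - 0.3) return("decreased")
    if (final >= 0.6 * vmax && late_max - first >= 0.3) {
      return("sustained_increase")
    }
    if (t_max < 5 && final <= 0.4 * vmax) return("transient")
    "other"
  })
}

#' Cluster regulated time-course profiles and label their shapes
#'
#' Convenience wrapper: scales profiles ([scale_profiles()]), runs fuzzy
#' c-means ([fuzzy_cmeans()]), hard-assigns each site to its
#' maximum-membership cluster and labels every cluster centroid by shape
#' ([label_cluster_shapes()]).
#'
#' @param sites Site tibble with time-course columns.
#' @param centers,m,seed Clustering parameters (see [fuzzy_cmeans()]).
#' @param timepoints_min Timepoints in minutes.
#' @param max_missing Missing-timepoint tolerance for [scale_profiles()].
#' @return Tibble: `site_id`, `cluster`, `membership` (of the assigned
#'   cluster), `shape`; the `fcm_fit` is attached as attribute `"fit"`.
#' @export
cluster_profiles <- function(sites, centers = 18L, m = 2, seed = 1L,
                             timepoints_min = PHOS_TIMEPOINTS,
                             max_missing = 3L) {
  scaled <- scale_profiles(sites, timepoints_min, max_missing)
  fit <- fuzzy_cmeans(scaled, centers = centers, m = m, seed = seed)
  shapes <- label_cluster_shapes(fit$centroids, timepoints_min)
  out <- tibble(
    site_id = scaled$site_id,
    cluster = fit$cluster,
    membership = fit$membership[cbind(seq_len(nrow(scaled)), fit$cluster)],
    shape = shapes[fit$cluster]
  )
  attr(out, "fit") <- fit
  out
}
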