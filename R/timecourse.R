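# Time-course machinery: two-step differential-expression filter,
# medoid clustering, 50%-dynamic-range response classification, cubic
# interpolation to a fine grid, and the time-delay Spearman correlation map.

# centred moving-average fit (window 3; 2-point means at the ends),
# applied row-wise to a genes x times matrix
.ma_fit <- function(m) {
  n <- ncol(m)
  f <- m
  if (n >= 3) {
    f[, 2:(n - 1)] <- (m[, 1:(n - 2)] + m[, 2:(n - 1)] + m[, 3:n]) / 3
    f[, 1] <- (m[, 1] + m[, 2]) / 2
    f[, n] <- (m[, n - 1] + m[, n]) / 2
  }
  f
}

.row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

# smoothness statistic: variance explained by a moving-average fit over
# residual variance; smooth temporal profiles score high, noise scores ~1
.smoothness_stat <- function(m) {
  f <- .ma_fit(m)
  vs <- .row_var(f)
  vr <- .row_var(m - f)
  ifelse(vr == 0, Inf, vs / vr)
}

#' Two-step time-course differential-expression filter
#'
#' Step 1 keeps genes whose profile spans at least `min_log2_range` log2
#' units (a minimum fold change of 1 in log2 scale by default). Step 2
#' removes noisy genes with a permutation-calibrated smoothness filter: the
#' statistic is the ratio of the variance captured by a centred
#' moving-average fit to the residual variance around it, and its null
#' distribution comes from shuffling the time order; genes are retained at
#' permutation level `alpha`. This filter plays the role of an
#' empirical-Bayes time-course noise filter while needing no replicate
#' structure (see the methods vignette).
#'
#' @param tc a [timecourse()] with at least 4 time points.
#' @param min_log2_range minimum profile range (default 1 log2 unit).
#' @param alpha retention level of the noise filter (default 0.001).
#' @param n_perm time-order permutations; the default scales as `5/alpha`
#'   so the smallest achievable p-value sits below `alpha`.
#' @param seed integer RNG seed.
#' @return character vector of retained gene identifiers, with the per-gene
#'   permutation p-values of the step-1 survivors attached as attribute
#'   `p_values`.
#' @export
timecourse_de_filter <- function(tc, min_log2_range = 1, alpha = 0.001,
                                 n_perm = max(1999, ceiling(5 / alpha) - 1),
                                 seed = 1) {
  stopifnot(inherits(tc, "timecourse"))
  nt <- length(tc$times_h)
  if (nt < 4) stop("need at least 4 time points")
  x <- tc$values
  rng <- apply(x, 1, function(v) diff(range(v)))
  step1 <- rng >= min_log2_range
  if (!any(step1)) {
    out <- character()
    attr(out, "p_values") <- numeric()
    return(out)
  }
  x1 <- x[step1, , drop = FALSE]
  obs <- .smoothness_stat(x1)
  set.seed(seed)
  exceed <- integer(nrow(x1))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nt)
    exceed <- exceed + (.smoothness_stat(x1[, perm, drop = FALSE]) >= obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  keep <- rownames(x1)[p < alpha]
  attr(keep, "p_values") <- setNames(p, rownames(x1))
  keep
}

#' Cluster time-course profiles around medoids
#'
#' Partitioning-around-medoids ([cluster::pam()]) on correlation distance
#' (1 - Pearson), so genes cluster by profile shape regardless of absolute
#' level. Medoids are actual gene profiles. Each cluster is classified by
#' its response time ([classify_response()]); the average silhouette width
#' is reported to guide the choice of `k`.
#'
#' @param tc a [timecourse()].
#' @param k number of clusters (2 <= k <= genes; k = 1 allowed for the
#'   degenerate single-cluster case).
#' @param seed integer seed (PAM is deterministic; kept for interface
#'   uniformity).
#' @param n_points interpolation grid for response classification.
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   gene id vectors), `medoids` (k x times matrix), `medoid_genes`,
#'   `times_h`, `response` (data.frame `cluster`, `response_time_h`,
#'   `response_class`, `dynamic_range`), `silhouette`, `membership`.
#' @export
cluster_profiles <- function(tc, k, seed = 1, n_points = 100) {
  stopifnot(inherits(tc, "timecourse"))
  x <- tc$values
  if (k > nrow(x)) stop("k must not exceed the number of genes")
  if (k < 1) stop("k must be positive")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profiles dropped before clustering")
    x <- x[sds > 0, , drop = FALSE]
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  set.seed(seed)
  if (k == 1) {
    dm <- as.matrix(d)
    medoid <- rownames(x)[which.min(colSums(dm))]
    membership <- setNames(rep(1L, nrow(x)), rownames(x))
    sil <- NA_real_
    medoid_genes <- medoid
  } else {
    fit <- cluster::pam(d, k = k, diss = TRUE)
    membership <- setNames(as.integer(fit$clustering), rownames(x))
    medoid_genes <- fit$medoids
    sil <- fit$silinfo$avg.width
  }
  medoids <- x[medoid_genes, , drop = FALSE]
  rownames(medoids) <- paste0("cluster", seq_len(k))
  resp <- lapply(seq_len(k), function(c) {
    r <- tryCatch(classify_response(medoids[c, ], tc$times_h,
                                    n_points = n_points),
                  error = function(e) list(response_time_h = NA_real_,
                                           response_class = "unclassified",
                                           dynamic_range = 0))
    data.frame(cluster = c, response_time_h = r$response_time_h,
               response_class = r$response_class,
               dynamic_range = r$dynamic_range)
  })
  structure(list(clusters = split(names(membership), membership),
                 medoids = medoids, medoid_genes = medoid_genes,
                 times_h = tc$times_h, response = do.call(rbind, resp),
                 silhouette = sil, membership = membership),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      length(x$membership), "genes; avg silhouette",
      round(x$silhouette, 3), "\n")
  print(x$response, row.names = FALSE)
  invisible(x)
}

#' Interpolate a profile to a fine uniform grid
#'
#' Cubic piecewise-polynomial (spline) interpolation through the observed
#' knots, evaluated on `n_points` uniformly spaced times spanning the
#' sampled interval. Endpoint values are preserved exactly. A piecewise
#' cubic is used rather than one global high-degree polynomial to avoid
#' Runge oscillation between knots.
#'
#' @param medoid numeric profile at the observed times.
#' @param times_h observed times (>= 3, strictly increasing, no
#'   duplicates).
#' @param n_points output grid size (default 100).
#' @return list with `times_h` (uniform grid) and `values`.
#' @export
interpolate_profile <- function(medoid, times_h, n_points = 100) {
  if (length(times_h) < 3) stop("need at least 3 time points")
  if (anyDuplicated(times_h)) stop("duplicate times")
  if (length(medoid) != length(times_h))
    stop("profile and times differ in length")
  s <- stats::spline(times_h, medoid, n = n_points, method = "fmm")
  list(times_h = s$x, values = s$y)
}

#' Response time and class at 50% of the dynamic range
#'
#' The response time is the earliest time at which the interpolated
#' profile has moved away from its initial value by at least half the
#' profile's dynamic range (max - min of the observed medoid; the raw
#' knots, not the interpolant, define the range so that spline over- and
#' undershoot between knots cannot inflate it). The
#' class windows follow the implantation time-course convention: rapid
#' (up to 12 h), intermediate (12-24 h), delayed (36-48 h); crossing times
#' outside these windows (notably the empty 24-36 h band) are
#' unclassified. The classification is invariant to affine rescaling of
#' the profile.
#'
#' @param medoid numeric profile (non-constant).
#' @param times_h observed times.
#' @param n_points interpolation grid size.
#' @return list with `response_time_h`, `response_class` and
#'   `dynamic_range`.
#' @export
classify_response <- function(medoid, times_h, n_points = 100) {
  if (diff(range(medoid)) == 0)
    stop("constant profile: dynamic range is zero")
  ip <- interpolate_profile(medoid, times_h, n_points)
  rng <- diff(range(medoid))
  moved <- abs(ip$values - ip$values[1]) >= 0.5 * rng
  if (!any(moved)) # interpolant never reaches the half-range: degenerate
    return(list(response_time_h = NA_real_,
                response_class = "unclassified", dynamic_range = rng))
  t_resp <- ip$times_h[which(moved)[1]]
  # the detected crossing is quantized upward by up to one grid step;
  # discount that step before testing the class windows so a crossing at a
  # window's upper edge is not pushed out of it
  t_eff <- t_resp - diff(ip$times_h[1:2])
  cls <- if (t_eff <= 12) "rapid"
         else if (t_eff <= 24) "intermediate"
         else if (t_eff > 36 && t_eff <= 48) "delayed"
         else "unclassified"
  list(response_time_h = t_resp, response_class = cls, dynamic_range = rng)
}

#' Time-delay Spearman correlation between two interpolated profiles
#'
#' Spearman correlation evaluated at zero lag and at every grid lag whose
#' absolute value falls in the delay window (13-24 h by default), in both
#' directions, over the overlapping segments only. The reported result is
#' the lag attaining the maximum signed correlation (so anti-correlated
#' pairs are never significant); the pair is significant when that maximum
#' exceeds `rho_threshold`. A positive lag means the second profile lags
#' (repeats) the first.
#'
#' @param p1,p2 equal-length profiles on the same uniform grid.
#' @param grid_h grid step in hours.
#' @param lag_window_h length-2 window of admissible absolute lags.
#' @param rho_threshold significance threshold on the maximum rho
#'   (default 0.9).
#' @param min_overlap smallest admissible overlap after shifting
#'   (default 10 points); lags with less overlap are skipped.
#' @param absolute rank lags by `|rho|` instead of signed rho.
#' @return An object of class `lag_correlation`: list with `best_rho`,
#'   `best_lag_h`, `significant`, and the full `by_lag` table.
#' @export
lag_correlation <- function(p1, p2, grid_h, lag_window_h = c(13, 24),
                            rho_threshold = 0.9, min_overlap = 10,
                            absolute = FALSE) {
  n <- length(p1)
  if (length(p2) != n) stop("profiles must have equal length")
  steps <- seq_len(n - 1)
  admissible <- steps[steps * grid_h >= lag_window_h[1] &
                      steps * grid_h <= lag_window_h[2]]
  lags <- c(0L, admissible, -admissible)
  rows <- lapply(lags, function(s) {
    if (s >= 0) { a <- p1[seq_len(n - s)]; b <- p2[seq_len(n - s) + s] }
    else        { a <- p1[seq_len(n + s) - s]; b <- p2[seq_len(n + s)] }
    if (length(a) < min_overlap) return(NULL)
    rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
    if (is.na(rho)) return(NULL)
    data.frame(lag_h = s * grid_h, rho = rho)
  })
  by_lag <- do.call(rbind, rows)
  if (is.null(by_lag) || nrow(by_lag) == 0)
    stop("no admissible lag retains enough overlap")
  key <- if (absolute) abs(by_lag$rho) else by_lag$rho
  # ties: prefer zero lag, then the smallest shift
  ord <- order(-key, abs(by_lag$lag_h))
  best <- by_lag[ord[1], ]
  structure(list(best_rho = best$rho, best_lag_h = best$lag_h,
                 significant = (if (absolute) abs(best$rho) else best$rho) >
                   rho_threshold,
                 by_lag = by_lag, rho_threshold = rho_threshold),
            class = "lag_correlation")
}

#' Time-delay correlation map over all cluster pairs
#'
#' Interpolates every cluster medoid to a common fine grid and evaluates
#' [lag_correlation()] for all unordered cluster pairs. The map is
#' symmetric with the lag sign indicating direction: a positive lag means
#' the second cluster of the pair lags the first.
#'
#' @param clusters a `cluster_set` (see [cluster_profiles()]) with >= 2
#'   clusters (a single cluster yields an empty map).
#' @param rho_threshold significance threshold (default 0.9).
#' @param n_points interpolation grid size (default 100).
#' @param lag_window_h admissible absolute lag window (default 13-24 h).
#' @param absolute forwarded to [lag_correlation()].
#' @return data.frame with one row per pair: `cluster_i`, `cluster_j`,
#'   `rho`, `lag_h`, `significant`.
#' @export
build_dynamic_map <- function(clusters, rho_threshold = 0.9, n_points = 100,
                              lag_window_h = c(13, 24), absolute = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"))
  k <- nrow(clusters$medoids)
  empty <- data.frame(cluster_i = integer(), cluster_j = integer(),
                      rho = numeric(), lag_h = numeric(),
                      significant = logical())
  if (k < 2) return(empty)
  ips <- lapply(seq_len(k), function(c)
    interpolate_profile(clusters$medoids[c, ], clusters$times_h, n_points))
  grid_h <- diff(ips[[1]]$times_h[1:2])
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lc <- tryCatch(
      lag_correlation(ips[[i]]$values, ips[[j]]$values, grid_h,
                      lag_window_h = lag_window_h,
                      rho_threshold = rho_threshold, absolute = absolute),
      error = function(e) NULL)
    if (is.null(lc)) next
    rows[[length(rows) + 1]] <-
      data.frame(cluster_i = i, cluster_j = j, rho = lc$best_rho,
                 lag_h = lc$best_lag_h, significant = lc$significant)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
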