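times10 <- seq(0, 108, by = 12)

test_that("two-step filter keeps smooth responders and drops flat profiles", {
  tcs <- make_timecourse(2, 6, response_times_h = c(30, 78),
                         times_h = times10, noise_sd = 0,
                         shared_noise_sd = 0, seed = 1)
  flat <- matrix(7, 3, 10,
                 dimnames = list(paste0("flat", 1:3), NULL))
  tc <- timecourse(rbind(tcs$tc$values, flat), times10)
  kept <- timecourse_de_filter(tc, seed = 2, n_perm = 1999, alpha = 0.01)
  expect_false(any(grepl("flat", kept)))            # range rule
  expect_true(all(rownames(tcs$tc$values) %in% kept)) # noiseless sigmoids
  expect_error(timecourse_de_filter(timecourse(flat[, 1:3,
                                                    drop = FALSE],
                                               c(0, 12, 24))),
               "4 time points")
})

test_that("noise filter retains about alpha of pure-noise genes", {
  set.seed(3)
  noise <- matrix(rnorm(3000 * 10, 0, 0.5), 3000, 10)
  rng <- apply(noise, 1, function(v) diff(range(v)))
  noise <- noise[rng >= 1, , drop = FALSE][1:1000, ]
  rownames(noise) <- sprintf("n%04d", 1:1000)
  tc <- timecourse(noise, times10)
  kept <- timecourse_de_filter(tc, alpha = 0.001, seed = 4)
  expect_lte(length(kept), 6)   # ~1 expected at alpha = 0.001
})

test_that("PAM clustering recovers planted profile groups", {
  # two noiseless shape groups
  tcs <- make_timecourse(2, 10, response_times_h = c(30, 30),
                         directions = c(1, -1), noise_sd = 0.05,
                         shared_noise_sd = 0, seed = 5)
  cl <- cluster_profiles(tcs$tc, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(
    cl$membership, tcs$membership[names(cl$membership)]), 1)

  # k = 1: medoid minimizes total correlation distance (brute check)
  small <- timecourse(tcs$tc$values[1:12, ], times10)
  c1 <- cluster_profiles(small, k = 1, seed = 1)
  d <- 1 - cor(t(small$values))
  expect_equal(c1$medoid_genes,
               rownames(small$values)[which.min(colSums(d))])
  expect_error(cluster_profiles(small, k = 50, seed = 1), "exceed")
})

test_that("a planted 14-cluster course is recovered at high ARI", {
  t0 <- rep(c(6, 18, 30, 42, 54, 66, 78), 2)
  tcs <- make_timecourse(14, 10, response_times_h = t0,
                         noise_sd = 0.1, seed = 6)
  cl <- cluster_profiles(tcs$tc, k = 14, seed = 2)
  ari <- mclust::adjustedRandIndex(cl$membership,
                                   tcs$membership[names(cl$membership)])
  expect_gte(ari, 0.8)
})

test_that("interpolation is cubic, exact on lines, accurate on sines", {
  lin <- 2 * times10 + 1
  ip <- interpolate_profile(lin, times10)
  expect_equal(ip$values, 2 * ip$times_h + 1, tolerance = 1e-9)
  expect_length(ip$values, 100)
  expect_equal(ip$values[c(1, 100)], unname(lin[c(1, 10)]))

  tt <- seq(0, 2 * pi, length.out = 10)
  sp <- interpolate_profile(sin(tt), tt)
  expect_lt(max(abs(sp$values - sin(sp$times_h))), 0.05)

  expect_error(interpolate_profile(c(1, 2, 3), c(0, 0, 1)), "duplicate")
  expect_error(interpolate_profile(c(1, 2), c(0, 1)), "3 time points")
})

test_that("response classification follows the 50% dynamic-range rule", {
  step6 <- c(0, 2, 2, 2, 2, 2, 2, 2, 2, 2)   # jumps in (0, 12]
  r <- classify_response(step6, times10)
  expect_equal(r$response_class, "rapid")

  ramp <- seq(0, 2, length.out = 10)          # crosses half range at 54 h
  r2 <- classify_response(ramp, times10)
  expect_equal(r2$response_time_h, 54, tolerance = 1.2)
  expect_equal(r2$response_class, "unclassified")

  # ramp engineered to cross at 30 h: inside the empty 24-36 h band
  prof30 <- pmin(pmax(times10 / 60, 0), 1)
  r3 <- classify_response(prof30, times10)
  expect_equal(r3$response_time_h, 30, tolerance = 1.2)
  expect_equal(r3$response_class, "unclassified")

  # affine invariance
  m <- 2 * plogis(0.25 * (times10 - 42))
  r4 <- classify_response(m, times10)
  r5 <- classify_response(-3 * m + 11, times10)
  expect_equal(r4$response_time_h, r5$response_time_h)
  expect_equal(r4$response_class, "delayed")

  expect_error(classify_response(rep(1, 10), times10), "constant")
})

test_that("lag correlation finds planted shifts and honors the sign rule", {
  grid <- seq(0, 108, length.out = 100)
  gh <- diff(grid[1:2])
  f <- function(t) 2 * plogis(0.25 * (t - 40)) + 0.6 * sin(2 * pi * t / 30)
  p1 <- f(grid)
  p2 <- f(grid - 18)
  lc <- lag_correlation(p1, p2, gh)
  expect_gt(lc$best_rho, 0.99)
  expect_lte(abs(lc$best_lag_h - 18), gh + 1e-9)
  expect_true(lc$significant)

  # identical profiles: rho 1 at lag 0
  lc0 <- lag_correlation(p1, p1, gh)
  expect_equal(lc0$best_lag_h, 0)
  expect_equal(lc0$best_rho, 1)

  # anti-correlated pair is never significant under the signed maximum
  lcn <- lag_correlation(p1, -p1, gh)
  expect_lt(lcn$best_rho, 0)
  expect_false(lcn$significant)
  lca <- lag_correlation(p1, -p1, gh, absolute = TRUE)
  expect_true(lca$significant)

  # direction symmetry: (p1, p2) at L equals (p2, p1) at -L
  lc_rev <- lag_correlation(p2, p1, gh)
  expect_equal(lc_rev$best_lag_h, -lc$best_lag_h)
  expect_equal(lc_rev$best_rho, lc$best_rho)

  expect_error(lag_correlation(p1, p2[1:50], gh), "equal length")
  expect_error(lag_correlation(p1[1:5], p2[1:5], gh, min_overlap = 10),
               "overlap")
})

test_that("dynamic map flags exactly the planted pair in a 3-cluster design", {
  tcs <- make_timecourse(3, 20, response_times_h = c(24, 24, 60),
                         lags_h = data.frame(from = 1, to = 2, lag_h = 18),
                         directions = c(1, 1, -1), seed = 1)
  cl <- cluster_profiles(tcs$tc, k = 3, seed = 1)
  dyn <- build_dynamic_map(cl)
  med_truth <- tcs$membership[cl$medoid_genes]
  i1 <- which(med_truth == 1); i2 <- which(med_truth == 2)
  planted <- dyn$cluster_i == min(i1, i2) & dyn$cluster_j == max(i1, i2)
  expect_true(dyn$significant[planted])
  lag <- if (i1 < i2) dyn$lag_h[planted] else -dyn$lag_h[planted]
  expect_lte(abs(lag - 18), 6)   # within half a sampling interval
  expect_false(any(dyn$significant[!planted]))

  # independent noise clusters: no significant pair
  set.seed(9)
  noise <- matrix(rnorm(40 * 10, 0, 1), 40, 10,
                  dimnames = list(sprintf("x%02d", 1:40), NULL))
  cln <- cluster_profiles(timecourse(noise, times10), k = 5, seed = 2)
  dynn <- build_dynamic_map(cln)
  expect_false(any(dynn$significant))

  # single cluster: empty map
  c1 <- cluster_profiles(timecourse(noise[1:5, ], times10), k = 1, seed = 1)
  expect_equal(nrow(build_dynamic_map(c1)), 0)
})
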