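test_that("interactome generator: tree case, determinism, planted module", {
  net <- make_interactome(10, attach_m = 1, module_size = 3, seed = 1)
  expect_equal(igraph::vcount(net$graph), 10)
  expect_equal(igraph::ecount(net$graph), 9)  # m = 1 gives a tree
  expect_true(igraph::is_connected(net$graph))
  expect_length(net$truth$planted_module, 3)
  sub <- igraph::induced_subgraph(net$graph, net$truth$planted_module)
  expect_true(igraph::is_connected(sub))

  a <- make_interactome(60, 2, 8, seed = 7)
  b <- make_interactome(60, 2, 8, seed = 7)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$truth$planted_module, b$truth$planted_module)

  expect_error(make_interactome(10, 1, 10, seed = 1), "module_size")
})

test_that("interactome degree distribution is heavy-tailed", {
  net <- make_interactome(500, attach_m = 3, module_size = 30, seed = 2)
  deg <- igraph::degree(net$graph)
  expect_gt(max(deg), 5 * stats::median(deg))
  expect_true(igraph::is_simple(net$graph))
})

test_that("two-condition expression couples targets only in their condition", {
  net <- make_interactome(300, 3, 20, seed = 5)
  tr <- assign_condition_hubs(net$truth, 2, 2, 5, seed = 6)
  sim <- make_two_condition_expression(tr, 200, 200, target_corr = 0.9,
                                       noise_sd = 0.5, seed = 8)
  sa <- names(sim$expr$conditions)[sim$expr$conditions == "gradeII"]
  sb <- names(sim$expr$conditions)[sim$expr$conditions == "gradeIV"]
  for (h in tr$regulator_ids) {
    tg <- tr$condition_specific_targets[[h]]
    for (t in tg$A) {
      r_match <- cor(sim$expr$values[h, sa], sim$expr$values[t, sa])
      r_other <- cor(sim$expr$values[h, sb], sim$expr$values[t, sb])
      expect_gt(r_match, 0.8)
      expect_lt(r_match, 0.96)
      expect_lt(abs(r_other), 0.2)
    }
    for (t in tg$B) {
      expect_gt(cor(sim$expr$values[h, sb], sim$expr$values[t, sb]), 0.8)
      expect_lt(abs(cor(sim$expr$values[h, sa], sim$expr$values[t, sa])),
                0.2)
    }
  }
})

test_that("zero coupling noise degenerates to exact linear dependence", {
  net <- make_interactome(50, 2, 5, seed = 3)
  tr <- assign_condition_hubs(net$truth, 1, 0, 3, seed = 4)
  sim <- make_two_condition_expression(tr, 20, 20, target_corr = 0.999,
                                       noise_sd = 0, seed = 5)
  h <- tr$regulator_ids[1]
  t1 <- tr$condition_specific_targets[[h]]$A[1]
  sa <- names(sim$expr$conditions)[sim$expr$conditions == "gradeII"]
  expect_equal(cor(sim$expr$values[h, sa], sim$expr$values[t1, sa]), 1)
  expect_error(make_two_condition_expression(tr, 0, 10, seed = 1), "sample")
  expect_error(make_two_condition_expression(tr, 10, 10, target_corr = 1,
                                             seed = 1), "target_corr")
})

test_that("timecourse generator plants exact noiseless structure", {
  # noiseless: medoid crosses half range at the stated response time
  tcs <- make_timecourse(3, 5, response_times_h = c(48, 18, 6),
                         noise_sd = 0, shared_noise_sd = 0, seed = 1)
  cl <- cluster_profiles(tcs$tc, k = 3, seed = 1)
  grid_h <- diff(range(tcs$tc$times_h)) / 99
  resp <- cl$response[order(cl$response$response_time_h, decreasing = TRUE), ]
  expect_equal(resp$response_time_h, c(48, 18, 6),
               tolerance = grid_h * 1.01 / 6)
  expect_equal(resp$response_class, c("delayed", "intermediate", "rapid"))

  # noiseless planted lag: profiles are identical after the 18-h shift
  tcs2 <- make_timecourse(2, 3, response_times_h = c(24, 24),
                          lags_h = data.frame(from = 1, to = 2, lag_h = 18),
                          noise_sd = 0, shared_noise_sd = 0, seed = 2)
  # reference: an independent cluster whose response time is 24 + 18 h has
  # exactly the profile the lagged copy must follow
  ref <- make_timecourse(2, 3, response_times_h = c(24, 42),
                         directions = c(1, 1),
                         noise_sd = 0, shared_noise_sd = 0, seed = 2)
  expect_equal(unname(tcs2$tc$values[4, ]), unname(ref$tc$values[4, ]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(tcs2$tc$values[1, ]),
                                unname(tcs2$tc$values[4, ]))))

  # dimensions match the request
  tcs3 <- make_timecourse(14, 4, response_times_h = rep(c(6, 18, 42), len = 14),
                          seed = 3)
  expect_equal(dim(tcs3$tc$values), c(56, 10))
  expect_length(unique(tcs3$membership), 14)

  expect_error(make_timecourse(2, 3, response_times_h = c(6, 200), seed = 1),
               "span")
  expect_error(
    make_timecourse(2, 3, response_times_h = c(6, 18),
                    lags_h = data.frame(from = 1, to = 2, lag_h = 200),
                    seed = 1),
    "lag")
})

test_that("survival generator: censoring control and planted hazard", {
  st0 <- make_survival(50, surv_truth(2), censor_max = 0, seed = 1)
  expect_true(all(st0$event == 1))

  # null hazard ratio: median-split log-rank p is uniform
  pvals <- vapply(1:200, function(s) {
    st <- make_survival(60, surv_truth(1), seed = s)
    g <- st$covariate > stats::median(st$covariate)
    logrank_test(st, g)$p_value
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  expect_gt(mean(pvals), 0.4)

  # strong hazard ratio: high power
  rej <- vapply(1:50, function(s) {
    st <- make_survival(200, surv_truth(3), seed = s + 300)
    g <- st$covariate > stats::median(st$covariate)
    logrank_test(st, g)$p_value < 0.01
  }, logical(1))
  expect_gt(mean(rej), 0.9)

  expect_error(make_survival(1, surv_truth(2), seed = 1), "patients")
})

test_that("generators are bit-reproducible and truth validates", {
  s1 <- make_survival(30, surv_truth(2), seed = 9)
  s2 <- make_survival(30, surv_truth(2), seed = 9)
  expect_identical(s1$time, s2$time)
  t1 <- make_timecourse(2, 3, response_times_h = c(18, 60), seed = 4)
  t2 <- make_timecourse(2, 3, response_times_h = c(18, 60), seed = 4)
  expect_identical(t1$tc$values, t2$tc$values)

  expect_error(synthetic_truth("g1", regulator_ids = "g9"), "universe")
  expect_error(
    synthetic_truth(c("g1", "g2", "g3"),
                    regulator_ids = "g1",
                    condition_specific_targets =
                      list(g1 = list(A = "g2", B = "g2"))),
    "disjoint")
  expect_error(synthetic_truth("g1", hazard_ratio = -1), "hazard")
})
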