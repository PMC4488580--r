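test_that("MI estimator: worked values, symmetry, non-negativity", {
  set.seed(1)
  x <- rnorm(500); y <- rnorm(500)
  expect_lt(estimate_mi(x, y), 0.05)          # independence
  # identical vectors with 2 equal-frequency bins: plug-in MI is ln 2
  expect_equal(estimate_mi(x, x, n_bins = 2, correct = FALSE), log(2),
               tolerance = 1e-12)
  expect_identical(estimate_mi(x, y), estimate_mi(y, x))
  expect_gte(estimate_mi(x, y), 0)
  expect_equal(estimate_mi(rep(1, 20), rnorm(20)), 0)  # constant input
  # invariance under monotone transforms (rank binning)
  z <- rnorm(200); w <- z + rnorm(200, 0, 0.3)
  expect_equal(estimate_mi(z, w), estimate_mi(exp(z), w^3 + w))
  expect_error(estimate_mi(1:5, 1:5), "at least 8")
  expect_error(estimate_mi(1:10, 1:9), "equal length")
})

test_that("mi_threshold matches the empirical null quantile and is monotone", {
  thr05 <- mi_threshold(100, 0.05, n_perm = 10000, seed = 1)
  q95 <- stats::quantile(attr(thr05, "null"), 0.95, names = FALSE)
  expect_lt(abs(as.numeric(thr05) - q95), 0.1 * q95)

  thr01 <- mi_threshold(100, 0.01, n_perm = 2000, seed = 1)
  thr10 <- mi_threshold(100, 0.10, n_perm = 2000, seed = 1)
  thr1e5 <- mi_threshold(100, 1e-5, n_perm = 2000, seed = 1)
  expect_gte(as.numeric(thr1e5), as.numeric(thr01))
  expect_gte(as.numeric(thr01), as.numeric(thr10))
  # threshold decreases with sample size
  thr_small_n <- mi_threshold(30, 0.01, n_perm = 2000, seed = 2)
  thr_big_n <- mi_threshold(300, 0.01, n_perm = 2000, seed = 2)
  expect_gt(as.numeric(thr_small_n), as.numeric(thr_big_n))
  # determinism
  expect_identical(as.numeric(mi_threshold(50, 0.01, seed = 7)),
                   as.numeric(mi_threshold(50, 0.01, seed = 7)))
  expect_error(mi_threshold(50, 0.6, seed = 1), "alpha")
  expect_error(mi_threshold(50, 0.01, n_perm = 10, seed = 1),
               "permutations")
})

.make_net <- function(edges, hubs, condition = "A") {
  structure(list(condition = condition, hubs = hubs, edges = edges,
                 n_samples = 100, alpha = 1e-5, threshold = 0,
                 skipped_hubs = character()),
            class = "mi_network")
}

test_that("DPI removes exactly the weakest edge of a closed triangle", {
  tri <- data.frame(hub = c("h", "h", "x"), target = c("x", "y", "y"),
                    mi = c(0.9, 0.8, 0.1), p_value = 1e-6)
  pruned <- apply_dpi(.make_net(tri, "h"), tolerance = 0)
  expect_equal(nrow(pruned$edges), 2)
  expect_false(any(pruned$edges$mi == 0.1))

  # generous tolerance spares the weak edge: 0.1 >= 0.05 * 0.8
  kept <- apply_dpi(.make_net(tri, "h"), tolerance = 0.95)
  expect_equal(nrow(kept$edges), 3)

  # an open path has no triangle and passes through unchanged
  path <- data.frame(hub = c("h", "h"), target = c("x", "y"),
                     mi = c(0.9, 0.1), p_value = 1e-6)
  expect_equal(nrow(apply_dpi(.make_net(path, "h"))$edges), 2)

  expect_error(apply_dpi(.make_net(tri, "h"), tolerance = 1), "tolerance")
})

test_that("DPI never removes an edge that dominates all its triangles", {
  set.seed(3)
  for (rep in 1:10) {
    nodes <- paste0("n", 1:8)
    pairs <- t(utils::combn(nodes, 2))
    take <- runif(nrow(pairs)) < 0.5
    e <- data.frame(hub = pairs[take, 1], target = pairs[take, 2],
                    mi = runif(sum(take)), p_value = 1e-6)
    pruned <- apply_dpi(.make_net(e, nodes), tolerance = 0)
    # recompute which edges dominate every triangle they sit in
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mi_of <- setNames(e$mi, key(e$hub, e$target))
    for (i in seq_len(nrow(e))) {
      a <- e$hub[i]; b <- e$target[i]
      others <- setdiff(nodes, c(a, b))
      dominated <- FALSE
      for (c in others) {
        k1 <- key(a, c); k2 <- key(b, c)
        if (!is.na(mi_of[k1]) && !is.na(mi_of[k2]) &&
            e$mi[i] < min(mi_of[k1], mi_of[k2]))
          dominated <- TRUE
      }
      if (!dominated)
        expect_true(key(a, b) %in% key(pruned$edges$hub,
                                       pruned$edges$target))
    }
  }
})

test_that("hub networks recover planted condition-specific targets", {
  net <- make_interactome(200, 3, 15, seed = 41)
  tr <- assign_condition_hubs(net$truth, 1, 1, 10, seed = 42)
  sim <- make_two_condition_expression(tr, 150, 150, target_corr = 0.8,
                                       noise_sd = 0.5, seed = 43)
  hub_A <- names(tr$hub_side)[tr$hub_side == "A"]
  netA <- build_hub_network(sim$expr, "gradeII", tr$regulator_ids,
                            alpha = 1e-3, seed = 44)
  netB <- build_hub_network(sim$expr, "gradeIV", tr$regulator_ids,
                            alpha = 1e-3, seed = 45)
  partner <- function(net, h) {
    inc <- net$edges$hub == h | net$edges$target == h
    ifelse(net$edges$hub[inc] == h, net$edges$target[inc],
           net$edges$hub[inc])
  }
  planted <- tr$condition_specific_targets[[hub_A]]$A
  expect_gte(sum(partner(netA, hub_A) %in% planted), 8)
  expect_lte(length(partner(netB, hub_A)), 2)   # null side: few false edges

  # empty hub list gives an empty network; absent hubs are reported
  empty <- build_hub_network(sim$expr, "gradeII", character(), seed = 1)
  expect_equal(nrow(empty$edges), 0)
  skip_net <- build_hub_network(sim$expr, "gradeII",
                                c(hub_A, "not_a_gene"), alpha = 1e-3,
                                seed = 46)
  expect_equal(skip_net$skipped_hubs, "not_a_gene")
})

test_that("tightening alpha never adds edges", {
  net <- make_interactome(120, 3, 10, seed = 51)
  tr <- assign_condition_hubs(net$truth, 2, 0, 8, seed = 52)
  sim <- make_two_condition_expression(tr, 60, 60, seed = 53)
  loose <- build_hub_network(sim$expr, "gradeII", tr$regulator_ids,
                             alpha = 1e-2, seed = 54)
  tight <- build_hub_network(sim$expr, "gradeII", tr$regulator_ids,
                             alpha = 1e-4, seed = 54)
  expect_lte(nrow(tight$edges), nrow(loose$edges))
})

test_that("grade specificity computes the bounded degree contrast", {
  eA <- data.frame(hub = c(rep("h1", 2), rep("h2", 10)),
                   target = paste0("t", 1:12), mi = 0.5, p_value = 1e-6)
  eB <- data.frame(hub = c(rep("h1", 18), rep("h2", 2)),
                   target = paste0("u", 1:20), mi = 0.5, p_value = 1e-6)
  # equalize network totals so the contrast is pure degree arithmetic
  eA2 <- rbind(eA, data.frame(hub = "h3", target = paste0("f", 1:8),
                              mi = 0.5, p_value = 1e-6))
  netA <- .make_net(eA2, c("h1", "h2", "h3"), "gII")
  netB <- .make_net(eB, c("h1", "h2", "h3"), "gIV")
  prof <- grade_specificity(netA, netB, threshold = 0.4)
  # h1: 2/20 vs 18/20 -> d = -0.8 -> B-specific
  expect_equal(prof$d[prof$hub == "h1"], -0.8)
  expect_equal(prof$class[prof$hub == "h1"], "gIV")
  # h2: 10/20 vs 2/20 -> d = +2/3 -> A-specific
  expect_equal(prof$d[prof$hub == "h2"], (0.5 - 0.1) / 0.6)
  expect_equal(prof$class[prof$hub == "h2"], "gII")
  # h3: degree only in A -> d = +1
  expect_equal(prof$d[prof$hub == "h3"], 1)

  # equal degrees and totals: non-specific
  same <- .make_net(eA, c("h1", "h2"), "x")
  same2 <- .make_net(eA, c("h1", "h2"), "y")
  p2 <- grade_specificity(same, same2)
  expect_true(all(p2$d == 0))
  expect_true(all(p2$class == "non-specific"))

  # isolated hub in both networks: undefined, flagged
  netC <- .make_net(eA, c("h1", "h2", "h9"), "x")
  netD <- .make_net(eB, c("h1", "h2", "h9"), "y")
  p3 <- grade_specificity(netC, netD)
  expect_true(p3$undefined[p3$hub == "h9"])
  expect_equal(p3$class[p3$hub == "h9"], "non-specific")

  expect_error(grade_specificity(.make_net(eA, "h1"), .make_net(eB, "h2")),
               "hub list")
})
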