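test_that("bh_fdr matches the step-up formula on worked cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("bh_fdr is invariant under permutation of input order", {
  set.seed(1)
  p <- runif(50)
  perm <- sample.int(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # monotone non-decreasing in the p-value ordering
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("de_signature applies Welch tests and the selection conjunction", {
  set.seed(2)
  m <- matrix(rnorm(100 * 30, 8), 100, 30,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("s%02d", 1:30)))
  m[1:10, 16:30] <- m[1:10, 16:30] + 3     # strong DE, passes both rules
  m[11:15, 16:30] <- m[11:15, 16:30] + 0.4 # below the fold-change rule
  m[99, ] <- 5                             # zero variance everywhere
  expr <- expression_matrix(m, setNames(rep(c("lo", "hi"), each = 15),
                                        colnames(m)))
  sig <- de_signature(expr, "lo", "hi")
  expect_true(all(sig$selected[1:10]))
  expect_false(any(sig$selected[11:100]))
  expect_true(sig$zero_variance[99])
  expect_equal(sig$p_value[99], 1)
  # selection invariant: selected implies both thresholds
  expect_true(all(abs(sig$log2_fold_change[sig$selected]) > 1.5))
  expect_true(all(sig$q_value[sig$selected] < 0.01))

  # per-gene agreement with stats::t.test (Welch)
  for (g in c(1, 20, 50)) {
    tt <- t.test(m[g, 16:30], m[g, 1:15])
    expect_equal(sig$t_statistic[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(sig$p_value[g], tt$p.value, tolerance = 1e-10)
  }
  expect_error(de_signature(expr, "lo", "absent"), "condition")
})

test_that("identical groups yield null signature", {
  m <- matrix(rnorm(40 * 10, 8), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", 1:20)
  expr <- expression_matrix(m2, setNames(rep(c("a", "b"), each = 10),
                                         colnames(m2)))
  sig <- de_signature(expr, "a", "b")
  expect_equal(sig$log2_fold_change, rep(0, 40))
  expect_false(any(sig$selected))
})

test_that("DE selection is calibrated on label-permuted data", {
  net <- make_interactome(200, 3, 20, seed = 31)
  tr <- assign_condition_hubs(net$truth, 2, 2, 5, seed = 32)
  sim <- make_two_condition_expression(tr, 40, 40, n_de_genes = 40,
                                       seed = 33)
  set.seed(34)
  n_sel <- vapply(1:20, function(i) {
    cond <- setNames(sample(sim$expr$conditions),
                     names(sim$expr$conditions))
    perm <- expression_matrix(sim$expr$values, cond)
    sum(de_signature(perm, "gradeII", "gradeIV")$selected)
  }, numeric(1))
  expect_lte(mean(n_sel), 0.5)  # about zero false signatures at FDR 1%
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  expr <- expression_matrix(m, c(a = "x", b = "y"))
  qn <- quantile_normalize(expr)
  expect_equal(unname(qn$values[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, "b"]), c(2.5, 3.5, 4.5))

  set.seed(5)
  m2 <- matrix(rnorm(200, 8, 2), 50, 4,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expr2 <- expression_matrix(m2, setNames(rep("c", 4), colnames(m2)))
  qn2 <- quantile_normalize(expr2)
  sorted <- apply(qn2$values, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])

  # identical samples are a fixed point
  m3 <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9))
  rownames(m3) <- paste0("g", 1:3)
  expr3 <- expression_matrix(m3, c(s1 = "x", s2 = "x"))
  expect_equal(quantile_normalize(expr3)$values, expr3$values)

  m4 <- m3[, 1, drop = FALSE]
  expr4 <- expression_matrix(m4, c(s1 = "x"))
  expect_warning(quantile_normalize(expr4), "single")
})

test_that("cross-hybridization filter applies both removal rules", {
  tab <- data.frame(probe_id = c("keep_clean", "remove_abs", "keep_both",
                                 "remove_frac", "keep_zero"),
                    own_species_signal = c(1000, 1000, 400, 100, 0),
                    other_species_signal = c(0, 100, 60, 30, 0))
  res <- crosshyb_filter(tab)
  expect_setequal(res$kept$probe_id, c("keep_clean", "keep_both",
                                       "keep_zero"))
  expect_setequal(res$removed$probe_id, c("remove_abs", "remove_frac"))
  # keep_both: 60 <= 64 and 60/460 ~ 0.130 <= 0.15
  expect_lt(res$kept$contribution[res$kept$probe_id == "keep_both"], 0.15)
  expect_error(crosshyb_filter(data.frame(own_species_signal = -1,
                                          other_species_signal = 0)),
               "non-negative")
})

test_that("enrichment matches exact hypergeometric enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5))
  query <- paste0("g", 1:4)
  res <- enrichment(query, sets, universe)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_enum(10, 5, 4, 4), tolerance = 1e-12)

  # zero overlap: upper tail P(X >= 0) = 1
  res0 <- enrichment(paste0("g", 6:9), list(s = paste0("g", 1:3)), universe)
  expect_equal(res0$p_value, 1)
  # saturated query: overlap forced, p = 1
  res1 <- enrichment(universe, list(s = paste0("g", 1:5)), universe)
  expect_equal(res1$p_value, 1)
  expect_equal(res1$overlap, 5)

  expect_error(enrichment("g1", sets, character()), "universe")
  expect_error(enrichment("zz", sets, universe), "subset")
})

test_that("enrichment flag respects the FDR threshold over many sets", {
  set.seed(11)
  universe <- paste0("g", 1:60)
  query <- paste0("g", 1:12)
  sets <- c(list(real = paste0("g", 1:10)),
            lapply(setNames(1:20, paste0("rand", 1:20)),
                   function(i) sample(universe, 10)))
  res <- enrichment(query, sets, universe, fdr_threshold = 0.10)
  expect_true(res$enriched[res$set == "real"])
  expect_true(all(res$q_value[res$enriched] < 0.10))
})

test_that("gmt round trip preserves gene sets", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[order(names(back))], sets[order(names(sets))])
})
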