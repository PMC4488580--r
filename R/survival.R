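# Kaplan-Meier estimation, log-rank comparison, and the optimal
# covariate-cutpoint procedure: rank patients, scan every admissible
# binary split with a vectorized log-rank (Cox score) statistic, and
# adjust the minimum p-value for the scan by covariate permutation.

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the step function as a plain
#' table. `S(0) = 1`; with censored-only data the curve stays at 1.
#'
#' @param table a [survival_table()].
#' @return A `data.frame` of class `km_curve` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(table))
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom, via [survival::survdiff()]. Invariant under swapping the group
#' labels.
#'
#' @param table a [survival_table()].
#' @param groups vector with exactly two distinct values, one per patient.
#' @return list with `chi_square`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(table, groups) {
  stopifnot(inherits(table, "survival_table"))
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("need exactly two non-empty groups")
  df <- as.data.frame(table)
  df$g <- g
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(chi_square = unname(fit$chisq),
       p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
       observed = unname(fit$obs), expected = unname(fit$exp))
}

# Vectorized log-rank chi-square over many binary splits at once.
# `G`: n_patients x n_splits 0/1 membership matrix (group 1).
# Returns the chi-square per split (0 where the variance vanishes).
.logrank_scan <- function(time, event, G) {
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0) return(rep(0, ncol(G)))
  R <- outer(ut, time, function(t, x) x >= t) * 1      # at-risk
  Ev <- outer(ut, time, "==") * matrix(event, length(ut), length(time),
                                       byrow = TRUE)   # events at t_i
  d <- rowSums(Ev)
  n <- rowSums(R)
  N1 <- R %*% G                     # at-risk in group 1, per time x split
  O1 <- as.vector(crossprod(matrix(event, ncol = 1), G))
  E1 <- colSums(d * N1 / n)
  vterm <- d * (n - d) / pmax(n - 1, 1) * (N1 / n) * (1 - N1 / n)
  vterm[n <= 1, ] <- 0
  V <- colSums(vterm)
  ifelse(V > 0, (O1 - E1)^2 / V, 0)
}

#' Optimal survival cutpoint with permutation adjustment
#'
#' Ranks patients by the covariate and tests every binary split leaving at
#' least `min_group_fraction` of the cohort on each side with the log-rank
#' statistic (the score test of the binary-covariate Cox model, so
#' maximizing it maximizes the Cox model's significance). The split with
#' the smallest p-value is returned. Because the minimum p over a scan is
#' anti-conservative, a permutation-adjusted p-value is always reported
#' alongside: the covariate is permuted and the full scan repeated
#' `n_perm` times.
#'
#' @param table a [survival_table()] with >= 20 patients and a
#'   non-constant covariate.
#' @param min_group_fraction smallest admissible group fraction
#'   (default 0.1).
#' @param n_perm permutations for the adjusted p (default 200).
#' @param seed integer RNG seed.
#' @return An object of class `cutpoint_result`: list with `cut_rank`
#'   (size of the low group), `cut_value` (covariate midpoint of the
#'   boundary), `group_sizes`, `chi_square`, `p_value`, `p_adjusted`,
#'   `hazard_ratio`, `hr_ci` (95%), `scan` (per-split table).
#' @export
optimal_cutpoint <- function(table, min_group_fraction = 0.1, n_perm = 200,
                             seed = 1) {
  stopifnot(inherits(table, "survival_table"))
  n <- nrow(table)
  if (n < 20) stop("need at least 20 patients")
  if (stats::sd(table$covariate) == 0) stop("constant covariate")
  ord <- order(table$covariate, table$id)  # deterministic tie-break
  time <- table$time[ord]; event <- table$event[ord]
  lo <- max(1L, ceiling(n * min_group_fraction))
  hi <- min(n - 1L, floor(n * (1 - min_group_fraction)))
  if (lo > hi) stop("min_group_fraction leaves no admissible split")
  cuts <- lo:hi
  G <- outer(seq_len(n), cuts, ">")    # group 1 = above the cut
  chi <- .logrank_scan(time, event, G)
  best <- which.max(chi)
  k <- cuts[best]
  chi_best <- chi[best]
  p_raw <- stats::pchisq(chi_best, 1, lower.tail = FALSE)

  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    max(.logrank_scan(time[perm], event[perm], G))
  }, numeric(1))
  p_adj <- (sum(null_max >= chi_best) + 1) / (n_perm + 1)

  cov_sorted <- table$covariate[ord]
  grp <- as.integer(seq_len(n) > k)
  cox <- survival::coxph(survival::Surv(time, event) ~ grp)
  ci <- exp(stats::confint(cox))
  structure(list(cut_rank = k,
                 cut_value = mean(cov_sorted[k:(k + 1)]),
                 group_sizes = c(low = k, high = n - k),
                 chi_square = chi_best, p_value = p_raw,
                 p_adjusted = max(p_adj, p_raw),
                 hazard_ratio = unname(exp(stats::coef(cox))),
                 hr_ci = unname(ci[1, ]),
                 scan = data.frame(cut_rank = cuts, chi_square = chi,
                                   p_value = stats::pchisq(chi, 1,
                                     lower.tail = FALSE))),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "cutpoint_result: split at rank %d (low %d / high %d), HR = %.2f\n",
    x$cut_rank, x$group_sizes["low"], x$group_sizes["high"],
    x$hazard_ratio))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g, adjusted p = %.4g\n",
              x$chi_square, x$p_value, x$p_adjusted))
  invisible(x)
}

#' Survival comparison of predefined patient categories
#'
#' Kaplan-Meier curves per category and pairwise log-rank tests with BH
#' correction across the pairs. Categories with fewer than 2 patients are
#' dropped with a warning.
#'
#' @param table a [survival_table()].
#' @param group_labels one label per patient (>= 2 usable categories).
#' @return list with `km` (named list of `km_curve`s) and `pairs`
#'   (data.frame `group_a`, `group_b`, `chi_square`, `p_value`,
#'   `q_value`).
#' @export
fixed_group_compare <- function(table, group_labels) {
  stopifnot(inherits(table, "survival_table"))
  g <- as.character(group_labels)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping categories with < 2 patients: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    table <- table[keep, , drop = FALSE]
    class(table) <- c("survival_table", "data.frame")
    g <- g[keep]
  }
  cats <- sort(unique(g))
  if (length(cats) < 2) stop("need at least two usable categories")
  km <- lapply(setNames(cats, cats), function(cc)
    km_estimate(structure(table[g == cc, , drop = FALSE],
                          class = c("survival_table", "data.frame"))))
  pairs <- utils::combn(cats, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- g %in% pairs[, i]
    sub <- structure(table[sel, , drop = FALSE],
                     class = c("survival_table", "data.frame"))
    lr <- logrank_test(sub, g[sel])
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               chi_square = lr$chi_square, p_value = lr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  list(km = km, pairs = out)
}
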