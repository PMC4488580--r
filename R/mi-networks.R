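# Hub-anchored mutual-information networks (ARACNE-style): rank-binned MI
# estimation, permutation-calibrated significance thresholds with an
# exponential tail extrapolation, data-processing-inequality pruning, and
# the grade-specificity contrast of hub connectivity between conditions.

# equal-frequency bin labels; ties broken by position for determinism
.mi_bins <- function(x, n_bins) {
  ceiling(n_bins * rank(x, ties.method = "first") / length(x))
}

.mi_from_bins <- function(bx, by, n_bins, n, correct = TRUE) {
  joint <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins)
  pj <- joint / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  nz <- pj > 0
  outer_p <- as.vector(outer(px, py))
  mi <- sum(pj[nz] * log(pj[nz] / outer_p[nz]))
  if (correct) {
    # Miller-Madow bias correction on the entropy decomposition
    k_xy <- sum(nz); k_x <- sum(px > 0); k_y <- sum(py > 0)
    mi <- mi - (k_xy - k_x - k_y + 1) / (2 * n)
  }
  max(mi, 0)
}

#' Mutual information between two expression profiles
#'
#' Plug-in mutual information (in nats) from equal-frequency (rank) binning
#' with `B = max(2, floor(n^(1/3)))` bins by default, with Miller-Madow
#' bias correction and clipping at zero. Rank binning makes the estimate
#' invariant to monotone transforms of either profile; the estimator is
#' symmetric in its arguments. A constant vector carries no information and
#' returns 0.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param n_bins number of bins; `NULL` selects the cube-root default.
#' @param correct apply the Miller-Madow correction (default `TRUE`).
#' @return non-negative mutual information in nats.
#' @export
estimate_mi <- function(x, y, n_bins = NULL, correct = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8) stop("need at least 8 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  if (is.null(n_bins)) n_bins <- max(2L, floor(n^(1 / 3)))
  .mi_from_bins(.mi_bins(x, n_bins), .mi_bins(y, n_bins), n_bins, n, correct)
}

#' Permutation-calibrated mutual-information significance threshold
#'
#' Null distribution of the MI estimator between two independently shuffled
#' profiles of length `n_samples`, with an exponential fit to the upper
#' tail so thresholds for `alpha` far below `1/n_perm` (e.g. the 1e-5 to
#' 1e-8 cutoffs used for co-expression networks) can be extrapolated
#' without running millions of permutations. The tail model anchors at the
#' null's 90th percentile `t0` and uses the mean excess `theta` above it:
#' `threshold(alpha) = t0 + theta * log(0.1 / alpha)`, which is monotone
#' decreasing in `alpha` by construction.
#'
#' @param n_samples profile length the networks will be built from.
#' @param alpha tail probability, in (0, 0.5).
#' @param n_perm number of null permutations (>= 1000).
#' @param seed integer RNG seed.
#' @param n_bins bins forwarded to [estimate_mi()].
#' @return the MI threshold (nats), with the tail fit (`t0`, `theta`, `p0`)
#'   and the null sample attached as attributes for p-value assignment.
#' @export
mi_threshold <- function(n_samples, alpha, n_perm = 2000, seed = 1,
                         n_bins = NULL) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  if (n_perm < 1000) stop("need at least 1000 permutations")
  set.seed(seed)
  if (is.null(n_bins)) n_bins <- max(2L, floor(n_samples^(1 / 3)))
  null <- vapply(seq_len(n_perm), function(i) {
    .mi_from_bins(.mi_bins(stats::runif(n_samples), n_bins),
                  .mi_bins(stats::runif(n_samples), n_bins),
                  n_bins, n_samples)
  }, numeric(1))
  p0 <- 0.1
  t0 <- stats::quantile(null, 1 - p0, names = FALSE)
  excess <- null[null > t0] - t0
  theta <- if (length(excess)) mean(excess) else 1e-12
  thr <- t0 + theta * log(p0 / alpha)
  structure(thr, t0 = t0, theta = theta, p0 = p0, null = null,
            n_samples = n_samples)
}

# tail p-value of an observed MI under a fitted permutation null
.mi_pvalue <- function(mi, thr_fit) {
  t0 <- attr(thr_fit, "t0"); theta <- attr(thr_fit, "theta")
  p0 <- attr(thr_fit, "p0"); null <- attr(thr_fit, "null")
  ifelse(mi > t0,
         pmin(1, p0 * exp(-(mi - t0) / theta)),
         vapply(mi, function(m) mean(null >= m), numeric(1)))
}

#' Build a hub-anchored mutual-information network for one condition
#'
#' Computes MI between every declared hub and every other gene (including
#' the other hubs) on the samples of one condition, keeps the pairs whose
#' MI exceeds the permutation-calibrated threshold for `alpha`, and prunes
#' indirect edges with the data-processing inequality ([apply_dpi()]).
#' Hubs absent from the matrix are skipped and reported, not fatal.
#'
#' @param expr an [expression_matrix()].
#' @param condition condition label whose samples are used (>= 8 samples).
#' @param hubs character vector of hub gene identifiers.
#' @param alpha edge significance cutoff (default 1e-5).
#' @param tolerance DPI tolerance in \[0, 1) (default 0, strict).
#' @param seed integer RNG seed (threshold calibration).
#' @param n_perm permutations for the null (default 2000).
#' @return An object of class `mi_network`: list with `condition`, `hubs`,
#'   `edges` (data.frame `hub`, `target`, `mi`, `p_value`), `n_samples`,
#'   `alpha`, `threshold`, `skipped_hubs`.
#' @export
build_hub_network <- function(expr, condition, hubs, alpha = 1e-5,
                              tolerance = 0, seed = 1, n_perm = 2000) {
  samples <- condition_samples(expr, condition)
  if (length(samples) < 8) stop("need >= 8 samples in the condition")
  hubs <- unique(as.character(hubs))
  skipped <- setdiff(hubs, rownames(expr$values))
  hubs_use <- setdiff(hubs, skipped)
  x <- expr$values[, samples, drop = FALSE]
  n <- ncol(x)
  n_bins <- max(2L, floor(n^(1 / 3)))
  thr <- mi_threshold(n, alpha, n_perm = n_perm, seed = seed,
                      n_bins = n_bins)

  edges <- data.frame(hub = character(), target = character(),
                      mi = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(hubs_use)) {
    bins <- t(apply(x, 1, .mi_bins, n_bins = n_bins))
    genes <- rownames(x)
    hub_index <- match(hubs_use, genes)
    rows <- vector("list", length(hubs_use))
    for (i in seq_along(hubs_use)) {
      h <- hubs_use[i]
      # each unordered pair once: later hubs and all non-hub genes
      others <- c(hubs_use[-seq_len(i)], setdiff(genes, hubs_use))
      mi <- vapply(others, function(g) {
        .mi_from_bins(bins[hub_index[i], ], bins[match(g, genes), ],
                      n_bins, n)
      }, numeric(1))
      keep <- mi >= as.numeric(thr)
      rows[[i]] <- data.frame(hub = rep(h, sum(keep)), target = others[keep],
                              mi = unname(mi[keep]),
                              stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, rows)
    edges$p_value <- if (nrow(edges)) .mi_pvalue(edges$mi, thr) else numeric()
  }
  net <- structure(list(condition = condition, hubs = hubs_use,
                        edges = edges, n_samples = n, alpha = alpha,
                        threshold = as.numeric(thr),
                        skipped_hubs = skipped),
                   class = "mi_network")
  apply_dpi(net, tolerance = tolerance)
}

#' @export
print.mi_network <- function(x, ...) {
  cat("mi_network [", x$condition, "]: ", length(x$hubs), " hubs, ",
      nrow(x$edges), " edges (alpha ", format(x$alpha), ", n = ",
      x$n_samples, ")\n", sep = "")
  invisible(x)
}

#' Data-processing-inequality pruning
#'
#' For every triangle of edges fully present in the network, the weakest
#' edge is presumed indirect and removed: edge (i, j) is deleted iff
#' `MI_ij < (1 - tolerance) * min(MI_ik, MI_jk)` for some common neighbour
#' k. All triangles are evaluated against the pre-pruning network
#' (simultaneous, not sequential), so the outcome does not depend on
#' triangle order.
#'
#' @param net an `mi_network` (see [build_hub_network()]).
#' @param tolerance fraction in \[0, 1); larger values spare more edges.
#' @return the pruned `mi_network`.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  stopifnot(inherits(net, "mi_network"))
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must lie in [0, 1)")
  e <- net$edges
  if (is.null(e) || nrow(e) < 3) return(net)
  g <- igraph::graph_from_data_frame(e[, c("hub", "target")],
                                     directed = FALSE)
  igraph::E(g)$mi <- e$mi
  tri <- matrix(igraph::triangles(g), nrow = 3)
  if (ncol(tri) == 0) return(net)
  drop <- logical(igraph::ecount(g))
  for (t in seq_len(ncol(tri))) {
    vs <- tri[, t]
    eid <- igraph::get_edge_ids(g, c(vs[1], vs[2], vs[1], vs[3],
                                     vs[2], vs[3]))
    mi3 <- igraph::E(g)$mi[eid]
    weakest <- which.min(mi3)
    others <- mi3[-weakest]
    if (mi3[weakest] < (1 - tolerance) * min(others))
      drop[eid[weakest]] <- TRUE
  }
  # map igraph edge order back to the edge table rows
  el <- igraph::as_edgelist(g)
  key_g <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  key_e <- paste(pmin(e$hub, e$target), pmax(e$hub, e$target))
  net$edges <- e[!(key_e %in% key_g[drop]), , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Grade-specific hub connectivity
#'
#' Contrasts each hub's connectivity between two condition networks built
#' on the same hub list. Degrees are normalized by the total number of
#' hub-incident edges of their network (the two networks differ in size),
#' and the specificity statistic is the bounded contrast
#' `d = (k_A - k_B) / (k_A + k_B)` of the normalized degrees, positive
#' toward the first condition. Hubs with `|d|` above the threshold are
#' called condition-specific; hubs with zero degree in both networks have
#' undefined `d` and are reported as non-specific with a flag.
#'
#' @param net_A,net_B `mi_network` objects sharing the same hub list.
#' @param threshold specificity cutoff on `|d|` (default 0.4).
#' @return A `data.frame` of class `connectivity_profile`: `hub`,
#'   `degree_A`, `degree_B`, `k_hat_A`, `k_hat_B`, `d`, `class` (condition
#'   label or `"non-specific"`), `undefined`.
#' @export
grade_specificity <- function(net_A, net_B, threshold = 0.4) {
  stopifnot(inherits(net_A, "mi_network"), inherits(net_B, "mi_network"))
  if (!setequal(net_A$hubs, net_B$hubs))
    stop("the two networks must share the hub list")
  hubs <- sort(net_A$hubs)
  deg <- function(net, h) sum(net$edges$hub == h | net$edges$target == h)
  dA <- vapply(hubs, deg, numeric(1), net = net_A)
  dB <- vapply(hubs, deg, numeric(1), net = net_B)
  totA <- nrow(net_A$edges); totB <- nrow(net_B$edges)
  kA <- if (totA > 0) dA / totA else dA * 0
  kB <- if (totB > 0) dB / totB else dB * 0
  d <- ifelse(kA + kB == 0, NA_real_, (kA - kB) / (kA + kB))
  cls <- ifelse(is.na(d), "non-specific",
                ifelse(d > threshold, net_A$condition,
                       ifelse(d < -threshold, net_B$condition,
                              "non-specific")))
  structure(data.frame(hub = hubs, degree_A = dA, degree_B = dB,
                       k_hat_A = kA, k_hat_B = kB, d = d, class = cls,
                       undefined = is.na(d), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("connectivity_profile", "data.frame"),
            threshold = threshold,
            condition_A = net_A$condition, condition_B = net_B$condition)
}
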