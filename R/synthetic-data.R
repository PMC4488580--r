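#' Planted ground truth for the synthetic study
#'
#' Every generator returns (or consumes) a `synthetic_truth` object recording
#' what was planted: the designated hub genes, their condition-specific
#' target sets, the high-prize interactome module, the planted time-course
#' lags, and the gene whose level drives the survival hazard. Downstream
#' tests recover these plants; they are the ground truth real clinical data
#' cannot provide.
#'
#' @param gene_universe all gene identifiers in play.
#' @param regulator_ids hub gene identifiers.
#' @param condition_specific_targets named list (by hub) of
#'   `list(A = ..., B = ...)` target identifier vectors; the A and B sets of
#'   one hub must be disjoint.
#' @param planted_module identifiers of the planted high-prize module
#'   (connected in the generated interactome).
#' @param planted_lags data.frame with columns `from`, `to`, `lag_h`.
#' @param survival_gene identifier whose level multiplies the hazard.
#' @param hazard_ratio positive real.
#' @param seed integer RNG seed used by the generator.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(gene_universe, regulator_ids = character(),
                            condition_specific_targets = list(),
                            planted_module = character(),
                            planted_lags = NULL, survival_gene = NA_character_,
                            hazard_ratio = 1, seed = NA_integer_) {
  ids <- unique(c(regulator_ids, planted_module,
                  unlist(condition_specific_targets),
                  if (!is.na(survival_gene)) survival_gene))
  if (length(ids) && !all(ids %in% gene_universe))
    stop("truth references identifiers outside the gene universe")
  for (h in names(condition_specific_targets)) {
    tg <- condition_specific_targets[[h]]
    if (length(intersect(tg$A, tg$B)))
      stop("condition-specific target sets must be disjoint for hub ", h)
  }
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  structure(list(gene_universe = gene_universe,
                 regulator_ids = regulator_ids,
                 condition_specific_targets = condition_specific_targets,
                 planted_module = planted_module,
                 planted_lags = planted_lags,
                 survival_gene = survival_gene,
                 hazard_ratio = hazard_ratio,
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate a scale-free interactome with a planted connected module
#'
#' Emulates a protein-protein interaction network assembled from interaction
#' databases: a preferential-attachment (Barabasi-Albert) graph whose
#' heavy-tailed degree distribution makes hub detection meaningful. A
#' connected module of `module_size` nodes is planted by a randomized
#' breadth-first expansion from a random start node, so it is connected by
#' construction without altering the degree structure; optional extra
#' internal edges can densify it.
#'
#' @param n_nodes number of genes (nodes).
#' @param attach_m edges attached per new node (preferential attachment).
#' @param module_size size of the planted connected module; must be smaller
#'   than `n_nodes`.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param module_extra_density probability of adding each missing internal
#'   edge of the planted module (0 leaves the graph untouched).
#' @return list with `graph` (an igraph object, vertices named `g1..gN`) and
#'   `truth` (a [synthetic_truth()] with `planted_module` filled in).
#' @export
make_interactome <- function(n_nodes, attach_m = 3, module_size, seed,
                             module_extra_density = 0) {
  if (module_size >= n_nodes) stop("module_size must be < n_nodes")
  if (attach_m < 1) stop("attach_m must be >= 1")
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE,
                         algorithm = "psumtree")
  igraph::V(g)$name <- paste0("g", seq_len(n_nodes))

  # connected module via randomized BFS from a random start
  start <- sample(igraph::V(g)$name, 1)
  module <- start
  frontier <- start
  while (length(module) < module_size) {
    nb <- setdiff(unique(unlist(lapply(
      igraph::adjacent_vertices(g, frontier), names))), module)
    if (length(nb) == 0) { # dead end: restart frontier from module
      nb <- setdiff(unique(unlist(lapply(
        igraph::adjacent_vertices(g, module), names))), module)
    }
    take <- sample(nb, min(length(nb), module_size - length(module)))
    module <- c(module, take)
    frontier <- take
  }
  module <- sort(module)

  if (module_extra_density > 0) {
    pairs <- utils::combn(module, 2)
    have <- mapply(function(a, b) igraph::are_adjacent(g, a, b),
                   pairs[1, ], pairs[2, ])
    add <- which(!have & stats::runif(ncol(pairs)) < module_extra_density)
    if (length(add))
      g <- igraph::add_edges(g, as.vector(pairs[, add]))
    g <- igraph::simplify(g)
  }

  truth <- synthetic_truth(gene_universe = igraph::V(g)$name,
                           planted_module = module, seed = seed)
  list(graph = g, truth = truth)
}

#' Generate a two-condition expression matrix with condition-specific hubs
#'
#' Emulates a two-grade tumour expression study: each hub gene is linearly
#' coupled to its condition-A targets only in condition-A samples (and
#' analogously for B), at a controlled population correlation; all other
#' genes are independent Gaussian noise; a configurable subset of genes gets
#' a mean shift between conditions to create a differential-expression
#' signature.
#'
#' The coupling is `target = a * (hub - mean) + e`, with `a` chosen so that
#' the population Pearson correlation equals `target_corr` given the
#' residual standard deviation `noise_sd`; `noise_sd = 0` degenerates to an
#' exact copy of the hub profile (exact linear dependence).
#'
#' @param truth a [synthetic_truth()] carrying `regulator_ids` and
#'   `condition_specific_targets` (created here if absent: each hub gets
#'   `n_targets` A-targets and `n_targets` B-targets).
#' @param n_samples_A,n_samples_B samples per condition (both > 0).
#' @param target_corr population hub-target correlation, strictly in (0, 1).
#' @param noise_sd residual standard deviation of the coupling.
#' @param n_de_genes number of genes receiving a mean shift in condition B.
#' @param de_shift log2 mean shift applied to the DE genes (B minus A).
#' @param conditions length-2 character vector of condition labels (A, B).
#' @param baseline_mean baseline log2 expression level.
#' @param seed integer RNG seed.
#' @return list with `expr` (an [expression_matrix()]) and `truth` (the
#'   input truth, augmented with `de_genes` and target maps if generated).
#' @export
make_two_condition_expression <- function(truth, n_samples_A, n_samples_B,
                                          target_corr = 0.8, noise_sd = 1,
                                          n_de_genes = 0, de_shift = 2,
                                          conditions = c("gradeII", "gradeIV"),
                                          baseline_mean = 8, seed = 1) {
  if (n_samples_A < 1 || n_samples_B < 1)
    stop("both conditions need at least one sample")
  if (target_corr <= 0 || target_corr >= 1)
    stop("target_corr must be strictly between 0 and 1")
  set.seed(seed)
  genes <- truth$gene_universe
  n <- n_samples_A + n_samples_B
  samples <- sprintf("s%03d", seq_len(n))
  cond <- setNames(rep(conditions, c(n_samples_A, n_samples_B)), samples)

  m <- matrix(stats::rnorm(length(genes) * n, baseline_mean, 1),
              nrow = length(genes), dimnames = list(genes, samples))

  tg_map <- truth$condition_specific_targets
  hubs <- truth$regulator_ids
  if (length(hubs) && length(tg_map) == 0)
    stop("truth carries hubs but no condition_specific_targets")

  couple <- function(hub_vals, n_t, sd_res) {
    # rows: targets; population corr with hub = target_corr exactly
    if (sd_res == 0)
      return(matrix(rep(hub_vals, each = n_t), nrow = n_t))
    a <- target_corr / sqrt(1 - target_corr^2) * sd_res
    centred <- hub_vals - mean(hub_vals)
    sweep(matrix(stats::rnorm(n_t * length(hub_vals), 0, sd_res),
                 nrow = n_t), 2, -a * centred) + baseline_mean
  }
  idx_A <- seq_len(n_samples_A)
  idx_B <- n_samples_A + seq_len(n_samples_B)
  for (h in hubs) {
    tg <- tg_map[[h]]
    if (length(tg$A))
      m[tg$A, idx_A] <- couple(m[h, idx_A], length(tg$A), noise_sd)
    if (length(tg$B))
      m[tg$B, idx_B] <- couple(m[h, idx_B], length(tg$B), noise_sd)
  }

  de_genes <- character()
  if (n_de_genes > 0) {
    pool <- setdiff(genes, hubs)
    # planted-module genes first, so DE evidence accumulates on the module
    pool <- c(intersect(truth$planted_module, pool),
              sample(setdiff(pool, truth$planted_module)))
    de_genes <- pool[seq_len(min(n_de_genes, length(pool)))]
    m[de_genes, idx_B] <- m[de_genes, idx_B] + de_shift
  }
  truth$de_genes <- de_genes
  list(expr = expression_matrix(m, cond), truth = truth)
}

#' Default hub/target wiring for a two-condition study
#'
#' Convenience builder: designates `n_hubs_A + n_hubs_B` hub genes in an
#' existing universe and assigns each `n_targets` targets coupled only in
#' its own condition (A-hubs couple in A, B-hubs in B), mirroring a set of
#' regulators whose wiring switches with tumour grade.
#'
#' @param truth a [synthetic_truth()] (only its `gene_universe` is used).
#' @param n_hubs_A,n_hubs_B hubs active in condition A / condition B.
#' @param n_targets targets per hub.
#' @param seed integer RNG seed.
#' @return the truth, with `regulator_ids`, `condition_specific_targets` and
#'   `hub_side` (named "A"/"B" vector) filled in.
#' @export
assign_condition_hubs <- function(truth, n_hubs_A, n_hubs_B, n_targets,
                                  seed = 1) {
  set.seed(seed)
  genes <- truth$gene_universe
  n_h <- n_hubs_A + n_hubs_B
  need <- n_h * (1 + n_targets)
  if (need > length(genes)) stop("gene universe too small for requested hubs")
  picked <- sample(genes, need)
  hubs <- picked[seq_len(n_h)]
  rest <- picked[-seq_len(n_h)]
  side <- setNames(rep(c("A", "B"), c(n_hubs_A, n_hubs_B)), hubs)
  tg <- list()
  for (i in seq_along(hubs)) {
    t_i <- rest[(i - 1) * n_targets + seq_len(n_targets)]
    tg[[hubs[i]]] <- if (side[i] == "A") list(A = t_i, B = character())
                     else list(A = character(), B = t_i)
  }
  truth$regulator_ids <- hubs
  truth$condition_specific_targets <- tg
  truth$hub_side <- side
  truth
}

#' Generate a clustered sigmoidal expression time course with planted lags
#'
#' Emulates a tumour-implantation time course sampled on a regular grid.
#' Each cluster follows a latent trajectory: a logistic (sigmoid-in-time)
#' response crossing half its dynamic range at the cluster's response
#' time, plus a smooth cluster-wide fluctuation (a cubic spline through
#' Gaussian knots at the sampling times) representing shared biological
#' variation of co-regulated genes. Genes of a cluster are the latent
#' trajectory plus independent per-gene noise. Pairs listed in `lags_h`
#' are time-shifted copies: the `to` cluster re-executes the `from`
#' cluster's entire latent trajectory — sigmoid and shared fluctuation —
#' `lag_h` hours later, the signature a delay-correlation analysis is
#' meant to recover.
#'
#' With `noise_sd = 0` and `shared_noise_sd = 0` the construction is
#' noiseless: profiles are pure logistics and lagged clusters are exact
#' shifted copies.
#'
#' @param n_clusters number of clusters.
#' @param genes_per_cluster genes per cluster.
#' @param times_h strictly increasing sampling times (hours).
#' @param response_times_h length-`n_clusters` vector of half-range crossing
#'   times, each within the sampled span.
#' @param lags_h optional data.frame (`from`, `to`, `lag_h`) of planted
#'   lagged cluster pairs; lags must not exceed the time span.
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param shared_noise_sd SD of the smooth cluster-wide fluctuation.
#' @param amplitude dynamic range of each cluster profile (log2 units).
#' @param steepness logistic slope parameter (per hour); the default 0.25
#'   spreads the transition over roughly two sampling intervals of the
#'   default 12-h grid.
#' @param directions optional vector of +1/-1 response directions per
#'   cluster (default alternating); the direction of a lagged copy always
#'   follows its source.
#' @param seed integer RNG seed.
#' @return list with `tc` (a [timecourse()]), `truth` (planted lags and
#'   cluster membership) and `membership` (named integer vector).
#' @export
make_timecourse <- function(n_clusters, genes_per_cluster,
                            times_h = seq(0, 108, by = 12),
                            response_times_h, lags_h = NULL,
                            noise_sd = 0.12, shared_noise_sd = 0.35,
                            amplitude = 2, steepness = 0.25,
                            directions = NULL, seed = 1) {
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  if (length(response_times_h) != n_clusters)
    stop("need one response time per cluster")
  span <- range(times_h)
  if (any(response_times_h < span[1] | response_times_h > span[2]))
    stop("response times must lie within the sampled span")
  if (!is.null(lags_h) && any(abs(lags_h$lag_h) > diff(span)))
    stop("planted lag exceeds the time span")
  set.seed(seed)

  direction <- if (is.null(directions))
    rep(c(1, -1), length.out = n_clusters) else directions
  if (length(direction) != n_clusters || !all(direction %in% c(-1, 1)))
    stop("directions must be one +1/-1 value per cluster")
  t0 <- response_times_h
  # continuous latent trajectory per cluster; lagged clusters evaluate the
  # source cluster's trajectory at t - lag
  # fluctuation knots at twice the sampling interval: smoother than the
  # sampling rate, so a shifted copy is faithfully reconstructed from its
  # own samples (a fluctuation at the Nyquist edge would alias)
  step <- mean(diff(times_h))
  wknots <- seq(span[1] - 4 * step, span[2] + 4 * step, by = 2 * step)
  wiggle <- lapply(seq_len(n_clusters), function(c) {
    if (shared_noise_sd == 0) return(function(t) 0 * t)
    stats::splinefun(wknots, stats::rnorm(length(wknots), 0,
                                          shared_noise_sd), method = "fmm")
  })
  latent <- vector("list", n_clusters)
  for (c in seq_len(n_clusters)) {
    local({
      cc <- c
      latent[[cc]] <<- function(t)
        direction[cc] * amplitude * stats::plogis(steepness * (t - t0[cc])) +
          wiggle[[cc]](t)
    })
  }
  if (!is.null(lags_h)) {
    for (i in seq_len(nrow(lags_h))) {
      local({
        from <- lags_h$from[i]; to <- lags_h$to[i]; lag <- lags_h$lag_h[i]
        latent[[to]] <<- function(t) latent[[from]](t - lag)
      })
      t0[lags_h$to[i]] <- t0[lags_h$from[i]] + lags_h$lag_h[i]
      direction[lags_h$to[i]] <- direction[lags_h$from[i]]
    }
  }

  vals <- matrix(0, n_clusters * genes_per_cluster, length(times_h))
  membership <- rep(seq_len(n_clusters), each = genes_per_cluster)
  for (c in seq_len(n_clusters)) {
    rows <- which(membership == c)
    base <- matrix(rep(latent[[c]](times_h), each = length(rows)),
                   nrow = length(rows))
    vals[rows, ] <- base +
      matrix(stats::rnorm(length(base), 0, noise_sd), nrow = length(rows))
  }
  rownames(vals) <- sprintf("tg%04d", seq_len(nrow(vals)))
  names(membership) <- rownames(vals)
  tc <- timecourse(vals, times_h)
  truth <- synthetic_truth(gene_universe = rownames(vals),
                           planted_lags = lags_h, seed = seed)
  truth$cluster_membership <- membership
  truth$response_times_h <- t0
  list(tc = tc, truth = truth, membership = membership)
}

#' Generate survival data with a proportional-hazards link to one gene
#'
#' Exponential event times whose hazard is multiplied by
#' `truth$hazard_ratio` for patients whose covariate (the level of
#' `truth$survival_gene`) lies above the `split_quantile` of the cohort,
#' with independent uniform right-censoring.
#'
#' @param n_patients cohort size (>= 2).
#' @param truth a [synthetic_truth()] with a positive `hazard_ratio`.
#' @param baseline_hazard baseline exponential hazard (per day).
#' @param split_quantile covariate quantile above which the hazard is
#'   multiplied (0.5 = median split).
#' @param censor_max upper bound of the uniform censoring distribution in
#'   days; `0` disables censoring (all events observed).
#' @param seed integer RNG seed.
#' @return a [survival_table()]; the planted split rank is attached as
#'   attribute `planted_rank`.
#' @export
make_survival <- function(n_patients, truth, baseline_hazard = 0.01,
                          split_quantile = 0.5, censor_max = 2 / baseline_hazard,
                          seed = 1) {
  if (n_patients < 2) stop("need at least 2 patients")
  if (truth$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  set.seed(seed)
  covariate <- stats::rnorm(n_patients)
  cut <- stats::quantile(covariate, split_quantile, names = FALSE)
  high <- covariate > cut
  hazard <- baseline_hazard * ifelse(high, truth$hazard_ratio, 1)
  t_event <- stats::rexp(n_patients, hazard)
  if (censor_max > 0) {
    t_cens <- stats::runif(n_patients, 0, censor_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_patients)
  }
  out <- survival_table(sprintf("p%03d", seq_len(n_patients)),
                        pmax(time, 1e-8), event, covariate)
  attr(out, "planted_rank") <- sum(!high)
  out
}
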