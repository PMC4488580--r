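# End-to-end orchestration on synthetic data: one validated configuration
# object, per-stage seeds derived from a single global seed by stable
# hashing of stage names, every intermediate artifact written as
# plain-text, and a machine-readable run manifest.

.config_defaults <- function() list(
  global_seed = 1,
  out_dir = NULL,
  # synthetic study conditions
  n_nodes = 300, attach_m = 3, module_size = 25,
  n_hubs_A = 7, n_hubs_B = 7, n_targets_per_hub = 10,
  n_samples_A = 60, n_samples_B = 60, target_corr = 0.8, noise_sd = 0.5,
  n_de_genes = 60, de_shift = 2,
  n_clusters = 6, genes_per_cluster = 15, timecourse_noise_sd = 0.12,
  n_patients = 150, baseline_hazard = 0.01, hazard_ratio = 3,
  # stage thresholds (the printed defaults of the analysis)
  fc_threshold = 1.5, fdr_threshold = 0.01,
  enrichment_fdr = 0.10, min_module_size = 5,
  mi_alpha = 1e-3, mi_n_perm = 2000, dpi_tolerance = 0,
  specificity_threshold = 0.4,
  tc_min_log2_range = 1, tc_alpha = 0.001,
  rho_threshold = 0.9, lag_window_h = c(13, 24),
  bum_fdr = 0.05, beta = 1, gamma = 1, edge_cost = 1.5,
  module_n_perm = 50,
  cutpoint_min_fraction = 0.1, cutpoint_n_perm = 200,
  stages = c("simulate", "de", "ppi", "mi", "timecourse", "integrate",
             "survival"))

# lower bound, upper bound, lower bound inclusive?
.config_domains <- list(
  target_corr = list(0, 1, FALSE), specificity_threshold = list(0, 1, FALSE),
  rho_threshold = list(0, 1, FALSE), fdr_threshold = list(0, 1, FALSE),
  enrichment_fdr = list(0, 1, FALSE), bum_fdr = list(0, 1, FALSE),
  tc_alpha = list(0, 1, FALSE), mi_alpha = list(0, 0.5, FALSE),
  dpi_tolerance = list(0, 1, TRUE),
  cutpoint_min_fraction = list(0, 0.5, FALSE))

#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the pipeline — synthetic study conditions and
#' all stage thresholds — in one validated list. Unknown keys are
#' rejected; parameters with a bounded domain are range-checked.
#'
#' @param ... named overrides of the defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (nm in names(.config_domains)) {
    dom <- .config_domains[[nm]]
    v <- cfg[[nm]]
    low_bad <- if (dom[[3]]) v < dom[[1]] else v <= dom[[1]]
    if (!is.numeric(v) || any(low_bad | v >= dom[[2]]))
      stop(sprintf("'%s' must lie in %s%g, %g)", nm,
                   if (dom[[3]]) "[" else "(", dom[[1]], dom[[2]]))
  }
  bad_stage <- setdiff(cfg$stages, .config_defaults()$stages)
  if (length(bad_stage))
    stop("unknown stages: ", paste(bad_stage, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Derive a per-stage seed from the global seed
#'
#' Stable string hash of the stage name folded into the global seed, kept
#' below 2^31 so it is a valid R integer seed. Toggling one stage never
#' perturbs another stage's random stream.
#'
#' @param global_seed integer.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000000007
  as.integer((global_seed * 7919 + h) %% 2147483587 + 1)
}

#' Run the synthetic demonstration pipeline
#'
#' Executes the enabled stages in dependency order on generated data:
#' simulate -> differential expression -> interactome modularization
#' (percolation hubs, neighbour expansion, communities) -> per-condition
#' mutual-information networks and grade specificity -> time-course
#' filtering, clustering and the time-delay map -> evidence integration by
#' prize-collecting Steiner tree with significance -> survival cutpoint
#' analysis. Every intermediate artifact is written under `out_dir` as
#' plain text, together with `manifest.json` (parameters, per-stage seeds,
#' file digests) and a human-readable `run.log`.
#'
#' @param config a [pipeline_config()]; `out_dir` must be set.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir)) stop("config$out_dir must be set")
  need <- .config_defaults()$stages
  enabled <- need[need %in% config$stages]
  # dependency closure: everything downstream needs simulate + de
  deps <- list(de = "simulate", ppi = c("simulate", "de"),
               mi = c("simulate", "de"), timecourse = "simulate",
               integrate = c("simulate", "de", "timecourse"),
               survival = "simulate")
  for (st in enabled) {
    miss <- setdiff(deps[[st]], enabled)
    if (length(miss))
      stop(sprintf("stage '%s' requires disabled stage(s): %s",
                   st, paste(miss, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  out <- list()
  art <- function(name) file.path(config$out_dir, name)
  written <- character()
  note_file <- function(p) written <<- c(written, p)

  ## simulate -------------------------------------------------------------
  s_seed <- stage_seed(config$global_seed, "simulate")
  say("stage simulate (seed %d)", s_seed)
  net <- make_interactome(config$n_nodes, config$attach_m,
                          config$module_size, seed = s_seed)
  truth <- assign_condition_hubs(net$truth, config$n_hubs_A,
                                 config$n_hubs_B,
                                 config$n_targets_per_hub,
                                 seed = s_seed + 1)
  truth$survival_gene <- truth$planted_module[1]
  truth$hazard_ratio <- config$hazard_ratio
  sim <- make_two_condition_expression(
    truth, config$n_samples_A, config$n_samples_B,
    target_corr = config$target_corr, noise_sd = config$noise_sd,
    n_de_genes = config$n_de_genes, de_shift = config$de_shift,
    seed = s_seed + 2)
  truth <- sim$truth
  # response times spaced so that no unplanned same-direction cluster pair
  # differs by a window-admissible lag; cluster 2 is the planted 18-h
  # repeat of cluster 1
  tcs <- make_timecourse(config$n_clusters, config$genes_per_cluster,
                         response_times_h = rep_len(c(18, 18, 60, 6, 96, 102),
                                                    config$n_clusters),
                         lags_h = data.frame(from = 1, to = 2, lag_h = 18),
                         directions = rep_len(c(1, 1, -1, -1, 1, -1),
                                              config$n_clusters),
                         noise_sd = config$timecourse_noise_sd,
                         seed = s_seed + 3)
  surv <- make_survival(config$n_patients, truth,
                        baseline_hazard = config$baseline_hazard,
                        seed = s_seed + 4)
  note_file(write_graph_tsv(net$graph, art("interactome.tsv")))
  note_file(write_graphml(net$graph, art("interactome.graphml")))
  note_file(write_expression_tsv(sim$expr, art("expression.tsv")))
  note_file(write_timecourse_tsv(tcs$tc, art("timecourse.tsv")))
  note_file(write_survival_tsv(surv, art("survival.tsv")))
  note_file(write_truth_yaml(truth, art("truth.yaml")))
  out$truth <- truth; out$graph <- net$graph; out$expr <- sim$expr
  out$tc <- tcs$tc; out$tc_truth <- tcs$truth; out$surv <- surv
  conds <- unique(unname(sim$expr$conditions))

  ## differential expression ----------------------------------------------
  if ("de" %in% enabled) {
    say("stage de")
    sig <- de_signature(out$expr, conds[1], conds[2],
                        fc_threshold = config$fc_threshold,
                        fdr_threshold = config$fdr_threshold)
    utils::write.table(as.data.frame(sig), art("de_signature.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note_file(art("de_signature.tsv"))
    say("  %d genes selected", sum(sig$selected))
    out$signature <- sig
  }

  ## interactome modularization -------------------------------------------
  if ("ppi" %in% enabled) {
    p_seed <- stage_seed(config$global_seed, "ppi")
    say("stage ppi (seed %d)", p_seed)
    sub <- subset_by_signature(out$graph, out$signature)
    hubs_rep <- percolation_scores(sub)
    hub_nodes <- hubs_rep$node[hubs_rep$is_hub]
    expanded <- if (length(hub_nodes))
      expand_to_neighbours(sub, hub_nodes) else sub
    mods <- if (igraph::ecount(expanded) > 0)
      detect_communities(expanded, min_size = config$min_module_size,
                         seed = p_seed) else NULL
    utils::write.table(as.data.frame(hubs_rep), art("hub_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note_file(art("hub_report.tsv"))
    if (!is.null(mods)) {
      memb <- data.frame(node = names(mods$membership),
                         module = unname(mods$membership))
      utils::write.table(memb, art("communities.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note_file(art("communities.tsv"))
    }
    say("  %d hubs, %d communities", length(hub_nodes),
        if (is.null(mods)) 0L else length(mods$communities))
    out$hub_report <- hubs_rep; out$modules <- mods
  }

  ## mutual-information networks -------------------------------------------
  if ("mi" %in% enabled) {
    m_seed <- stage_seed(config$global_seed, "mi")
    say("stage mi (seed %d)", m_seed)
    hubs <- out$truth$regulator_ids
    netA <- build_hub_network(out$expr, conds[1], hubs,
                              alpha = config$mi_alpha,
                              tolerance = config$dpi_tolerance,
                              seed = m_seed, n_perm = config$mi_n_perm)
    netB <- build_hub_network(out$expr, conds[2], hubs,
                              alpha = config$mi_alpha,
                              tolerance = config$dpi_tolerance,
                              seed = m_seed + 1, n_perm = config$mi_n_perm)
    prof <- grade_specificity(netA, netB,
                              threshold = config$specificity_threshold)
    for (nm in c("A", "B")) {
      nn <- if (nm == "A") netA else netB
      f <- art(sprintf("mi_network_%s.tsv", nn$condition))
      utils::write.table(nn$edges, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_file(f)
    }
    utils::write.table(as.data.frame(prof), art("grade_specificity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note_file(art("grade_specificity.tsv"))
    say("  edges: %d (%s), %d (%s)", nrow(netA$edges), netA$condition,
        nrow(netB$edges), netB$condition)
    out$mi_A <- netA; out$mi_B <- netB; out$specificity <- prof
  }

  ## time course -------------------------------------------------------------
  if ("timecourse" %in% enabled) {
    t_seed <- stage_seed(config$global_seed, "timecourse")
    say("stage timecourse (seed %d)", t_seed)
    kept <- timecourse_de_filter(out$tc,
                                 min_log2_range = config$tc_min_log2_range,
                                 alpha = config$tc_alpha, seed = t_seed)
    tc_f <- timecourse(out$tc$values[kept, , drop = FALSE], out$tc$times_h)
    cl <- cluster_profiles(tc_f, k = config$n_clusters, seed = t_seed)
    dyn <- build_dynamic_map(cl, rho_threshold = config$rho_threshold,
                             lag_window_h = config$lag_window_h)
    memb <- data.frame(gene_id = names(cl$membership),
                       cluster = unname(cl$membership))
    utils::write.table(memb, art("tc_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cl$response, art("tc_response.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dyn, art("dynamic_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note_file(art("tc_clusters.tsv")); note_file(art("tc_response.tsv"))
    note_file(art("dynamic_map.tsv"))
    say("  %d genes kept, %d significant lag pairs", length(kept),
        sum(dyn$significant))
    out$tc_kept <- kept; out$tc_clusters <- cl; out$dynamic_map <- dyn
  }

  ## evidence integration -----------------------------------------------------
  if ("integrate" %in% enabled) {
    i_seed <- stage_seed(config$global_seed, "integrate")
    say("stage integrate (seed %d)", i_seed)
    p_de <- setNames(out$signature$p_value, out$signature$gene_id)
    fit <- fit_bum(p_de, fdr = config$bum_fdr)
    bait <- out$truth$planted_module[1]
    # interactor evidence: planted-module overlap stands in for an
    # immunoprecipitation hit list (60% of the module, plus decoys)
    set.seed(i_seed)
    mod <- out$truth$planted_module
    interactors <- c(sample(setdiff(mod, bait),
                            round(0.6 * (length(mod) - 1))),
                     sample(setdiff(out$truth$gene_universe, mod), 10))
    # co-expression evidence with the bait from the dynamic map: genes of
    # clusters lag-correlated with the bait's cluster get the |rho|
    coexpr <- setNames(rep(0.8, length(mod)), mod)
    prizes <- score_nodes(out$graph, p_de, interactors, coexpr, fit,
                          beta = config$beta, gamma = config$gamma)
    module <- solve_pcst(out$graph, prizes, bait,
                         edge_cost = config$edge_cost)
    sig <- module_significance(out$graph, prizes, module,
                               n_perm = config$module_n_perm,
                               seed = i_seed + 1)
    utils::write.table(as.data.frame(prizes), art("node_prizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mg <- igraph::graph_from_edgelist(module$edges, directed = FALSE)
    note_file(write_graphml(mg, art("steiner_module.graphml")))
    note_file(art("node_prizes.tsv"))
    mod_tab <- data.frame(node = module$nodes,
                          prize = unname(module$prizes),
                          in_planted = module$nodes %in% mod)
    utils::write.table(mod_tab, art("steiner_module.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note_file(art("steiner_module.tsv"))
    say("  module: %d nodes, net score %.2f, p_emp %.3g, p_param %.3g",
        length(module$nodes), module$net_score, sig$p_empirical,
        sig$p_parametric)
    out$bum <- fit; out$prizes <- prizes; out$module <- module
    out$module_significance <- sig
  }

  ## survival ------------------------------------------------------------------
  if ("survival" %in% enabled) {
    v_seed <- stage_seed(config$global_seed, "survival")
    say("stage survival (seed %d)", v_seed)
    cp <- optimal_cutpoint(out$surv,
                           min_group_fraction = config$cutpoint_min_fraction,
                           n_perm = config$cutpoint_n_perm, seed = v_seed)
    km <- km_estimate(out$surv)
    utils::write.table(cp$scan, art("cutpoint_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(km), art("km_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note_file(art("cutpoint_scan.tsv")); note_file(art("km_curve.tsv"))
    say("  cut at rank %d, log-rank p %.3g (adjusted %.3g)", cp$cut_rank,
        cp$p_value, cp$p_adjusted)
    out$cutpoint <- cp; out$km <- km
  }

  ## manifest -----------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("gliomanet")),
    global_seed = config$global_seed,
    stage_seeds = setNames(
      lapply(enabled, stage_seed, global_seed = config$global_seed),
      enabled),
    parameters = unclass(config)[setdiff(names(config),
                                         c("out_dir", "stages"))],
    stages = enabled,
    files = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  out$manifest <- manifest
  invisible(out)
}
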