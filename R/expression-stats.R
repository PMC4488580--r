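#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values, clipped to 1 and order-preserving
#' with the input positions. Thin wrapper around [stats::p.adjust()] kept so
#' the multiple-testing rule used across the pipeline lives behind one name.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; `NA` is an error.
#' @return q-values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values))) stop("NA p-values not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression signature between two conditions
#'
#' Per-gene Welch (unequal-variance) two-sample t-test between the samples
#' of `cond_A` and `cond_B`, Benjamini-Hochberg correction across genes, and
#' selection of genes passing both an absolute log2 fold-change threshold
#' and an FDR threshold. The fold change is `mean(cond_B) - mean(cond_A)` on
#' log2-scale data, so positive values are up in `cond_B`.
#'
#' Genes with zero variance in both groups cannot be tested; they get
#' `p = 1` and are flagged in the `zero_variance` column rather than raising
#' an error.
#'
#' @param expr an [expression_matrix()].
#' @param cond_A,cond_B condition labels present in `expr` (A is the
#'   reference, e.g. the lower grade).
#' @param fc_threshold absolute log2 fold-change cutoff (default 1.5).
#' @param fdr_threshold FDR cutoff (default 0.01, i.e. FDR < 1%).
#' @return A `data.frame` of class `gene_signature` with columns `gene_id`,
#'   `log2_fold_change`, `t_statistic`, `p_value`, `q_value`,
#'   `zero_variance`, `selected`; thresholds are kept as attributes.
#' @export
de_signature <- function(expr, cond_A, cond_B, fc_threshold = 1.5,
                         fdr_threshold = 0.01) {
  sa <- condition_samples(expr, cond_A)
  sb <- condition_samples(expr, cond_B)
  if (length(sa) < 2 || length(sb) < 2)
    stop("need at least 2 samples per condition")
  xa <- expr$values[, sa, drop = FALSE]
  xb <- expr$values[, sb, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  lfc <- mb - ma
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se2 == 0
  p[zero_var] <- 1
  tstat[zero_var] <- 0
  q <- bh_fdr(p)
  sig <- data.frame(gene_id = rownames(expr$values),
                    log2_fold_change = lfc, t_statistic = tstat,
                    p_value = p, q_value = q, zero_variance = zero_var,
                    selected = abs(lfc) > fc_threshold & q < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(sig, class = c("gene_signature", "data.frame"),
            fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
            cond_A = cond_A, cond_B = cond_B)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the identical empirical
#' distribution: the across-sample mean of the sorted columns, assigned
#' back by rank, with ties receiving the average of the reference values
#' over the tied ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr an [expression_matrix()].
#' @return the normalized [expression_matrix()]; a single-sample matrix is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 2) {
    warning("single sample: nothing to normalize")
    return(expr)
  }
  v <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(v) <- dimnames(expr$values)
  expression_matrix(v, expr$conditions)
}

#' Cross-hybridization probe filter
#'
#' Removes probes whose signal in the other species' reference
#' hybridization indicates cross-hybridization: a probe is removed iff the
#' other-species signal exceeds `abs_threshold` fluorescence units *or* its
#' relative contribution to the total signal,
#' `other / (own + other)`, exceeds `frac_threshold`. Probes with zero total
#' signal carry no evidence and are kept. Signals are assumed
#' background-subtracted (net).
#'
#' @param table data.frame with numeric columns `own_species_signal` and
#'   `other_species_signal` (non-negative) and optionally `probe_id`.
#' @param abs_threshold absolute other-species signal cutoff (default 64).
#' @param frac_threshold relative-contribution cutoff (default 0.15).
#' @return list with `kept` and `removed` data.frames (same columns as the
#'   input, plus the computed `contribution`).
#' @export
crosshyb_filter <- function(table, abs_threshold = 64, frac_threshold = 0.15) {
  own <- table$own_species_signal
  oth <- table$other_species_signal
  if (any(own < 0) || any(oth < 0)) stop("signals must be non-negative")
  total <- own + oth
  contribution <- ifelse(total == 0, 0, oth / total)
  remove <- oth > abs_threshold | contribution > frac_threshold
  table$contribution <- contribution
  list(kept = table[!remove, , drop = FALSE],
       removed = table[remove, , drop = FALSE])
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene set and each annotation set, within a stated universe; annotation
#' sets are intersected with the universe before testing and BH-corrected
#' across sets. A set is called enriched when its q-value falls below
#' `fdr_threshold` (default: FDR < 10%).
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param collections named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all testable genes.
#' @param fdr_threshold FDR cutoff for the `enriched` flag.
#' @return data.frame with one row per set: `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`, `enriched`.
#' @export
enrichment <- function(query, collections, universe, fdr_threshold = 0.10) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  res <- lapply(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), universe)
    k <- length(intersect(set, query))
    # P(X >= k), X ~ Hypergeom(|set| white, N - |set| black, |query| drawn)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = length(query),
               universe_size = length(universe), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out$enriched <- out$q_value < fdr_threshold
  out[order(out$p_value), , drop = FALSE]
}
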