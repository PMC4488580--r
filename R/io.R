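#' Read and write pipeline objects as plain-text files
#'
#' All tabular artifacts are tab-separated with a header row. Expression and
#' time-course matrices have the gene identifier in the first column; graphs
#' travel as two-column edge lists or GraphML; gene-set collections use the
#' GMT dialect (set name, description, then members, tab-separated); the
#' synthetic ground truth is a YAML sidecar.
#'
#' @param expr an [expression_matrix()].
#' @param path file path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name gliomanet-io
NULL

#' @rdname gliomanet-io
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cond_path <- paste0(path, ".conditions")
  utils::write.table(
    data.frame(sample_id = names(expr$conditions),
               condition = unname(expr$conditions)),
    cond_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cond <- utils::read.delim(paste0(path, ".conditions"),
                            stringsAsFactors = FALSE)
  expression_matrix(m, setNames(cond$condition, cond$sample_id))
}

#' @rdname gliomanet-io
#' @param tc a [timecourse()].
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  df <- data.frame(gene_id = rownames(tc$values), tc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_timecourse_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  timecourse(m, as.numeric(colnames(m)))
}

#' @rdname gliomanet-io
#' @param graph an `igraph` object with vertex names.
#' @export
write_graph_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_graph_tsv <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
  igraph::simplify(g)
}

#' @rdname gliomanet-io
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname gliomanet-io
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname gliomanet-io
#' @param sets named list of character vectors (gene sets).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gliomanet-io
#' @param table a [survival_table()].
#' @export
write_survival_tsv <- function(table, path) {
  stopifnot(inherits(table, "survival_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  survival_table(df$id, df$time, df$event, df$covariate)
}

#' @rdname gliomanet-io
#' @param truth a `synthetic_truth` object.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  if (!is.null(x$planted_lags))
    x$planted_lags <- lapply(seq_len(nrow(x$planted_lags)), function(i)
      as.list(x$planted_lags[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname gliomanet-io
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$planted_lags) && length(x$planted_lags))
    x$planted_lags <- do.call(rbind, lapply(x$planted_lags, as.data.frame))
  structure(x, class = "synthetic_truth")
}
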