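#' Construct a log2 expression matrix with condition labels
#'
#' The central expression container used throughout the pipeline: a numeric
#' genes-by-samples matrix on the log2 scale, plus a condition label per
#' sample (e.g. tumour grade). Row and column names are the gene and sample
#' identifiers; identifiers are opaque strings matched exactly.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames; all values must be finite.
#' @param conditions named character vector mapping every sample (column
#'   name) to a condition label.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `conditions`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, setNames(rep(c("A", "B"), each = 2), colnames(m)))
#' @export
expression_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  conditions <- conditions[colnames(values)]
  if (any(is.na(conditions)))
    stop("every sample needs a condition label")
  structure(list(values = values,
                 conditions = setNames(as.character(conditions),
                                       colnames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(table(x$conditions)),
                    table(x$conditions)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a time-course expression container
#'
#' @param values numeric matrix, genes x time points, log2 units, with gene
#'   rownames.
#' @param times_h strictly increasing numeric vector of sampling times in
#'   hours, one per column.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(values, times_h) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' needs unique gene rownames")
  if (length(times_h) != ncol(values))
    stop("length(times_h) must equal ncol(values)")
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing")
  if (!all(is.finite(values)))
    stop("all values must be finite")
  colnames(values) <- as.character(times_h)
  structure(list(values = values, times_h = as.numeric(times_h)),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("timecourse:", nrow(x$values), "genes,", length(x$times_h),
      "time points spanning", min(x$times_h), "-", max(x$times_h), "h\n")
  invisible(x)
}

#' Construct a per-patient survival table
#'
#' One row per patient: positive follow-up time, a binary event indicator
#' (1 = death observed, 0 = right-censored) and a real covariate such as the
#' expression or standardized copy-number value of a gene.
#'
#' @param id unique patient identifiers.
#' @param time positive follow-up times (days).
#' @param event 0/1 event indicators.
#' @param covariate numeric covariate driving the stratification.
#' @return A `data.frame` of class `survival_table`.
#' @export
survival_table <- function(id, time, event, covariate) {
  if (anyDuplicated(id)) stop("duplicate patient ids")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  structure(data.frame(id = as.character(id), time = as.numeric(time),
                       event = as.integer(event),
                       covariate = as.numeric(covariate),
                       stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

# samples of one condition, erroring on an unknown label
condition_samples <- function(expr, condition) {
  stopifnot(inherits(expr, "expression_matrix"))
  s <- names(expr$conditions)[expr$conditions == condition]
  if (length(s) == 0)
    stop("condition label not present in matrix: ", condition)
  s
}
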