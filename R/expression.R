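#' Expression matrix with sample group labels
#'
#' Genes-by-samples intensity matrix (unitless microarray-like scale) with a
#' group label per sample. Construction enforces the ingest invariants: no
#' missing values, unique gene and sample identifiers, and exactly one group
#' label per sample.
#'
#' @param values numeric matrix, rows = genes (rownames = symbols),
#'   columns = samples (colnames = sample identifiers).
#' @param groups named character vector mapping every sample to a group
#'   label (e.g. \code{"control"}, \code{"case"}, FIGO stage labels).
#' @return An object of class \code{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression values must not contain missing data")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse duplicates before construction")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  groups <- as.character(groups)[match(colnames(values), names(groups))]
  if (anyNA(groups))
    stop("every sample needs exactly one group label; missing: ",
         paste(colnames(values)[is.na(groups)], collapse = ", "))
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene symbols measured by an expression matrix
#' @param x an \code{ExpressionMatrix}.
#' @return Character vector of gene symbols.
#' @export
genes <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an \code{ExpressionMatrix}.
#' @return Character vector of sample identifiers.
#' @export
samples <- function(x) colnames(x$values)

#' Group labels of an expression matrix or functionome
#' @param x an \code{ExpressionMatrix} or \code{Functionome}.
#' @return Named character vector, sample -> group label.
#' @export
sample_groups <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x$groups)
  attr(x, "groups")
}

#' Restrict an expression matrix to a subset of samples
#'
#' @param x an \code{ExpressionMatrix}.
#' @param samples character vector of sample identifiers, or NULL.
#' @param group single group label selecting all its samples (alternative
#'   to \code{samples}).
#' @return An \code{ExpressionMatrix} containing the selected samples.
#' @export
subset_samples <- function(x, samples = NULL, group = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(samples)) {
    if (is.null(group)) stop("give either 'samples' or 'group'")
    samples <- names(x$groups)[x$groups == group]
  }
  missing <- setdiff(samples, colnames(x$values))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (!length(samples)) stop("no samples selected")
  ExpressionMatrix(x$values[, samples, drop = FALSE], x$groups[samples])
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}
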