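# Pairwise ordering comparison shared by template voting and index scoring.
# Ties in expression are broken deterministically: the lexicographically
# smaller gene symbol is deemed lower, identically on both sides.
.pair_less <- function(vi, vj, gi, gj) {
  vi < vj | (vi == vj & gi < gj)
}

#' Restrict a gene set collection to the genes measured by a matrix
#'
#' Each set's members are intersected with the measured genes, preserving
#' member order; sets that fall below \code{min_set_size} are dropped.
#' Pairwise ordering needs at least two genes, and very small sets give
#' coarse indices, so the default floor is 5.
#'
#' @param collection a \code{\link{GeneSetCollection}}.
#' @param matrix an \code{\link{ExpressionMatrix}}.
#' @param min_set_size minimum measured members a set must retain
#'   (default 5, floor 2).
#' @return The restricted \code{GeneSetCollection}.
#' @export
restrict_sets <- function(collection, matrix, min_set_size = 5L) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(matrix, "ExpressionMatrix"))
  if (min_set_size < 2L)
    stop("'min_set_size' must be >= 2: pairwise ordering needs gene pairs")
  measured <- genes(matrix)
  members <- lapply(collection$members, function(m) m[m %in% measured])
  keep <- lengths(members) >= min_set_size
  if (!any(keep))
    stop("no gene set retains >= ", min_set_size, " measured genes")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " of ", length(members),
            " sets dropped below min_set_size = ", min_set_size)
  GeneSetCollection(members[keep], collection$term_names[keep])
}

#' Build a pairwise-ordering template from control samples
#'
#' For every unordered gene pair in the set, each control sample votes by
#' strict comparison of the two expression values (expression ties broken
#' by gene symbol, see Details). The stored direction is the majority vote
#' — the most common gene expression ordering in the control group — and
#' the support is the fraction of controls voting that way. Exact 50/50
#' splits are stored with support 0.5 and the direction "lexicographically
#' smaller symbol is lower".
#'
#' @details The per-pair majority ordering maximizes total pairwise rank
#' agreement with the control cohort, so the template is the rank-ordering
#' the controls collectively conserve. Support always lies in [0.5, 1].
#'
#' @param controls an \code{\link{ExpressionMatrix}} already restricted to
#'   the control group (see \code{\link{subset_samples}}).
#' @param gene_set character vector of member gene symbols; all must be
#'   measured by \code{controls}.
#' @param set_id optional set identifier stored on the template.
#' @return An object of class \code{PairOrderTemplate} with fields
#'   \code{genes}, pair indices \code{i}/\code{j}, logical
#'   \code{direction} (TRUE means gene i's expression is below gene j's)
#'   and \code{support}.
#' @export
build_template <- function(controls, gene_set, set_id = NULL) {
  stopifnot(inherits(controls, "ExpressionMatrix"))
  if (ncol(controls$values) < 1L) stop("no control samples")
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, genes(controls))
  if (length(missing))
    stop("gene(s) not measured in controls: ",
         paste(missing, collapse = ", "))
  m <- length(gene_set)
  if (m < 2L) stop("a template needs at least 2 genes")
  V <- controls$values[gene_set, , drop = FALSE]
  pr <- utils::combn(m, 2L)
  ii <- pr[1L, ]; jj <- pr[2L, ]
  less <- .pair_less(V[ii, , drop = FALSE], V[jj, , drop = FALSE],
                     gene_set[ii], gene_set[jj])
  n <- ncol(V)
  n_less <- rowSums(less)
  direction <- ifelse(n_less * 2L == n, gene_set[ii] < gene_set[jj],
                      n_less * 2L > n)
  support <- pmax(n_less, n - n_less) / n
  structure(list(set_id = set_id, genes = gene_set,
                 i = ii, j = jj,
                 direction = as.logical(direction),
                 support = as.numeric(support)),
            class = "PairOrderTemplate")
}

#' @export
print.PairOrderTemplate <- function(x, ...) {
  cat("PairOrderTemplate", if (!is.null(x$set_id)) x$set_id else "",
      "\n  genes:", length(x$genes), " pairs:", length(x$i),
      "\n  mean support:", round(mean(x$support), 3), "\n")
  invisible(x)
}

#' Gene set regularity index of one sample
#'
#' The GSR index is the fraction of within-set gene pairs whose expression
#' ordering in the sample matches the control-derived template: 1 means the
#' set's regularity is fully conserved, 0 means every pair is ordered
#' opposite to the control majority (the most dysregulated state). In-sample
#' expression ties are broken by the same symbol rule used when voting.
#'
#' @param sample_values named numeric vector of expression values covering
#'   every template gene.
#' @param template a \code{PairOrderTemplate}.
#' @return A single number in [0, 1].
#' @export
gsr_index <- function(sample_values, template) {
  stopifnot(inherits(template, "PairOrderTemplate"))
  g <- template$genes
  if (is.null(names(sample_values)))
    stop("'sample_values' must be named by gene symbol")
  v <- sample_values[g]
  if (anyNA(v))
    stop("missing value(s) for template gene(s): ",
         paste(g[is.na(v)], collapse = ", "))
  less <- .pair_less(v[template$i], v[template$j],
                     g[template$i], g[template$j])
  mean(less == template$direction)
}

#' Build templates for every set of a collection
#'
#' One template per gene set, all from the same pooled control group.
#'
#' @param controls an \code{\link{ExpressionMatrix}} of control samples.
#' @param collection a restricted \code{\link{GeneSetCollection}} whose
#'   members are all measured (see \code{\link{restrict_sets}}).
#' @return Named list of \code{PairOrderTemplate}, one per set.
#' @export
build_templates <- function(controls, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  out <- lapply(names(collection), function(id)
    build_template(controls, collection$members[[id]], set_id = id))
  names(out) <- names(collection)
  out
}

#' Functionome: per-sample GSR indices over a gene set collection
#'
#' Scores every sample of the matrix against every set's template, giving
#' the functionome profile — the vector of GSR indices that quantifies each
#' sample's whole-collection ordering regularity relative to the controls.
#'
#' @param matrix an \code{\link{ExpressionMatrix}} (any group; the
#'   templates stay fixed).
#' @param collection the restricted \code{\link{GeneSetCollection}}.
#' @param templates named list of templates covering every set in the
#'   collection (see \code{\link{build_templates}}).
#' @return A numeric matrix of class \code{Functionome}, rows = samples,
#'   columns = set identifiers, entries in [0, 1]; the samples' group
#'   labels are kept in the \code{"groups"} attribute.
#' @export
functionome <- function(matrix, collection, templates) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(collection, "GeneSetCollection"))
  ids <- names(collection)
  if (!all(ids %in% names(templates)))
    stop("templates missing for set(s): ",
         paste(setdiff(ids, names(templates)), collapse = ", "))
  V <- matrix$values
  out <- vapply(ids, function(id) {
    tpl <- templates[[id]]
    g <- tpl$genes
    miss <- setdiff(g, rownames(V))
    if (length(miss))
      stop("set ", id, ": unmeasured gene(s) ",
           paste(miss, collapse = ", "))
    S <- V[g, , drop = FALSE]
    less <- .pair_less(S[tpl$i, , drop = FALSE], S[tpl$j, , drop = FALSE],
                       g[tpl$i], g[tpl$j])
    colMeans(less == tpl$direction)
  }, numeric(ncol(V)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = ncol(V), dimnames = list(colnames(V), ids))
  structure(out, groups = matrix$groups, class = c("Functionome", "matrix"))
}

#' Split a functionome by group label
#' @param profiles a \code{Functionome}.
#' @param group a group label present in the profiles' group attribute.
#' @return The sub-matrix of profiles for that group (plain matrix).
#' @export
profiles_for_group <- function(profiles, group) {
  grp <- attr(profiles, "groups")
  if (is.null(grp)) stop("profiles carry no group labels")
  sel <- names(grp)[grp == group]
  if (!length(sel)) stop("no samples in group: ", group)
  unclass(profiles)[sel, , drop = FALSE]
}

#' @export
print.Functionome <- function(x, ...) {
  cat("Functionome:", nrow(x), "samples x", ncol(x), "gene sets\n")
  cat("  GSR range:", round(min(x), 3), "-", round(max(x), 3), "\n")
  invisible(x)
}

#' Histogram table of GSR indices
#'
#' Bins all GSR entries of a profile matrix on [0, 1]; the per-group tables
#' mirror the usual functionome histogram report.
#'
#' @param profiles a \code{Functionome} or numeric matrix of GSR indices.
#' @param binwidth bin width on [0, 1] (default 0.02).
#' @return Data frame with \code{bin_low}, \code{bin_high}, \code{count}.
#' @export
gsr_histogram <- function(profiles, binwidth = 0.02) {
  stopifnot(binwidth > 0, binwidth <= 1)
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cnt <- table(cut(as.numeric(profiles), breaks = breaks,
                   include.lowest = TRUE, right = FALSE))
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1L],
             count = as.integer(cnt))
}
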