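#' Intersect per-group top-k pathway lists
#'
#' Finds every pathway identifier present in all groups' ordered top-k
#' lists, recording its 1-based rank within each group. With five disease
#' groups of serous ovarian tumors this is the screen that singles out the
#' pathway dysfunctional across the whole spectrum, e.g. aryl hydrocarbon
#' receptor binding (GO:0017162).
#'
#' @param lists named list, one ordered character vector of identifiers per
#'   group (best-ranked first); identifiers must be unique within a list.
#' @return Data frame with \code{set_id}, one \code{rank_<group>} column
#'   per group, \code{mean_rank} and \code{n_groups}, ordered by ascending
#'   mean rank (ties by identifier). Zero rows when no identifier is
#'   common to all groups.
#' @export
intersect_top_pathways <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need ordered lists for at least 2 groups")
  if (any(lengths(lists) == 0L)) stop("empty input list")
  for (nm in seq_along(lists)) {
    if (anyDuplicated(lists[[nm]]))
      stop("duplicate identifiers within a group list")
  }
  if (is.null(names(lists)))
    names(lists) <- paste0("group", seq_along(lists))
  common <- Reduce(intersect, lists)
  ranks <- vapply(lists, function(l) match(common, l),
                  integer(length(common)))
  if (length(common) == 1L) ranks <- matrix(ranks, nrow = 1L)
  out <- data.frame(set_id = common, stringsAsFactors = FALSE)
  if (length(common)) {
    colnames(ranks) <- paste0("rank_", names(lists))
    out <- cbind(out, as.data.frame(ranks))
    out$mean_rank <- rowMeans(ranks)
  } else {
    for (nm in names(lists)) out[[paste0("rank_", nm)]] <- integer(0)
    out$mean_rank <- numeric(0)
  }
  out$n_groups <- rep(length(lists), nrow(out))
  out <- out[order(out$mean_rank, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' EMT transcription-factor biomarker panel
#'
#' The epithelial-mesenchymal transition marker genes used for the
#' cross-check of selected genes: E-cadherin, beta-catenin, Snail, Slug
#' and Twist1.
#'
#' @return Character vector of gene symbols.
#' @export
emt_panel <- function() c("CDH1", "CTNNB1", "SNAI1", "SNAI2", "TWIST1")

#' Member genes of the aryl hydrocarbon receptor binding pathway
#'
#' The genes annotated to GO:0017162, the single pathway found
#' dysfunctional across all serous ovarian tumor groups.
#'
#' @return Character vector of gene symbols.
#' @export
ahr_pathway_genes <- function()
  c("AHR", "AIP", "ARNT", "ARNT2", "ARNTL",
    "NCOA1", "NCOA2", "TAF4", "TAF6", "TBP")

#' Annotation frequency of genes across selected GO terms
#'
#' Counts, for every gene, the number of selected terms annotating it —
#' the "repetitive frequency" used to pick the most relevant genes from a
#' group of regrouped GO terms — and flags membership of the EMT biomarker
#' panel for the cross-check.
#'
#' @param selected_terms character vector of set identifiers; every one
#'   must exist in \code{annotations}.
#' @param annotations a \code{\link{GeneSetCollection}}.
#' @param panel gene symbols flagged in the output (default
#'   \code{\link{emt_panel}()}).
#' @return Data frame \code{gene}, \code{count}, \code{emt_panel}, sorted
#'   by descending count then symbol. Zero rows for an empty selection.
#' @export
gene_frequency <- function(selected_terms, annotations,
                           panel = emt_panel()) {
  stopifnot(inherits(annotations, "GeneSetCollection"))
  selected_terms <- as.character(selected_terms)
  unknown <- setdiff(selected_terms, names(annotations))
  if (length(unknown))
    stop("unknown term identifier(s): ", paste(unknown, collapse = ", "))
  if (!length(selected_terms))
    return(data.frame(gene = character(0), count = integer(0),
                      emt_panel = logical(0), stringsAsFactors = FALSE))
  all_genes <- unlist(annotations$members[selected_terms], use.names = FALSE)
  tab <- table(all_genes)
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$emt_panel <- out$gene %in% panel
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply an external per-gene keep list
#'
#' Hook for filters computed outside the package (e.g. a survival screen
#' requiring a consistent effect on progression-free and overall
#' survival): restricts a gene frequency table to an externally supplied
#' keep list, preserving order.
#'
#' @param freq_table result of \code{\link{gene_frequency}}.
#' @param keep character vector of gene symbols to retain.
#' @return The filtered table.
#' @export
apply_gene_filter <- function(freq_table, keep) {
  freq_table[freq_table$gene %in% keep, , drop = FALSE]
}

#' Immunohistochemistry composite score
#'
#' The composite score multiplies the staining intensity grade I (integer
#' 0-3) by the percentage of positive cells P (0-100): Q = I x P, maximum
#' 300. Vectorized over paired inputs.
#'
#' @param intensity staining intensity grade(s), integers in 0..3.
#' @param percent percentage(s) of positive cells in [0, 100].
#' @return Data frame \code{intensity}, \code{percent}, \code{score}.
#' @examples
#' ihc_score(3, 100)$score  # 300, the maximum
#' @export
ihc_score <- function(intensity, percent) {
  if (length(intensity) != length(percent))
    stop("'intensity' and 'percent' must have equal length")
  if (any(!is.finite(intensity)) || any(intensity != as.integer(intensity)) ||
      any(intensity < 0) || any(intensity > 3))
    stop("'intensity' must be integer grades in 0..3")
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100))
    stop("'percent' must lie in [0, 100]")
  data.frame(intensity = as.integer(intensity),
             percent = as.numeric(percent),
             score = as.numeric(intensity) * as.numeric(percent))
}
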