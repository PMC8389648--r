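# Packaged reference tables for the serous ovarian tumor case study:
# published per-group top-50 dysfunctional pathway lists, the expert
# three-category regrouping of the 25 common dysregulated GO terms, and
# the per-category most-relevant genes. The category assignments are
# curated input, not something the pipeline computes.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "gsreg", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Published top-50 dysfunctional pathway lists for serous ovarian tumors
#'
#' The p-value-ranked top-50 GO-defined pathway lists for five disease
#' groups — serous borderline ovarian tumors and serous carcinomas at FIGO
#' stages I-IV — shipped as a reference fixture for the cross-group
#' intersection analysis.
#'
#' @param as_table if TRUE return the long data frame (\code{group},
#'   \code{rank}, \code{go_id}, \code{term}); otherwise a named list of
#'   five ordered GO identifier vectors, suitable for
#'   \code{\link{intersect_top_pathways}}.
#' @return A named list of character vectors, or a data frame.
#' @examples
#' lists <- top50_pathway_lists()
#' intersect_top_pathways(lists)
#' @export
top50_pathway_lists <- function(as_table = FALSE) {
  df <- .extdata("top50_pathways_serous.tsv")
  if (as_table) return(df)
  groups <- unique(df$group)
  out <- lapply(groups, function(g) {
    sub <- df[df$group == g, ]
    sub$go_id[order(sub$rank)]
  })
  names(out) <- groups
  out
}

#' Curated categories of the 25 common dysregulated GO terms
#'
#' The 25 GO terms found dysregulated across all serous ovarian tumor
#' groups, regrouped by expert curation into three functional categories
#' (cellular cycle/signaling, membrane/transport, and metabolic/
#' immunological/other effects). Consumed as fixture input.
#'
#' @return Data frame \code{go_id}, \code{term}, \code{category}.
#' @export
top25_term_categories <- function() .extdata("top25_terms_categories.tsv")

#' Per-category most relevant genes of the serous tumor case study
#'
#' The highest-annotation-frequency genes reported for each of the three
#' curated categories of \code{\link{top25_term_categories}}; packaged as
#' an expected-output reference for regression comparison of the
#' annotation-frequency gene selection.
#'
#' @return Data frame \code{category}, \code{gene}.
#' @export
category_top_genes <- function() .extdata("category_top_genes.tsv")
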