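#' Read a GMT gene set file
#'
#' One set per line: identifier, description, then one or more member gene
#' symbols, tab-separated (the MSigDB convention, e.g. the GO collection
#' \code{c5.all} used to define a functionome). Members are deduplicated
#' preserving first occurrence; the description becomes the term name and
#' may be empty.
#'
#' @param path path to a GMT file.
#' @return A \code{\link{GeneSetCollection}} preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated ",
         "fields (id, description, members...)")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set identifier(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  GeneSetCollection(members, term_names = vapply(fields, `[[`, "", 2L))
}

#' Write a gene set collection to GMT
#'
#' Inverse of \code{\link{read_gmt}}: re-reading the written file yields an
#' identical collection (ids, names, member order).
#'
#' @param collection a \code{GeneSetCollection}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection), function(id) {
    paste(c(id, collection$term_names[[id]], collection$members[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is tab-delimited with sample identifiers in the first
#' row and gene symbols in the first column. Any sample column containing a
#' missing or non-numeric cell is dropped entirely, with a warning naming
#' the sample: an expression profile with missing data is abandoned rather
#' than imputed. Duplicate gene symbols (multiple probes) are collapsed by
#' per-sample maximum. The groups file is tab-delimited with a header and
#' two columns, sample identifier and group label; every retained sample
#' must appear in it.
#'
#' @param matrix_path path to the tab-delimited expression matrix.
#' @param groups_path path to the tab-delimited sample/group table.
#' @return An \code{\link{ExpressionMatrix}}.
#' @export
read_expression <- function(matrix_path, groups_path) {
  if (!file.exists(matrix_path)) stop("file not found: ", matrix_path)
  if (!file.exists(groups_path)) stop("file not found: ", groups_path)
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  gene_col <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  num <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw))))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(raw))
  keep <- !apply(is.na(num), 2L, any)
  if (any(!keep))
    warning("dropped sample(s) with missing/non-numeric data: ",
            paste(sample_ids[!keep], collapse = ", "))
  if (!any(keep)) stop("no samples remain after dropping incomplete profiles")
  num <- num[, keep, drop = FALSE]
  colnames(num) <- sample_ids[keep]
  rownames(num) <- gene_col

  if (anyDuplicated(gene_col)) {
    # probe-level duplicates: per-sample maximum, first-occurrence row order
    mx <- do.call(rbind, lapply(unique(gene_col), function(g) {
      apply(num[gene_col == g, , drop = FALSE], 2L, max)
    }))
    rownames(mx) <- unique(gene_col)
    num <- mx
  }

  grp <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(grp) < 2L) stop("groups file needs sample and group columns")
  groups <- stats::setNames(grp[[2L]], grp[[1L]])
  missing <- setdiff(colnames(num), names(groups))
  if (length(missing))
    stop("sample(s) present in matrix but absent from groups file: ",
         paste(missing, collapse = ", "))
  ExpressionMatrix(num, groups[colnames(num)])
}

#' Write an expression matrix and its sample annotation
#'
#' @param x an \code{ExpressionMatrix}.
#' @param matrix_path output path for the tab-delimited matrix.
#' @param groups_path output path for the sample/group table.
#' @return The matrix path, invisibly.
#' @export
write_expression <- function(x, matrix_path, groups_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gdf <- data.frame(sample = names(x$groups), group = unname(x$groups),
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a minimal OBO ontology file into a GO graph
#'
#' Parses \code{[Term]} stanzas for \code{id:}, \code{name:}, \code{is_a:}
#' and \code{is_obsolete:} tags (the OBO 1.2 subset needed for term
#' clustering). Obsolete terms are skipped. Edges are directed child ->
#' parent \code{is_a} relations; a cyclic graph is rejected.
#'
#' @param path path to an OBO file.
#' @return A directed \code{igraph} graph; vertex attribute \code{name}
#'   holds GO identifiers, \code{term} the term names.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(g)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(0); terms <- character(0)
  edges <- character(0)
  for (s in seq_along(starts)) {
    blk <- lines[starts[s]:ends[s]]
    if (any(grepl("^is_obsolete: *true", blk))) next
    id <- sub("^id: *", "", grep("^id:", blk, value = TRUE)[1L])
    if (is.na(id)) next
    nm <- sub("^name: *", "", grep("^name:", blk, value = TRUE)[1L])
    if (is.na(nm)) nm <- ""
    ids <- c(ids, id); terms <- c(terms, nm)
    parents <- sub("^is_a: *([^ !]+).*$", "\\1",
                   grep("^is_a:", blk, value = TRUE))
    if (length(parents)) edges <- c(edges, rbind(id, parents))
  }
  # drop edges pointing at obsolete/unknown terms
  if (length(edges)) {
    em <- matrix(edges, ncol = 2L, byrow = TRUE)
    em <- em[em[, 2L] %in% ids, , drop = FALSE]
    edges <- as.vector(t(em))
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(ids, term = terms)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  if (!igraph::is_dag(g)) stop("cyclic is_a relations in OBO file")
  g
}

#' Write a result table with a commented provenance header
#'
#' All pipeline outputs are tab-delimited with a leading comment line
#' recording the package version and a short configuration note, so a
#' result file is self-describing.
#'
#' @param df a data frame.
#' @param path output path.
#' @param config optional short character note (e.g. a parameter summary)
#'   recorded in the header.
#' @return The path, invisibly.
#' @export
write_result_table <- function(df, path, config = "") {
  hdr <- sprintf("# gsreg %s%s", as.character(utils::packageVersion("gsreg")),
                 if (nzchar(config)) paste0("; ", config) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by \code{write_result_table}
#' @param path path to the tab-delimited file.
#' @return A data frame (comment lines skipped).
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
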