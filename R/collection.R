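#' Gene set collection
#'
#' A named, ordered collection of gene sets (typically GO terms), the index
#' set of the functionome. Each set has a unique identifier (e.g.
#' \code{"GO:0017162"}), a display name, and an ordered vector of unique
#' member gene symbols.
#'
#' @param members named list; one character vector of gene symbols per set,
#'   names are the set identifiers. Members are deduplicated preserving
#'   first occurrence.
#' @param term_names character vector of display names, one per set (recycled
#'   empty string if missing).
#' @return An object of class \code{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("A", "B", "C"), S2 = c("B", "D")),
#'                          term_names = c("first", "second"))
#' length(gsc)
#' set_members(gsc, "S1")
#' @export
GeneSetCollection <- function(members, term_names = NULL) {
  if (!is.list(members) || is.null(names(members)))
    stop("'members' must be a named list of character vectors")
  ids <- names(members)
  if (anyDuplicated(ids))
    stop("duplicate set identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  members <- lapply(members, function(m) unique(as.character(m)))
  sizes <- lengths(members)
  if (any(sizes < 1L))
    stop("every gene set must have at least one member after deduplication")
  if (is.null(term_names)) term_names <- rep("", length(ids))
  term_names <- as.character(term_names)
  if (length(term_names) != length(ids))
    stop("'term_names' must have one entry per set")
  names(term_names) <- ids
  structure(list(members = members, term_names = term_names),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$members)

#' @export
names.GeneSetCollection <- function(x) names(x$members)

#' Set identifiers of a collection
#' @param x a \code{GeneSetCollection}.
#' @return Character vector of set identifiers in file/definition order.
#' @export
set_ids <- function(x) names(x$members)

#' Members of one or all gene sets
#' @param x a \code{GeneSetCollection}.
#' @param id optional single set identifier; when omitted the full named
#'   list of member vectors is returned.
#' @return Character vector of gene symbols, or a named list of them.
#' @export
set_members <- function(x, id = NULL) {
  if (is.null(id)) return(x$members)
  if (!id %in% names(x$members)) stop("unknown set identifier: ", id)
  x$members[[id]]
}

#' Display names of the sets in a collection
#' @param x a \code{GeneSetCollection}.
#' @return Named character vector of term names.
#' @export
term_names <- function(x) x$term_names

#' @export
`[.GeneSetCollection` <- function(x, i) {
  ids <- names(x$members)
  if (is.character(i)) {
    missing <- setdiff(i, ids)
    if (length(missing))
      stop("unknown set identifier(s): ", paste(missing, collapse = ", "))
  }
  GeneSetCollection(x$members[i], x$term_names[i])
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection with", length(x), "sets\n")
  sz <- lengths(x$members)
  cat("  set sizes:", min(sz), "-", max(sz),
      "(median", stats::median(sz), ")\n")
  show <- utils::head(names(x), 3L)
  cat("  first sets:", paste(show, collapse = ", "),
      if (length(x) > 3L) "..." else "", "\n")
  invisible(x)
}
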