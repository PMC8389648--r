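#' Per-gene-set dysregulation test between a case group and controls
#'
#' For each gene set, the per-sample GSR indices of the case group are
#' compared with those of the control group by a two-sided Mann-Whitney
#' U-test, and the p-values are adjusted across all sets by the
#' Benjamini-Hochberg step-up procedure. The test is exact when the pooled
#' sample size is at most 20 and the values are tie-free, otherwise the
#' normal approximation with tie correction (and continuity correction) is
#' used. A set on which every sample of both groups has an identical GSR
#' value is maximally uninformative and is assigned p = 1 by convention.
#'
#' @param case_profiles,control_profiles numeric matrices of GSR indices
#'   (rows = samples, columns = set identifiers; see
#'   \code{\link{functionome}} and \code{\link{profiles_for_group}}).
#'   Both must share one set index.
#' @param alpha significance level on the adjusted values (default 0.05).
#' @return A data frame of class \code{DysregulationTable}, one row per
#'   set: \code{set_id}, \code{case_mean}, \code{control_mean}, \code{U},
#'   \code{p}, \code{q}, \code{significant}, \code{pvalue_rank} (rank of
#'   ascending p, ties broken by set identifier).
#' @export
compare_groups <- function(case_profiles, control_profiles, alpha = 0.05) {
  x <- as.matrix(unclass(case_profiles))
  y <- as.matrix(unclass(control_profiles))
  if (is.null(colnames(x)) || is.null(colnames(y)) ||
      !identical(colnames(x), colnames(y)))
    stop("case and control profiles must share one set index")
  if (nrow(x) < 2L || nrow(y) < 2L)
    stop("each group needs at least 2 samples")
  n1 <- nrow(x); n2 <- nrow(y)
  res <- lapply(seq_len(ncol(x)), function(k) {
    a <- x[, k]; b <- y[, k]
    if (max(a, b) == min(a, b))  # complete ties: no evidence either way
      return(c(U = n1 * n2 / 2, p = 1))
    exact <- (n1 + n2 <= 20L) && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    c(U = unname(wt$statistic), p = min(wt$p.value, 1))
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  out <- data.frame(set_id = colnames(x),
                    case_mean = colMeans(x),
                    control_mean = colMeans(y),
                    U = res[, "U"], p = res[, "p"], q = q,
                    significant = q < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pvalue_rank <- rank_with_id_ties(out$p, out$set_id)
  attr(out, "alpha") <- alpha
  class(out) <- c("DysregulationTable", "data.frame")
  out
}

# deterministic 1..K ranking: ascending key, ties by identifier
rank_with_id_ties <- function(key, id) {
  ord <- order(key, id)
  rk <- integer(length(key))
  rk[ord] <- seq_along(key)
  rk
}

#' Grand mean GSR of a group, alongside the control mean
#'
#' Averages every GSR index over all sets and samples in the group; the
#' control group's grand mean is reported alongside for reference, as in
#' the usual per-group functionome summaries.
#'
#' @param profiles numeric matrix of the group's GSR indices.
#' @param control_profiles numeric matrix of the control group's indices.
#' @param group label recorded on the output (default \code{"case"}).
#' @return A one-row data frame: \code{group}, \code{mean_gsr},
#'   \code{sd_gsr}, \code{control_mean_gsr}, \code{control_sd_gsr},
#'   \code{n_samples}, \code{n_control_samples}, \code{n_sets}.
#' @export
group_summary <- function(profiles, control_profiles, group = "case") {
  x <- as.matrix(unclass(profiles))
  y <- as.matrix(unclass(control_profiles))
  if (length(x) == 0L || length(y) == 0L)
    stop("empty profile collection")
  data.frame(group = group,
             mean_gsr = mean(x), sd_gsr = stats::sd(as.numeric(x)),
             control_mean_gsr = mean(y),
             control_sd_gsr = stats::sd(as.numeric(y)),
             n_samples = nrow(x), n_control_samples = nrow(y),
             n_sets = ncol(x), stringsAsFactors = FALSE)
}

#' Cluster weight index (CWI) for significant gene sets
#'
#' Each significant term (q below \code{alpha}) receives the weight
#' \code{w = -log10(max(q, epsilon))}; its CWI is that weight divided by
#' the total weight of all clustered significant terms, so the CWI values
#' sum to one and rank terms by their share of the total dysregulation
#' evidence. Clusters are the connected components of the subgraph that
#' the significant terms induce on the GO graph's (undirected) is_a edges;
#' with no graph supplied all significant terms form one global cluster.
#' Optionally each weight is multiplied by the absolute classifier weight
#' of the term, tying the ranking to a fitted SVM.
#'
#' @param table a \code{DysregulationTable} from
#'   \code{\link{compare_groups}}.
#' @param graph optional GO graph from \code{\link{read_obo}}.
#' @param alpha significance level on q (default 0.05).
#' @param epsilon floor applied to q before taking logs, preventing
#'   infinite weights at q = 0 (default 1e-16).
#' @param svm_weights optional named numeric vector of per-set classifier
#'   weights; absolute values multiply the log-q weights.
#' @return The table with \code{weight}, \code{cluster_id}, \code{cwi} and
#'   \code{cwi_rank} columns filled: CWI is 0 and the rank NA for
#'   non-significant terms; rank ties are broken by set identifier.
#' @export
compute_cwi <- function(table, graph = NULL, alpha = 0.05,
                        epsilon = 1e-16, svm_weights = NULL) {
  stopifnot(inherits(table, "DysregulationTable") || is.data.frame(table))
  if (!all(c("set_id", "q") %in% names(table)))
    stop("table must carry 'set_id' and 'q' columns")
  sig <- table$q < alpha
  w <- rep(0, nrow(table))
  w[sig] <- -log10(pmax(table$q[sig], epsilon))
  if (!is.null(svm_weights)) {
    sw <- abs(svm_weights[table$set_id])
    sw[is.na(sw)] <- 0
    w <- w * sw
  }
  cluster_id <- rep(NA_integer_, nrow(table))
  if (any(sig)) {
    if (is.null(graph)) {
      cluster_id[sig] <- 1L
    } else {
      ids <- table$set_id[sig]
      in_graph <- ids[ids %in% igraph::V(graph)$name]
      sub <- igraph::induced_subgraph(igraph::as_undirected(graph), in_graph)
      comp <- igraph::components(sub)
      memb <- comp$membership[in_graph]
      cl <- rep(NA_integer_, length(ids))
      cl[ids %in% in_graph] <- memb
      # significant terms absent from the graph: own singleton clusters
      n_known <- if (length(memb)) max(memb) else 0L
      orphan <- is.na(cl)
      cl[orphan] <- n_known + seq_len(sum(orphan))
      cluster_id[sig] <- cl
    }
  } else {
    message("no significant terms at alpha = ", alpha,
            "; empty CWI ranking")
  }
  total <- sum(w[sig])
  cwi <- rep(0, nrow(table))
  if (any(sig) && total > 0) cwi[sig] <- w[sig] / total
  cwi_rank <- rep(NA_integer_, nrow(table))
  if (any(sig)) {
    rk <- rank_with_id_ties(-cwi[sig], table$set_id[sig])
    cwi_rank[sig] <- rk
  }
  table$weight <- w
  table$cluster_id <- cluster_id
  table$cwi <- cwi
  table$cwi_rank <- cwi_rank
  table
}

#' Top dysregulated terms ranked by CWI
#'
#' @param table a table with \code{cwi} filled (see
#'   \code{\link{compute_cwi}}).
#' @param k number of terms to keep (default 50).
#' @return The significant rows sorted by descending CWI (ties by set
#'   identifier), truncated to \code{k}.
#' @export
top_terms <- function(table, k = 50L) {
  if (k < 1L) stop("'k' must be >= 1")
  if (!"cwi" %in% names(table)) stop("run compute_cwi() first")
  sig <- table[!is.na(table$cwi_rank), , drop = FALSE]
  sig <- sig[order(sig$cwi_rank), , drop = FALSE]
  utils::head(sig, k)
}

#' Rank dysfunctional pathways by p-value
#'
#' Pathways (GO-defined gene sets) are ordered by ascending dysregulation
#' p-value, ties broken by set identifier, and truncated to the top
#' \code{k}. The pathway screen uses the unadjusted p-value at the stated
#' threshold by default — a deliberately less stringent counting than the
#' q-based term ranking — with the adjusted variant available.
#'
#' @param table a \code{DysregulationTable}.
#' @param k list length (default 50).
#' @param alpha significance threshold (default 0.05).
#' @param adjusted if TRUE threshold the BH-adjusted q instead of raw p.
#' @return Data frame \code{set_id}, \code{p}, \code{rank}; fewer than
#'   \code{k} rows when fewer pathways are significant.
#' @export
rank_pathways <- function(table, k = 50L, alpha = 0.05, adjusted = FALSE) {
  if (k < 1L) stop("'k' must be >= 1")
  keep <- if (adjusted) table$q < alpha else table$p < alpha
  sig <- table[keep, , drop = FALSE]
  sig <- sig[order(sig$p, sig$set_id), , drop = FALSE]
  sig <- utils::head(sig, k)
  data.frame(set_id = sig$set_id, p = sig$p,
             rank = seq_len(nrow(sig)),
             stringsAsFactors = FALSE, row.names = NULL)
}
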