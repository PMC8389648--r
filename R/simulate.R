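#' Configuration for a synthetic two-group cohort
#'
#' Describes a control/case expression cohort in which a chosen fraction of
#' gene sets lose their within-set expression ordering in the case group.
#' Control samples are distinct gene baselines plus Gaussian measurement
#' noise; case samples are identical except that, within each dysregulated
#' set and independently per case sample, \code{ceiling(scramble_intensity
#' * m)} of the set's \code{m} genes have their baselines randomly permuted
#' among themselves before noise is added. Ordering regularity is thus
#' destroyed with controlled intensity while the marginal intensity
#' distribution is untouched.
#'
#' @param n_sets number of gene sets.
#' @param set_size genes per set (>= 2).
#' @param n_controls,n_cases samples per group.
#' @param frac_dysregulated fraction f of sets scrambled in cases;
#'   \code{round(f * n_sets)} sets are flagged.
#' @param scramble_intensity theta in [0, 1]; fraction of each dysregulated
#'   set's genes whose baselines are permuted per case sample.
#' @param noise_sd additive Gaussian noise SD, on the baseline scale
#'   (baselines are uniform on [0, 10]).
#' @param n_genes total genes (default exactly covers the disjoint sets).
#' @param seed integer RNG seed; mandatory, the cohort is a pure function
#'   of the configuration.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(n_sets = 200L, set_size = 10L,
                       n_controls = 30L, n_cases = 30L,
                       frac_dysregulated = 0.2, scramble_intensity = 1,
                       noise_sd = 0.1, n_genes = n_sets * set_size,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  cfg <- list(n_sets = as.integer(n_sets), set_size = as.integer(set_size),
              n_controls = as.integer(n_controls),
              n_cases = as.integer(n_cases),
              frac_dysregulated = as.numeric(frac_dysregulated),
              scramble_intensity = as.numeric(scramble_intensity),
              noise_sd = as.numeric(noise_sd),
              n_genes = as.integer(n_genes), seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_sets, set_size, n_controls, n_cases, n_genes) < 1L))
      stop("all counts must be positive")
    if (set_size < 2L) stop("'set_size' must be >= 2")
    if (frac_dysregulated < 0 || frac_dysregulated > 1)
      stop("'frac_dysregulated' must lie in [0, 1]")
    if (scramble_intensity < 0 || scramble_intensity > 1)
      stop("'scramble_intensity' must lie in [0, 1]")
    if (noise_sd < 0) stop("'noise_sd' must be >= 0")
    if (n_genes < n_sets * set_size)
      stop("infeasible geometry: disjoint sets need n_genes >= ",
           "n_sets * set_size")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-group cohort with known dysregulated gene sets
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with components \code{matrix}
#'   (\code{\link{ExpressionMatrix}}, groups \code{"control"} and
#'   \code{"case"}), \code{sets} (disjoint
#'   \code{\link{GeneSetCollection}}), and \code{truth} (data frame
#'   \code{set_id}, \code{dysregulated}, \code{theta}).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_sets = 20, set_size = 5,
#'                                      n_controls = 10, n_cases = 10,
#'                                      seed = 7))
#' sum(cohort$truth$dysregulated)  # round(0.2 * 20) = 4
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(G))

  # distinct baselines: jittered uniform, re-jittered in the (measure-zero)
  # event of ties so the canonical ordering is unambiguous
  mu <- stats::runif(G, 0, 10)
  while (anyDuplicated(mu)) {
    dup <- duplicated(mu)
    mu[dup] <- mu[dup] + stats::runif(sum(dup), 0, 1e-6)
  }
  names(mu) <- gene_ids

  set_ids <- sprintf("GS%04d", seq_len(config$n_sets))
  members <- split(gene_ids[seq_len(config$n_sets * config$set_size)],
                   rep(seq_len(config$n_sets), each = config$set_size))
  names(members) <- set_ids

  n_dys <- round(config$frac_dysregulated * config$n_sets)
  dys <- rep(FALSE, config$n_sets)
  if (n_dys > 0L) dys[sample.int(config$n_sets, n_dys)] <- TRUE
  truth <- data.frame(set_id = set_ids, dysregulated = dys,
                      theta = ifelse(dys, config$scramble_intensity, 0),
                      stringsAsFactors = FALSE)

  n_ctl <- config$n_controls; n_case <- config$n_cases
  ctl <- matrix(mu, nrow = G, ncol = n_ctl) +
    matrix(stats::rnorm(G * n_ctl, 0, config$noise_sd), nrow = G)

  n_scr <- ceiling(config$scramble_intensity * config$set_size)
  case <- matrix(0, nrow = G, ncol = n_case)
  for (s in seq_len(n_case)) {
    mu_s <- mu
    if (n_scr >= 2L) {
      for (k in which(dys)) {
        idx <- match(members[[k]], gene_ids)
        sel <- idx[sample.int(length(idx), n_scr)]
        mu_s[sel] <- mu_s[sel][sample.int(n_scr)]
      }
    }
    case[, s] <- mu_s
  }
  case <- case + matrix(stats::rnorm(G * n_case, 0, config$noise_sd),
                        nrow = G)

  values <- cbind(ctl, case)
  rownames(values) <- gene_ids
  colnames(values) <- c(sprintf("CTRL%03d", seq_len(n_ctl)),
                        sprintf("CASE%03d", seq_len(n_case)))
  groups <- stats::setNames(rep(c("control", "case"), c(n_ctl, n_case)),
                            colnames(values))
  list(matrix = ExpressionMatrix(values, groups),
       sets = GeneSetCollection(members),
       truth = truth,
       config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the matrix, group annotation, GMT collection and ground truth as
#' tab-delimited text, the same formats the readers ingest.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$matrix,
                   file.path(dir, "matrix.tsv"),
                   file.path(dir, "groups.tsv"))
  write_gmt(cohort$sets, file.path(dir, "sets.gmt"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
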