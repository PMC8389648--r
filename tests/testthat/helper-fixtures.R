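# Small in-code builders shared across the test files.

# expression matrix from a genes x samples numeric matrix given as rows
make_em <- function(values, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(rep("control", ncol(values)),
                              colnames(values))
  ExpressionMatrix(values, groups)
}

# single-control matrix over the given genes with the given values
single_control <- function(genes, values, sample_id = "ctrl1") {
  m <- matrix(values, ncol = 1, dimnames = list(genes, sample_id))
  make_em(m)
}

# independent GSR oracle: loops over every unordered pair and counts
# template matches one at a time (no shared code with gsr_index)
oracle_gsr <- function(sample_values, template) {
  g <- template$genes
  n_match <- 0L; n_pair <- 0L
  for (a in seq_along(g)) {
    for (b in seq_along(g)) {
      if (a >= b) next
      k <- which(template$i == a & template$j == b)
      va <- sample_values[[g[a]]]; vb <- sample_values[[g[b]]]
      less <- if (va == vb) g[a] < g[b] else va < vb
      n_match <- n_match + as.integer(less == template$direction[k])
      n_pair <- n_pair + 1L
    }
  }
  n_match / n_pair
}

# write a GMT file from raw lines, returning its path
write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# write matrix + groups TSV files from a character matrix body
write_expression_files <- function(header, rows, groups_df) {
  mpath <- withr::local_tempfile(fileext = ".tsv",
                                 .local_envir = parent.frame())
  gpath <- withr::local_tempfile(fileext = ".tsv",
                                 .local_envir = parent.frame())
  writeLines(c(header, rows), mpath)
  utils::write.table(groups_df, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(matrix = mpath, groups = gpath)
}

# compute a cohort's functionome and split it by group
cohort_profiles <- function(cohort, min_set_size = 2L) {
  ctl <- subset_samples(cohort$matrix, group = "control")
  sets <- restrict_sets(cohort$sets, cohort$matrix,
                        min_set_size = min_set_size)
  tpl <- build_templates(ctl, sets)
  fn <- functionome(cohort$matrix, sets, tpl)
  list(fn = fn,
       case = profiles_for_group(fn, "case"),
       control = profiles_for_group(fn, "control"),
       sets = sets)
}
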