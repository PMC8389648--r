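make_profiles <- function(mat, ids = NULL) {
  if (is.null(ids)) ids <- paste0("GS", seq_len(ncol(mat)))
  colnames(mat) <- ids
  rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  mat
}

test_that("complete separation at 5v5 gives the exact two-sided p", {
  cs <- make_profiles(matrix(c(0.1, 0.2, 0.3, 0.4, 0.45), ncol = 1))
  ct <- make_profiles(matrix(c(0.6, 0.7, 0.8, 0.9, 0.95), ncol = 1))
  tab <- compare_groups(cs, ct)
  expect_equal(tab$p, 2 / 252)
  expect_equal(tab$U, 0)
})

test_that("all-tied input returns p = 1 by convention", {
  cs <- make_profiles(matrix(0.5, nrow = 4, ncol = 2))
  ct <- make_profiles(matrix(0.5, nrow = 6, ncol = 2))
  tab <- compare_groups(cs, ct)
  expect_equal(tab$p, c(1, 1))
  expect_equal(tab$U, rep(4 * 6 / 2, 2))
  expect_false(any(tab$significant))
})

test_that("group comparison validates its inputs", {
  cs <- make_profiles(matrix(runif(8), ncol = 2))
  ct <- make_profiles(matrix(runif(8), ncol = 2))
  expect_error(compare_groups(cs[1, , drop = FALSE], ct), "2 samples")
  bad <- ct; colnames(bad) <- c("GS1", "OTHER")
  expect_error(compare_groups(cs, bad), "set index")
})

test_that("BH-adjusted q is monotone in p and bounds the smallest p", {
  set.seed(42)
  cs <- make_profiles(matrix(runif(10 * 30), nrow = 10))
  ct <- make_profiles(matrix(runif(10 * 30), nrow = 10))
  tab <- compare_groups(cs, ct)
  ord <- order(tab$p)
  expect_true(all(diff(tab$q[ord]) >= -1e-12))
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_true(all(tab$q <= 1))
  expect_identical(sort(tab$pvalue_rank), seq_len(nrow(tab)))
})

test_that("group summaries report grand means of all indices", {
  cs <- make_profiles(matrix(c(0.6, 0.8), ncol = 1))
  ct <- make_profiles(matrix(c(0.8, 0.8), ncol = 1))
  s <- group_summary(cs, ct, group = "stage_I")
  expect_equal(s$mean_gsr, 0.7)
  expect_equal(s$control_mean_gsr, 0.8)
  expect_equal(s$group, "stage_I")

  all1 <- make_profiles(matrix(1, nrow = 3, ncol = 4))
  expect_equal(group_summary(all1, all1)$mean_gsr, 1)
  expect_error(group_summary(cs[0, , drop = FALSE], ct), "empty")
})

cwi_table <- function(q, ids = paste0("GO:", seq_along(q))) {
  structure(data.frame(set_id = ids, q = q, stringsAsFactors = FALSE),
            class = c("DysregulationTable", "data.frame"))
}

test_that("CWI normalizes -log10 q weights over significant terms", {
  # single significant term takes the whole weight
  t1 <- compute_cwi(cwi_table(c(0.001, 0.9)))
  expect_equal(t1$cwi, c(1, 0))
  expect_equal(t1$cwi_rank, c(1L, NA_integer_))

  # equal q split evenly, ranked lexicographically
  t2 <- compute_cwi(cwi_table(c(0.01, 0.01), ids = c("GO:B", "GO:A")))
  expect_equal(t2$cwi, c(0.5, 0.5))
  expect_equal(t2$cwi_rank[t2$set_id == "GO:A"], 1L)

  # q (1e-4, 1e-2) -> weights (4, 2) -> cwi (2/3, 1/3)
  t3 <- compute_cwi(cwi_table(c(1e-4, 1e-2)))
  expect_equal(t3$weight, c(4, 2))
  expect_equal(t3$cwi, c(2 / 3, 1 / 3))

  # epsilon floors q = 0 instead of producing infinite weight
  t4 <- compute_cwi(cwi_table(c(0, 0.01)), epsilon = 1e-16)
  expect_equal(t4$weight[1], 16)
  expect_true(all(is.finite(t4$cwi)))

  # no significant terms: all-zero cwi with a notice
  expect_message(t5 <- compute_cwi(cwi_table(c(0.5, 0.9))), "no significant")
  expect_equal(t5$cwi, c(0, 0))
  expect_true(all(is.na(t5$cwi_rank)))
})

test_that("CWI sums to one whenever any term is significant", {
  set.seed(9)
  for (i in 1:20) {
    q <- runif(50)^2
    tab <- compute_cwi(cwi_table(q))
    if (any(q < 0.05)) expect_equal(sum(tab$cwi), 1)
  }
})

test_that("GO-graph clustering assigns connected-component ids", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "",
               "[Term]", "id: GO:2", "is_a: GO:1", "",
               "[Term]", "id: GO:3", "",
               "[Term]", "id: GO:4", "is_a: GO:3"), obo)
  g <- read_obo(obo)
  # GO:1, GO:2 significant and linked; GO:4 significant but its neighbor
  # GO:3 is not, so it clusters alone; GO:9 is absent from the graph
  tab <- compute_cwi(cwi_table(c(0.01, 0.02, 0.9, 0.03, 0.04),
                               ids = c("GO:1", "GO:2", "GO:3", "GO:4",
                                       "GO:9")),
                     graph = g)
  cl <- tab$cluster_id
  expect_equal(cl[1], cl[2])
  expect_true(is.na(cl[3]))
  expect_false(cl[4] == cl[1])
  expect_false(cl[5] %in% cl[c(1, 2, 4)])
  expect_equal(sum(tab$cwi), 1)
})

test_that("pathway ranking orders by ascending p with deterministic ties", {
  tab <- cwi_table(rep(0.001, 4), ids = c("GO:D", "GO:B", "GO:A", "GO:C"))
  tab$p <- c(0.04, 0.01, 0.001, 0.01)
  ranked <- rank_pathways(tab, k = 50)
  expect_identical(ranked$set_id, c("GO:A", "GO:B", "GO:C", "GO:D"))
  expect_identical(ranked$rank, 1:4)

  # truncation and fewer-than-k behavior
  tab2 <- cwi_table(rep(0.001, 60), ids = sprintf("GO:%02d", 1:60))
  tab2$p <- seq(0.0001, 0.049, length.out = 60)
  expect_equal(nrow(rank_pathways(tab2, k = 50)), 50)
  tab2$p[1:55] <- 0.5
  expect_equal(nrow(rank_pathways(tab2, k = 50)), 5)
  expect_error(rank_pathways(tab2, k = 0), ">= 1")
})

test_that("top_terms returns the CWI-ranked significant head", {
  tab <- compute_cwi(cwi_table(c(1e-6, 1e-2, 0.5, 1e-4)))
  tt <- top_terms(tab, k = 2)
  expect_identical(tt$set_id, c("GO:1", "GO:4"))
})
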