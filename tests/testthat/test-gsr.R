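test_that("restrict_sets intersects with measured genes and drops small sets", {
  gsc <- GeneSetCollection(list(S1 = c("A", "B", "C"), S2 = c("A", "Z")))
  em <- make_em(matrix(1:6, nrow = 3,
                       dimnames = list(c("A", "B", "D"), c("s1", "s2"))))
  res <- suppressMessages(restrict_sets(gsc, em, min_set_size = 2))
  expect_identical(set_ids(res), "S1")
  expect_identical(set_members(res, "S1"), c("A", "B"))  # order preserved

  expect_error(restrict_sets(gsc, em, min_set_size = 1), ">= 2")
  em2 <- make_em(matrix(1:2, nrow = 1,
                        dimnames = list("Z", c("s1", "s2"))))
  expect_error(suppressMessages(restrict_sets(gsc, em2, min_set_size = 2)),
               "no gene set")
})

test_that("templates store per-pair majority directions with support", {
  # single control, increasing values: all pairs point up, support 1
  tpl <- build_template(single_control(c("A", "B", "C"), c(1, 2, 3)),
                        c("A", "B", "C"))
  expect_true(all(tpl$direction))
  expect_equal(tpl$support, rep(1, 3))

  # three controls voting (A<B, A<B, B<A): majority A<B, support 2/3
  m <- matrix(c(1, 2, 1, 3, 5, 1), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  tpl2 <- build_template(make_em(m), c("A", "B"))
  expect_true(tpl2$direction)
  expect_equal(tpl2$support, 2 / 3)

  # exact 2/2 split: support 0.5, lexicographically smaller symbol lower
  m4 <- matrix(c(1, 2, 1, 2, 2, 1, 2, 1), nrow = 2,
               dimnames = list(c("B", "A"), paste0("s", 1:4)))
  tpl3 <- build_template(make_em(m4), c("B", "A"))
  expect_equal(tpl3$support, 0.5)
  # pair is (B, A) in member order; direction FALSE means A deemed lower
  expect_false(tpl3$direction)

  expect_error(build_template(single_control("A", 1), c("A", "Q")),
               "not measured")
})

test_that("gsr_index hits the definitional endpoints and partial matches", {
  tpl <- build_template(single_control(LETTERS[1:5], 1:5), LETTERS[1:5])
  expect_equal(gsr_index(stats::setNames(c(10, 20, 30, 40, 50),
                                         LETTERS[1:5]), tpl), 1)
  expect_equal(gsr_index(stats::setNames(c(50, 40, 30, 20, 10),
                                         LETTERS[1:5]), tpl), 0)

  # template A<B<C, sample B<A<C: pair (A,B) discordant, 2/3 concordant
  tpl3 <- build_template(single_control(c("A", "B", "C"), c(1, 2, 3)),
                         c("A", "B", "C"))
  expect_equal(gsr_index(c(A = 2, B = 1, C = 3), tpl3), 2 / 3)

  expect_error(gsr_index(c(A = 1, B = 2), tpl3), "missing value")
})

test_that("gsr_index equals the brute-force pair oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(2:6, 1)
    genes <- paste0("g", sample(100, m))
    n_ctl <- sample(1:5, 1)
    ctl <- matrix(sample(1:8, m * n_ctl, replace = TRUE), nrow = m,
                  dimnames = list(genes, paste0("c", seq_len(n_ctl))))
    tpl <- build_template(make_em(ctl), genes)
    v <- stats::setNames(sample(1:8, m, replace = TRUE), genes)
    expect_identical(gsr_index(v, tpl), oracle_gsr(v, tpl))
  }
})

test_that("gsr_index is a rank statistic: invariant to monotone transforms", {
  set.seed(7)
  genes <- paste0("g", 1:6)
  tpl <- build_template(
    make_em(matrix(rnorm(18), nrow = 6,
                   dimnames = list(genes, paste0("c", 1:3)))), genes)
  v <- stats::setNames(runif(6, 1, 2), genes)
  base <- gsr_index(v, tpl)
  expect_equal(gsr_index(exp(v), tpl), base)
  expect_equal(gsr_index(2 * v + 10, tpl), base)
  expect_equal(gsr_index(v^3, tpl), base)
})

test_that("consistent gene relabeling leaves the index unchanged", {
  set.seed(11)
  genes <- paste0("g", 1:5)
  ctl <- matrix(rnorm(15), nrow = 5, dimnames = list(genes, paste0("c", 1:3)))
  v <- stats::setNames(rnorm(5), genes)
  base <- gsr_index(v, build_template(make_em(ctl), genes))
  # relabel preserving lexicographic order so the tie rule is untouched
  relab <- stats::setNames(paste0("h", 1:5), genes)
  ctl2 <- ctl; rownames(ctl2) <- relab[rownames(ctl)]
  v2 <- stats::setNames(v, relab[names(v)])
  expect_equal(gsr_index(v2, build_template(make_em(ctl2), unname(relab))),
               base)
})

test_that("functionome profiles cover every set and respect identities", {
  set.seed(3)
  genes <- paste0("g", 1:9)
  ctl_vals <- stats::setNames(runif(9), genes)
  # negation reverses every pairwise ordering
  em <- make_em(cbind(ctrl = ctl_vals, same = ctl_vals, rev = -ctl_vals),
                c(ctrl = "control", same = "case", rev = "case"))
  gsc <- GeneSetCollection(list(S1 = genes[1:3], S2 = genes[4:6],
                                S3 = genes[7:9]))
  tpl <- build_templates(subset_samples(em, group = "control"), gsc)
  fn <- functionome(em, gsc, tpl)
  expect_identical(dim(unclass(fn)), c(3L, 3L))
  expect_true(all(fn >= 0 & fn <= 1))
  # the control the template came from scores 1 everywhere, as does a copy
  expect_equal(unname(unclass(fn)["ctrl", ]), rep(1, 3))
  expect_equal(unname(unclass(fn)["same", ]), rep(1, 3))
  # per-set value-reversed sample scores 0 everywhere
  expect_equal(unname(unclass(fn)["rev", ]), rep(0, 3))

  expect_error(functionome(em, gsc, tpl[1:2]), "missing")
})

test_that("in-sample expression ties use the symbol rule on both sides", {
  tpl <- build_template(single_control(c("B", "A"), c(1, 2)), c("B", "A"))
  # tie in the sample: A deemed lower than B, template says B lower
  expect_equal(gsr_index(c(B = 5, A = 5), tpl), 0)
  tpl2 <- build_template(single_control(c("B", "A"), c(2, 1)), c("B", "A"))
  expect_equal(gsr_index(c(B = 5, A = 5), tpl2), 1)
})

test_that("GSR histograms bin every entry over [0, 1]", {
  x <- matrix(c(0, 0.01, 0.5, 0.999, 1), nrow = 1)
  h <- gsr_histogram(x, binwidth = 0.02)
  expect_equal(sum(h$count), 5)
  expect_equal(nrow(h), 50)
  expect_equal(h$count[1], 2)          # 0 and 0.01 in [0, 0.02)
  expect_equal(h$count[nrow(h)], 2)    # 0.999 and 1 in [0.98, 1]
})
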