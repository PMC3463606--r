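test_that("pearson_cc matches hand-computed values and validates input", {
  expect_equal(pearson_cc(1:6, 2 * (1:6)), 1.0)
  expect_equal(pearson_cc(1:6, 6:1), -1.0)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cc(1:3, 1:4), "length")
  expect_error(pearson_cc(1:2, 2:1), ">= 3")
})

test_that("pearson_cc is symmetric, affine-invariant and bounded", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pearson_cc(x, y), pearson_cc(y, x))
    expect_equal(pearson_cc(2.5 * x + 3, y), pearson_cc(x, y))
    expect_true(abs(pearson_cc(x, y)) <= 1)
  }
})

test_that("correlation_matrix agrees with elementwise pearson_cc", {
  set.seed(2)
  expr <- expr_fixture(
    list(g1 = rnorm(5), g2 = rnorm(5), g3 = rnorm(5),
         m1 = rnorm(5), m2 = rnorm(5)),
    c(g1 = "gene", g2 = "gene", g3 = "gene", m1 = "miRNA", m2 = "miRNA"))
  cm <- correlation_matrix(expr, c("g1", "g2", "g3"), c("m1", "m2"))
  for (g in rownames(cm)) for (m in colnames(cm))
    expect_equal(cm[g, m],
                 pearson_cc(expr$values[g, ], expr$values[m, ]))
  # identical and negated (centered) profiles
  p <- rnorm(5)
  e2 <- expr_fixture(list(g = p, m = p, mn = -(p - mean(p))),
                     c(g = "gene", m = "miRNA", mn = "miRNA"))
  cm2 <- correlation_matrix(e2, "g", c("m", "mn"))
  expect_equal(unname(cm2[1, ]), c(1, -1))
  expect_error(correlation_matrix(expr, "nope", "m1"), "unknown")
})

test_that("entity clustering recovers planted groups and filters by size", {
  bump1 <- c(5, 3, 1, 1, 1, 1)
  bump2 <- c(1, 1, 1, 1, 3, 5)
  profs <- c(lapply(1:3, function(i) bump1), lapply(1:3, function(i) bump2))
  names(profs) <- paste0("g", 1:6)
  expr <- expr_fixture(profs, stats::setNames(rep("gene", 6), names(profs)))
  cl <- cluster_entities(expr, "gene", min_size = 2)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, character(1), "peak"), c("T1", "T6"))
  sizes <- vapply(cl, `[[`, integer(1), "size")
  expect_equal(sort(sizes), c(3L, 3L))
  # clusters are disjoint
  expect_equal(anyDuplicated(unlist(lapply(cl, `[[`, "members"))), 0L)

  # all near-identical profiles -> one cluster with everything
  profs1 <- lapply(1:5, function(i) bump1 + i * 1e-9)
  names(profs1) <- paste0("g", 1:5)
  e1 <- expr_fixture(profs1, stats::setNames(rep("gene", 5), names(profs1)))
  cl1 <- cluster_entities(e1, "gene", min_size = 2)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$size, 5L)

  # min_size larger than n -> empty list
  expect_length(cluster_entities(expr, "gene", min_size = 10), 0)
  expect_error(cluster_entities(expr, "gene", min_size = 0), "min_size")
})

test_that("correlation-bin report: totals invariant, null preserves sizes", {
  cfg <- sim_config(n_tf = 3, n_mirna = 8, n_gene = 120, seed = 21)
  irn <- simulate_irn(cfg)
  expr <- simulate_expression(cfg, irn)
  r1 <- target_correlation_z(expr, irn, n_rand = 20, seed = 1)
  r2 <- target_correlation_z(expr, irn, n_rand = 20, seed = 99)
  expect_equal(sum(r1$table$observed), r1$n_pairs)
  expect_equal(sum(r2$table$observed), r2$n_pairs)
  expect_equal(r1$table$observed, r2$table$observed)  # observed is seed-free
  # null histograms account for every pair in every draw
  expect_equal(sum(r1$table$null_mean), r1$n_pairs)
  # determinism under a fixed seed
  r1b <- target_correlation_z(expr, irn, n_rand = 20, seed = 1)
  expect_identical(r1$table, r1b$table)
  expect_error(target_correlation_z(expr, irn, bin_width = 0.3), "evenly")
})

test_that("degenerate nulls give NA z, never infinities", {
  # one miRNA, one measured gene: every null draw is the same target set
  net <- typed_network(rbind(c("m", "g")), c(m = "miRNA", g = "gene"))
  expr <- expr_fixture(list(m = c(1, 2, 3, 4), g = c(4, 3, 2, 1)),
                       c(m = "miRNA", g = "gene"))
  r <- target_correlation_z(expr, net, bin_width = 0.5, n_rand = 2, seed = 1)
  expect_true(all(is.na(r$table$z) | is.finite(r$table$z)))
  expect_true(any(r$table$null_sd == 0))
  expect_true(all(is.na(r$table$z[r$table$null_sd == 0])))
})

test_that("time-point clustering separates duplicated column blocks", {
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  m <- cbind(A1 = a, A2 = a + rnorm(10, sd = 1e-4),
             B1 = b, B2 = b + rnorm(10, sd = 1e-4))
  rownames(m) <- paste0("g", 1:10)
  expr <- expression_matrix(m, stats::setNames(rep("gene", 10), rownames(m)))
  part <- cluster_timepoints(expr)
  expect_equal(part$groups[["A1"]], part$groups[["A2"]])
  expect_equal(part$groups[["B1"]], part$groups[["B2"]])
  expect_true(part$groups[["A1"]] != part$groups[["B1"]])
  # deterministic for fixed input
  part2 <- cluster_timepoints(expr)
  expect_identical(part$groups, part2$groups)
  expect_identical(as_newick(part), as_newick(part2))
  expect_error(cluster_timepoints(m[, 1:2]), ">= 3")
})

test_that("expression TSV round-trips", {
  set.seed(4)
  expr <- expr_fixture(list(g = rnorm(4), m = rnorm(4), t = rnorm(4)),
                       c(g = "gene", m = "miRNA", t = "TF"))
  f <- tempfile(fileext = ".tsv")
  write_expression(expr, f)
  back <- read_expression(f)
  expect_equal(back$values, expr$values)
  expect_identical(back$type, expr$type)
})
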