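test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(n_gene = 0, seed = 1), "positive")
  expect_error(sim_config(anticorr_fraction = 1.2, seed = 1), "fractions")
  expect_error(sim_config(regimes = c("early", "late"), seed = 1),
               "per time point")
  expect_error(sim_config(seed = 2^31), "below")
})

test_that("simulate_irn honors the planting manifest and determinism", {
  cfg <- sim_config(n_tf = 5, n_mirna = 10, n_gene = 120,
                    planted_motifs = c(FFL = 20, RML = 10), seed = 71)
  irn <- simulate_irn(cfg)
  man <- attr(irn, "manifest")
  expect_equal(nrow(man), 30)
  key <- paste(network_edges(irn)$source, network_edges(irn)$target)
  for (r in seq_len(nrow(man))) {
    if (man$family[r] == "FFL") {
      expect_true(all(c(paste(man$a[r], man$b[r]), paste(man$a[r], man$c[r]),
                        paste(man$b[r], man$c[r])) %in% key))
    } else {
      expect_true(all(c(paste(man$a[r], man$b[r]), paste(man$b[r], man$a[r]),
                        paste(man$a[r], man$c[r])) %in% key))
    }
    # planted pairs mix regulator classes
    types <- network_nodes(irn)
    ty <- types$type[match(c(man$a[r], man$b[r]), types$id)]
    expect_setequal(ty, c("TF", "miRNA"))
  }
  irn2 <- simulate_irn(cfg)
  expect_identical(network_edges(irn), network_edges(irn2))
})

test_that("simulate_expression plants clusters and forced correlations", {
  cfg0 <- sim_config(n_tf = 3, n_mirna = 6, n_gene = 80, noise_sd = 0,
                     n_clusters = 2, anticorr_fraction = 0,
                     poscorr_fraction = 0, seed = 73)
  irn <- simulate_irn(cfg0)
  expr <- suppressMessages(simulate_expression(cfg0, irn))
  cl <- attr(expr, "manifest")$cluster
  # zero noise: within-cluster correlation is exactly 1
  ids1 <- names(cl)[cl == 1][1:2]
  expect_equal(pearson_cc(expr$values[ids1[1], ], expr$values[ids1[2], ]), 1)

  cfg1 <- sim_config(n_tf = 3, n_mirna = 6, n_gene = 80, noise_sd = 0,
                     anticorr_fraction = 1, poscorr_fraction = 0, seed = 73)
  irn1 <- simulate_irn(cfg1)
  expr1 <- suppressMessages(simulate_expression(cfg1, irn1))
  pairs <- attr(expr1, "manifest")$pairs
  expect_true(nrow(pairs) > 0)
  expect_equal(pairs$cc, rep(-1, nrow(pairs)))

  # determinism
  e2 <- suppressMessages(simulate_expression(cfg1, irn1))
  expect_identical(expr1$values, e2$values)
})

test_that("regime networks separate early and late topology", {
  cfg <- sim_config(n_tf = 5, n_mirna = 15, regime_n_gene = 100, seed = 79)
  nets <- simulate_regimes(cfg)
  expect_equal(names(nets), c("E15", "E18", "P1", "P5", "P12", "Adult"))
  man <- attr(nets, "manifest")
  cc <- vapply(nets, function(nw) network_metrics(nw)$cc_mean, numeric(1))
  expect_true(min(cc[man$regime == "early"]) > max(cc[man$regime == "late"]))
  # late modules shed satellites faster under hub removal
  sing <- vapply(nets, function(nw)
    sum(perturb_hubs(nw, 8)$n_singletons[6:8]), numeric(1))
  expect_true(mean(sing[man$regime == "late"]) >
                mean(sing[man$regime == "early"]))
  nets2 <- simulate_regimes(cfg)
  expect_identical(network_edges(nets[[1]]), network_edges(nets2[[1]]))
})

test_that("planted annotations are recovered by enrichment", {
  cfg <- sim_config(n_tf = 3, n_mirna = 6, n_gene = 150, noise_sd = 0.1,
                    n_clusters = 3, anticorr_fraction = 0,
                    poscorr_fraction = 0, annotate_fraction = 1,
                    background_fraction = 0, seed = 83)
  irn <- simulate_irn(cfg)
  expr <- simulate_expression(cfg, irn)
  cl <- cluster_entities(expr, "gene", min_size = 5)
  expect_true(length(cl) >= 2)
  ann <- simulate_annotations(cfg, cl)
  truth <- attr(ann, "truth")
  res <- enrich(cl[[1]]$members, ann)
  planted <- names(truth)[vapply(truth, identical, logical(1), 1L)]
  expect_equal(res$term_id[1], planted)
  # GMT round trip preserves the collection
  f <- tempfile(fileext = ".gmt")
  write_gmt(ann, f)
  back <- read_gmt(f, universe = ann$universe)
  expect_identical(back$sets, ann$sets)
})
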