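test_that("ESU enumerates each connected triple exactly once", {
  expect_equal(nrow(enumerate_size3(star_net(3))), 3)
  tri_net <- typed_network(rbind(c("T1", "T2"), c("T1", "g"), c("T2", "g")),
                           c(T1 = "TF", T2 = "TF", g = "gene"))
  expect_equal(nrow(enumerate_size3(tri_net)), 1)

  set.seed(41)
  for (i in 1:25) {
    net <- rand_typed_net(sample(1:3, 1), sample(1:3, 1), sample(4:8, 1),
                          sample(6:30, 1))
    expect_identical(triple_key(enumerate_size3(net)),
                     triple_key(bf_triples(net)))
  }
})

test_that("canonical labels are relabeling-invariant and families correct", {
  # RML: TF <-> miRNA pair plus attached gene, under two labelings
  m1 <- canonical_typed_label(
    typed_network(rbind(c("a", "b"), c("b", "a"), c("a", "c")),
                  c(a = "TF", b = "miRNA", c = "gene")))
  m2 <- canonical_typed_label(
    typed_network(rbind(c("y", "x"), c("x", "y"), c("y", "z")),
                  c(x = "miRNA", y = "TF", z = "gene")))
  expect_identical(m1$label, m2$label)
  expect_equal(m1$family, "RML")

  sim <- canonical_typed_label(
    typed_network(rbind(c("t", "g1"), c("t", "g2")),
                  c(t = "TF", g1 = "gene", g2 = "gene")))
  expect_equal(sim$family, "SIM")

  crm <- canonical_typed_label(
    typed_network(rbind(c("t", "g"), c("m", "g")),
                  c(t = "TF", m = "miRNA", g = "gene")))
  expect_equal(crm$family, "CRM")

  ffl <- canonical_typed_label(
    typed_network(rbind(c("t", "m"), c("t", "g"), c("m", "g")),
                  c(t = "TF", m = "miRNA", g = "gene")))
  expect_equal(ffl$family, "FFL")

  expect_error(canonical_typed_label(star_net(3)), "exactly 3")
  expect_error(canonical_typed_label(c("gene", "TF", "gene"),
                                     matrix(c(0, 0, 0, 1, 0, 0, 1, 0, 0), 3,
                                            byrow = TRUE)),
               "gene")
})

test_that("motif counts partition the connected triples", {
  cm <- count_motifs(star_net(3))
  expect_equal(cm$count[cm$family == "SIM"], 3)
  expect_equal(nrow(count_motifs(star_net(3), require_tf_and_mirna = TRUE)), 0)

  set.seed(43)
  for (i in 1:10) {
    net <- rand_typed_net(2, 2, 6, sample(8:25, 1))
    cm <- count_motifs(net)
    expect_equal(sum(cm$count), nrow(enumerate_size3(net)))
    # filtered counts never exceed unfiltered ones
    cf <- count_motifs(net, require_tf_and_mirna = TRUE)
    expect_true(sum(cf$count) <= sum(cm$count))
  }
})

test_that("typed edge swap conserves degrees and neighbor-type composition", {
  tiny <- typed_network(rbind(c("T1", "g1")), c(T1 = "TF", g1 = "gene"))
  expect_message(sw <- typed_edge_swap(tiny, 10), "copy")
  expect_identical(network_edges(sw), network_edges(tiny))

  set.seed(47)
  for (i in 1:20) {
    net <- rand_typed_net(sample(2:4, 1), sample(2:4, 1), sample(5:9, 1),
                          sample(10:40, 1))
    sw <- suppressMessages(typed_edge_swap(net, 10 * n_arcs(net)))
    expect_equal(n_arcs(sw), n_arcs(net))
    f0 <- swap_fingerprint(net); f1 <- swap_fingerprint(sw)
    expect_identical(f1, f0)
    e <- network_edges(sw)
    expect_false(any(e$source == e$target))
    expect_equal(anyDuplicated(paste(e$source, e$target)), 0L)
  }

  # deterministic under a fixed seed
  net <- rand_typed_net(3, 3, 8, 30)
  s1 <- typed_edge_swap(net, 100, seed = 5)
  s2 <- typed_edge_swap(net, 100, seed = 5)
  expect_identical(network_edges(s1), network_edges(s2))
})

test_that("motif z-scores are deterministic and recover planted FFLs", {
  cfg <- sim_config(planted_motifs = c(FFL = 50), seed = 53)
  irn <- simulate_irn(cfg)
  z1 <- motif_zscores(irn, n_rand = 30, seed = 17, by = "family")
  z2 <- motif_zscores(irn, n_rand = 30, seed = 17, by = "family")
  expect_identical(z1$table, z2$table)
  expect_true(z1$table$z[z1$table$family == "FFL"] > 2)
  # z is NA exactly where the null sd vanishes
  expect_identical(is.na(z1$table$z), z1$table$null_sd == 0)
})

test_that("unswappable network yields a degenerate null", {
  net <- typed_network(rbind(c("T1", "g1"), c("M1", "g2")),
                       c(T1 = "TF", M1 = "miRNA",
                         g1 = "gene", g2 = "gene"))
  # two arcs in different type classes: no legal swap partner exists
  z <- suppressMessages(motif_zscores(net, n_rand = 5, seed = 1,
                                      require_tf_and_mirna = FALSE))
  expect_true(all(is.na(z$table$z) | z$table$z == 0))
})

test_that("two-node mutual loops are counted exactly", {
  net <- typed_network(rbind(c("T1", "M1"), c("M1", "T1")),
                       c(T1 = "TF", M1 = "miRNA"))
  expect_equal(count_2node_mutual(net)$observed, 1)
  dag <- chain_net()
  expect_equal(count_2node_mutual(dag)$observed, 0)

  set.seed(59)
  for (i in 1:20) {
    net <- rand_typed_net(3, 3, 4, sample(10:40, 1))
    e <- network_edges(net)
    key <- paste(e$source, e$target)
    brute <- sum(e$source < e$target & paste(e$target, e$source) %in% key)
    expect_equal(count_2node_mutual(net)$observed, brute)
  }
})

test_that("motif dynamics aligns profiles and is stable across columns", {
  cfg <- sim_config(n_tf = 4, n_mirna = 8, n_gene = 60,
                    regime_n_gene = 40, seed = 61)
  nets <- simulate_regimes(cfg)
  dup <- list(a = nets[[1]], b = nets[[1]], c = nets[[4]])
  dyn <- motif_dynamics(dup, n_rand = 20, seed = 3)
  # identical networks get identical Z columns
  expect_identical(dyn$z[, "a"], stats::setNames(dyn$z[, "b"],
                                                 rownames(dyn$z)))
  # row space is the union of labels seen in any profile
  labs <- unique(unlist(lapply(dyn$profiles, function(p) p$table$label)))
  expect_setequal(rownames(dyn$z), labs)
  expect_equal(ncol(dyn$z), 3)
})

test_that("z-matrix time-point clustering separates duplicated blocks", {
  set.seed(67)
  za <- rnorm(8); zb <- rnorm(8)
  zm <- cbind(A1 = za, A2 = za + rnorm(8, sd = 1e-3),
              B1 = zb, B2 = zb + rnorm(8, sd = 1e-3))
  rownames(zm) <- paste0("motif", 1:8)
  part <- cluster_timepoints(zm)
  expect_equal(part$groups[["A1"]], part$groups[["A2"]])
  expect_true(part$groups[["A1"]] != part$groups[["B1"]])

  # a single distinct column merges last
  zm2 <- cbind(C1 = za, C2 = za, C3 = za, D = za + 10)
  rownames(zm2) <- paste0("motif", 1:8)
  p2 <- cluster_timepoints(zm2)
  expect_equal(sum(p2$groups == p2$groups[["D"]]), 1)
})
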