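test_that("clustering coefficient on hand-checked neighborhoods", {
  # v with N(v) = {a, b}, only arc a -> b: 1 of 2 possible ordered arcs
  net <- typed_network(rbind(c("v", "a"), c("v", "b"), c("a", "b")),
                       c(v = "TF", a = "TF", b = "gene"))
  expect_equal(clustering_coefficient(net, "v"), 0.5)
  # both directions present
  net2 <- typed_network(rbind(c("v", "a"), c("v", "b"),
                              c("a", "b"), c("b", "a")),
                        c(v = "TF", a = "TF", b = "TF"))
  expect_equal(clustering_coefficient(net2, "v"), 1.0)
  # fewer than 2 neighbors -> 0
  expect_equal(clustering_coefficient(chain_net(), "c"), 0)
})

test_that("betweenness and reachability on the 3-chain", {
  net <- chain_net()
  expect_equal(betweenness(net, "b"), 1)
  expect_equal(unname(reachability(net)), c(1, 0.5, 0))
  m <- network_metrics(net)
  expect_equal(m$apl, 4 / 3)
  expect_equal(m$reach_mean, 0.5)
  # isolated node has zero betweenness
  net_iso <- typed_network(rbind(c("a", "b")),
                           c(a = "TF", b = "gene", z = "gene"))
  expect_equal(betweenness(net_iso, "z"), 0)
})

test_that("degree means follow regulator/target conventions", {
  net <- star_net(5)
  m <- network_metrics(net)
  expect_equal(m$out_degree_mean, 5)
  expect_equal(m$in_degree_mean, 1)
  expect_error(network_metrics(typed_network(NULL, character(0))))
})

test_that("metrics match matrix-power oracles on random graphs", {
  set.seed(21)
  for (i in 1:25) {
    net <- rand_typed_net(sample(1:3, 1), sample(1:3, 1), sample(3:6, 1),
                          sample(6:24, 1))
    A <- adjacency_matrix(net)
    expect_equal(unname(betweenness(net)), bf_betweenness(A),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_coefficient(net)), bf_clustering(A),
                 tolerance = 1e-12)
    expect_equal(unname(reachability(net)), unname(bf_reachability(A)),
                 tolerance = 1e-12)
    m <- network_metrics(net)
    expect_equal(m$apl, bf_apl(A), tolerance = 1e-12)
  }
})

test_that("random-subnetwork null is reproducible and degenerates correctly", {
  cfg <- sim_config(n_tf = 4, n_mirna = 6, n_gene = 50, seed = 41)
  irn <- simulate_irn(cfg)
  n1 <- random_subnetwork_null(irn, 2, 3, 10, n_rand = 3, seed = 9)
  n2 <- random_subnetwork_null(irn, 2, 3, 10, n_rand = 3, seed = 9)
  expect_identical(n1$mean, n2$mean)
  expect_identical(n1$sd, n2$sd)

  # sampling every node reproduces the IRN itself, with zero spread
  s <- summarize_network(irn)
  nfull <- random_subnetwork_null(irn, s$n_tf, s$n_mirna, s$n_gene,
                                  n_rand = 2, seed = 1)
  expect_true(all(nfull$sd == 0))
  m <- network_metrics(irn)
  for (k in names(nfull$mean))
    expect_equal(unname(nfull$mean[[k]]), m[[k]])

  expect_error(random_subnetwork_null(irn, s$n_tf + 1, 1, 1, n_rand = 2),
               "available")
})

test_that("hub perturbation matches a step-by-step recount", {
  # star: removing the hub isolates all three leaves
  pc <- perturb_hubs(star_net(3), 1)
  expect_equal(pc$n_singletons, 3L)
  expect_equal(pc$removed_id, "hub")

  # bidirectional 4-clique: removing any node leaves everything connected
  ids <- paste0("r", 1:4)
  prs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  prs <- prs[prs$a != prs$b, ]
  clique <- typed_network(as.matrix(prs),
                          stats::setNames(rep("TF", 4), ids))
  expect_equal(perturb_hubs(clique, 1)$n_singletons, 0L)

  # random graphs against a brute-force recount
  set.seed(31)
  for (i in 1:10) {
    net <- rand_typed_net(3, 3, sample(6:10, 1), sample(10:40, 1))
    k_max <- min(5, length(net$node_id))
    pc <- perturb_hubs(net, k_max)
    edges <- network_edges(net)
    alive <- net$node_id
    deg_in_full <- table(factor(c(edges$source, edges$target),
                                levels = net$node_id))
    had <- names(deg_in_full)[deg_in_full > 0]
    for (k in seq_len(k_max)) {
      e <- edges[edges$source %in% alive & edges$target %in% alive, ]
      deg <- table(factor(c(e$source, e$target), levels = alive))
      hub <- sort(names(deg)[deg == max(deg)])[1]
      expect_equal(pc$removed_id[k], hub)
      alive <- setdiff(alive, hub)
      e <- edges[edges$source %in% alive & edges$target %in% alive, ]
      deg <- table(factor(c(e$source, e$target), levels = alive))
      expect_equal(pc$n_singletons[k],
                   sum(deg == 0 & names(deg) %in% had))
    }
    expect_true(all(pc$n_singletons <=
                      length(net$node_id) - pc$step))
  }
  expect_error(perturb_hubs(star_net(3), 0), "k_max")
  expect_error(perturb_hubs(star_net(3), 10), "exceeds")
})
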