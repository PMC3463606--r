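test_that("initial active set respects absolute and percentile rules", {
  expr <- expr_fixture(list(a = c(2, 0, 0), b = c(8, 0, 0), c = c(5, 0, 0)),
                       c(a = "gene", b = "gene", c = "gene"))
  expect_setequal(initial_active_set(expr, "T1", activity_rule("absolute", 4)),
                  c("b", "c"))
  expect_length(initial_active_set(expr, "T1", activity_rule("absolute", 100)), 0)

  e4 <- expr_fixture(list(a = c(1, 0, 0), b = c(2, 0, 0),
                          c = c(3, 0, 0), d = c(4, 0, 0)),
                     c(a = "gene", b = "gene", c = "gene", d = "gene"))
  expect_setequal(initial_active_set(e4, "T1", "percentile:50"), c("c", "d"))
  expect_error(initial_active_set(expr, "T99"), "unknown time point")
})

test_that("backtrack closure pulls in all upstream regulators", {
  net <- backtrack_net()
  expect_setequal(backtrack_closure("G1", net), c("G1", "T1", "T2", "M1"))
  # idempotence on an already-closed set
  closed <- backtrack_closure("G1", net)
  expect_setequal(backtrack_closure(closed, net), closed)
  expect_equal(backtrack_closure(character(0), net), character(0))
})

test_that("backtrack closure equals the reverse-reachability oracle", {
  set.seed(11)
  for (i in 1:30) {
    net <- rand_typed_net(sample(2:4, 1), sample(2:4, 1), sample(4:8, 1),
                          sample(8:30, 1))
    seed_ids <- sample(net$node_id, sample(1:4, 1))
    got <- sort(backtrack_closure(seed_ids, net))
    expect_identical(got, bf_closure(seed_ids, net))
    # monotonicity: a larger seed gives a superset closure
    bigger <- union(seed_ids, sample(net$node_id, 2))
    expect_true(all(got %in% backtrack_closure(bigger, net)))
    # every backtracked addition regulates something inside the closure
    added <- setdiff(got, seed_ids)
    edges <- network_edges(net)
    for (u in added)
      expect_true(any(edges$source == u & edges$target %in% got))
  }
})

test_that("extract_active wires the closed set as an induced subgraph", {
  net <- backtrack_net()
  expr <- expr_fixture(list(G1 = c(9, 0, 0), T1 = c(0, 0, 0),
                            T2 = c(0, 0, 0), M1 = c(0, 0, 0)),
                       c(G1 = "gene", T1 = "TF", T2 = "TF", M1 = "miRNA"))
  act <- extract_active(expr, net, "T1", activity_rule("absolute", 5))
  expect_equal(act$initial_set, "G1")
  expect_setequal(act$closed_set, c("G1", "T1", "T2", "M1"))
  expect_equal(n_arcs(act$subnet), 3)
  expect_true(all(act$initial_set %in% act$closed_set))

  # empty initial set -> empty subnetwork
  act0 <- extract_active(expr, net, "T1", activity_rule("absolute", 100))
  expect_length(act0$closed_set, 0)
  expect_equal(n_arcs(act0$subnet), 0)
})

test_that("active subnetwork arcs are exactly the IRN arcs inside the set", {
  cfg <- sim_config(n_tf = 4, n_mirna = 6, n_gene = 60, seed = 31)
  irn <- simulate_irn(cfg)
  expr <- simulate_expression(cfg, irn)
  for (tp in timepoint_labels(expr)[c(1, 4)]) {
    act <- extract_active(expr, irn, tp)
    expect_equal(length(act$closed_set), length(act$subnet$node_id))
    sub_e <- network_edges(act$subnet)
    irn_e <- network_edges(irn)
    inside <- irn_e$source %in% act$closed_set &
      irn_e$target %in% act$closed_set
    expect_setequal(paste(sub_e$source, sub_e$target),
                    paste(irn_e$source[inside], irn_e$target[inside]))
  }
})

test_that("specific sets exclude housekeeping and cover multi-point activity", {
  expr <- expr_fixture(
    list(hk = c(9, 9, 9), early = c(9, 0, 0), mid2 = c(9, 9, 0),
         lowa = c(0, 0, 0), lowb = c(1, 1, 1)),
    c(hk = "gene", early = "gene", mid2 = "gene",
      lowa = "gene", lowb = "gene"))
  ss <- specific_sets(expr, activity_rule("absolute", 5))
  expect_equal(ss$housekeeping, "hk")
  expect_true("early" %in% ss$specific$T1)
  expect_false("early" %in% ss$specific$T2)
  expect_true(all(c("T1", "T2") %in%
                    names(which(vapply(ss$specific, function(s)
                      "mid2" %in% s, logical(1))))))
  expect_false("mid2" %in% ss$specific$T3)
  # housekeeping never appears in a specific set
  expect_false(any(vapply(ss$specific, function(s) "hk" %in% s, logical(1))))
  # union property: specifics + housekeeping = anything active somewhere
  active_any <- unique(unlist(lapply(colnames(expr$values), function(tp)
    initial_active_set(expr, tp, activity_rule("absolute", 5)))))
  expect_setequal(union(unlist(ss$specific), ss$housekeeping), active_any)
})
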