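# Directed topology metrics, the random same-size sub-network null, and
# the hub-removal perturbation curve.

#' Directed clustering coefficient
#'
#' For node v with neighborhood N(v) (the union of in- and out-neighbors),
#' the clustering coefficient is the number of arcs among distinct members
#' of N(v) divided by |N(v)|(|N(v)|-1), the number of ordered pairs that
#' could carry an arc. Nodes with fewer than two neighbors score 0.
#'
#' @param net a `typed_network`.
#' @param v a node id, or NULL for all nodes.
#' @return A named numeric vector in \[0, 1\] (or a single value for one
#'   node).
#' @export
clustering_coefficient <- function(net, v = NULL) {
  cc <- cpp_clustering_coeff(n_nodes(net), net$from, net$to)
  names(cc) <- net$node_id
  if (is.null(v)) cc else cc[[node_index(net, v)]]
}

#' Directed betweenness centrality
#'
#' BW(v) is the sum over ordered node pairs (s, t), s != t != v, of the
#' fraction of directed geodesics from s to t that pass through v. The
#' raw (unnormalized) sum is reported; pairs with no connecting path
#' contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector (or single value).
#' @export
betweenness <- function(net, v = NULL) {
  pm <- cpp_path_metrics(n_nodes(net), net$from, net$to)
  bw <- pm$betweenness
  names(bw) <- net$node_id
  if (is.null(v)) bw else bw[[node_index(net, v)]]
}

#' Directed reachability
#'
#' R(v) is the fraction of the other |V|-1 nodes that can be reached from
#' v along directed paths.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector in \[0, 1\] (or single value).
#' @export
reachability <- function(net, v = NULL) {
  n <- n_nodes(net)
  if (n < 2) stop("reachability needs >= 2 nodes")
  pm <- cpp_path_metrics(n, net$from, net$to)
  r <- pm$reach_count / (n - 1)
  names(r) <- net$node_id
  if (is.null(v)) r else r[[node_index(net, v)]]
}

#' Full topology report for a network
#'
#' Computes per-node out-degree, in-degree, clustering coefficient,
#' betweenness and reachability, plus the directed average path length
#' (APL) over reachable ordered pairs. The summary means follow the
#' conventions of regulatory-network reporting: out-degree (targets per
#' regulator) is averaged over TF/miRNA nodes only, in-degree (regulators
#' per target) over nodes with at least one incoming arc, and the other
#' three metrics over all nodes. The number of reachable ordered pairs
#' behind the APL is reported alongside.
#'
#' @param net a non-empty `typed_network`.
#' @return A `topology_report`: list with `out_degree_mean`,
#'   `in_degree_mean`, `cc_mean`, `apl`, `bw_mean`, `reach_mean`,
#'   `n_reachable_pairs`, and `node_table` (per-node data frame).
#' @export
network_metrics <- function(net) {
  n <- n_nodes(net)
  if (n == 0) stop("empty network")
  deg <- degree_table(net)
  cc <- cpp_clustering_coeff(n, net$from, net$to)
  pm <- cpp_path_metrics(n, net$from, net$to)
  reach <- if (n > 1) pm$reach_count / (n - 1) else rep(0, n)

  node_table <- data.frame(deg,
                           cc = cc,
                           betweenness = pm$betweenness,
                           reachability = reach,
                           stringsAsFactors = FALSE)
  is_reg <- deg$type %in% c("TF", "miRNA")
  has_in <- deg$in_degree >= 1
  structure(list(
    out_degree_mean = if (any(is_reg)) mean(deg$out_degree[is_reg]) else NA_real_,
    in_degree_mean = if (any(has_in)) mean(deg$in_degree[has_in]) else NA_real_,
    cc_mean = mean(cc),
    apl = if (pm$n_reachable_pairs > 0) pm$apl_sum / pm$n_reachable_pairs else NA_real_,
    bw_mean = mean(pm$betweenness),
    reach_mean = mean(reach),
    n_reachable_pairs = pm$n_reachable_pairs,
    node_table = node_table
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0("topology_report: out-deg %.3f | in-deg %.3f | ",
                     "CC %.4f | APL %.3f | BW %.3f | reach %.4f\n"),
              x$out_degree_mean, x$in_degree_mean, x$cc_mean, x$apl,
              x$bw_mean, x$reach_mean))
  invisible(x)
}

topology_metric_names <- c("out_degree_mean", "in_degree_mean", "cc_mean",
                           "apl", "bw_mean", "reach_mean")

#' Random same-size sub-network null for topology metrics
#'
#' Each replicate samples the requested number of TFs, miRNAs and genes
#' uniformly from the static network, applies the backtrack closure and
#' induced wiring exactly as [extract_active()] does, and computes
#' [network_metrics()]. Means and standard deviations over replicates
#' give the reference against which an observed active sub-network's
#' topology is judged. Metrics undefined in a replicate (e.g. APL in an
#' arcless sample) are dropped from that metric's summary.
#'
#' @param irn the static `typed_network`.
#' @param n_tf,n_mirna,n_gene node counts to sample per type (each must
#'   not exceed availability in `irn`).
#' @param n_rand number of replicates (>= 2; 300 is the conventional
#'   choice).
#' @param seed integer RNG seed.
#' @return A `null_topology`: list with `mean` and `sd` (named by
#'   metric), `replicates` (data frame), `n_rand`, `seed`.
#' @export
random_subnetwork_null <- function(irn, n_tf, n_mirna, n_gene,
                                   n_rand = 300, seed = 1L) {
  if (n_rand < 2) stop("`n_rand` must be >= 2")
  pools <- split(irn$node_id, factor(irn$node_type, levels = NODE_TYPES))
  want <- c(TF = n_tf, miRNA = n_mirna, gene = n_gene)
  for (ty in NODE_TYPES) {
    if (want[[ty]] > length(pools[[ty]]))
      stop("requested ", want[[ty]], " ", ty, " nodes but only ",
           length(pools[[ty]]), " available")
  }
  set.seed(seed)
  reps <- matrix(NA_real_, n_rand, length(topology_metric_names),
                 dimnames = list(NULL, topology_metric_names))
  for (r in seq_len(n_rand)) {
    picked <- c(sample(pools$TF, n_tf),
                sample(pools$miRNA, n_mirna),
                sample(pools$gene, n_gene))
    closed <- backtrack_closure(picked, irn)
    sub <- induced_subnetwork(irn, closed)
    m <- network_metrics(sub)
    reps[r, ] <- unlist(m[topology_metric_names])
  }
  structure(list(
    mean = colMeans(reps, na.rm = TRUE),
    sd = apply(reps, 2, sd, na.rm = TRUE),
    replicates = as.data.frame(reps),
    n_rand = n_rand, seed = seed
  ), class = "null_topology")
}

#' @export
print.null_topology <- function(x, ...) {
  cat("null_topology over", x$n_rand, "random sub-networks (seed",
      x$seed, "):\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Hub-removal perturbation curve
#'
#' Repeatedly removes the node with the highest total (in + out) degree,
#' recomputing degrees after every removal and breaking ties by
#' lexicographically smallest node id, and counts the singletons produced:
#' remaining nodes with total degree 0 that had positive degree in the
#' input network. A fragile, modular network sheds satellites quickly;
#' a densely interconnected one resists.
#'
#' @param net a `typed_network`.
#' @param k_max number of hubs to remove (1 <= k_max <= number of nodes).
#' @return A `perturbation_curve`: data frame with columns `step`,
#'   `removed_id`, `n_singletons`.
#' @export
perturb_hubs <- function(net, k_max) {
  if (k_max < 1) stop("`k_max` must be >= 1")
  if (k_max > n_nodes(net)) stop("`k_max` exceeds the number of nodes")
  n <- n_nodes(net)
  from <- net$from; to <- net$to
  alive <- rep(TRUE, n)
  deg0 <- tabulate(c(from, to), nbins = n)
  had_degree <- deg0 > 0

  steps <- data.frame(step = integer(k_max),
                      removed_id = character(k_max),
                      n_singletons = integer(k_max),
                      stringsAsFactors = FALSE)
  for (k in seq_len(k_max)) {
    live_arc <- alive[from] & alive[to]
    deg <- tabulate(c(from[live_arc], to[live_arc]), nbins = n)
    deg[!alive] <- -1L
    cand <- which(deg == max(deg))
    hub <- cand[order(net$node_id[cand])][1]
    alive[hub] <- FALSE
    live_arc <- alive[from] & alive[to]
    deg <- tabulate(c(from[live_arc], to[live_arc]), nbins = n)
    singles <- sum(alive & had_degree & deg == 0)
    steps$step[k] <- k
    steps$removed_id[k] <- net$node_id[hub]
    steps$n_singletons[k] <- singles
  }
  structure(steps, class = c("perturbation_curve", "data.frame"))
}
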