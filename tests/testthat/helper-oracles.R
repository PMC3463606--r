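# Independent brute-force oracles used to validate the graph kernels.
# They are deliberately implemented through a different route than the
# package (boolean/counting matrix powers and exhaustive scans), so that
# agreement is meaningful.

# random typed network: regulator sources, arbitrary targets, simple graph
rand_typed_net <- function(n_tf = 2, n_mirna = 2, n_gene = 6, n_arc = 15) {
  ids <- c(if (n_tf) sprintf("T%02d", seq_len(n_tf)),
           if (n_mirna) sprintf("M%02d", seq_len(n_mirna)),
           if (n_gene) sprintf("G%02d", seq_len(n_gene)))
  types <- stats::setNames(rep(c("TF", "miRNA", "gene"),
                               c(n_tf, n_mirna, n_gene)), ids)
  regs <- ids[types %in% c("TF", "miRNA")]
  src <- sample(regs, n_arc, replace = TRUE)
  tgt <- sample(ids, n_arc, replace = TRUE)
  keep <- src != tgt
  suppressMessages(typed_network(cbind(src[keep], tgt[keep]), types))
}

adjacency_matrix <- function(net) {
  n <- length(net$node_id)
  A <- matrix(0, n, n, dimnames = list(net$node_id, net$node_id))
  A[cbind(net$from, net$to)] <- 1
  A
}

# all-pairs shortest-path lengths from successive counting-matrix powers:
# d(s,t) = smallest k with (A^k)[s,t] > 0. Also returns the geodesic
# counts sigma(s,t) = (A^d)[s,t] (a minimal-length walk is a path).
bf_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  P <- diag(n)
  for (k in seq_len(max(n - 1, 1))) {
    P <- P %*% A
    newly <- is.infinite(D) & P > 0
    D[newly] <- k
    S[newly] <- P[newly]
    if (!any(is.infinite(D[row(D) != col(D)]) & TRUE)) break
  }
  list(D = D, S = S)
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  bp <- bf_paths(A)
  D <- bp$D
  # sigma for arbitrary (s,t) at their own distances needs per-distance
  # powers; precompute A^k for k = 0..n-1
  pow <- vector("list", n)
  pow[[1]] <- diag(n)
  for (k in 2:max(n, 2)) pow[[k]] <- pow[[k - 1]] %*% A
  sig <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d)) return(0)
    pow[[d + 1]][s, t]
  }
  bw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      d <- D[s, t]
      if (!is.finite(d)) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == d) {
        acc <- acc + sig(s, v) * sig(v, t) / sig(s, t)
      }
    }
    bw[v] <- acc
  }
  bw
}

bf_clustering <- function(A) {
  n <- nrow(A)
  U <- (A + t(A)) > 0
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(U[v, ] | U[, v]); nb <- setdiff(nb, v)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    cc[v] <- sum(A[nb, nb]) / (k * (k - 1))
  }
  cc
}

bf_reachability <- function(A) {
  n <- nrow(A)
  R <- (diag(n) + A) > 0
  for (i in seq_len(n)) R <- (R %*% R) > 0   # boolean closure
  diag(R) <- FALSE
  rowSums(R) / (n - 1)
}

bf_apl <- function(A) {
  D <- bf_paths(A)$D
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off) & off > 0]
  if (!length(fin)) return(NA_real_)
  mean(fin)
}

# exhaustive scan for connected node triples
bf_triples <- function(net) {
  n <- length(net$node_id)
  if (n < 3) return(matrix(character(0), ncol = 3))
  A <- adjacency_matrix(net)
  U <- (A + t(A)) > 0
  combs <- utils::combn(n, 3)
  keep <- apply(combs, 2, function(tr) {
    u <- U[tr, tr]
    e <- sum(u) / 2
    if (e < 2) return(FALSE)
    # connected 3-node undirected graph: 2 or 3 undirected edges, and if
    # 2 they must share a node (always true on 3 nodes with 2 edges)
    TRUE
  })
  t(apply(combs[, keep, drop = FALSE], 2, function(tr) net$node_id[tr]))
}

triple_key <- function(m) {
  if (!nrow(m)) return(character(0))
  sort(apply(m, 1, function(r) paste(sort(r), collapse = "|")))
}

# per-node in/out-degree and neighbor-type composition fingerprint
swap_fingerprint <- function(net) {
  n <- length(net$node_id)
  out_t <- matrix(0L, n, 3)
  in_t <- matrix(0L, n, 3)
  tc <- match(net$node_type, c("TF", "miRNA", "gene"))
  for (e in seq_along(net$from)) {
    out_t[net$from[e], tc[net$to[e]]] <- out_t[net$from[e], tc[net$to[e]]] + 1L
    in_t[net$to[e], tc[net$from[e]]] <- in_t[net$to[e], tc[net$from[e]]] + 1L
  }
  list(out_type = out_t, in_type = in_t,
       out_deg = tabulate(net$from, n), in_deg = tabulate(net$to, n))
}

# ancestors of a seed set by boolean matrix closure (reverse reachability)
bf_closure <- function(seed_ids, net) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  R <- (diag(n) + A) > 0
  for (i in seq_len(n)) R <- (R %*% R) > 0
  seed_idx <- match(seed_ids, net$node_id)
  anc <- which(rowSums(R[, seed_idx, drop = FALSE]) > 0)
  sort(unique(net$node_id[union(anc, seed_idx)]))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
bf_hyper_tail <- function(c, k, G, n) {
  draws <- utils::combn(G, c)
  succ <- seq_len(n)   # first n elements carry the function
  hits <- apply(draws, 2, function(d) sum(d %in% succ))
  mean(hits >= k)
}
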