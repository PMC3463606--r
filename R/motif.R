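# Typed size-3 network motifs: ESU enumeration, canonical typed labels,
# family classification, degree-preserving typed edge-swap nulls, motif
# Z-scores and their dynamics across a series of networks.

# decode a canonical code into its type vector and 3x3 adjacency matrix
decode_motif_code <- function(code) {
  bits <- code %% 64
  tcode <- code %/% 64
  t3 <- tcode %% 3; tcode <- tcode %/% 3
  t2 <- tcode %% 3; t1 <- tcode %/% 3
  types <- NODE_TYPES[c(t1, t2, t3) + 1]
  b <- as.integer(intToBits(bits))[6:1]  # (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- b[1]; adj[1, 3] <- b[2]
  adj[2, 1] <- b[3]; adj[2, 3] <- b[4]
  adj[3, 1] <- b[5]; adj[3, 2] <- b[6]
  list(types = types, adj = adj)
}

motif_label_string <- function(code) {
  d <- decode_motif_code(code)
  bits <- c(d$adj[1, 2], d$adj[1, 3], d$adj[2, 1],
            d$adj[2, 3], d$adj[3, 1], d$adj[3, 2])
  paste0(paste(d$types, collapse = ","), "|", paste(bits, collapse = ""))
}

#' Motif family of a canonical code or 3-node subgraph
#'
#' Families follow the standard small-motif vocabulary for mixed
#' TF/miRNA networks:
#' * `RML` (regulating/regulated mutual loop): two regulators that
#'   regulate each other (a 2-cycle) plus an attached third node. Any
#'   3-node pattern containing a 2-cycle is tagged RML -- a 2-cycle's two
#'   sources are necessarily regulators.
#' * `FFL` (feed-forward loop): exactly the arcs A->B, A->C, B->C.
#' * `SIM` (single input module): one regulator controlling two targets,
#'   no other arcs.
#' * `CRM` (co-regulating module): two regulators sharing one target, no
#'   other arcs.
#' * `other`: everything else.
#'
#' @param code integer canonical code (as produced by
#'   [canonical_typed_label()] or [count_motifs()]).
#' @return A string: one of `"RML"`, `"FFL"`, `"SIM"`, `"CRM"`, `"other"`.
#' @export
motif_family <- function(code) {
  d <- decode_motif_code(code)
  a <- d$adj
  if (any(a & t(a))) return("RML")
  s <- sum(a)
  if (s == 3) {
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    for (p in perms)
      if (a[p[1], p[2]] && a[p[1], p[3]] && a[p[2], p[3]]) return("FFL")
  }
  if (s == 2) {
    if (any(rowSums(a) == 2)) return("SIM")
    if (any(colSums(a) == 2)) return("CRM")
  }
  "other"
}

#' Canonical label of a typed 3-node subgraph
#'
#' Two 3-node subgraphs receive the same canonical label exactly when a
#' node bijection preserves both node types and arcs (typed isomorphism).
#' The label is the minimum, over the six node permutations, of a fixed
#' serialization of the (type vector, adjacency bits) pair.
#'
#' @param x either a `typed_network` with exactly 3 nodes, or a character
#'   vector of 3 node types (`"TF"`, `"miRNA"`, `"gene"`).
#' @param adj when `x` is a type vector: a 3x3 0/1 (or logical) adjacency
#'   matrix, `adj[i, j] == 1` meaning an arc from node i to node j.
#' @return A `typed_motif`: list with integer `code`, string `label`
#'   (types in canonical order, then the 6 adjacency bits), and `family`.
#' @export
canonical_typed_label <- function(x, adj = NULL) {
  if (inherits(x, "typed_network")) {
    if (n_nodes(x) != 3) stop("subgraph must have exactly 3 nodes")
    types <- x$node_type
    adj <- matrix(0L, 3, 3)
    adj[cbind(x$from, x$to)] <- 1L
  } else {
    types <- as.character(x)
    if (length(types) != 3 || is.null(adj))
      stop("supply a 3-node typed_network, or 3 types plus a 3x3 adjacency")
    adj <- matrix(as.integer(adj != 0), 3, 3)
    if (any(diag(adj) != 0)) stop("self-loops are not allowed")
  }
  tcodes <- match(types, NODE_TYPES)
  if (anyNA(tcodes)) stop("types must be TF, miRNA or gene")
  if (any(adj[tcodes == 3, ] != 0))
    stop("arc source typed 'gene' is invalid")
  code <- cpp_canonical_code(tcodes, adj)
  structure(list(code = code,
                 label = motif_label_string(code),
                 family = motif_family(code)),
            class = "typed_motif")
}

#' @export
print.typed_motif <- function(x, ...) {
  cat("typed_motif:", x$label, "(", x$family, ")\n")
  invisible(x)
}

#' Enumerate connected 3-node induced subgraphs (ESU)
#'
#' Exhaustive, non-redundant enumeration in the style of Wernicke's ESU
#' algorithm: every 3-node induced subgraph that is connected when arc
#' direction is ignored is produced exactly once.
#'
#' @param net a `typed_network`.
#' @return Character matrix with 3 columns; each row is one node triple.
#' @export
enumerate_size3 <- function(net) {
  tri <- cpp_esu_triples(n_nodes(net), net$from, net$to)
  matrix(net$node_id[tri], ncol = 3)
}

#' Count typed size-3 motifs
#'
#' Canonicalizes every connected triple from [enumerate_size3()] and
#' tallies counts per canonical label. With `require_tf_and_mirna = TRUE`
#' only triples containing at least one TF and at least one miRNA are
#' kept -- the filter used when the interest is in mixed
#' transcriptional/post-transcriptional circuitry.
#'
#' @param net a `typed_network`.
#' @param require_tf_and_mirna keep only triples with >= 1 TF and >= 1
#'   miRNA.
#' @return Data frame with columns `code`, `label`, `family`, `count`,
#'   ordered by code. With the filter off, the counts sum to the number
#'   of connected triples.
#' @export
count_motifs <- function(net, require_tf_and_mirna = FALSE) {
  res <- cpp_count_motifs(n_nodes(net), net$from, net$to,
                          type_codes(net), require_tf_and_mirna)
  data.frame(code = res$code,
             label = vapply(res$code, motif_label_string, character(1)),
             family = vapply(res$code, motif_family, character(1)),
             count = res$count,
             stringsAsFactors = FALSE)
}

#' Typed degree-preserving edge swap
#'
#' Randomizes a network by repeated double-arc swaps in which the partner
#' arc must have the same (source type, target type) class; a proposed
#' swap is rejected if it would create a self-loop or duplicate an
#' existing arc. Every node keeps its exact in-degree, out-degree, and
#' the type composition of its in- and out-neighborhoods -- the null
#' model used for motif significance. Networks with nothing to swap are
#' returned as an unchanged copy (with a message).
#'
#' @param net a `typed_network`.
#' @param n_attempts number of proposed swaps (default 10 x arc count).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (so that callers can manage seeding).
#' @return A `typed_network` with the same nodes and degree structure;
#'   the achieved swap count is in `attr(, "n_swapped")`.
#' @export
typed_edge_swap <- function(net, n_attempts = 10 * n_arcs(net), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_arcs(net)
  if (m < 2) {
    out <- net
    attr(out, "n_swapped") <- 0
    message("typed_edge_swap: fewer than 2 arcs, returning a copy")
    return(out)
  }
  res <- cpp_typed_edge_swap(n_nodes(net), net$from, net$to,
                             type_codes(net), n_attempts)
  out <- net
  out$from <- res$from
  out$to <- res$to
  attr(out, "n_swapped") <- res$n_swapped
  if (res$n_swapped == 0)
    message("typed_edge_swap: no swap was accepted; network unchanged")
  out
}

# align a list of count data frames (code/count or family/count) on the
# union of keys; returns a matrix draws x keys
align_counts <- function(count_list, keys) {
  mat <- matrix(0, length(count_list), length(keys),
                dimnames = list(NULL, keys))
  for (i in seq_along(count_list)) {
    cl <- count_list[[i]]
    mat[i, match(cl$key, keys)] <- cl$count
  }
  mat
}

motif_counts_keyed <- function(net, require_tf_and_mirna, by) {
  cm <- count_motifs(net, require_tf_and_mirna)
  if (by == "family") {
    agg <- tapply(cm$count, cm$family, sum)
    data.frame(key = names(agg), count = as.vector(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = cm$label, count = cm$count, code = cm$code,
               family = cm$family, stringsAsFactors = FALSE)
  }
}

#' Motif Z-scores against the typed edge-swap null
#'
#' Compares the observed count of every canonical motif (or motif family)
#' with its distribution over `n_rand` independently randomized copies of
#' the network, each produced by [typed_edge_swap()] from the original.
#' Z = (observed - null mean) / null SD; motifs seen only in the null (or
#' only in the real network) enter with count 0, and a zero null SD gives
#' `NA` rather than an infinite Z.
#'
#' @param net a `typed_network`.
#' @param n_rand number of randomized networks (>= 2).
#' @param n_swap_attempts swap attempts per randomization (default
#'   10 x arc count).
#' @param seed optional integer seed (recorded in the result).
#' @param require_tf_and_mirna restrict to triples with >= 1 TF and >= 1
#'   miRNA (the default, as in mixed-regulator motif analysis).
#' @param by score individual canonical labels (`"label"`) or aggregate
#'   counts into families first (`"family"`).
#' @param network_label optional label (e.g. a time point) stored in the
#'   result.
#' @return A `motif_zprofile`: list with `table` (data frame `label`,
#'   `family`, `observed`, `null_mean`, `null_sd`, `z`), `n_rand`,
#'   `seed`, `by`, `network_label`.
#' @export
motif_zscores <- function(net, n_rand = 1000, n_swap_attempts = NULL,
                          seed = NULL, require_tf_and_mirna = TRUE,
                          by = c("label", "family"),
                          network_label = NULL) {
  by <- match.arg(by)
  if (n_rand < 2) stop("`n_rand` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swap_attempts)) n_swap_attempts <- 10 * n_arcs(net)

  obs <- motif_counts_keyed(net, require_tf_and_mirna, by)
  nulls <- vector("list", n_rand)
  for (r in seq_len(n_rand)) {
    rn <- suppressMessages(typed_edge_swap(net, n_swap_attempts))
    nulls[[r]] <- motif_counts_keyed(rn, require_tf_and_mirna, by)
  }
  keys <- unique(c(obs$key, unlist(lapply(nulls, `[[`, "key"))))
  keys <- keys[order(keys)]
  observed <- as.vector(align_counts(list(obs), keys))
  null_mat <- align_counts(nulls, keys)
  null_mean <- colMeans(null_mat)
  null_sd <- apply(null_mat, 2, sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)

  fam <- if (by == "family") keys
         else vapply(keys, function(k) {
           hit <- match(k, obs$key)
           if (!is.na(hit)) obs$family[hit]
           else {
             for (nl in nulls) {
               hit <- match(k, nl$key)
               if (!is.na(hit)) return(nl$family[hit])
             }
             NA_character_
           }
         }, character(1))
  structure(list(
    table = data.frame(label = keys, family = unname(fam),
                       observed = observed, null_mean = null_mean,
                       null_sd = null_sd, z = z,
                       row.names = NULL, stringsAsFactors = FALSE),
    n_rand = n_rand, seed = seed, by = by,
    n_swap_attempts = n_swap_attempts,
    network_label = network_label
  ), class = "motif_zprofile")
}

#' @export
print.motif_zprofile <- function(x, ...) {
  cat("motif_zprofile", if (!is.null(x$network_label))
    paste0("@ ", x$network_label), "(", x$n_rand, "randomizations, by",
    x$by, "):\n")
  tab <- x$table[order(-abs(ifelse(is.na(x$table$z), 0, x$table$z))), ]
  print(head(tab, 10), row.names = FALSE)
  invisible(x)
}

#' Two-node mutual-regulation count and Z-score
#'
#' Counts unordered regulator pairs \{a, b\} carrying both arcs a->b and
#' b->a, optionally scored against the same typed edge-swap null as the
#' 3-node motifs.
#'
#' @inheritParams motif_zscores
#' @param n_rand randomizations for the Z-score; NULL for the raw count
#'   only.
#' @return List with `observed` and, when `n_rand` is given, `null_mean`,
#'   `null_sd`, `z`, `n_rand`, `seed`.
#' @export
count_2node_mutual <- function(net, n_rand = NULL, seed = NULL,
                               n_swap_attempts = NULL) {
  mutual_count <- function(nw) {
    key <- paste(nw$from, nw$to)
    rev_key <- paste(nw$to, nw$from)
    sum(nw$from < nw$to & rev_key %in% key)
  }
  observed <- mutual_count(net)
  if (is.null(n_rand)) return(list(observed = observed))
  if (n_rand < 2) stop("`n_rand` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swap_attempts)) n_swap_attempts <- 10 * n_arcs(net)
  null_counts <- vapply(seq_len(n_rand), function(r)
    mutual_count(suppressMessages(typed_edge_swap(net, n_swap_attempts))),
    numeric(1))
  nm <- mean(null_counts); ns <- sd(null_counts)
  list(observed = observed, null_mean = nm, null_sd = ns,
       z = if (ns > 0) (observed - nm) / ns else NA_real_,
       n_rand = n_rand, seed = seed)
}

#' Motif dynamics across a series of networks
#'
#' Runs [motif_zscores()] on each network of a series (typically the
#' per-time-point active sub-networks) and aligns the profiles on the
#' union of canonical labels, yielding a motif x network Z-matrix.
#' Undefined Z-values (zero null SD) are `NA` in the matrix.
#'
#' @param subnets list of `typed_network` or `active_subnetwork` objects;
#'   column labels come from each element's `timepoint`, the list names,
#'   or positional defaults.
#' @inheritParams motif_zscores
#' @param seed master seed; one shared sub-seed for the per-network null
#'   ensembles is drawn from it, so identical networks receive identical
#'   Z columns.
#' @return A `motif_dynamics`: list with `z` (matrix, rows = motifs,
#'   columns = networks), `observed` (same shape), and `profiles` (the
#'   per-network `motif_zprofile`s).
#' @export
motif_dynamics <- function(subnets, n_rand = 1000, seed = 1L,
                           n_swap_attempts = NULL,
                           require_tf_and_mirna = TRUE,
                           by = c("label", "family")) {
  by <- match.arg(by)
  if (length(subnets) < 2) stop("need >= 2 networks")
  nets <- lapply(subnets, function(s)
    if (inherits(s, "active_subnetwork")) s$subnet else s)
  labels <- vapply(seq_along(subnets), function(i) {
    s <- subnets[[i]]
    if (inherits(s, "active_subnetwork") && !is.null(s$timepoint))
      as.character(s$timepoint)
    else if (!is.null(names(subnets)) && nzchar(names(subnets)[i]))
      names(subnets)[i]
    else paste0("net", i)
  }, character(1))

  set.seed(seed)
  # one shared sub-seed: identical networks then yield identical Z columns
  sub_seed <- sample.int(.Machine$integer.max, 1)
  profiles <- lapply(seq_along(nets), function(i)
    motif_zscores(nets[[i]], n_rand = n_rand,
                  n_swap_attempts = n_swap_attempts, seed = sub_seed,
                  require_tf_and_mirna = require_tf_and_mirna, by = by,
                  network_label = labels[i]))
  keys <- sort(unique(unlist(lapply(profiles, function(p) p$table$label))))
  zmat <- matrix(NA_real_, length(keys), length(nets),
                 dimnames = list(keys, labels))
  omat <- matrix(0, length(keys), length(nets),
                 dimnames = list(keys, labels))
  for (i in seq_along(profiles)) {
    tb <- profiles[[i]]$table
    zmat[match(tb$label, keys), i] <- tb$z
    omat[match(tb$label, keys), i] <- tb$observed
  }
  structure(list(z = zmat, observed = omat, profiles = profiles,
                 by = by, n_rand = n_rand, seed = seed),
            class = "motif_dynamics")
}

#' @export
print.motif_dynamics <- function(x, ...) {
  cat("motif_dynamics:", nrow(x$z), "motifs x", ncol(x$z),
      "networks (by", x$by, ",", x$n_rand, "randomizations)\n")
  invisible(x)
}

#' @rdname cluster_timepoints
#' @export
cluster_timepoints.motif_dynamics <- function(x, ...) {
  cluster_timepoints(x$z)
}

#' Write a motif Z-profile table
#'
#' @param profile a `motif_zprofile`.
#' @param path output TSV path.
#' @export
write_motif_table <- function(profile, path) {
  utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
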