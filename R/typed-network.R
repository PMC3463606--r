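#' @useDynLib retnetdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree dist hclust quantile sd as.dist phyper rnorm runif
#' @importFrom utils head
NULL

# Node type vocabulary, in the integer coding used by the compiled kernels:
# TF = 1, miRNA = 2, gene = 3.
NODE_TYPES <- c("TF", "miRNA", "gene")

#' Construct a typed regulatory network
#'
#' A typed network is a simple directed graph whose nodes carry one of the
#' three regulator types `TF`, `miRNA` or `gene`. Arcs point from a
#' regulator to its target; only TF- and miRNA-typed nodes may appear as
#' arc sources (plain genes never regulate). Self-loops are dropped at
#' construction (with a message reporting how many) and duplicate arcs are
#' collapsed, so the result is always a simple graph -- the form assumed by
#' the clustering-coefficient definition and the size-3 motif machinery.
#'
#' @param edges two-column data frame, matrix, or NULL: arcs as
#'   (source id, target id) character pairs.
#' @param types named character vector giving the type (`"TF"`, `"miRNA"`
#'   or `"gene"`) of every node; names are node ids. Nodes listed here but
#'   absent from `edges` become isolated nodes.
#' @return An object of class `typed_network` with elements `node_id`
#'   (character), `node_type` (character, parallel to `node_id`), and
#'   `from`/`to` (integer indices into `node_id`).
#' @seealso [load_edge_lists()], [summarize_network()],
#'   [induced_subnetwork()]
#' @export
typed_network <- function(edges, types) {
  if (is.null(names(types)) || anyNA(names(types)) || any(names(types) == ""))
    stop("`types` must be a character vector named by node id")
  if (anyDuplicated(names(types))) {
    # unique type per node id: keep the first listing
    types <- types[!duplicated(names(types))]
  }
  bad <- setdiff(unique(types), NODE_TYPES)
  if (length(bad))
    stop("unknown node type(s): ", paste(bad, collapse = ", "))

  node_id <- names(types)
  node_type <- unname(as.character(types))

  if (is.null(edges) || NROW(edges) == 0) {
    from <- integer(0); to <- integer(0)
    n_self <- 0L; n_dup <- 0L
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("`edges` must have two columns (source, target)")
    src <- as.character(edges[, 1]); tgt <- as.character(edges[, 2])
    unknown <- setdiff(unique(c(src, tgt)), node_id)
    if (length(unknown))
      stop("edge endpoints without a declared type: ",
           paste(head(unknown, 5), collapse = ", "))
    self <- src == tgt
    n_self <- sum(self)
    src <- src[!self]; tgt <- tgt[!self]
    key <- paste(src, tgt, sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    src <- src[!dup]; tgt <- tgt[!dup]
    from <- match(src, node_id)
    to <- match(tgt, node_id)
  }

  src_types <- node_type[from]
  if (any(src_types == "gene"))
    stop("arc source(s) typed 'gene': ",
         paste(head(unique(node_id[from][src_types == "gene"]), 5),
               collapse = ", "),
         " (only TFs and miRNAs may regulate)")

  net <- structure(
    list(node_id = node_id, node_type = node_type, from = from, to = to),
    class = "typed_network",
    n_self_loops_dropped = n_self,
    n_duplicates_dropped = n_dup
  )
  if (n_self > 0)
    message("typed_network: dropped ", n_self, " self-loop arc(s)")
  net
}

#' @export
print.typed_network <- function(x, ...) {
  tab <- table(factor(x$node_type, levels = NODE_TYPES))
  cat("typed_network:", length(x$node_id), "nodes (",
      tab[["TF"]], "TF,", tab[["miRNA"]], "miRNA,", tab[["gene"]], "gene ),",
      length(x$from), "arcs\n")
  invisible(x)
}

n_nodes <- function(net) length(net$node_id)
n_arcs <- function(net) length(net$from)

# integer node-type codes for the compiled kernels
type_codes <- function(net) match(net$node_type, NODE_TYPES)

node_index <- function(net, ids) {
  idx <- match(ids, net$node_id)
  if (anyNA(idx))
    stop("unknown node id(s): ", paste(head(ids[is.na(idx)], 5), collapse = ", "))
  idx
}

#' Nodes of a typed network
#'
#' @param net a `typed_network`.
#' @return Data frame with columns `id` and `type`.
#' @export
network_nodes <- function(net) {
  data.frame(id = net$node_id, type = net$node_type,
             stringsAsFactors = FALSE)
}

#' Arcs of a typed network
#'
#' @param net a `typed_network`.
#' @return Data frame with columns `source`, `target`, `source_type`.
#' @export
network_edges <- function(net) {
  data.frame(source = net$node_id[net$from],
             target = net$node_id[net$to],
             source_type = net$node_type[net$from],
             stringsAsFactors = FALSE)
}

#' Induced subnetwork on a node set
#'
#' Keeps the requested nodes and every arc of `net` whose two endpoints
#' both belong to the set.
#'
#' @param net a `typed_network`.
#' @param ids character vector of node ids (must exist in `net`).
#' @return A `typed_network` on exactly those nodes.
#' @export
induced_subnetwork <- function(net, ids) {
  ids <- unique(as.character(ids))
  idx <- node_index(net, ids)
  keep_node <- logical(n_nodes(net))
  keep_node[idx] <- TRUE
  keep_arc <- keep_node[net$from] & keep_node[net$to]
  types <- net$node_type[idx]
  names(types) <- net$node_id[idx]
  edges <- cbind(net$node_id[net$from[keep_arc]],
                 net$node_id[net$to[keep_arc]])
  typed_network(edges, types)
}

#' In- and out-neighbor sets of a node
#'
#' `neighborhood()` returns the union of in- and out-neighbors, the N(v)
#' set over which the clustering coefficient is defined.
#'
#' @param net a `typed_network`.
#' @param id a single node id.
#' @return Character vector of neighbor ids (excluding `id` itself).
#' @export
neighborhood <- function(net, id) {
  v <- node_index(net, id)
  nb <- c(net$to[net$from == v], net$from[net$to == v])
  setdiff(unique(net$node_id[nb]), id)
}

#' Degree table of a typed network
#'
#' @param net a `typed_network`.
#' @return Data frame with `id`, `type`, `out_degree`, `in_degree`.
#' @export
degree_table <- function(net) {
  n <- n_nodes(net)
  data.frame(id = net$node_id,
             type = net$node_type,
             out_degree = tabulate(net$from, nbins = n),
             in_degree = tabulate(net$to, nbins = n),
             stringsAsFactors = FALSE)
}
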