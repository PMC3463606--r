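# Per-time-point active sub-network extraction: expression thresholding,
# backtrack regulator closure, induced wiring, and time-point-specific
# gene sets.

#' Activity threshold rule
#'
#' An activity rule decides which entities count as "expressed" at a time
#' point: either an absolute log2 cutoff, or a per-time-point percentile
#' of the expression values at that time point. Entities strictly above
#' the threshold are active. A rule can also be given as a string such as
#' `"percentile:50"` or `"absolute:6"`.
#'
#' @param type `"percentile"` or `"absolute"`.
#' @param value percentile in \[0, 100\], or an absolute log2 value.
#' @return An `activity_rule` object.
#' @export
activity_rule <- function(type = c("percentile", "absolute"), value = 50) {
  type <- match.arg(type)
  if (type == "percentile" && (value < 0 || value > 100))
    stop("percentile must be in [0, 100]")
  structure(list(type = type, value = value), class = "activity_rule")
}

as_activity_rule <- function(rule) {
  if (inherits(rule, "activity_rule")) return(rule)
  if (is.character(rule) && length(rule) == 1) {
    parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("rule string must look like 'percentile:50'")
    return(activity_rule(parts[1], as.numeric(parts[2])))
  }
  stop("`rule` must be an activity_rule or a 'type:value' string")
}

#' @export
print.activity_rule <- function(x, ...) {
  cat("activity_rule:", x$type, x$value, "\n")
  invisible(x)
}

#' Initial active set at a time point
#'
#' Entities whose expression at the given time point is strictly greater
#' than the rule's threshold.
#'
#' @param expr an `expression_matrix`.
#' @param timepoint a time-point label present in `expr`.
#' @param rule an [activity_rule()] (or `"type:value"` string); default is
#'   the per-time-point 50th percentile.
#' @return Character vector of active entity ids.
#' @export
initial_active_set <- function(expr, timepoint, rule = activity_rule()) {
  rule <- as_activity_rule(rule)
  if (!timepoint %in% colnames(expr$values))
    stop("unknown time point: ", timepoint)
  v <- expr$values[, timepoint]
  thr <- if (rule$type == "absolute") rule$value
         else unname(quantile(v, rule$value / 100))
  rownames(expr$values)[v > thr]
}

#' Backtrack regulator closure
#'
#' The smallest superset S of `seed_set` such that every TF or miRNA with
#' an arc into a member of S is itself in S. Regulators are pulled in
#' regardless of their own expression; the process repeats until no new
#' regulator is added (a fixpoint). Because only TFs and miRNAs can be
#' arc sources, this equals the set of all upstream ancestors of the seed
#' set under directed reachability.
#'
#' @param seed_set character vector of node ids (subset of `net` nodes).
#' @param net a `typed_network`.
#' @return Character vector: the closed node set (a superset of
#'   `seed_set`), in network node order.
#' @export
backtrack_closure <- function(seed_set, net) {
  seed_set <- unique(as.character(seed_set))
  if (!length(seed_set)) return(character(0))
  idx <- node_index(net, seed_set)
  in_set <- logical(n_nodes(net))
  in_set[idx] <- TRUE
  repeat {
    regs <- net$from[in_set[net$to] & !in_set[net$from]]
    if (!length(regs)) break
    in_set[regs] <- TRUE
  }
  net$node_id[in_set]
}

#' Extract the active sub-network at a time point
#'
#' Thresholds expression at the time point, intersects with the network's
#' node set, applies the backtrack closure, and wires the closed set by
#' taking the induced subgraph of the static network.
#'
#' @inheritParams initial_active_set
#' @param net a `typed_network` (the static IRN).
#' @return An `active_subnetwork`: list with `timepoint`, `initial_set`
#'   (above-threshold ids, restricted to network nodes), `closed_set`,
#'   and `subnet` (a `typed_network` induced on `closed_set`).
#' @export
extract_active <- function(expr, net, timepoint, rule = activity_rule()) {
  act <- initial_active_set(expr, timepoint, rule)
  initial <- intersect(act, net$node_id)
  closed <- backtrack_closure(initial, net)
  structure(list(timepoint = timepoint,
                 initial_set = initial,
                 closed_set = closed,
                 subnet = induced_subnetwork(net, closed)),
            class = "active_subnetwork")
}

#' @export
print.active_subnetwork <- function(x, ...) {
  cat("active_subnetwork @", x$timepoint, ":", length(x$initial_set),
      "seed nodes ->", length(x$closed_set), "after backtrack,",
      n_arcs(x$subnet), "arcs\n")
  invisible(x)
}

#' Time-point-specific and housekeeping sets
#'
#' Housekeeping entities are active (by the same rule as the active-set
#' extraction) at every time point. The specific set of a time point is
#' its active set minus the housekeeping set; an entity active at several
#' but not all time points therefore appears in each of those specific
#' sets.
#'
#' @inheritParams initial_active_set
#' @return A `specific_sets` object: list with `housekeeping` (character
#'   vector) and `specific` (named list of character vectors, one per
#'   time point).
#' @export
specific_sets <- function(expr, rule = activity_rule()) {
  tps <- colnames(expr$values)
  if (length(tps) < 2) stop("need >= 2 time points")
  active <- lapply(tps, function(tp) initial_active_set(expr, tp, rule))
  names(active) <- tps
  housekeeping <- Reduce(intersect, active)
  specific <- lapply(active, setdiff, y = housekeeping)
  structure(list(housekeeping = housekeeping, specific = specific),
            class = "specific_sets")
}

#' @export
print.specific_sets <- function(x, ...) {
  cat("specific_sets:", length(x$housekeeping), "housekeeping;",
      paste(sprintf("%s: %d", names(x$specific), lengths(x$specific)),
            collapse = ", "), "\n")
  invisible(x)
}
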