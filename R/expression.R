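# Expression-matrix handling: Pearson correlation, entity clustering, the
# miRNA-target correlation-bin randomization test, and time-point
# clustering from expression profiles.

#' Construct an expression matrix over an ordered time-point axis
#'
#' Values are log2-scale expression measurements for typed entities
#' (genes, miRNAs, TFs) over an ordered series of time points. Rows
#' containing missing values are dropped with a message; column order is
#' preserved as given and is meaningful (it is the developmental axis).
#'
#' @param values numeric matrix, entities x time points; rownames are
#'   entity ids, colnames are time-point labels.
#' @param types named character vector giving each entity's type
#'   (`"TF"`, `"miRNA"`, `"gene"`).
#' @return An object of class `expression_matrix` with elements `values`
#'   and `type` (named character vector aligned with the rows).
#' @export
expression_matrix <- function(values, types) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs rownames (entity ids) and colnames (time points)")
  if (anyDuplicated(rownames(values))) stop("duplicated entity ids")
  miss <- setdiff(rownames(values), names(types))
  if (length(miss))
    stop("entities without a declared type: ",
         paste(head(miss, 5), collapse = ", "))
  bad_type <- setdiff(unique(types[rownames(values)]), NODE_TYPES)
  if (length(bad_type)) stop("unknown type(s): ", paste(bad_type, collapse = ", "))
  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    message("expression_matrix: dropped ", sum(incomplete),
            " row(s) with missing values")
    values <- values[!incomplete, , drop = FALSE]
  }
  type <- as.character(types[rownames(values)])
  names(type) <- rownames(values)
  structure(list(values = values, type = type), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(factor(x$type, levels = NODE_TYPES))
  cat("expression_matrix:", nrow(x$values), "entities (",
      tab[["TF"]], "TF,", tab[["miRNA"]], "miRNA,", tab[["gene"]], "gene ) x",
      ncol(x$values), "time points:",
      paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Time-point labels of an expression matrix
#' @param expr an `expression_matrix`.
#' @return Character vector, in axis order.
#' @export
timepoint_labels <- function(expr) colnames(expr$values)

#' Entities of an expression matrix
#' @param expr an `expression_matrix`.
#' @return Data frame with columns `id`, `type`.
#' @export
expression_entities <- function(expr) {
  data.frame(id = rownames(expr$values), type = unname(expr$type),
             stringsAsFactors = FALSE)
}

#' Write / read the expression TSV format
#'
#' Columns: `id`, `type`, then one column per time point, with a header
#' row. Time-point order in the file is the axis order.
#'
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(id = rownames(expr$values), type = unname(expr$type),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @return `read_expression()` returns an `expression_matrix`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expression TSV needs id, type and >= 1 time point")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_matrix(vals, stats::setNames(df[[2]], df[[1]]))
}

#' Pearson correlation between two expression profiles
#'
#' The standard product-moment coefficient. Profiles of fewer than three
#' time points, or with zero variance, raise an error: a constant profile
#' has no defined correlation, and the caller decides whether to skip the
#' pair.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A number in \[-1, 1\].
#' @examples
#' pearson_cc(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("profiles must have length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant profile")
  cor(x, y)
}

#' Gene x miRNA correlation matrix
#'
#' Entry (g, m) is the Pearson correlation between the profile of gene `g`
#' and miRNA `m`. Pairs involving a constant profile are returned as `NA`
#' (the undefined-correlation marker) with a warning giving the count.
#'
#' @param expr an `expression_matrix`.
#' @param genes,mirnas character vectors of entity ids present in `expr`.
#' @return Numeric matrix with `genes` as rows and `mirnas` as columns.
#' @export
correlation_matrix <- function(expr, genes, mirnas) {
  all_ids <- rownames(expr$values)
  missing <- setdiff(c(genes, mirnas), all_ids)
  if (length(missing))
    stop("unknown entity id(s): ", paste(head(missing, 5), collapse = ", "))
  gx <- expr$values[genes, , drop = FALSE]
  mx <- expr$values[mirnas, , drop = FALSE]
  const_g <- apply(gx, 1, sd) == 0
  const_m <- apply(mx, 1, sd) == 0
  suppressWarnings(res <- cor(t(gx), t(mx)))
  if (any(const_g) || any(const_m)) {
    res[const_g, ] <- NA_real_
    res[, const_m] <- NA_real_
    warning(sum(const_g) + sum(const_m),
            " constant profile(s): correlations set to NA")
  }
  res
}

# rows standardized to mean 0, sd 1; rows with sd 0 are flagged via the
# 'ok' attribute
standardize_rows <- function(values) {
  mu <- rowMeans(values)
  cen <- values - mu
  s <- sqrt(rowSums(cen^2) / (ncol(values) - 1))
  z <- cen / s
  attr(z, "ok") <- s > 0
  z
}

#' Cluster entities by expression-profile correlation
#'
#' Hierarchical clustering with distance 1 - cc and average linkage, cut
#' at a fixed height; only clusters of at least `min_size` members are
#' returned. This mirrors the common practice of keeping the large,
#' well-populated expression clusters (e.g. >= 100 genes, >= 4 miRNAs)
#' and reporting each cluster's mean profile and peak time point.
#' Entities with constant profiles have no defined correlation and are
#' dropped with a message.
#'
#' @param expr an `expression_matrix`.
#' @param which entity type to cluster: `"gene"`, `"miRNA"` or `"TF"`.
#' @param min_size smallest cluster size to report (>= 1).
#' @param cut_height cut level on the 1 - cc scale (default 0.5).
#' @return List of clusters; each has `members`, `size`, `mean_profile`,
#'   and `peak` (the time-point label where the mean profile is maximal).
#'   Clusters are disjoint.
#' @export
cluster_entities <- function(expr, which = c("gene", "miRNA", "TF"),
                             min_size = 2, cut_height = 0.5) {
  which <- match.arg(which)
  if (min_size < 1) stop("`min_size` must be >= 1")
  ids <- rownames(expr$values)[expr$type == which]
  if (length(ids) < 2) stop("need >= 2 entities of type ", which)
  vals <- expr$values[ids, , drop = FALSE]
  const <- apply(vals, 1, sd) == 0
  if (any(const)) {
    message("cluster_entities: dropped ", sum(const),
            " constant profile(s)")
    vals <- vals[!const, , drop = FALSE]
    if (nrow(vals) < 2) stop("fewer than 2 non-constant profiles")
  }
  d <- as.dist(1 - cor(t(vals)))
  tree <- hclust(d, method = "average")
  grp <- cutree(tree, h = cut_height)
  out <- list()
  for (g in sort(unique(grp))) {
    members <- rownames(vals)[grp == g]
    if (length(members) < min_size) next
    mp <- colMeans(vals[members, , drop = FALSE])
    out[[length(out) + 1]] <- list(
      members = members,
      size = length(members),
      mean_profile = mp,
      peak = colnames(vals)[which.max(mp)]
    )
  }
  # largest clusters first, ties by earliest peak position for determinism
  if (length(out)) {
    sizes <- vapply(out, `[[`, integer(1), "size")
    peaks <- vapply(out, function(cl) match(cl$peak, colnames(vals)), integer(1))
    out <- out[order(-sizes, peaks)]
  }
  out
}

#' miRNA-target correlation distribution against a random-target null
#'
#' Scores the Pearson correlation between every miRNA and each of its
#' predicted targets (the miRNA-sourced arcs of `net` whose endpoints are
#' both measured), bins the correlations over \[-1, 1\], and compares the
#' per-bin counts with a null in which every miRNA's target set is
#' replaced by an equal-sized uniform sample (without replacement) of
#' measured genes. The per-bin Z-value is
#' (observed - null mean) / null SD; bins whose null SD is zero get `NA`
#' (the undefined marker), never +/-Inf.
#'
#' Pairs with an unmeasured endpoint, and pairs involving a constant
#' profile, are excluded (counts reported in the result).
#'
#' @param expr an `expression_matrix`.
#' @param net a `typed_network` with miRNA-sourced arcs.
#' @param bin_width bin width over \[-1, 1\]; must divide 2 into an
#'   integer number of bins (default 0.05). Bins are right-closed.
#' @param n_rand number of target-set randomizations (>= 2).
#' @param seed integer RNG seed (recorded in the result).
#' @return A `correlation_bin_report`: list with `table` (data frame
#'   `bin_lo`, `bin_hi`, `observed`, `null_mean`, `null_sd`, `z`),
#'   `n_pairs`, `n_excluded`, `n_rand`, `bin_width`, `seed`.
#' @export
target_correlation_z <- function(expr, net, bin_width = 0.05,
                                 n_rand = 1000, seed = 1L) {
  n_bins <- 2 / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("`bin_width` must divide the interval [-1, 1] evenly")
  n_bins <- as.integer(round(n_bins))
  if (n_rand < 2) stop("`n_rand` must be >= 2")

  measured <- rownames(expr$values)
  zrows <- standardize_rows(expr$values)
  ok <- attr(zrows, "ok")

  is_mir_arc <- net$node_type[net$from] == "miRNA"
  mir_id <- net$node_id[net$from[is_mir_arc]]
  tgt_id <- net$node_id[net$to[is_mir_arc]]
  keep <- mir_id %in% measured & tgt_id %in% measured
  n_unmeasured <- sum(!keep)
  mir_id <- mir_id[keep]; tgt_id <- tgt_id[keep]
  defined <- ok[match(mir_id, measured)] & ok[match(tgt_id, measured)]
  n_const <- sum(!defined)
  mir_id <- mir_id[defined]; tgt_id <- tgt_id[defined]
  if (!length(mir_id))
    stop("no measurable miRNA-target pairs with defined correlations")

  nt <- ncol(expr$values)
  cc_of <- function(i, j)   # correlation from pre-standardized rows
    pmin(1, pmax(-1, rowSums(zrows[i, , drop = FALSE] *
                             zrows[j, , drop = FALSE]) / (nt - 1)))
  bin_of <- function(cc) {  # right-closed bins; -1 falls in the first bin
    b <- ceiling((cc + 1) / bin_width)
    pmin(pmax(b, 1L), n_bins)
  }

  mi <- match(mir_id, measured)
  ti <- match(tgt_id, measured)
  observed <- tabulate(bin_of(cc_of(mi, ti)), nbins = n_bins)

  # null: per-miRNA target-set sizes are preserved exactly
  gene_pool <- which(expr$type == "gene" & ok)
  if (length(gene_pool) < max(table(mir_id)))
    stop("fewer measured genes than the largest target set")
  per_mir <- table(mir_id)
  mir_rep <- match(rep(names(per_mir), per_mir), measured)

  set.seed(seed)
  null_counts <- matrix(0L, n_rand, n_bins)
  for (r in seq_len(n_rand)) {
    rt <- unlist(lapply(as.integer(per_mir), function(k)
      sample(gene_pool, k)), use.names = FALSE)
    null_counts[r, ] <- tabulate(bin_of(cc_of(mir_rep, rt)), nbins = n_bins)
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)

  edges <- seq(-1, 1, by = bin_width)
  structure(list(
    table = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       observed = observed, null_mean = null_mean,
                       null_sd = null_sd, z = z),
    n_pairs = length(mir_id),
    n_excluded = c(unmeasured = n_unmeasured, constant = n_const),
    n_rand = n_rand, bin_width = bin_width, seed = seed
  ), class = "correlation_bin_report")
}

#' @export
print.correlation_bin_report <- function(x, ...) {
  cat("correlation_bin_report:", x$n_pairs, "miRNA-target pairs,",
      nrow(x$table), "bins,", x$n_rand, "randomizations (seed",
      x$seed, ")\n")
  hot <- x$table[!is.na(x$table$z) & abs(x$table$z) > 2, ]
  if (nrow(hot)) {
    cat("bins with |z| > 2:\n")
    print(hot, row.names = FALSE)
  }
  invisible(x)
}

#' Write a correlation-bin report
#'
#' TSV table plus a JSON sidecar carrying seed and randomization count.
#'
#' @param report a `correlation_bin_report`.
#' @param path output TSV path (`<path>.json` gets the metadata).
#' @export
write_correlation_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- report[c("n_pairs", "n_rand", "bin_width", "seed")]
  meta$n_excluded <- as.list(report$n_excluded)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Cluster time points
#'
#' Groups the columns of a time-course object by hierarchical clustering
#' (Euclidean distance, average linkage) and reports the full merge tree
#' together with its 2-group cut. For an expression matrix, each entity's
#' profile is standardized first so that profile shape, not absolute
#' level, drives the grouping; constant profiles contribute zeros. For a
#' motif Z-matrix (see [motif_dynamics()]), undefined Z-values are imputed
#' as 0 before computing distances.
#'
#' @param x an `expression_matrix`, a numeric matrix whose columns are
#'   time points, or a `motif_dynamics` object.
#' @param ... unused.
#' @return A `timepoint_partition`: list with `tree` (an `hclust`) and
#'   `groups` (named integer vector of 1/2 group labels).
#' @export
cluster_timepoints <- function(x, ...) UseMethod("cluster_timepoints")

cluster_columns <- function(mat) {
  if (ncol(mat) < 3) stop("need >= 3 time points to cluster")
  tree <- hclust(dist(t(mat)), method = "average")
  groups <- cutree(tree, k = 2)
  structure(list(tree = tree, groups = groups),
            class = "timepoint_partition")
}

#' @rdname cluster_timepoints
#' @export
cluster_timepoints.expression_matrix <- function(x, ...) {
  z <- standardize_rows(x$values)
  z[!attr(z, "ok"), ] <- 0
  cluster_columns(z)
}

#' @rdname cluster_timepoints
#' @export
cluster_timepoints.matrix <- function(x, ...) {
  x[is.na(x)] <- 0
  cluster_columns(x)
}

#' @export
print.timepoint_partition <- function(x, ...) {
  g1 <- names(x$groups)[x$groups == 1]
  g2 <- names(x$groups)[x$groups == 2]
  cat("timepoint_partition: {", paste(g1, collapse = ", "), "} vs {",
      paste(g2, collapse = ", "), "}\n")
  invisible(x)
}

#' Newick string for a time-point dendrogram
#'
#' @param partition a `timepoint_partition`.
#' @return Single-element character vector in Newick format.
#' @export
as_newick <- function(partition) {
  ape::write.tree(ape::as.phylo(partition$tree))
}
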