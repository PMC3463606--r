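# Synthetic-data generators: typed regulatory networks with planted
# motifs, clustered time-course expression with miRNA-target
# anti-correlation, early/late-regime network series, and planted
# annotation collections. Every generator is a pure function of its
# configuration: rerunning with the same config gives identical output.
# Stage seeds are derived from the master seed by fixed offsets
# (irn +0, expression +1, regimes +2, annotations +3).

#' Simulation configuration
#'
#' One configuration object drives all four generators. Defaults describe
#' a desk-scale analogue of a developmental time-course study: a
#' hub-dominated static network of 10 TFs, 30 miRNAs and 800 genes; six
#' ordered time points; four expression clusters peaking at distinct time
#' points; a fraction of miRNA-target pairs forced to strong expression
#' anti-correlation (plus a small positively correlated tail); and a
#' series of per-time-point networks split into an early regime (densely
#' cross-wired, mutual regulator loops) and a late regime (hub-and-spoke
#' modules bridged sparsely, with feed-forward and co-regulation
#' patterns).
#'
#' @param n_tf,n_mirna,n_gene node counts of the static network.
#' @param n_timepoints number of ordered time points (6 gives the labels
#'   E15, E18, P1, P5, P12, Adult).
#' @param n_clusters number of expression clusters; peaks are spread
#'   evenly over the time axis.
#' @param cluster_amplitude peak height of the cluster bump (log2 units).
#' @param cluster_width bump width in time-point units.
#' @param noise_sd Gaussian noise SD (log2 units) added to every profile,
#'   including the anti-correlated target profiles.
#' @param anticorr_fraction fraction of miRNA-to-gene arcs whose target
#'   profile is replaced by the negated miRNA profile plus noise.
#' @param poscorr_fraction fraction replaced by the positively correlated
#'   copy (the correlated tail).
#' @param degree_exponent exponent of the discrete power law from which
#'   regulator out-degrees are drawn.
#' @param min_out_degree lower cutoff of the out-degree law.
#' @param planted_motifs named integer vector: how many `FFL` and/or
#'   `RML` instances to plant into the static network.
#' @param regimes character vector, one `"early"`/`"late"` per time
#'   point.
#' @param regime_n_gene genes per regime network.
#' @param n_mutual_pairs mutually regulating regulator pairs per early
#'   network; `NULL` (the default) scales with the regulator count as
#'   15% of all regulator pairs, keeping the early regime densely
#'   cross-wired at any configured size.
#' @param reg_reg_p one-way regulator-to-regulator wiring probability in
#'   early networks.
#' @param gene_in_degree regulators per gene in early networks.
#' @param n_ffl_late,n_crm_late feed-forward loops and co-regulation
#'   patterns planted per late network.
#' @param annotate_fraction fraction of a cluster's genes annotated to
#'   its planted term.
#' @param background_fraction background genes added to each term, as a
#'   fraction of the term's cluster size.
#' @param seed master seed (mandatory; must be a positive integer below
#'   2^31 - 10).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tf = 10, n_mirna = 30, n_gene = 800,
                       n_timepoints = 6,
                       n_clusters = 4, cluster_amplitude = 3,
                       cluster_width = 1, noise_sd = 0.2,
                       anticorr_fraction = 0.3, poscorr_fraction = 0.05,
                       degree_exponent = 2.5, min_out_degree = 4,
                       planted_motifs = c(FFL = 0, RML = 0),
                       regimes = rep(c("early", "late"), each = 3),
                       regime_n_gene = 150,
                       n_mutual_pairs = NULL, reg_reg_p = 0.08,
                       gene_in_degree = 3,
                       n_ffl_late = 25, n_crm_late = 25,
                       annotate_fraction = 0.8,
                       background_fraction = 0.2,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed) || seed < 1 || seed > 2^31 - 10)
    stop("`seed` must be a positive integer below 2^31 - 10")
  seed <- as.integer(seed)
  counts <- c(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
              n_timepoints = n_timepoints, n_clusters = n_clusters,
              regime_n_gene = regime_n_gene)
  if (any(counts <= 0))
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  fracs <- c(anticorr_fraction = anticorr_fraction,
             poscorr_fraction = poscorr_fraction,
             annotate_fraction = annotate_fraction,
             background_fraction = background_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (anticorr_fraction + poscorr_fraction > 1)
    stop("anticorr_fraction + poscorr_fraction must be <= 1")
  if (length(regimes) != n_timepoints)
    stop("`regimes` must name one regime per time point")
  if (!all(regimes %in% c("early", "late")))
    stop("regimes must be 'early' or 'late'")
  if (degree_exponent <= 2)
    stop("`degree_exponent` must exceed 2 (finite mean out-degree)")
  pm <- c(FFL = 0, RML = 0)
  pm[names(planted_motifs)] <- planted_motifs
  structure(list(
    n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
    n_timepoints = n_timepoints,
    n_clusters = n_clusters, cluster_amplitude = cluster_amplitude,
    cluster_width = cluster_width, noise_sd = noise_sd,
    anticorr_fraction = anticorr_fraction,
    poscorr_fraction = poscorr_fraction,
    degree_exponent = degree_exponent, min_out_degree = min_out_degree,
    planted_motifs = pm,
    regimes = regimes, regime_n_gene = regime_n_gene,
    n_mutual_pairs = n_mutual_pairs, reg_reg_p = reg_reg_p,
    gene_in_degree = gene_in_degree,
    n_ffl_late = n_ffl_late, n_crm_late = n_crm_late,
    annotate_fraction = annotate_fraction,
    background_fraction = background_fraction,
    seed = seed
  ), class = "sim_config")
}

sim_timepoint_labels <- function(cfg) {
  if (cfg$n_timepoints == 6) c("E15", "E18", "P1", "P5", "P12", "Adult")
  else paste0("T", seq_len(cfg$n_timepoints))
}

sim_node_ids <- function(cfg) {
  list(tf = sprintf("TF%03d", seq_len(cfg$n_tf)),
       mirna = sprintf("MIR%04d", seq_len(cfg$n_mirna)),
       gene = sprintf("G%05d", seq_len(cfg$n_gene)))
}

sim_types <- function(ids) {
  stats::setNames(rep(c("TF", "miRNA", "gene"),
                      c(length(ids$tf), length(ids$mirna), length(ids$gene))),
                  c(ids$tf, ids$mirna, ids$gene))
}

# discrete power-law sampler for out-degrees, truncated at `cap`
rpower_degree <- function(n, xmin, alpha, cap) {
  d <- floor(xmin * runif(n)^(-1 / (alpha - 1)))
  pmin(as.integer(d), as.integer(cap))
}

#' Simulate a static typed regulatory network
#'
#' Regulator out-degrees are drawn from a truncated discrete power law
#' (heavy-tailed, hub-dominated); TF targets are sampled uniformly from
#' all other nodes and miRNA targets from genes and TFs. Requested motif
#' instances (`planted_motifs` in the config) are added on top: an FFL
#' plants arcs A->B, A->C, B->C for regulators A, B and gene C; an RML
#' plants the mutual pair A<->B plus A->C.
#'
#' @param cfg a [sim_config()].
#' @return A `typed_network`; `attr(, "manifest")` is a data frame of the
#'   planted triples (`a`, `b`, `c`, `family`).
#' @export
simulate_irn <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sim_node_ids(cfg)
  regs <- c(ids$tf, ids$mirna)
  if (sum(cfg$planted_motifs) > 0 && (length(regs) < 2 || cfg$n_gene < 1))
    stop("too few nodes to plant the requested motifs")

  edges <- list()
  all_ids <- c(ids$tf, ids$mirna, ids$gene)
  dtf <- rpower_degree(cfg$n_tf, cfg$min_out_degree, cfg$degree_exponent,
                       max(cfg$n_gene %/% 4, cfg$min_out_degree))
  for (i in seq_len(cfg$n_tf)) {
    pool <- setdiff(all_ids, ids$tf[i])
    edges[[length(edges) + 1]] <- cbind(ids$tf[i], sample(pool, dtf[i]))
  }
  dmir <- rpower_degree(cfg$n_mirna, cfg$min_out_degree, cfg$degree_exponent,
                        max(cfg$n_gene %/% 4, cfg$min_out_degree))
  mir_pool <- c(ids$gene, ids$tf)
  for (i in seq_len(cfg$n_mirna)) {
    edges[[length(edges) + 1]] <- cbind(ids$mirna[i], sample(mir_pool, dmir[i]))
  }

  manifest <- data.frame(a = character(0), b = character(0),
                         c = character(0), family = character(0),
                         stringsAsFactors = FALSE)
  plant <- function(fam, k) {
    if (k == 0) return(NULL)
    for (j in seq_len(k)) {
      # planted pairs mix one TF with one miRNA so the planted circuit is
      # visible to the mixed-regulator motif filter
      ab <- if (cfg$n_tf >= 1 && cfg$n_mirna >= 1)
        sample(c(sample(ids$tf, 1), sample(ids$mirna, 1)))
      else sample(regs, 2)
      g <- sample(ids$gene, 1)
      if (fam == "FFL") {
        edges[[length(edges) + 1]] <<- rbind(c(ab[1], ab[2]),
                                             c(ab[1], g), c(ab[2], g))
      } else {
        edges[[length(edges) + 1]] <<- rbind(c(ab[1], ab[2]),
                                             c(ab[2], ab[1]), c(ab[1], g))
      }
      manifest[nrow(manifest) + 1, ] <<- c(ab[1], ab[2], g, fam)
    }
  }
  plant("FFL", cfg$planted_motifs[["FFL"]])
  plant("RML", cfg$planted_motifs[["RML"]])

  net <- suppressMessages(typed_network(do.call(rbind, edges), sim_types(ids)))
  attr(net, "manifest") <- manifest
  net
}

#' Simulate a clustered time-course expression matrix
#'
#' Every network node is assigned to one of the configured clusters; its
#' profile is a Gaussian bump centered on the cluster's peak time point,
#' on a baseline of 6 log2 units, plus Gaussian noise. A configured
#' fraction of miRNA-to-gene arcs then has the target profile replaced by
#' the negated (anti-correlated) miRNA profile plus noise, and a smaller
#' fraction by the positively correlated copy. Each target is rewritten
#' at most once.
#'
#' @param cfg a [sim_config()].
#' @param net the `typed_network` whose nodes are to be measured
#'   (typically from [simulate_irn()]).
#' @return An `expression_matrix`; `attr(, "manifest")` lists cluster
#'   assignments and the rewritten miRNA-target pairs with their realized
#'   correlations.
#' @export
simulate_expression <- function(cfg, net) {
  stopifnot(inherits(cfg, "sim_config"), inherits(net, "typed_network"))
  set.seed(cfg$seed + 1L)
  tps <- sim_timepoint_labels(cfg)
  nt <- cfg$n_timepoints
  ids <- net$node_id
  n <- length(ids)

  peaks <- round(seq(1, nt, length.out = cfg$n_clusters))
  cl <- sample.int(cfg$n_clusters, n, replace = TRUE)
  tgrid <- seq_len(nt)
  vals <- matrix(6, n, nt, dimnames = list(ids, tps))
  for (i in seq_len(n)) {
    bump <- cfg$cluster_amplitude *
      exp(-0.5 * ((tgrid - peaks[cl[i]]) / cfg$cluster_width)^2)
    vals[i, ] <- 6 + bump + rnorm(nt, sd = cfg$noise_sd)
  }

  # rewrite a fraction of miRNA -> gene targets to forced (anti)correlation
  is_mg <- net$node_type[net$from] == "miRNA" & net$node_type[net$to] == "gene"
  arcs <- data.frame(m = net$node_id[net$from[is_mg]],
                     g = net$node_id[net$to[is_mg]],
                     stringsAsFactors = FALSE)
  arcs <- arcs[!duplicated(arcs$g), , drop = FALSE]  # one rewrite per target
  n_anti <- round(cfg$anticorr_fraction * nrow(arcs))
  n_pos <- round(cfg$poscorr_fraction * nrow(arcs))
  pick <- if (nrow(arcs)) sample.int(nrow(arcs), min(nrow(arcs), n_anti + n_pos))
          else integer(0)
  pairs <- data.frame(mirna = character(0), target = character(0),
                      sign = character(0), cc = numeric(0),
                      stringsAsFactors = FALSE)
  for (j in seq_along(pick)) {
    a <- arcs[pick[j], ]
    mp <- vals[a$m, ]
    sgn <- if (j <= n_anti) -1 else 1
    vals[a$g, ] <- 6 + sgn * (mp - mean(mp)) + rnorm(nt, sd = cfg$noise_sd)
    cc <- if (sd(mp) > 0 && sd(vals[a$g, ]) > 0) cor(mp, vals[a$g, ]) else NA
    pairs[nrow(pairs) + 1, ] <- list(a$m, a$g,
                                     if (sgn < 0) "anti" else "pos", cc)
  }

  expr <- expression_matrix(vals, stats::setNames(net$node_type, ids))
  attr(expr, "manifest") <- list(
    cluster = stats::setNames(cl, ids),
    cluster_peak = stats::setNames(peaks, paste0("cluster", seq_along(peaks))),
    pairs = pairs
  )
  expr
}

# one regime network: 'early' = densely cross-wired with mutual regulator
# loops; 'late' = hub-and-spoke modules on a sparse regulator ring with
# planted FFL and co-regulation patterns
simulate_regime_network <- function(cfg, regime) {
  ids <- list(tf = sprintf("TF%03d", seq_len(cfg$n_tf)),
              mirna = sprintf("MIR%04d", seq_len(cfg$n_mirna)),
              gene = sprintf("G%05d", seq_len(cfg$regime_n_gene)))
  regs <- c(ids$tf, ids$mirna)
  nr <- length(regs)
  edges <- list()

  if (regime == "early") {
    n_mut <- if (is.null(cfg$n_mutual_pairs)) round(0.15 * choose(nr, 2))
             else cfg$n_mutual_pairs
    n_mut <- min(n_mut, choose(nr, 2))
    pair_idx <- sample.int(choose(nr, 2), n_mut)
    all_pairs <- utils::combn(regs, 2)
    for (p in pair_idx) {
      a <- all_pairs[1, p]; b <- all_pairs[2, p]
      edges[[length(edges) + 1]] <- rbind(c(a, b), c(b, a))
    }
    oneway <- which(matrix(runif(nr * nr) < cfg$reg_reg_p, nr, nr) &
                      upper.tri(matrix(TRUE, nr, nr)), arr.ind = TRUE)
    if (nrow(oneway))
      edges[[length(edges) + 1]] <- cbind(regs[oneway[, 1]], regs[oneway[, 2]])
    for (g in ids$gene) {
      edges[[length(edges) + 1]] <-
        cbind(sample(regs, min(cfg$gene_in_degree, nr)), g)
    }
  } else {
    module <- split(ids$gene, rep_len(seq_len(nr), length(ids$gene)))
    for (i in seq_len(nr)) {
      if (length(module[[i]]))
        edges[[length(edges) + 1]] <- cbind(regs[i], module[[i]])
    }
    ring <- cbind(regs, regs[c(2:nr, 1)])
    edges[[length(edges) + 1]] <- ring
    # FFLs: ring arc a->b plus shared target in b's module
    ffl_rows <- sample.int(nr, min(cfg$n_ffl_late, nr))
    for (i in ffl_rows) {
      b <- c(2:nr, 1)[i]
      if (!length(module[[b]])) next
      g <- sample(module[[b]], 1)
      edges[[length(edges) + 1]] <- cbind(regs[i], g)
    }
    # CRMs: non-adjacent regulator pairs sharing a target
    for (j in seq_len(cfg$n_crm_late)) {
      ab <- sample.int(nr, 2)
      if (abs(diff(ab)) %in% c(1, nr - 1)) next  # skip ring neighbors
      if (!length(module[[ab[2]]])) next
      g <- sample(module[[ab[2]]], 1)
      edges[[length(edges) + 1]] <- cbind(regs[ab[1]], g)
    }
  }
  suppressMessages(typed_network(do.call(rbind, edges), sim_types(ids)))
}

#' Simulate early/late-regime network series
#'
#' Generates one network per configured time point. Early-regime networks
#' are densely cross-wired: mutually regulating regulator pairs, extra
#' one-way regulator wiring, and genes regulated by several regulators
#' with overlapping neighborhoods -- high clustering coefficient, robust
#' to hub removal. Late-regime networks are modular and hub-centralized:
#' each regulator owns a star of satellite genes, regulators form a
#' sparse ring, and feed-forward loops plus co-regulated targets are
#' planted on top -- low clustering coefficient, fragile to hub removal.
#'
#' @param cfg a [sim_config()].
#' @return Named list (by time-point label) of `typed_network`s, each
#'   carrying `attr(, "timepoint")` and `attr(, "regime")`;
#'   `attr(, "manifest")` on the list records the regime assignment.
#' @export
simulate_regimes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  tps <- sim_timepoint_labels(cfg)
  out <- vector("list", length(tps))
  names(out) <- tps
  for (i in seq_along(tps)) {
    nw <- simulate_regime_network(cfg, cfg$regimes[i])
    attr(nw, "timepoint") <- tps[i]
    attr(nw, "regime") <- cfg$regimes[i]
    out[[i]] <- nw
  }
  attr(out, "manifest") <- data.frame(timepoint = tps, regime = cfg$regimes,
                                      stringsAsFactors = FALSE)
  out
}

#' Simulate an annotation collection planted on expression clusters
#'
#' Builds one term per cluster, annotating a configured fraction of the
#' cluster's gene-typed members plus a sample of background genes. The
#' universe is the full gene set of the configuration.
#'
#' @param cfg a [sim_config()].
#' @param clusters cluster list as returned by [cluster_entities()] (or
#'   any list whose elements have a `members` character vector).
#' @return An `annotation_collection`; `attr(, "truth")` maps each term
#'   to the cluster it was planted from.
#' @export
simulate_annotations <- function(cfg, clusters) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  universe <- sprintf("G%05d", seq_len(cfg$n_gene))
  sets <- list(); truth <- list()
  for (i in seq_along(clusters)) {
    members <- intersect(clusters[[i]]$members, universe)
    if (!length(members)) next
    core <- sample(members, max(1, round(cfg$annotate_fraction * length(members))))
    bg_pool <- setdiff(universe, members)
    bg <- sample(bg_pool, min(length(bg_pool),
                              round(cfg$background_fraction * length(members))))
    id <- sprintf("TERM%03d", i)
    sets[[id]] <- c(core, bg)
    truth[[id]] <- i
  }
  if (!length(sets)) stop("no cluster contributed any universe gene")
  ann <- annotation_collection(sets, universe)
  attr(ann, "truth") <- truth
  ann
}
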