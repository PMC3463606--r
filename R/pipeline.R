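# End-to-end orchestration: build or simulate the inputs, extract active
# sub-networks per time point, run topology + nulls, motif dynamics,
# the correlation randomization test and enrichment, writing every
# artifact with provenance (stage, seed, config hash).

default_run_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    simulate = TRUE,
    sim = list(),                 # overrides passed to sim_config()
    tf_edges = NULL, mirna_edges = NULL, expression = NULL, gmt = NULL,
    rule = "percentile:50",
    bin_width = 0.05,
    n_rand_correlation = 1000,
    n_rand_topology = 300,
    n_rand_motif = 1000,
    swap_attempts = NULL,
    motif_by = "label",
    require_tf_mirna = TRUE,
    min_cluster_size = c(gene = 10, miRNA = 4)
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path")
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) stop("config must set `out_dir`")
  if (!isTRUE(cfg$simulate)) {
    for (f in c("tf_edges", "mirna_edges", "expression")) {
      if (is.null(cfg[[f]]))
        stop("config must set `", f, "` when simulate is FALSE")
      if (!file.exists(cfg[[f]]))
        stop("input path does not exist: ", cfg[[f]], " (", f, ")")
    }
    if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
      stop("input path does not exist: ", cfg$gmt, " (gmt)")
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(path, stage, seed, hash) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = hash,
         package = "retnetdyn",
         version = as.character(utils::packageVersion("retnetdyn"))),
    paste0(path, ".prov.json"), auto_unbox = TRUE)
}

#' Run the full regulatory-network dynamics pipeline
#'
#' Executes the stages in dependency order: input construction (load the
#' edge lists and expression TSV, or simulate them), static-network
#' summary, per-time-point active sub-network extraction, topology
#' metrics with the random same-size null, motif Z-score dynamics with
#' time-point clustering, the miRNA-target correlation randomization
#' test, and (when annotations are available) enrichment of each
#' time-point-specific gene set. Each artifact is written under
#' `out_dir` together with a `.prov.json` sidecar naming the stage, the
#' seed used and a hash of the configuration. Stages whose outputs
#' already exist are skipped unless `force = TRUE`.
#'
#' All randomized stages draw independent sub-seeds from the master
#' `seed` (via one `sample.int()` stream seeded with it), so a rerun with
#' the same configuration reproduces every number exactly.
#'
#' @param config a list (or path to a YAML file) with entries `out_dir`
#'   (required), `seed`, and either `simulate = TRUE` plus optional `sim`
#'   overrides for [sim_config()], or `simulate = FALSE` plus paths
#'   `tf_edges`, `mirna_edges`, `expression` and optionally `gmt`.
#'   Analysis knobs: `rule`, `bin_width`, `n_rand_correlation`,
#'   `n_rand_topology`, `n_rand_motif`, `swap_attempts`, `motif_by`,
#'   `require_tf_mirna`.
#' @param force rerun stages whose outputs already exist.
#' @return The run manifest (named list of artifact paths), invisibly
#'   also written as `manifest.json`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list(config_hash = hash, seed = cfg$seed)

  set.seed(cfg$seed)
  stage_seed <- stats::setNames(
    sample.int(.Machine$integer.max, 6),
    c("simulate", "topology_null", "motifs", "correlation",
      "regimes_unused", "reserve"))

  done <- function(paths) all(file.exists(paths)) && !force

  ## stage: inputs -----------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_args <- cfg$sim
    sim_args$seed <- if (!is.null(sim_args$seed)) sim_args$seed
                     else stage_seed[["simulate"]] %% (2^31 - 10) + 1
    scfg <- do.call(sim_config, sim_args)
    irn <- simulate_irn(scfg)
    expr <- simulate_expression(scfg, irn)
    net_path <- out("irn.tsv"); expr_path <- out("expression.tsv")
    if (!done(c(net_path, expr_path))) {
      write_network(irn, net_path)
      write_expression(expr, expr_path)
      write_provenance(net_path, "simulate", scfg$seed, hash)
      message("stage simulate: wrote ", net_path, ", ", expr_path)
    }
    ann <- NULL
  } else {
    irn <- load_edge_lists(cfg$tf_edges, cfg$mirna_edges, quiet = TRUE)
    expr <- read_expression(cfg$expression)
    ann <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  }
  manifest$irn_summary <- out("irn-summary.json")
  if (!done(manifest$irn_summary)) {
    jsonlite::write_json(unclass(summarize_network(irn)),
                         manifest$irn_summary, auto_unbox = TRUE)
    write_provenance(manifest$irn_summary, "irn_summary", cfg$seed, hash)
  }

  ## stage: active sub-networks ---------------------------------------
  tps <- timepoint_labels(expr)
  rule <- as_activity_rule(cfg$rule)
  subnets <- lapply(tps, function(tp) extract_active(expr, irn, tp, rule))
  names(subnets) <- tps
  sub_paths <- out(paste0("subnet-", tps, ".tsv"))
  if (!done(sub_paths)) {
    for (i in seq_along(tps)) {
      write_network(subnets[[i]]$subnet, sub_paths[i])
      utils::write.table(degree_table(subnets[[i]]$subnet),
                         out(paste0("subnet-", tps[i], "-nodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_provenance(sub_paths[1], "active", cfg$seed, hash)
    message("stage active: ", length(tps), " sub-networks")
  }
  manifest$subnets <- sub_paths

  spec <- specific_sets(expr, rule)
  spec_paths <- out(paste0("specific-", tps, ".txt"))
  if (!done(spec_paths)) {
    for (i in seq_along(tps)) writeLines(spec$specific[[tps[i]]], spec_paths[i])
    writeLines(spec$housekeeping, out("housekeeping.txt"))
  }
  manifest$specific_sets <- spec_paths

  ## stage: topology ----------------------------------------------------
  topo_path <- out("topology.json")
  if (!done(topo_path)) {
    topo <- lapply(subnets, function(s) {
      m <- network_metrics(s$subnet)
      utils::write.table(m$node_table,
                         out(paste0("topology-", s$timepoint, "-nodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      m[topology_metric_names]
    })
    nulls <- lapply(seq_along(subnets), function(i) {
      s <- subnets[[i]]
      tab <- table(factor(s$subnet$node_type, levels = NODE_TYPES))
      if (any(tab[c("TF", "miRNA")] == 0) || tab[["gene"]] == 0) return(NULL)
      nt <- random_subnetwork_null(
        irn, tab[["TF"]], tab[["miRNA"]], tab[["gene"]],
        n_rand = cfg$n_rand_topology,
        seed = (stage_seed[["topology_null"]] + i) %% (2^31 - 10) + 1)
      list(mean = as.list(nt$mean), sd = as.list(nt$sd),
           n_rand = nt$n_rand, seed = nt$seed)
    })
    names(nulls) <- tps
    jsonlite::write_json(list(observed = topo, null = nulls),
                         topo_path, auto_unbox = TRUE, digits = NA)
    write_provenance(topo_path, "topology",
                     stage_seed[["topology_null"]], hash)
    message("stage topology: metrics + ", cfg$n_rand_topology,
            "-replicate null")
  }
  manifest$topology <- topo_path

  ## stage: motifs ------------------------------------------------------
  zmat_path <- out("motif-z-matrix.tsv")
  if (!done(zmat_path)) {
    nonempty <- vapply(subnets, function(s) n_arcs(s$subnet) >= 2, logical(1))
    dyn <- motif_dynamics(subnets[nonempty], n_rand = cfg$n_rand_motif,
                          seed = stage_seed[["motifs"]] %% (2^31 - 10) + 1,
                          n_swap_attempts = cfg$swap_attempts,
                          require_tf_and_mirna = cfg$require_tf_mirna,
                          by = cfg$motif_by)
    for (p in dyn$profiles)
      write_motif_table(p, out(paste0("motifs-", p$network_label, ".tsv")))
    utils::write.table(data.frame(motif = rownames(dyn$z), dyn$z,
                                  check.names = FALSE),
                       zmat_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    part <- cluster_timepoints(dyn)
    writeLines(as_newick(part), out("motif-timepoints.nwk"))
    jsonlite::write_json(as.list(part$groups), out("motif-2cut.json"),
                         auto_unbox = TRUE)
    expr_part <- cluster_timepoints(expr)
    writeLines(as_newick(expr_part), out("expression-timepoints.nwk"))
    write_provenance(zmat_path, "motifs", stage_seed[["motifs"]], hash)
    message("stage motifs: dynamics over ", sum(nonempty), " networks")
  }
  manifest$motif_z_matrix <- zmat_path

  ## stage: correlation -------------------------------------------------
  corr_path <- out("correlation-bins.tsv")
  if (!done(corr_path)) {
    rep <- target_correlation_z(
      expr, irn, bin_width = cfg$bin_width,
      n_rand = cfg$n_rand_correlation,
      seed = stage_seed[["correlation"]] %% (2^31 - 10) + 1)
    write_correlation_report(rep, corr_path)
    write_provenance(corr_path, "correlation", rep$seed, hash)
    message("stage correlation: ", rep$n_pairs, " pairs, ",
            rep$n_rand, " randomizations")
  }
  manifest$correlation <- corr_path

  ## stage: enrichment --------------------------------------------------
  if (isTRUE(cfg$simulate) && is.null(ann)) {
    cls <- tryCatch(
      cluster_entities(expr, "gene",
                       min_size = cfg$min_cluster_size[["gene"]]),
      error = function(e) list())
    if (length(cls)) ann <- simulate_annotations(scfg, cls)
  }
  if (!is.null(ann)) {
    enr_paths <- out(paste0("enrichment-", tps, ".tsv"))
    if (!done(enr_paths)) {
      for (i in seq_along(tps)) {
        q <- spec$specific[[tps[i]]]
        res <- tryCatch(enrich(q, ann), error = function(e)
          data.frame(term_id = character(0)))
        utils::write.table(res, enr_paths[i], sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      write_provenance(enr_paths[1], "enrichment", cfg$seed, hash)
      message("stage enrichment: ", length(tps), " specific sets")
    }
    manifest$enrichment <- enr_paths
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
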