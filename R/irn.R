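# Loading and summarizing the static integrated regulatory network (IRN).

# Parse a 2-column tab-separated edge file; '#' lines and blank lines are
# ignored. Errors name the offending (1-based, physical) line.
parse_edge_file <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 2)) {
    bad <- which(keep)[which(nf != 2)[1]]
    stop("malformed row in ", path, " at line ", bad,
         ": expected 2 tab-separated columns, found ", nf[which(nf != 2)[1]])
  }
  if (!length(rows)) return(matrix(character(0), ncol = 2))
  mat <- matrix(trimws(unlist(rows)), ncol = 2, byrow = TRUE)
  mat
}

#' Build the integrated regulatory network from edge lists
#'
#' Reads TF-target and miRNA-target relationships from two tab-separated
#' files (or in-memory tables) and combines them into one typed network.
#' The file of origin fixes the regulator type: sources in the TF file are
#' TFs, sources in the miRNA file are miRNAs, and any id appearing only as
#' a target is typed `gene`. An id appearing as a regulator in both files
#' is a type conflict and raises an error. A regulator may itself be the
#' target of other regulators (miRNA->TF and TF->miRNA arcs are allowed)
#' without changing its type.
#'
#' @param tf_edges path to a 2-column TSV (TF id, target id), or a
#'   2-column character matrix/data frame.
#' @param mirna_edges same, for miRNA-target arcs.
#' @param quiet suppress the parse report message.
#' @return A [typed_network()].
#' @examples
#' tf <- rbind(c("T1", "G1"), c("T1", "M1"))
#' mir <- rbind(c("M1", "G1"))
#' net <- load_edge_lists(tf, mir)
#' summarize_network(net)
#' @export
load_edge_lists <- function(tf_edges, mirna_edges, quiet = FALSE) {
  as_mat <- function(x) {
    if (is.character(x) && length(x) == 1) parse_edge_file(x)
    else {
      m <- as.matrix(x)
      if (NROW(m) && ncol(m) != 2) stop("edge table must have 2 columns")
      matrix(as.character(m), ncol = 2)
    }
  }
  tf <- as_mat(tf_edges)
  mir <- as_mat(mirna_edges)

  tf_regs <- unique(tf[, 1])
  mir_regs <- unique(mir[, 1])
  conflict <- intersect(tf_regs, mir_regs)
  if (length(conflict))
    stop("id(s) appear as regulator in both the TF and the miRNA file: ",
         paste(head(conflict, 5), collapse = ", "))

  all_ids <- unique(c(tf_regs, mir_regs, tf[, 2], mir[, 2]))
  types <- ifelse(all_ids %in% tf_regs, "TF",
                  ifelse(all_ids %in% mir_regs, "miRNA", "gene"))
  names(types) <- all_ids

  net <- typed_network(rbind(tf, mir), types)
  if (!quiet) {
    message("load_edge_lists: ", nrow(tf), " TF rows + ", nrow(mir),
            " miRNA rows -> ", n_arcs(net), " arcs (",
            attr(net, "n_duplicates_dropped"), " duplicates, ",
            attr(net, "n_self_loops_dropped"), " self-loops dropped)")
  }
  net
}

#' Summarize a typed network
#'
#' Counts nodes by type and arcs by the type of their source regulator.
#'
#' @param net a `typed_network`.
#' @return A `network_summary` list with `n_tf`, `n_mirna`, `n_gene`,
#'   `n_tf_arcs`, `n_mirna_arcs`, `n_arcs_total`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  tab <- table(factor(net$node_type, levels = NODE_TYPES))
  src <- net$node_type[net$from]
  out <- list(n_tf = unname(tab[["TF"]]),
              n_mirna = unname(tab[["miRNA"]]),
              n_gene = unname(tab[["gene"]]),
              n_tf_arcs = sum(src == "TF"),
              n_mirna_arcs = sum(src == "miRNA"),
              n_arcs_total = length(net$from))
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("nodes:", x$n_tf, "TF /", x$n_mirna, "miRNA /", x$n_gene, "gene\n")
  cat("arcs: ", x$n_tf_arcs, "TF-sourced +", x$n_mirna_arcs,
      "miRNA-sourced =", x$n_arcs_total, "\n")
  invisible(x)
}

#' Write a typed network as a 3-column TSV
#'
#' Canonical dump format: `source`, `target`, `source_type`, with a header
#' row. [read_network()] restores the arc set exactly; isolated nodes are
#' not represented in this format.
#'
#' @param net a `typed_network`.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  utils::write.table(network_edges(net), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed network written by [write_network()]
#'
#' Targets that never occur as a source are typed `gene`.
#'
#' @param path file path.
#' @return A `typed_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  types <- c()
  src_types <- df$source_type[!duplicated(df$source)]
  names(src_types) <- df$source[!duplicated(df$source)]
  tgt_only <- setdiff(unique(df$target), names(src_types))
  types <- c(src_types, stats::setNames(rep("gene", length(tgt_only)), tgt_only))
  typed_network(cbind(df$source, df$target), types)
}
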