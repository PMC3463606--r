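# Small shared fixtures, built in code.

# chain a -> b -> c with regulator typing (a, b TFs; c gene)
chain_net <- function() {
  typed_network(rbind(c("a", "b"), c("b", "c")),
                c(a = "TF", b = "TF", c = "gene"))
}

# star: one TF regulating three genes
star_net <- function(n_leaves = 3) {
  leaves <- paste0("g", seq_len(n_leaves))
  typed_network(cbind("hub", leaves),
                stats::setNames(c("TF", rep("gene", n_leaves)),
                                c("hub", leaves)))
}

# backtrack example: T2 -> T1, T1 -> G1, M1 -> T2
backtrack_net <- function() {
  typed_network(rbind(c("T2", "T1"), c("T1", "G1"), c("M1", "T2")),
                c(T1 = "TF", T2 = "TF", M1 = "miRNA", G1 = "gene"))
}

# small expression matrix from explicit profiles
expr_fixture <- function(profiles, types, tps = NULL) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  colnames(m) <- if (is.null(tps)) paste0("T", seq_len(ncol(m))) else tps
  expression_matrix(m, types)
}

tmp_edge_file <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(rows, f)
  f
}
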