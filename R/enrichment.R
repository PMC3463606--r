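# Hypergeometric functional enrichment with Bonferroni correction and
# e-values over user-supplied annotation (GMT) collections.

#' Annotation collection over a gene universe
#'
#' Holds term -> gene-set annotations together with the universe against
#' which enrichment is tested. Annotated genes outside the universe are
#' dropped (with a message); terms left empty are kept out of the tested
#' family.
#'
#' @param sets named list of character vectors (term id -> gene ids).
#' @param universe character vector: the universe of genes.
#' @param term_names optional character vector of human-readable names,
#'   parallel to `sets` (defaults to the term ids).
#' @return An `annotation_collection`: list with `sets`, `term_names`,
#'   `universe`.
#' @export
annotation_collection <- function(sets, universe, term_names = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list of gene-id vectors")
  universe <- unique(as.character(universe))
  if (is.null(term_names)) term_names <- names(sets)
  names(term_names) <- names(sets)
  clean <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
  dropped <- sum(lengths(lapply(sets, unique))) - sum(lengths(clean))
  if (dropped > 0)
    message("annotation_collection: dropped ", dropped,
            " annotation(s) outside the universe")
  structure(list(sets = clean, term_names = term_names,
                 universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection:", length(x$sets), "terms over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT: one term per line, tab-separated: term id, term name, then the
#' member gene ids.
#'
#' @param path file path.
#' @param universe universe for the resulting collection; defaults to the
#'   union of all annotated genes.
#' @return `read_gmt()` returns an `annotation_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(rows) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(rows, `[[`, character(1), 1)
  nms <- vapply(rows, `[[`, character(1), 2)
  sets <- lapply(rows, function(r) r[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- unique(unlist(sets))
  annotation_collection(sets, universe, term_names = nms)
}

#' @rdname read_gmt
#' @param ann an `annotation_collection`.
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(names(ann$sets), function(id)
    paste(c(id, ann$term_names[[id]], ann$sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' The probability that a uniformly drawn size-`c` subset of a universe
#' of `G` genes, `n` of which carry the function, overlaps the function
#' in at least `k` genes: P(X >= k) for X hypergeometric(G, n, c).
#'
#' @param c query (cluster) size.
#' @param k observed overlap with the term.
#' @param G universe size.
#' @param n term size within the universe.
#' @return A probability in (0, 1\].
#' @examples
#' hypergeom_p(2, 2, 4, 2)  # 1/6
#' @export
hypergeom_p <- function(c, k, G, n) {
  if (k < 0 || k > min(c, n) || c > G || n > G || c < 0 || n < 0 || G < 1)
    stop("require 0 <= k <= min(c, n), 0 <= c <= G, 0 <= n <= G")
  phyper(k - 1, n, G - n, c, lower.tail = FALSE)
}

#' Enrichment e-value
#'
#' The ratio of observed to expected overlap: k / (c * n / G). A value of
#' 1 means no enrichment, values above 1 mean over-representation.
#'
#' @inheritParams hypergeom_p
#' @return A non-negative number.
#' @examples
#' e_value(2, 2, 4, 2)  # 2.0
#' @export
e_value <- function(c, k, G, n) {
  if (G < 1) stop("`G` must be positive")
  if (c * n <= 0) stop("zero expected overlap: c * n must be positive")
  k / (c * n / G)
}

#' Hypergeometric enrichment of a gene set
#'
#' Tests the query set against every term of the collection that has at
#' least one universe gene (that is the family of tests, and the
#' Bonferroni denominator). Query genes outside the universe are dropped
#' with a message. Only terms with a non-empty overlap appear in the
#' output, sorted by Bonferroni-corrected p-value, ties broken by
#' descending e-value.
#'
#' @param query character vector of gene ids.
#' @param annotations an `annotation_collection`.
#' @return Data frame with columns `term_id`, `term_name`, `c`, `k`, `n`,
#'   `G`, `p_raw`, `p_bonferroni`, `e_value`.
#' @export
enrich <- function(query, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  query <- unique(as.character(query))
  eff <- intersect(query, annotations$universe)
  if (length(eff) < length(query))
    message("enrich: dropped ", length(query) - length(eff),
            " query gene(s) outside the universe")
  if (!length(eff)) stop("no query genes inside the universe")

  tested <- annotations$sets[lengths(annotations$sets) >= 1]
  n_tests <- length(tested)
  G <- length(annotations$universe)
  c_ <- length(eff)

  rows <- lapply(names(tested), function(id) {
    genes <- tested[[id]]
    k <- length(intersect(eff, genes))
    if (k == 0) return(NULL)
    n <- length(genes)
    p <- hypergeom_p(c_, k, G, n)
    data.frame(term_id = id,
               term_name = unname(annotations$term_names[[id]]),
               c = c_, k = k, n = n, G = G,
               p_raw = p,
               p_bonferroni = min(1, p * n_tests),
               e_value = e_value(c_, k, G, n),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      c = integer(0), k = integer(0), n = integer(0),
                      G = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$p_bonferroni, -res$e_value, res$term_id), ]
  rownames(res) <- NULL
  res
}
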