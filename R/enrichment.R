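#' Build a term-annotation map
#'
#' @param terms Named list: term id -> character vector of annotated gene
#'   ids (each non-empty).
#' @param universe Character vector of all annotated gene ids; defaults to
#'   the union of all terms' genes. Every term must be a subset of it.
#' @param labels Optional named character vector of human-readable term
#'   labels.
#' @return An object of class `term_map`.
#' @export
term_map <- function(terms, universe = NULL, labels = NULL) {
  if (!is.list(terms) || length(terms) == 0 || is.null(names(terms)))
    stop("`terms` must be a non-empty named list", call. = FALSE)
  terms <- lapply(terms, unique)
  if (any(lengths(terms) == 0))
    stop("empty term(s): ",
         paste(names(terms)[lengths(terms) == 0], collapse = ", "),
         call. = FALSE)
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  universe <- unique(universe)
  outside <- setdiff(unlist(terms), universe)
  if (length(outside))
    stop("term genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  structure(list(terms = terms, universe = universe, labels = labels),
            class = "term_map")
}

#' Read a gene-to-term annotation map from two-column TSV
#'
#' Accepts the simple `gene<TAB>term` format (one association per line,
#' e.g. KAAS-style KEGG assignments or flattened GO annotations).
#'
#' @param path Path to a two-column TSV (gene id, term id), no header.
#' @param universe Optional universe of annotated genes; defaults to all
#'   genes appearing in the file.
#' @return A [term_map()].
#' @export
read_term_map_tsv <- function(path, universe = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) != 2)
    stop("'", path, "' must have exactly two columns (gene, term)",
         call. = FALSE)
  term_map(split(df[[1]], df[[2]]), universe = universe)
}

#' Hypergeometric over-representation test
#'
#' For each term with at least one query gene, computes the upper-tail
#' hypergeometric probability of observing at least the overlap by chance
#' (population = annotated universe, successes = term size, draws = query
#' genes inside the universe), then applies Benjamini-Hochberg adjustment
#' across all tested terms. Over-representation only; depletion is not
#' tested.
#'
#' @param query Character vector of gene ids; genes outside the universe
#'   are dropped with a warning.
#' @param terms A [term_map()].
#' @param fdr_cutoff Significance threshold on the BH FDR (default 0.05).
#' @return A data frame of class `enrichment_result` sorted by ascending
#'   p-value: term, label, overlap, term_size, p_value, fdr, significant.
#'   The number of query genes dropped is attached as attribute
#'   `n_dropped`.
#' @examples
#' tm <- term_map(list(t1 = letters[1:5]), universe = letters[1:20])
#' enrich(letters[1:5], tm)
#' @export
enrich <- function(query, terms, fdr_cutoff = 0.05) {
  stopifnot(inherits(terms, "term_map"))
  if (length(terms$universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  n_dropped <- sum(!query %in% terms$universe)
  if (n_dropped > 0)
    warning(n_dropped, " query gene(s) outside the annotated universe dropped")
  query <- intersect(query, terms$universe)
  if (length(query) == 0)
    stop("no query genes inside the universe", call. = FALSE)
  N <- length(terms$universe)
  k <- length(query)
  overlap <- vapply(terms$terms, function(g) length(intersect(g, query)),
                    integer(1))
  tested <- overlap >= 1
  term_ids <- names(terms$terms)[tested]
  m <- lengths(terms$terms)[tested]
  ov <- overlap[tested]
  p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = term_ids,
                    label = if (!is.null(terms$labels))
                      unname(terms$labels[term_ids]) else term_ids,
                    overlap = unname(ov),
                    term_size = unname(m),
                    p_value = unname(p),
                    fdr = unname(fdr),
                    significant = unname(fdr < fdr_cutoff),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "query_size") <- k
  class(out) <- c("enrichment_result", "data.frame")
  out
}
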