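#' Screening criteria for reference-gene detection
#'
#' The four-criterion screen applied to replicate-averaged TPM values,
#' working on the log2 scale L = log2(TPM) for criteria II-IV:
#' \enumerate{
#'   \item expression observed in every condition (TPM strictly above
#'     `min_tpm_exclusive` everywhere);
#'   \item low variance: sample standard deviation of L strictly below
#'     `max_sd_log2`;
#'   \item no exceptional expression: no condition's L deviates from the
#'     gene's mean L by `max_abs_deviation_log2` or more;
#'   \item medium-to-high expression: mean L strictly above
#'     `min_mean_log2_exclusive`.
#' }
#' With the defaults (sd < 1, mean > 5) every candidate's coefficient of
#' variation CV = sd(L)/mean(L) is below 0.2; see [cv_bound_check()].
#'
#' @param min_tpm_exclusive Criterion-I threshold; TPM must exceed it in
#'   every condition (default 0).
#' @param max_sd_log2 Criterion-II strict upper bound on sd of log2(TPM)
#'   (default 1).
#' @param max_abs_deviation_log2 Criterion-III strict upper bound on the
#'   largest absolute deviation of log2(TPM) from the gene mean (default 2).
#' @param min_mean_log2_exclusive Criterion-IV strict lower bound on mean
#'   log2(TPM) (default 5).
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(min_tpm_exclusive = 0,
                            max_sd_log2 = 1,
                            max_abs_deviation_log2 = 2,
                            min_mean_log2_exclusive = 5) {
  if (min_tpm_exclusive < 0)
    stop("`min_tpm_exclusive` must be >= 0", call. = FALSE)
  if (max_sd_log2 <= 0 || max_abs_deviation_log2 <= 0 ||
      min_mean_log2_exclusive <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(min_tpm_exclusive = min_tpm_exclusive,
                 max_sd_log2 = max_sd_log2,
                 max_abs_deviation_log2 = max_abs_deviation_log2,
                 min_mean_log2_exclusive = min_mean_log2_exclusive),
            class = "screen_criteria")
}

#' Apply the four-criterion reference-gene screen
#'
#' Criteria are applied in the fixed order I -> II -> III -> IV on a
#' replicate-averaged [expression_matrix()]. Log2 statistics (mean, sd with
#' n-1 denominator, maximum absolute deviation) and CV = sd/mean are
#' computed for every gene passing criterion I; genes failing I carry NA
#' statistics and NA flags for II-IV, and are never candidates. Cascade
#' counts record how many genes survive after I, I-II, I-III and I-IV.
#'
#' @param x An [expression_matrix()] with at least two conditions.
#' @param criteria A [screen_criteria()] object.
#' @return An object of class `screen_result`: a list with `table` (one
#'   row per gene: flags, `mean_log2`, `sd_log2`, `max_abs_dev_log2`, `cv`,
#'   `candidate`, `rank` with 1 = most stable candidate), `cascade` (named
#'   counts), and the criteria used.
#' @examples
#' m <- matrix(2^c(6, 6, 6, 2, 9, 4), 2, 3, byrow = TRUE,
#'             dimnames = list(c("stable", "wild"), c("c1", "c2", "c3")))
#' screen_dataset(expression_matrix(m))$table
#' @export
screen_dataset <- function(x, criteria = screen_criteria()) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(criteria, "screen_criteria"))
  v <- x$values
  if (nrow(v) == 0) stop("empty expression matrix", call. = FALSE)
  if (ncol(v) < 2)
    stop("screening requires at least 2 conditions", call. = FALSE)

  pass1 <- apply(v > criteria$min_tpm_exclusive, 1, all)

  n <- nrow(v)
  mean_l <- sd_l <- dev_l <- cv <- rep(NA_real_, n)
  p2 <- p3 <- p4 <- rep(NA, n)
  if (any(pass1)) {
    L <- log2(v[pass1, , drop = FALSE])
    mean_l[pass1] <- rowMeans(L)
    sd_l[pass1] <- apply(L, 1, stats::sd)
    dev_l[pass1] <- apply(abs(L - rowMeans(L)), 1, max)
    cv[pass1] <- sd_l[pass1] / mean_l[pass1]
    p2[pass1] <- sd_l[pass1] < criteria$max_sd_log2
    p3[pass1] <- dev_l[pass1] < criteria$max_abs_deviation_log2
    p4[pass1] <- mean_l[pass1] > criteria$min_mean_log2_exclusive
  }
  candidate <- pass1 & !is.na(p2) & p2 & p3 & p4
  cascade <- c(I = sum(pass1),
               I_II = sum(pass1 & p2 %in% TRUE),
               I_III = sum(pass1 & p2 %in% TRUE & p3 %in% TRUE),
               I_IV = sum(candidate))

  rank_col <- rep(NA_integer_, n)
  if (any(candidate)) {
    idx <- which(candidate)
    ord <- idx[order(cv[idx], rownames(v)[idx])]
    rank_col[ord] <- seq_along(ord)
  }
  tab <- data.frame(gene_id = rownames(v),
                    passes_I = pass1, passes_II = p2, passes_III = p3,
                    passes_IV = p4,
                    mean_log2 = mean_l, sd_log2 = sd_l,
                    max_abs_dev_log2 = dev_l, cv = cv,
                    candidate = candidate, rank = rank_col,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, cascade = cascade, criteria = criteria,
                 n_genes = n, n_conditions = ncol(v)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d genes, %d conditions\n",
              x$n_genes, x$n_conditions))
  cat(sprintf("cascade: I=%d  I-II=%d  I-III=%d  I-IV=%d (candidates)\n",
              x$cascade["I"], x$cascade["I_II"], x$cascade["I_III"],
              x$cascade["I_IV"]))
  invisible(x)
}

#' Rank screen candidates by coefficient of variation
#'
#' @param result A `screen_result` from [screen_dataset()] with at least
#'   one candidate.
#' @param top_k Number of top genes to return (default 10); if larger than
#'   the candidate count the full table is returned.
#' @return A data frame (gene_id, cv, mean_log2) sorted by ascending CV,
#'   ties broken by ascending gene id.
#' @export
rank_by_cv <- function(result, top_k = 10) {
  stopifnot(inherits(result, "screen_result"))
  if (top_k < 1) stop("`top_k` must be >= 1", call. = FALSE)
  tab <- result$table[result$table$candidate, , drop = FALSE]
  if (nrow(tab) == 0) stop("no candidate genes to rank", call. = FALSE)
  tab <- tab[order(tab$cv, tab$gene_id), c("gene_id", "cv", "mean_log2")]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Intersect candidate sets across datasets
#'
#' Computes the Venn partition of 2 or more named candidate gene sets: the
#' count of every occupancy region, union and full-intersection sizes, and
#' the shared percentage 100 * |intersection| / |union| rounded to two
#' decimals (the "core set" summary).
#'
#' @param candidate_sets Named list of >= 2 character vectors of gene ids.
#' @return A list with `regions` (data frame: membership pattern, count),
#'   `union_size`, `intersection_size`, `shared_percentage`, and
#'   `core_genes` (the sorted full intersection).
#' @examples
#' core_set(list(a = c("g1", "g2"), b = c("g2", "g3")))
#' @export
core_set <- function(candidate_sets) {
  if (!is.list(candidate_sets) || length(candidate_sets) < 2)
    stop("need a list of at least 2 candidate sets", call. = FALSE)
  if (is.null(names(candidate_sets)) || any(names(candidate_sets) == ""))
    names(candidate_sets) <- paste0("set", seq_along(candidate_sets))
  sets <- lapply(candidate_sets, unique)
  all_genes <- sort(unique(unlist(sets)))
  if (length(all_genes) == 0)
    stop("all candidate sets are empty", call. = FALSE)
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(b)
    paste(names(sets)[b], collapse = "&"))
  counts <- table(pattern)
  k <- length(sets)
  # enumerate all 2^k - 1 occupancy regions, zero-filled
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  regions <- data.frame(region = combos,
                        count = as.integer(ifelse(combos %in% names(counts),
                                                  counts[combos], 0L)),
                        stringsAsFactors = FALSE)
  core <- all_genes[rowSums(member) == k]
  list(regions = regions,
       union_size = length(all_genes),
       intersection_size = length(core),
       shared_percentage = round(100 * length(core) / length(all_genes), 2),
       core_genes = core)
}

#' Analytic CV bound implied by the screening criteria
#'
#' A gene passing criterion II (sd of log2 TPM strictly below `max_sd_log2`)
#' and criterion IV (mean log2 TPM strictly above `min_mean_log2_exclusive`)
#' necessarily has CV = sd/mean strictly below their ratio. At the default
#' thresholds (1, 5) the supremum is 0.2.
#'
#' @param criteria A [screen_criteria()] with a positive mean threshold.
#' @return The supremum `max_sd_log2 / min_mean_log2_exclusive`.
#' @export
cv_bound_check <- function(criteria = screen_criteria()) {
  stopifnot(inherits(criteria, "screen_criteria"))
  if (criteria$min_mean_log2_exclusive <= 0)
    stop("mean threshold must be positive for the CV bound", call. = FALSE)
  criteria$max_sd_log2 / criteria$min_mean_log2_exclusive
}
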