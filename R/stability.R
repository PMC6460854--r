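#' Convert Ct values to relative quantities
#'
#' Transforms a Ct matrix to the relative-quantity input expected by
#' geNorm-style analyses:
#' \deqn{Q_{gs} = (1 + E_g)^{Ct_{min}(g) - Ct_{gs}},}
#' so that per gene the sample with the minimum Ct has quantity exactly 1
#' and all quantities lie in (0, 1]. E defaults to 1 (perfect doubling)
#' for genes without a supplied efficiency.
#'
#' @param x A [ct_matrix()].
#' @return A list of class `quantity_matrix` with element `q`, a
#'   gene-by-sample matrix of relative quantities, plus the groups carried
#'   over from `x`.
#' @examples
#' ct <- matrix(c(20, 21, 23), 1, 3,
#'              dimnames = list("g", c("s1", "s2", "s3")))
#' ct_to_quantity(ct_matrix(ct))$q   # 1, 0.5, 0.125
#' @export
ct_to_quantity <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  e <- ct_efficiencies(x)
  if (any(e <= -1)) stop("efficiency must be > -1", call. = FALSE)
  q <- (1 + e)^(apply(x$ct, 1, min) - x$ct)
  structure(list(q = q, groups = x$groups), class = "quantity_matrix")
}

#' Amplification efficiency from a dilution-series standard curve
#'
#' Fits ordinary least squares of Ct on log2(template input) over a
#' two-fold dilution series and converts the slope to a per-cycle
#' efficiency \eqn{E = 2^{-1/slope} - 1}; a slope of exactly -1 per
#' two-fold dilution gives E = 1 (perfect doubling).
#'
#' @param inputs Template amounts (ng), strictly decreasing by a factor of
#'   2 (e.g. `100 / 2^(0:7)` spans 100 ng down to 0.78 ng); >= 3 points.
#' @param ct Measured Ct at each point.
#' @return A list with `efficiency`, `slope` (cycles per log2 unit),
#'   `intercept`, and `r_squared`.
#' @export
amplification_efficiency <- function(inputs, ct) {
  if (length(inputs) < 3) stop("need >= 3 dilution points", call. = FALSE)
  if (length(inputs) != length(ct))
    stop("`inputs` and `ct` must have equal length", call. = FALSE)
  if (stats::var(inputs) == 0)
    stop("zero variance in dilution inputs", call. = FALSE)
  ratios <- inputs[-length(inputs)] / inputs[-1]
  if (any(abs(ratios - 2) > 1e-6))
    stop("dilution inputs must decrease strictly by a factor of 2",
         call. = FALSE)
  x <- log2(inputs)
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  # R^2 computed directly; summary.lm warns on exact fits
  r2 <- if (stats::var(ct) == 0) 0 else
    1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  list(efficiency = 2^(-1 / slope) - 1,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

as_quantity <- function(q) {
  if (inherits(q, "quantity_matrix")) return(q)
  if (inherits(q, "ct_matrix")) return(ct_to_quantity(q))
  if (is.matrix(q)) return(structure(list(q = q, groups = NULL),
                                     class = "quantity_matrix"))
  stop("expected a quantity_matrix, ct_matrix or matrix", call. = FALSE)
}

#' geNorm expression-stability measure M
#'
#' For genes j and k, the pairwise variation V_jk is the sample standard
#' deviation (n-1 denominator) over samples of the log2 expression ratio
#' A_jk(s) = log2(Q_js / Q_ks). A gene's M value is the arithmetic mean of
#' its pairwise variations against all other genes; lower M means more
#' stable expression.
#'
#' @param q A `quantity_matrix` (from [ct_to_quantity()]), [ct_matrix()],
#'   or a plain positive gene-by-sample matrix; >= 2 genes, >= 2 samples.
#' @return Named numeric vector of per-gene M values.
#' @export
genorm_M <- function(q) {
  q <- as_quantity(q)$q
  if (nrow(q) < 2) stop("geNorm M needs >= 2 genes", call. = FALSE)
  if (ncol(q) < 2) stop("geNorm M needs >= 2 samples", call. = FALSE)
  if (any(q <= 0) || any(!is.finite(q)))
    stop("quantities must be positive and finite", call. = FALSE)
  lg <- log2(q)
  n <- nrow(q)
  V <- matrix(0, n, n)
  for (j in seq_len(n - 1)) {
    diffs <- lg[rep(j, n - j), , drop = FALSE] -
      lg[(j + 1):n, , drop = FALSE]
    V[j, (j + 1):n] <- apply(diffs, 1, stats::sd)
  }
  V <- V + t(V)
  stats::setNames(rowSums(V) / (n - 1), rownames(q))
}

#' geNorm stepwise ranking and pairwise variation series
#'
#' Implements the full geNorm procedure: repeatedly recompute M on the
#' remaining genes and exclude the least stable (highest M) until two
#' genes remain. The final pair cannot be resolved and shares the average
#' rank 1.5. Along the resulting inclusion order, normalization factors
#' NF_n(s) are geometric means of the n top-ranked genes' quantities, and
#' the pairwise variation V(n/n+1) is the sample standard deviation over
#' samples of log2(NF_n / NF_{n+1}), for n = 2..k-1.
#'
#' @param q As in [genorm_M()]; >= 3 genes required.
#' @return A list of class `genorm_ranking`: `ranks` (named; final pair at
#'   1.5), `exclusion_order` (first removed = least stable),
#'   `inclusion_order` (most stable first), `M_final` (M at the step each
#'   gene was dropped, or of the final pair), and `pairwise_variation`
#'   (named numeric, "V2/3" etc.).
#' @export
genorm_rank <- function(q) {
  qm <- as_quantity(q)
  q <- qm$q
  k <- nrow(q)
  if (k < 3) stop("geNorm ranking needs >= 3 genes", call. = FALSE)
  remaining <- rownames(q)
  exclusion <- character(0)
  m_final <- stats::setNames(numeric(k), rownames(q))
  while (length(remaining) > 2) {
    m <- genorm_M(q[remaining, , drop = FALSE])
    # ties: drop the lexicographically last of the worst genes (determinism)
    worst <- names(m)[m == max(m)]
    worst <- worst[order(worst)][length(worst)]
    m_final[worst] <- m[worst]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  m_pair <- genorm_M(q[remaining, , drop = FALSE])
  m_final[remaining] <- m_pair
  inclusion <- c(sort(remaining), rev(exclusion))
  ranks <- stats::setNames(c(1.5, 1.5, 3:k), inclusion)[rownames(q)]
  lq <- log2(q)
  nf_log2 <- function(n) colMeans(lq[inclusion[1:n], , drop = FALSE])
  v <- vapply(2:(k - 1), function(n)
    stats::sd(nf_log2(n) - nf_log2(n + 1)), numeric(1))
  names(v) <- paste0("V", 2:(k - 1), "/", 3:k)
  structure(list(ranks = ranks, exclusion_order = exclusion,
                 inclusion_order = inclusion, M_final = m_final,
                 pairwise_variation = v),
            class = "genorm_ranking")
}

#' NormFinder-style model-based stability
#'
#' Works on the log2-quantity scale \eqn{y = -Ct \cdot log2(1 + E)}.
#' Ungrouped mode: a gene's stability is the sample standard deviation over
#' samples of its column-centered value (its deviation from the per-sample
#' mean over genes). Grouped mode combines the gene-by-group interaction
#' \eqn{d_{ig} = (\bar y_{ig} - \bar y_{i.}) - (\bar y_{.g} - \bar y_{..})}
#' with the within-group sampling error of the column-centered values:
#' stability_i = mean over groups of \eqn{|d_{ig}| + \sqrt{\sigma^2_{ig}/n_g}}.
#' This is a simplification of the Andersen et al. variance-decomposition
#' model (no shrinkage of the interaction estimates) with the same ordering
#' behavior on clean cases; lower is more stable.
#'
#' @param x A [ct_matrix()] with >= 3 genes. Grouped mode is used when `x`
#'   carries groups (>= 2 groups, each with >= 2 samples) unless
#'   `grouped = FALSE`.
#' @param grouped Force grouped (TRUE) or ungrouped (FALSE) mode; default
#'   uses groups when present.
#' @return Named numeric vector of per-gene stability values.
#' @export
normfinder_stability <- function(x, grouped = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (nrow(x$ct) < 3)
    stop("NormFinder needs >= 3 genes", call. = FALSE)
  e <- ct_efficiencies(x)
  y <- -x$ct * log2(1 + e)
  if (is.null(grouped)) grouped <- !is.null(x$groups)
  if (!grouped) {
    z <- sweep(y, 2, colMeans(y))
    return(apply(z, 1, stats::sd))
  }
  if (is.null(x$groups))
    stop("grouped mode requires sample groups", call. = FALSE)
  g <- x$groups[colnames(x$ct)]
  sizes <- table(g)
  if (length(sizes) < 2)
    stop("grouped mode needs >= 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; rerun with grouped = FALSE", call. = FALSE)
  z <- sweep(y, 2, colMeans(y))
  groups <- names(sizes)
  stab <- stats::setNames(numeric(nrow(y)), rownames(y))
  y_i. <- rowMeans(y)
  y_.. <- mean(y)
  for (i in seq_len(nrow(y))) {
    per_group <- vapply(groups, function(gr) {
      cols <- which(g == gr)
      d_ig <- (mean(y[i, cols]) - y_i.[i]) - (mean(y[, cols]) - y_..)
      s2 <- stats::var(z[i, cols])
      abs(d_ig) + sqrt(s2 / length(cols))
    }, numeric(1))
    stab[i] <- mean(per_group)
  }
  stab
}

#' Comparative delta-Ct stability
#'
#' For each gene pair (i, j), compute the per-sample Ct difference
#' \eqn{\Delta Ct_s = Ct_{is} - Ct_{js}} and its sample standard deviation
#' over samples. A gene's stability is the mean of these standard
#' deviations against all other genes, in cycles; lower is more stable.
#'
#' @param x A [ct_matrix()] with >= 2 genes and >= 2 samples.
#' @return Named numeric vector of per-gene stability values (cycles).
#' @export
deltact_stability <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  ct <- x$ct
  if (nrow(ct) < 2 || ncol(ct) < 2)
    stop("delta-Ct needs >= 2 genes and >= 2 samples", call. = FALSE)
  n <- nrow(ct)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    diffs <- ct[rep(i, n - i), , drop = FALSE] - ct[(i + 1):n, , drop = FALSE]
    S[i, (i + 1):n] <- apply(diffs, 1, stats::sd)
  }
  S <- S + t(S)
  stats::setNames(rowSums(S) / (n - 1), rownames(ct))
}

#' Geometric-mean comprehensive ranking
#'
#' Ranks each stability method's scores ascending (lower = more stable,
#' average ranks on ties), then combines them per gene as the geometric
#' mean of the three ranks. The final order is ascending comprehensive
#' score, ties broken by gene id.
#'
#' @param genorm,normfinder,deltact Named numeric score vectors over the
#'   same genes (e.g. [genorm_M()], [normfinder_stability()],
#'   [deltact_stability()]).
#' @return A data frame: gene_id, the three scores and their ranks,
#'   `comprehensive_score` (geometric mean of ranks, >= 1) and
#'   `comprehensive_rank` (1 = most stable), sorted by final rank.
#' @export
comprehensive_rank <- function(genorm, normfinder, deltact) {
  genes <- names(genorm)
  if (is.null(genes)) stop("score vectors must be named", call. = FALSE)
  for (m in list(normfinder = normfinder, deltact = deltact)) {
    if (!setequal(names(m), genes))
      stop("score vectors cover different gene sets", call. = FALSE)
  }
  bad <- function(v, what) {
    miss <- names(v)[!is.finite(v)]
    if (length(miss))
      stop("missing ", what, " score for gene ", miss[1], call. = FALSE)
  }
  bad(genorm, "geNorm"); bad(normfinder, "NormFinder")
  bad(deltact, "delta-Ct")
  r1 <- rank(genorm, ties.method = "average")
  r2 <- rank(normfinder[genes], ties.method = "average")
  r3 <- rank(deltact[genes], ties.method = "average")
  score <- (r1 * r2 * r3)^(1 / 3)
  out <- data.frame(gene_id = genes,
                    genorm_M = unname(genorm),
                    genorm_rank = unname(r1),
                    normfinder_stability = unname(normfinder[genes]),
                    normfinder_rank = unname(r2),
                    deltact_stability = unname(deltact[genes]),
                    deltact_rank = unname(r3),
                    comprehensive_score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$comprehensive_score, out$gene_id), ]
  out$comprehensive_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full stability report for a Ct matrix
#'
#' Runs geNorm M, NormFinder-style stability and the comparative delta-Ct
#' method on one Ct dataset and combines them by geometric-mean
#' comprehensive ranking. Technical replicate columns (e.g. qPCR
#' triplicates) can be averaged to one Ct per biological sample first via
#' `replicate_map`.
#'
#' @param x A [ct_matrix()].
#' @param grouped Passed to [normfinder_stability()].
#' @param replicate_map Optional named vector mapping technical-replicate
#'   columns to biological sample ids; Ct values are averaged per sample
#'   before analysis.
#' @return A data frame as returned by [comprehensive_rank()].
#' @export
stability_report <- function(x, grouped = NULL, replicate_map = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!is.null(replicate_map)) {
    avg <- average_replicates(x$ct, replicate_map)$values
    groups <- if (!is.null(x$groups)) {
      first <- !duplicated(unname(replicate_map[colnames(x$ct)]))
      stats::setNames(x$groups[colnames(x$ct)][first],
                      unname(replicate_map[colnames(x$ct)])[first])
    }
    x <- ct_matrix(avg, groups = groups, efficiencies = x$efficiencies)
  }
  comprehensive_rank(genorm = genorm_M(ct_to_quantity(x)),
                     normfinder = normfinder_stability(x, grouped = grouped),
                     deltact = deltact_stability(x))
}
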