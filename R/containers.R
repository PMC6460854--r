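#' Construct an expression matrix
#'
#' Bundles a gene-by-condition matrix of TPM values with optional replicate
#' provenance. Conditions are tissues or developmental stages; when the
#' matrix was produced by [average_replicates()], `replicate_map` records
#' which original sample columns were averaged into each condition.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), conditions
#'   in columns (unique colnames). All values must be finite and >= 0.
#' @param replicate_map Optional named character vector mapping original
#'   sample ids (names) to condition labels (values); provenance only.
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(c(10, 20, 12, 18), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("condA", "condB")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, replicate_map = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and condition colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate condition labels", call. = FALSE)
  if (any(!is.finite(values)))
    stop("TPM values must be finite (missing values are not permitted)",
         call. = FALSE)
  if (any(values < 0))
    stop("TPM values must be non-negative", call. = FALSE)
  if (!is.null(replicate_map)) {
    if (is.null(names(replicate_map)))
      stop("`replicate_map` must be a named vector (sample -> condition)",
           call. = FALSE)
    replicate_map <- stats::setNames(as.character(replicate_map),
                                     names(replicate_map))
  }
  structure(list(values = values, replicate_map = replicate_map),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(colnames(x$values), collapse = ", "), "\n")
  if (!is.null(x$replicate_map))
    cat(sprintf("replicate provenance: %d samples\n", length(x$replicate_map)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
condition_labels <- function(x) colnames(x$values)

#' Construct a Ct matrix
#'
#' Holds RT-qPCR quantification-cycle (Ct) values for a panel of genes
#' across samples, with optional sample grouping (tissue or developmental
#' stage) and optional per-gene amplification efficiencies E as estimated
#' from dilution-series standard curves (E = 1 is perfect doubling).
#'
#' @param ct Numeric matrix of Ct values, genes in rows, samples in columns,
#'   finite and in (0, 45].
#' @param groups Optional named character vector mapping every sample id to
#'   a group label.
#' @param efficiencies Optional named numeric vector of per-gene E values in
#'   (0, 1.2]; genes without an entry default to E = 1 downstream.
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, groups = NULL, efficiencies = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop("duplicate gene or sample ids", call. = FALSE)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct > 45))
    stop("Ct values must be finite and in (0, 45]", call. = FALSE)
  if (!is.null(groups)) {
    missing <- setdiff(colnames(ct), names(groups))
    if (length(missing))
      stop("`groups` must cover every sample; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    groups <- stats::setNames(as.character(groups[colnames(ct)]),
                              colnames(ct))
  }
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies)))
      stop("`efficiencies` must be named by gene id", call. = FALSE)
    if (any(efficiencies <= 0 | efficiencies > 1.2))
      stop("amplification efficiencies must lie in (0, 1.2]", call. = FALSE)
    unknown <- setdiff(names(efficiencies), rownames(ct))
    if (length(unknown))
      stop("efficiencies given for unknown genes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(ct = ct, groups = groups, efficiencies = efficiencies),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d samples\n",
              nrow(x$ct), ncol(x$ct)))
  if (!is.null(x$groups))
    cat("groups:", paste(unique(x$groups), collapse = ", "), "\n")
  if (!is.null(x$efficiencies))
    cat(sprintf("per-gene efficiencies for %d genes\n",
                length(x$efficiencies)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# Resolve the per-gene efficiency vector, defaulting to perfect doubling.
ct_efficiencies <- function(x) {
  e <- stats::setNames(rep(1, nrow(x$ct)), rownames(x$ct))
  if (!is.null(x$efficiencies))
    e[names(x$efficiencies)] <- x$efficiencies
  e
}
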