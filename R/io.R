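#' Read a numeric gene-by-sample matrix from TSV
#'
#' Expects a header row of sample/condition labels, a first column of gene
#' ids, tab separation and '.' decimals. Missing or non-numeric cells and
#' duplicate gene ids are rejected with the offending row number, matching
#' the screen's requirement that expression input be complete.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(fields) < 2)
    stop("'", path, "' has no data rows", call. = FALSE)
  if (length(unique(fields)) != 1)
    stop("ragged TSV: row ", which(fields != fields[1])[1],
         " has ", fields[which(fields != fields[1])[1]],
         " fields, expected ", fields[1], call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "NA" | vals == "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing cell at data row %d, column '%s'",
                 bad[1, 1], colnames(vals)[bad[1, 2]]), call. = FALSE)
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Read an expression matrix from TSV
#'
#' Columns are taken to be condition labels (replicates already averaged);
#' use [read_matrix_tsv()] plus [average_replicates()] for replicate-level
#' input.
#'
#' @param path Path to a TSV file (gene id first column, header row).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  expression_matrix(read_matrix_tsv(path))
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly. `read_expression_tsv(write_expression_tsv(x))`
#'   reproduces ids, labels and values to better than 1e-9.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  write_matrix_tsv(x$values, path, id_header = "gene_id")
}

write_matrix_tsv <- function(values, path, id_header = "gene_id") {
  df <- data.frame(id = rownames(values),
                   format(values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a Ct matrix from TSV, with optional groups and efficiencies
#'
#' @param path Path to a gene-by-sample Ct TSV (gene id first column).
#' @param groups_path Optional two-column TSV (sample, group).
#' @param efficiencies_path Optional two-column TSV (gene, efficiency E).
#' @return A [ct_matrix()].
#' @export
read_ct_tsv <- function(path, groups_path = NULL, efficiencies_path = NULL) {
  ct <- read_matrix_tsv(path)
  groups <- if (!is.null(groups_path)) read_map_tsv(groups_path)
  eff <- if (!is.null(efficiencies_path)) {
    m <- read_map_tsv(efficiencies_path)
    stats::setNames(as.numeric(m), names(m))
  }
  ct_matrix(ct, groups = groups, efficiencies = eff)
}

#' Read a two-column key/value map from TSV
#'
#' Used for sample-to-condition replicate maps, sample-to-group labels and
#' gene-to-efficiency tables. A header row is detected and skipped when the
#' first line's second field is non-numeric and the file is otherwise
#' numeric-valued; by default the file is read as-is with no header.
#'
#' @param path Path to a two-column tab-separated file.
#' @param header Does the file carry a header row (default FALSE)?
#' @return A named character vector (first column as names).
#' @export
read_map_tsv <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) != 2)
    stop("'", path, "' must have exactly two columns", call. = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate key(s) in '", path, "'", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}
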