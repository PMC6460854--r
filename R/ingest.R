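#' FASTQ read-quality filter parameters
#'
#' Reads are rejected when they contain any undetermined base ('N') or when
#' strictly more than `max_low_quality_positions` bases have a Phred quality
#' below `low_quality_threshold`. The defaults reproduce the common
#' "> 10 positions with quality scores < 20" rule.
#'
#' @param max_low_quality_positions Maximum tolerated number of low-quality
#'   positions; a read with more than this many is dropped (default 10).
#' @param low_quality_threshold Phred score below which a base counts as
#'   low quality (default 20; must lie in \[0, 93\]).
#' @param reject_any_N Drop reads containing one or more 'N'/'n' bases
#'   (default TRUE).
#' @return An object of class `fastq_filter_params`.
#' @export
fastq_filter_params <- function(max_low_quality_positions = 10,
                                low_quality_threshold = 20,
                                reject_any_N = TRUE) {
  if (max_low_quality_positions < 0)
    stop("`max_low_quality_positions` must be non-negative", call. = FALSE)
  if (low_quality_threshold < 0 || low_quality_threshold > 93)
    stop("`low_quality_threshold` must lie in [0, 93]", call. = FALSE)
  structure(list(max_low_quality_positions = as.integer(max_low_quality_positions),
                 low_quality_threshold = as.integer(low_quality_threshold),
                 reject_any_N = isTRUE(reject_any_N)),
            class = "fastq_filter_params")
}

# Read a whole FASTQ file (plain or gzip) into a list of 4-line records,
# validating record structure. Record index reported on malformed input.
read_fastq_records <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)), call. = FALSE)
  n <- length(lines) / 4
  for (i in seq_len(n)) {
    off <- (i - 1) * 4
    if (!startsWith(lines[off + 1], "@"))
      stop(sprintf("malformed FASTQ record %d: header does not start with '@'",
                   i), call. = FALSE)
    if (!startsWith(lines[off + 3], "+"))
      stop(sprintf("malformed FASTQ record %d: separator does not start with '+'",
                   i), call. = FALSE)
    if (nchar(lines[off + 2]) != nchar(lines[off + 4]))
      stop(sprintf("malformed FASTQ record %d: sequence and quality lengths differ (%d vs %d)",
                   i, nchar(lines[off + 2]), nchar(lines[off + 4])),
           call. = FALSE)
  }
  list(lines = lines, n = n)
}

# Classify each record: "kept", "dropped_N" or "dropped_quality".
# N takes precedence over quality, mirroring a sequential rule.
classify_fastq <- function(fq, params, phred_offset) {
  vapply(seq_len(fq$n), function(i) {
    off <- (i - 1) * 4
    seq_i <- fq$lines[off + 2]
    if (params$reject_any_N && grepl("N", seq_i, ignore.case = TRUE))
      return("dropped_N")
    qual <- utf8ToInt(fq$lines[off + 4]) - phred_offset
    if (any(qual < 0) || any(qual > 93))
      stop(sprintf("record %d: quality characters outside Phred+%d range",
                   i, phred_offset), call. = FALSE)
    n_low <- sum(qual < params$low_quality_threshold)
    if (n_low > params$max_low_quality_positions) "dropped_quality" else "kept"
  }, character(1))
}

#' Filter FASTQ reads on undetermined bases and quality
#'
#' Streams a FASTQ file (plain or gzip) and keeps reads that contain no 'N'
#' and have at most `max_low_quality_positions` bases below the quality
#' threshold. In paired mode both mates are dropped when either fails, and
#' counts are in units of read pairs.
#'
#' @param input Path to a FASTQ file (read 1 in paired mode).
#' @param output Optional path; kept reads are written there (plain text,
#'   or gzip when the name ends in `.gz`).
#' @param params A [fastq_filter_params()] object.
#' @param input2,output2 Optional mate-2 paths enabling paired mode.
#' @param phred_offset Quality encoding offset: 33 (Sanger/modern Illumina,
#'   default) or 64 (legacy Illumina).
#' @return A list with integer counts `kept`, `dropped_N`,
#'   `dropped_quality`, and `total`; the three categories partition the
#'   input reads (pairs in paired mode).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII",
#'              "@r2", "ACNT", "+", "IIII"), fq)
#' filter_fastq(fq)
#' @export
filter_fastq <- function(input, output = NULL,
                         params = fastq_filter_params(),
                         input2 = NULL, output2 = NULL,
                         phred_offset = 33) {
  stopifnot(inherits(params, "fastq_filter_params"))
  if (!phred_offset %in% c(33, 64))
    stop("`phred_offset` must be 33 or 64", call. = FALSE)
  fq1 <- read_fastq_records(input)
  status <- classify_fastq(fq1, params, phred_offset)
  if (!is.null(input2)) {
    fq2 <- read_fastq_records(input2)
    if (fq2$n != fq1$n)
      stop(sprintf("paired files differ in read count (%d vs %d)",
                   fq1$n, fq2$n), call. = FALSE)
    status2 <- classify_fastq(fq2, params, phred_offset)
    # pair status: any N in either mate -> dropped_N; else any quality
    # failure -> dropped_quality
    status <- ifelse(status == "dropped_N" | status2 == "dropped_N",
                     "dropped_N",
                     ifelse(status == "dropped_quality" |
                              status2 == "dropped_quality",
                            "dropped_quality", "kept"))
  }
  write_kept <- function(fq, path) {
    keep_idx <- which(status == "kept")
    line_idx <- as.vector(outer(1:4, (keep_idx - 1) * 4, `+`))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(fq$lines[sort(line_idx)], con)
  }
  if (!is.null(output)) write_kept(fq1, output)
  if (!is.null(input2) && !is.null(output2)) write_kept(fq2, output2)
  list(kept = sum(status == "kept"),
       dropped_N = sum(status == "dropped_N"),
       dropped_quality = sum(status == "dropped_quality"),
       total = length(status))
}

#' Convert raw counts to TPM
#'
#' Per sample, counts are divided by gene (effective) length to give a read
#' rate, and rates are rescaled to sum to one million:
#' \deqn{TPM_i = 10^6 \, (c_i / \ell_i) / \sum_k (c_k / \ell_k).}
#'
#' @param counts Numeric gene-by-sample matrix of non-negative raw counts.
#' @param lengths Numeric vector of per-gene effective lengths in bases,
#'   one per row of `counts`, all > 0.
#' @return A gene-by-sample TPM matrix; each column sums to 1e6.
#' @examples
#' counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' counts_to_tpm(counts, lengths = c(100, 200))
#' @export
counts_to_tpm <- function(counts, lengths) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("`lengths` must have one entry per gene (row of `counts`)",
         call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and finite", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  zero_cols <- which(colSums(counts) == 0)
  if (length(zero_cols))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[zero_cols] %||% zero_cols, collapse = ", "),
         call. = FALSE)
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average biological replicates on the linear TPM scale
#'
#' Collapses sample columns into condition columns by arithmetic mean of
#' TPM. Averaging happens on the linear scale, before any log transform;
#' condition order follows first appearance in `replicate_map`.
#'
#' @param tpm Numeric gene-by-sample TPM matrix with sample colnames.
#' @param replicate_map Named character vector: names are sample ids
#'   (covering every column of `tpm`), values are condition labels.
#' @return An [expression_matrix()] of genes by conditions, carrying
#'   `replicate_map` as provenance.
#' @export
average_replicates <- function(tpm, replicate_map) {
  if (!is.matrix(tpm)) tpm <- as.matrix(tpm)
  if (is.null(colnames(tpm)))
    stop("`tpm` must have sample colnames", call. = FALSE)
  unmapped <- setdiff(colnames(tpm), names(replicate_map))
  if (length(unmapped))
    stop("unmapped sample column(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  map <- replicate_map[names(replicate_map) %in% colnames(tpm)]
  conditions <- unique(unname(map))
  avg <- vapply(conditions, function(cond) {
    cols <- names(map)[map == cond]
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1) avg <- matrix(avg, nrow = 1, dimnames = list(rownames(tpm), conditions))
  colnames(avg) <- conditions
  rownames(avg) <- rownames(tpm)
  expression_matrix(avg, replicate_map = map)
}
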