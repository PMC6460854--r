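#' Specification for a synthetic expression matrix
#'
#' Describes a matrix mixing four gene archetypes: "stable" genes (low
#' log2-scale SD at medium-high mean — the planted reference genes),
#' "variable" genes (high log2-scale SD), "stage_specific" genes expressed
#' in a single condition, and "silent" genes at zero TPM everywhere.
#' Condition-level log2 expression is Normal(mean, sd) per gene; replicate
#' measurements add Normal(0, `noise_sd_log2`) on the log2 scale.
#'
#' @param n_stable,n_variable,n_stage_specific,n_silent Gene counts per
#'   archetype (defaults 50, 450, 0, 0).
#' @param n_conditions Number of conditions (tissues/stages; default 10).
#' @param n_replicates Biological replicates per condition (default 1).
#' @param stable_mean_log2,stable_sd_log2 Stable-gene parameters
#'   (defaults 8, 0.2).
#' @param variable_mean_log2,variable_sd_log2 Variable-gene parameters
#'   (defaults 6, 2).
#' @param noise_sd_log2 Per-replicate measurement noise SD (default 0.1).
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_stable = 50, n_variable = 450,
                                n_stage_specific = 0, n_silent = 0,
                                n_conditions = 10, n_replicates = 1,
                                stable_mean_log2 = 8, stable_sd_log2 = 0.2,
                                variable_mean_log2 = 6,
                                variable_sd_log2 = 2,
                                noise_sd_log2 = 0.1) {
  counts <- c(n_stable, n_variable, n_stage_specific, n_silent)
  if (any(counts < 0) || sum(counts) < 1)
    stop("gene counts must be >= 0 with at least one gene", call. = FALSE)
  if (n_conditions < 1) stop("need >= 1 condition", call. = FALSE)
  if (n_replicates < 1) stop("need >= 1 replicate", call. = FALSE)
  if (stable_sd_log2 < 0 || variable_sd_log2 < 0 || noise_sd_log2 < 0)
    stop("sd parameters must be >= 0", call. = FALSE)
  structure(as.list(environment())[
    c("n_stable", "n_variable", "n_stage_specific", "n_silent",
      "n_conditions", "n_replicates", "stable_mean_log2", "stable_sd_log2",
      "variable_mean_log2", "variable_sd_log2", "noise_sd_log2")],
    class = "expression_sim_spec")
}

#' Preset simulation specs shaped like typical multi-condition designs
#'
#' Three presets mirror common scallop study designs: 7 early-development
#' stages, 11 adult tissues, or 8 gonadal-development conditions, each
#' with 3 biological replicates and a mix of stable, variable,
#' stage-specific and silent genes.
#'
#' @param name One of "early", "tissues", "gonad".
#' @return An [expression_sim_spec()].
#' @export
expression_sim_preset <- function(name = c("early", "tissues", "gonad")) {
  name <- match.arg(name)
  n_cond <- switch(name, early = 7, tissues = 11, gonad = 8)
  expression_sim_spec(n_stable = 50, n_variable = 350,
                      n_stage_specific = 50, n_silent = 50,
                      n_conditions = n_cond, n_replicates = 3)
}

#' Generate a synthetic expression matrix with truth labels
#'
#' @param spec An [expression_sim_spec()].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A list: `expression` (replicate-averaged [expression_matrix()]),
#'   `replicate_tpm` (gene x sample TPM matrix before averaging),
#'   `replicate_map`, and `truth` (data frame gene_id, class).
#' @export
gen_expression <- function(spec = expression_sim_spec(), seed) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  classes <- rep(c("stable", "variable", "stage_specific", "silent"),
                 c(spec$n_stable, spec$n_variable, spec$n_stage_specific,
                   spec$n_silent))
  n_genes <- length(classes)
  ids <- sprintf("G%05d", seq_len(n_genes))
  n_samp <- spec$n_conditions * spec$n_replicates
  cond_labels <- sprintf("cond%02d", seq_len(spec$n_conditions))
  sample_ids <- sprintf("%s_rep%d",
                        rep(cond_labels, each = spec$n_replicates),
                        rep(seq_len(spec$n_replicates), spec$n_conditions))
  replicate_map <- stats::setNames(rep(cond_labels,
                                       each = spec$n_replicates),
                                   sample_ids)
  tpm <- matrix(0, n_genes, n_samp, dimnames = list(ids, sample_ids))
  for (g in seq_len(n_genes)) {
    cl <- classes[g]
    if (cl == "silent") next
    L_cond <- switch(cl,
      stable = stats::rnorm(spec$n_conditions, spec$stable_mean_log2,
                            spec$stable_sd_log2),
      variable = stats::rnorm(spec$n_conditions, spec$variable_mean_log2,
                              spec$variable_sd_log2),
      stage_specific = {
        l <- rep(NA_real_, spec$n_conditions)
        l[sample.int(spec$n_conditions, 1)] <-
          stats::rnorm(1, spec$stable_mean_log2, spec$stable_sd_log2)
        l
      })
    for (ci in seq_len(spec$n_conditions)) {
      if (is.na(L_cond[ci])) next  # stage-specific gene off here: TPM 0
      cols <- (ci - 1) * spec$n_replicates + seq_len(spec$n_replicates)
      tpm[g, cols] <- 2^(L_cond[ci] +
                           stats::rnorm(spec$n_replicates, 0,
                                        spec$noise_sd_log2))
    }
  }
  list(expression = average_replicates(tpm, replicate_map),
       replicate_tpm = tpm,
       replicate_map = replicate_map,
       truth = data.frame(gene_id = ids, class = classes,
                          stringsAsFactors = FALSE))
}

#' Specification for a synthetic Ct matrix coupled to expression
#'
#' Ct values are generated from TPM through a negative linear calibration
#' on the log2 scale plus Gaussian cycle noise, emulating the empirically
#' observed coupling between RT-qPCR quantification cycles and RNA-Seq
#' abundance.
#'
#' @param slope Cycles per log2(TPM) unit, negative (default -0.94).
#' @param intercept Cycles at log2(TPM) = 0 (default 29.67).
#' @param ct_noise_sd Cycle noise SD; scalar or per-gene named vector
#'   (default 0.25).
#' @param efficiency_range Length-2 range for per-gene amplification
#'   efficiencies drawn uniformly (default c(1, 1), i.e. E fixed at 1).
#' @return An object of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(slope = -0.94, intercept = 29.67,
                        ct_noise_sd = 0.25, efficiency_range = c(1, 1)) {
  if (slope >= 0) stop("`slope` must be negative", call. = FALSE)
  if (any(ct_noise_sd < 0)) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  if (length(efficiency_range) != 2 ||
      any(efficiency_range <= 0 | efficiency_range > 1.2))
    stop("`efficiency_range` must be two values in (0, 1.2]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 ct_noise_sd = ct_noise_sd,
                 efficiency_range = sort(efficiency_range)),
            class = "ct_sim_spec")
}

#' Generate a synthetic Ct matrix from TPM values
#'
#' Ct(g, s) = slope * log2(TPM(g, s)) + intercept + Normal(0, noise). Ct
#' values falling outside (0, 45] are clipped into range with a warning.
#'
#' @param x An [expression_matrix()] (or positive gene-by-sample matrix)
#'   restricted to the genes of interest; all TPM must be > 0.
#' @param spec A [ct_sim_spec()].
#' @param seed Integer seed (required).
#' @return A [ct_matrix()] over the same genes and columns, carrying the
#'   drawn per-gene efficiencies when the range is non-degenerate.
#' @export
gen_ct <- function(x, spec = ct_sim_spec(), seed) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  tpm <- if (inherits(x, "expression_matrix")) x$values else x
  if (any(tpm <= 0))
    stop("all TPM must be > 0 to couple Ct to log2(TPM)", call. = FALSE)
  set.seed(seed)
  noise_sd <- spec$ct_noise_sd
  if (!is.null(names(noise_sd))) {
    # genes without an entry fall back to the spec default
    sd_vec <- rep(formals(ct_sim_spec)$ct_noise_sd, nrow(tpm))
    names(sd_vec) <- rownames(tpm)
    sd_vec[names(noise_sd)[names(noise_sd) %in% rownames(tpm)]] <-
      noise_sd[names(noise_sd) %in% rownames(tpm)]
    noise_sd <- sd_vec
  } else if (length(noise_sd) == 1) {
    noise_sd <- rep(noise_sd, nrow(tpm))
  }
  ct <- spec$slope * log2(tpm) + spec$intercept +
    matrix(stats::rnorm(length(tpm), 0, rep(noise_sd, ncol(tpm))),
           nrow(tpm), ncol(tpm))
  out_of_range <- ct <= 0 | ct > 45
  if (any(out_of_range)) {
    warning(sum(out_of_range), " Ct value(s) outside (0, 45] clipped")
    ct[ct <= 0] <- 0.01
    ct[ct > 45] <- 45
  }
  eff <- NULL
  if (diff(spec$efficiency_range) > 0) {
    eff <- stats::setNames(stats::runif(nrow(tpm),
                                        spec$efficiency_range[1],
                                        spec$efficiency_range[2]),
                           rownames(tpm))
  }
  ct_matrix(ct, efficiencies = eff)
}

#' Generate a truth-labelled FASTQ file
#'
#' Emits reads in four known categories so the read filter's counts can be
#' checked exactly: `clean` (no N, all bases high quality), `boundary`
#' (exactly `max_low` positions below Q20 — kept under the default rule),
#' `low_quality` (exactly `max_low + 1` positions below Q20 — dropped),
#' and `with_N` (one 'N' base, otherwise high quality — dropped).
#'
#' @param n_reads Total reads (default 1000).
#' @param read_len Read length in bases (default 100).
#' @param fraction_with_N,fraction_low_quality,fraction_boundary Fractions
#'   of reads in the respective categories (defaults 0.1, 0.1, 0).
#' @param seed Integer seed (required).
#' @param path Output FASTQ path (default a tempfile).
#' @param max_low Low-quality position budget the boundary categories are
#'   built around (default 10).
#' @return A list: `path`, `truth` (data frame read_id, category,
#'   expect_kept), and `expected_counts` (kept, dropped_N,
#'   dropped_quality).
#' @export
gen_fastq <- function(n_reads = 1000, read_len = 100,
                      fraction_with_N = 0.1, fraction_low_quality = 0.1,
                      fraction_boundary = 0, seed,
                      path = tempfile(fileext = ".fastq"), max_low = 10) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  fr <- c(fraction_with_N, fraction_low_quality, fraction_boundary)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("fractions must lie in [0, 1] and sum to <= 1", call. = FALSE)
  if (read_len < max_low + 1)
    stop("`read_len` must exceed `max_low`", call. = FALSE)
  set.seed(seed)
  n_N <- round(n_reads * fraction_with_N)
  n_lq <- round(n_reads * fraction_low_quality)
  n_bd <- round(n_reads * fraction_boundary)
  category <- sample(rep(c("with_N", "low_quality", "boundary", "clean"),
                         c(n_N, n_lq, n_bd, n_reads - n_N - n_lq - n_bd)))
  hi <- intToUtf8(40 + 33)   # Q40
  lo <- intToUtf8(19 + 33)   # Q19 (< 20)
  lines <- character(4 * n_reads)
  for (i in seq_len(n_reads)) {
    seq_i <- paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
                   collapse = "")
    qual <- rep(hi, read_len)
    if (category[i] == "with_N") {
      pos <- sample.int(read_len, 1)
      substr(seq_i, pos, pos) <- "N"
    } else if (category[i] == "low_quality") {
      qual[sample.int(read_len, max_low + 1)] <- lo
    } else if (category[i] == "boundary") {
      qual[sample.int(read_len, max_low)] <- lo
    }
    lines[(i - 1) * 4 + 1:4] <- c(sprintf("@read%05d %s", i, category[i]),
                                  seq_i, "+", paste(qual, collapse = ""))
  }
  writeLines(lines, path)
  truth <- data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
                      category = category,
                      expect_kept = category %in% c("clean", "boundary"),
                      stringsAsFactors = FALSE)
  list(path = path, truth = truth,
       expected_counts = list(kept = sum(truth$expect_kept),
                              dropped_N = sum(category == "with_N"),
                              dropped_quality = sum(category == "low_quality")))
}
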