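#' Fit the linear Ct ~ log2(TPM) calibration
#'
#' Pools paired observations of RT-qPCR quantification cycle and RNA-Seq
#' log2(TPM) — typically all genes x samples of a validated reference
#' panel, minus user-excluded unstable genes — and fits ordinary least
#' squares Ct = slope * log2(TPM) + intercept, reporting Pearson's r (with
#' a two-sided t-test p-value) and R^2 alongside.
#'
#' @param x Either a numeric vector of log2(TPM) values, or a data frame
#'   with columns `log2_tpm` and `ct` (and optionally `gene` for
#'   exclusions).
#' @param ct Numeric Ct vector (when `x` is a vector).
#' @param exclude Character vector of gene ids dropped before fitting
#'   (data-frame input only).
#' @return An object of class `calibration_fit` with `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `p_value`, `n_points`.
#' @examples
#' l <- seq(4, 14, length.out = 11)
#' fit_ct_tpm(l, -0.94 * l + 29.67)
#' @export
fit_ct_tpm <- function(x, ct = NULL, exclude = character(0)) {
  if (is.data.frame(x)) {
    if (!all(c("log2_tpm", "ct") %in% names(x)))
      stop("data frame input needs columns `log2_tpm` and `ct`",
           call. = FALSE)
    if (length(exclude)) {
      if (is.null(x$gene))
        stop("`exclude` requires a `gene` column", call. = FALSE)
      x <- x[!x$gene %in% exclude, , drop = FALSE]
    }
    ct <- x$ct
    x <- x$log2_tpm
  }
  if (length(x) != length(ct))
    stop("`log2_tpm` and `ct` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(ct)))
    stop("non-finite values in calibration input", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in log2(TPM)", call. = FALSE)
  fit <- stats::lm(ct ~ x)
  if (stats::var(ct) == 0) {
    r <- 0; p <- 1
  } else {
    h <- stats::cor.test(x, ct)
    r <- unname(h$estimate); p <- h$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r,
                 r_squared = r^2,
                 p_value = p,
                 n_points = length(x)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Ct = %.4g * log2(TPM) + %.4g   (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("r = %.4g, R^2 = %.4g, p = %.3g\n",
              x$pearson_r, x$r_squared, x$p_value))
  invisible(x)
}

#' Predict Ct from log2(TPM)
#'
#' Applies a [fit_ct_tpm()] calibration, enabling an estimate of expected
#' quantification cycles from RNA-Seq expression prior to running qPCR.
#'
#' @param fit A `calibration_fit`.
#' @param log2_tpm Numeric vector of log2(TPM) values.
#' @return Predicted Ct values (cycles).
#' @export
predict_ct <- function(fit, log2_tpm) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$slope * log2_tpm + fit$intercept
}
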