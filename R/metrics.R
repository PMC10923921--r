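#' Elution time of a chromatographic method
#'
#' The elution time of an output method (OCM) is defined as the maximum
#' retention time of the calibrants measured on that method. It is the
#' denominator of all elution-time-relative error metrics, so that methods
#' with 10-minute and 100-minute gradients are assessed on a common scale.
#'
#' @param calibrant_rts Numeric vector of calibrant retention times in the
#'   OCM, in minutes. Must be non-empty and strictly positive.
#' @return Elution time in minutes (the maximum of `calibrant_rts`).
#' @export
#' @examples
#' elution_time(c(2.0, 9.5, 7.1))  # 9.5
elution_time <- function(calibrant_rts) {
  if (length(calibrant_rts) == 0L) {
    stop("elution_time: empty retention time vector", call. = FALSE)
  }
  if (any(!is.finite(calibrant_rts)) || any(calibrant_rts <= 0)) {
    stop("elution_time: retention times must be finite and > 0", call. = FALSE)
  }
  max(calibrant_rts)
}

#' Error relative to elution time
#'
#' Absolute RT error expressed as a percentage of the OCM elution time:
#' `100 * |pred - ref| / et`. Relative errors on raw RT explode for
#' non-retained molecules (RT near the dead time); normalizing by the
#' elution time instead keeps errors comparable across the RT range and
#' across methods with different run times.
#'
#' @param pred Predicted/projected RT, minutes (vectorized).
#' @param ref Reference RT, minutes (vectorized, recycled against `pred`).
#' @param et Elution time in minutes; must be > 0.
#' @return Error(s) in percent of elution time.
#' @export
error_ret <- function(pred, ref, et) {
  if (!is.numeric(et) || length(et) != 1L || !is.finite(et) || et <= 0) {
    stop("error_ret: elution time must be a single positive number", call. = FALSE)
  }
  100 * abs(pred - ref) / et
}

#' Squared Pearson correlation
#'
#' The r-squared used throughout the projection diagnostics (r2_a, r2_b,
#' r2_c) is the square of the Pearson correlation coefficient between two
#' RT vectors -- not the coefficient of determination of any fitted model.
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) {
    stop("r_squared: vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("r_squared: need at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("r_squared: zero variance in input", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Summarize projection errors relative to elution time
#'
#' Computes the error panel used to assess RT transfer between methods:
#' RMSE and median absolute error as a percent of the OCM elution time
#' (RMSE_Ret, MedE_Ret), the signed mean error (ME_Ret, a bias measure),
#' plus the same quantities in minutes and the squared Pearson correlation.
#'
#' @param pred Numeric vector of predicted/projected RTs, minutes.
#' @param ref Numeric vector of reference RTs, minutes (same length).
#' @param et Elution time in minutes (> 0); see [elution_time()].
#' @param signed_me If `TRUE` (default) ME_Ret is the signed mean error
#'   `100 * mean(pred - ref) / et`; if `FALSE` the mean absolute error is
#'   used instead (sensitivity check).
#' @return A one-row `data.frame` with columns `n`, `elution_time`,
#'   `rmse_min`, `rmse_ret`, `mede_ret`, `me_ret`, `mae_min`, `r2`.
#'   `r2` is `NA` when fewer than 2 points or a vector has zero variance.
#' @export
#' @examples
#' summarize_errors(c(1, 2, 3), c(1, 3, 5), et = 10)
summarize_errors <- function(pred, ref, et, signed_me = TRUE) {
  if (length(pred) != length(ref)) {
    stop("summarize_errors: pred and ref must have equal length", call. = FALSE)
  }
  if (length(pred) < 1L) {
    stop("summarize_errors: need at least one observation", call. = FALSE)
  }
  if (!is.numeric(et) || length(et) != 1L || !is.finite(et) || et <= 0) {
    stop("summarize_errors: elution time must be a single positive number",
         call. = FALSE)
  }
  err <- pred - ref
  rmse_min <- sqrt(mean(err^2))
  me <- if (signed_me) mean(err) else mean(abs(err))
  r2 <- if (length(pred) >= 2L && stats::sd(pred) > 0 && stats::sd(ref) > 0) {
    stats::cor(pred, ref)^2
  } else {
    NA_real_
  }
  data.frame(
    n = length(pred),
    elution_time = et,
    rmse_min = rmse_min,
    rmse_ret = 100 * rmse_min / et,
    mede_ret = 100 * stats::median(abs(err)) / et,
    me_ret = 100 * me / et,
    mae_min = mean(abs(err)),
    r2 = r2
  )
}
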