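#' Quantum-catch logarithmic structure-function model
#'
#' Photoreceptor-mediated function is modelled as proportional to the log of
#' the remaining quantum catch, which for a layer of surviving cones is
#' proportional to outer nuclear layer (ONL) thickness. Both targets are fit
#' with the same two-parameter curve \deqn{y = y_0 + a \cdot \log_{10}(x)}
#' where `x` is foveal ONL thickness in micrometres and `y` is either foveal
#' sensitivity (FS, dB) or decimal visual acuity (VA).
#'
#' The model is linear in `log10(x)`, so the least-squares optimum is obtained
#' by ordinary least squares after the log transform; coefficient standard
#' errors and two-sided p-values come from the t distribution with `n - 2`
#' degrees of freedom. The RMSE is computed over fit residuals with divisor
#' `n` (the population form used throughout the package for prediction
#' ranges), not `n - 2`.
#'
#' @param onl numeric vector of foveal ONL thicknesses (um), all > 0.
#' @param y numeric vector of target values (dB for FS, decimal for VA).
#' @param target `"FS"` or `"VA"`; recorded in the result.
#' @return An object of class `curve_fit` with fields `target`, `y0`, `a`,
#'   `se_y0`, `se_a`, `p_y0`, `p_a`, `rmse`, `n`.
#' @examples
#' fit <- fit_log_model(c(30, 60, 120), -1.07 + 0.91 * log10(c(30, 60, 120)), "VA")
#' fit$a   # 0.91
#' @export
fit_log_model <- function(onl, y, target = c("FS", "VA")) {
  target <- match.arg(target)
  onl <- as.numeric(onl)
  y <- as.numeric(y)
  if (length(onl) != length(y)) stopf("onl and y must have equal length")
  n <- length(onl)
  if (n < 3) stopf("need at least 3 points, got %d", n)
  if (any(!is.finite(onl)) || any(onl <= 0))
    stopf("all ONL values must be positive and finite")
  lx <- log10(onl)
  if (length(unique(lx)) < 2)
    stopf("rank-deficient design: all ONL values identical")

  fit <- lm(y ~ lx)
  # noiseless inputs trigger summary.lm's "essentially perfect fit" warning;
  # exact recovery is an expected use here
  sm <- suppressWarnings(summary(fit)$coefficients)
  res <- stats::residuals(fit)
  structure(list(
    target = target,
    y0 = unname(coef(fit)[1]), a = unname(coef(fit)[2]),
    se_y0 = sm[1, 2], se_a = sm[2, 2],
    p_y0 = sm[1, 4], p_a = sm[2, 4],
    rmse = sqrt(mean(res^2)), n = n
  ), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("Quantum-catch log fit (%s): y = %.4g + %.4g * log10(ONL)\n",
              x$target, x$y0, x$a))
  cat(sprintf("  n = %d, rmse = %.4g, p(a) = %.3g\n", x$n, x$rmse, x$p_a))
  invisible(x)
}

#' Predict function from foveal ONL via a fitted log curve
#'
#' Mirrors the clinical prediction rule: the per-patient prediction is the
#' mean of the curve evaluated at the foveal (0-eccentricity) ONL of each of
#' the patient's three B-scans, and the prediction range half-width is
#' `1.96 * rmse` of the fit.
#'
#' @param fit a [fit_log_model()] result.
#' @param onl_per_scan numeric vector of 3 foveal ONL values (um), one per
#'   scan, each > 0.
#' @return An object of class `prediction` with `value` and `half_width`.
#' @export
predict_cf <- function(fit, onl_per_scan) {
  stopifnot(inherits(fit, "curve_fit"))
  onl_per_scan <- as.numeric(onl_per_scan)
  if (length(onl_per_scan) != 3)
    stopf("expected 3 foveal ONL values (one per scan), got %d",
          length(onl_per_scan))
  if (any(!is.finite(onl_per_scan)) || any(onl_per_scan <= 0))
    stopf("all ONL values must be positive")
  value <- mean(fit$y0 + fit$a * log10(onl_per_scan))
  if (value < 0)
    warning("predicted value below measurable range (negative); reported as-is")
  new_prediction(value, 1.96 * fit$rmse, fit$target)
}

new_prediction <- function(value, half_width, target) {
  stopifnot(is.na(half_width) || half_width >= 0)
  structure(list(value = value, half_width = half_width, target = target),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("%s prediction: %.4g +/- %.4g\n", x$target, x$value,
              x$half_width))
  invisible(x)
}

# Frozen clinical coefficients of the reference structure-function curves.
.cf_coefs <- list(
  FS = c(y0 = -12.01, a = 17.38), # dB vs log10 um
  VA = c(y0 = -1.07, a = 0.91)    # decimal vs log10 um
)

#' Clinical visual-acuity formula from foveal ONL thickness
#'
#' Convenience evaluation of the frozen clinical curve
#' `VA = -1.07 + 0.91 * log10(ONL)` (decimal acuity, ONL in um). The zero
#' crossing sits at ONL = 10^(1.07/0.91) ~ 15 um; below that the formula is
#' negative and should be read as "below measurable acuity".
#'
#' @param onl foveal ONL thickness in micrometres, > 0 (vectorised).
#' @return decimal visual acuity.
#' @examples
#' round(va_from_onl(90), 2)  # 0.71
#' round(va_from_onl(59), 2)  # 0.54
#' @export
va_from_onl <- function(onl) {
  if (any(!is.finite(onl)) || any(onl <= 0))
    stopf("ONL must be positive")
  .cf_coefs$VA[["y0"]] + .cf_coefs$VA[["a"]] * log10(onl)
}

#' Clinical foveal-sensitivity formula from foveal ONL thickness
#'
#' Evaluates the frozen clinical curve `FS = -12.01 + 17.38 * log10(ONL)`
#' (dB; 10 dB = 1 log unit).
#'
#' @inheritParams va_from_onl
#' @return foveal sensitivity in dB.
#' @export
fs_from_onl <- function(onl) {
  if (any(!is.finite(onl)) || any(onl <= 0))
    stopf("ONL must be positive")
  .cf_coefs$FS[["y0"]] + .cf_coefs$FS[["a"]] * log10(onl)
}
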