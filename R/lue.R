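#' Green-canopy fAPAR from NDVI
#'
#' Linear NDVI calibration of the fraction of photosynthetically active
#' radiation absorbed by green canopy elements,
#' `fAPAR_green = 1.235 * NDVI - 0.211`, clamped to the physical range
#' \[0, 1\] (the raw line goes negative below NDVI = 0.171 and exceeds 1
#' above NDVI = 0.98).
#'
#' @param ndvi NDVI value(s) in \[-1, 1\].
#' @param slope,intercept Calibration coefficients.
#' @return fAPAR_green fraction(s) in \[0, 1\].
#' @export
#' @examples
#' fapar_green(0.5)
fapar_green <- function(ndvi, slope = 1.235, intercept = -0.211) {
  if (any(ndvi < -1 | ndvi > 1, na.rm = TRUE)) {
    stop("`ndvi` must lie in [-1, 1]", call. = FALSE)
  }
  pmin(pmax(slope * ndvi + intercept, 0), 1)
}

#' Fit a canopy-chlorophyll estimator from a spectral predictor
#'
#' Calibrates `CCC ~ predictor` with either a linear or an exponential
#' (log-linearised) regression, the two forms used across the estimator
#' registry (NDVI, red edge position, optimal EVI2 band pairs).
#'
#' @param x Predictor values (index value or REP in nm).
#' @param ccc Canopy chlorophyll content, g m-2; must be `> 0` for the
#'   exponential form.
#' @param form `"linear"` or `"exponential"`.
#' @param predictor Label describing the predictor (kept in the object).
#' @return A `ccc_estimator` object with fields `predictor`, `form`, `a`,
#'   `b`, `r2`, `n`.
#' @export
fit_ccc_estimator <- function(x, ccc, form = c("linear", "exponential"),
                              predictor = "index") {
  form <- match.arg(form)
  fit <- switch(form,
    linear = fit_linear(x, ccc),
    exponential = fit_exponential(x, ccc)
  )
  structure(
    list(predictor = predictor, form = form, a = fit$a, b = fit$b,
         r2 = fit$r2, n = fit$n),
    class = "ccc_estimator"
  )
}

#' @export
print.ccc_estimator <- function(x, ...) {
  cat(sprintf("<ccc_estimator> %s (%s): a = %.6g, b = %.6g, R2 = %.4f, n = %d\n",
              x$predictor, x$form, x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Predict canopy chlorophyll from a fitted estimator
#'
#' `a * x + b` (linear) or `a * exp(b * x)` (exponential), clamped at 0
#' since negative chlorophyll is unphysical.
#'
#' @param est A `ccc_estimator` from [fit_ccc_estimator()].
#' @param x Predictor value(s).
#' @return Estimated CCC in g m-2, `>= 0`.
#' @export
estimate_ccc <- function(est, x) {
  stopifnot(inherits(est, "ccc_estimator"))
  raw <- switch(est$form,
    linear = est$a * x + est$b,
    exponential = est$a * exp(est$b * x)
  )
  pmax(raw, 0)
}

#' Calibrate the light-use coefficient alpha
#'
#' The chlorophyll-based LUE model `GPP = PAR * fAPAR_green * alpha * CCC`
#' has no intercept, so `alpha` is the least-squares slope through the
#' origin of measured GPP against the combined predictor
#' `X = PAR * fAPAR_green * CCC`:
#' `alpha = sum(GPP * X) / sum(X^2)`.
#'
#' @param gpp_umol Measured midday GPP, umol CO2 m-2 s-1.
#' @param par PAR, umol photons m-2 s-1.
#' @param fapar fAPAR_green fraction.
#' @param ccc Canopy chlorophyll content, g m-2.
#' @return A `lue_calibration` object with `alpha` (umol CO2 per
#'   umol photons per g Chl m-2), `n`, `rmse` (umol CO2 m-2 s-1).
#' @export
calibrate_alpha <- function(gpp_umol, par, fapar, ccc) {
  n <- length(gpp_umol)
  if (length(par) != n || length(fapar) != n || length(ccc) != n) {
    stop("all calibration vectors must match in length", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 calibration days", call. = FALSE)
  x <- par * fapar * ccc
  if (all(x == 0)) stop("predictor PAR * fAPAR * CCC is identically zero", call. = FALSE)
  if (all(gpp_umol == 0)) {
    warning("measured GPP is identically zero; alpha = 0")
    alpha <- 0
  } else {
    alpha <- sum(gpp_umol * x) / sum(x^2)
  }
  structure(
    list(alpha = alpha, n = n, rmse = sqrt(mean((gpp_umol - alpha * x)^2))),
    class = "lue_calibration"
  )
}

#' @export
print.lue_calibration <- function(x, ...) {
  cat(sprintf("<lue_calibration> alpha = %.6g, n = %d, RMSE = %.4g umol m-2 s-1\n",
              x$alpha, x$n, x$rmse))
  invisible(x)
}

#' Estimate GPP from the chlorophyll-based LUE model
#'
#' `GPP = PAR * fAPAR_green * alpha * CCC`; equivalently the classical
#' `GPP = PAR * fAPAR * LUE` with `LUE = alpha * CCC`.
#'
#' @param par PAR, umol photons m-2 s-1, `>= 0`.
#' @param fapar fAPAR_green fraction, `>= 0`.
#' @param alpha Light-use coefficient, `>= 0`.
#' @param ccc Canopy chlorophyll content, g m-2, `>= 0`.
#' @return GPP in umol CO2 m-2 s-1.
#' @export
#' @examples
#' estimate_gpp(1500, 0.8, 0.002, 1.5)
estimate_gpp <- function(par, fapar, alpha, ccc) {
  if (any(par < 0) || any(fapar < 0) || any(alpha < 0) || any(ccc < 0)) {
    stop("all inputs must be >= 0", call. = FALSE)
  }
  par * fapar * alpha * ccc
}

#' Validate estimated against measured midday GPP
#'
#' Ordinary least squares of measured on estimated GPP (free intercept),
#' reporting slope, intercept, R2 and the 1:1 root-mean-square error
#' between the two series.
#'
#' @param estimated,measured Matched GPP vectors, `n >= 3`.
#' @return A `gpp_validation` object with `slope`, `intercept`, `r2`,
#'   `rmse`, `n`.
#' @export
validate_gpp <- function(estimated, measured) {
  if (length(estimated) != length(measured)) {
    stop("`estimated` and `measured` must match in length", call. = FALSE)
  }
  if (length(estimated) < 3) stop("need at least 3 days", call. = FALSE)
  if (var(estimated) == 0 || var(measured) == 0) {
    stop("degenerate (zero-variance) GPP series", call. = FALSE)
  }
  m <- lm(measured ~ estimated)
  structure(
    list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
         r2 = 1 - sum(residuals(m)^2) / sum((measured - mean(measured))^2),
         rmse = sqrt(mean((measured - estimated)^2)),
         n = length(estimated)),
    class = "gpp_validation"
  )
}

#' @export
print.gpp_validation <- function(x, ...) {
  cat(sprintf(
    "<gpp_validation> slope = %.4f, intercept = %.4g, R2 = %.4f, RMSE = %.4g, n = %d\n",
    x$slope, x$intercept, x$r2, x$rmse, x$n
  ))
  invisible(x)
}
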