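#' Ordinary least squares fit y = a*x + b
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return A `vi_regression` object with fields `form`, `a` (slope),
#'   `b` (intercept), `r2`, `n`. Zero variance in `x` or `y` yields a
#'   missing `r2` rather than an error.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must match in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("`x` and `y` must be free of NA", call. = FALSE)
  if (var(x) == 0) {
    fit <- list(form = "linear", a = NA_real_, b = mean(y), r2 = NA_real_,
                n = length(x))
  } else if (var(y) == 0) {
    fit <- list(form = "linear", a = 0, b = y[1], r2 = NA_real_, n = length(x))
  } else {
    m <- lm(y ~ x)
    # R2 computed directly; summary.lm warns on exact fits
    r2 <- 1 - sum(residuals(m)^2) / sum((y - mean(y))^2)
    fit <- list(form = "linear", a = unname(coef(m)[2]), b = unname(coef(m)[1]),
                r2 = r2, n = length(x))
  }
  structure(fit, class = "vi_regression")
}

#' Exponential fit y = a * exp(b * x) by log-linearisation
#'
#' Fits ordinary least squares on `(x, log(y))`; `a` is the
#' back-transformed intercept and `b` the slope. The reported R2 is that
#' of the log-linearised model.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; all `y > 0`.
#' @return A `vi_regression` object (see [fit_linear()]).
#' @export
fit_exponential <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must match in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("`x` and `y` must be free of NA", call. = FALSE)
  bad <- which(y <= 0)
  if (length(bad) > 0) {
    stop(sprintf("exponential fit requires y > 0; offending sample(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  base <- fit_linear(x, log(y))
  structure(
    list(form = "exponential", a = exp(base$b), b = base$a, r2 = base$r2,
         n = base$n),
    class = "vi_regression"
  )
}

#' @export
print.vi_regression <- function(x, ...) {
  cat(sprintf("<vi_regression> %s: a = %.6g, b = %.6g, R2 = %.4f, n = %d\n",
              x$form, x$a, x$b, if (is.na(x$r2)) NA else x$r2, x$n))
  invisible(x)
}

#' @export
predict.vi_regression <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  switch(object$form,
    linear = object$a * x + object$b,
    exponential = object$a * exp(object$b * x)
  )
}

# closed-form R2 of y against each column-pair index, accumulated over samples.
# Returns a square matrix aligned with `wl`.
r2_from_moments <- function(n, sx, sxx, sxy, sy, syy, bad) {
  varx <- sxx - sx * sx / n
  covxy <- sxy - sx * sy / n
  vary <- syy - sy * sy / n
  r2 <- (covxy * covxy) / (varx * vary)
  r2[!is.finite(r2)] <- NA_real_
  r2[varx <= 1e-30] <- NA_real_
  r2[bad > 0] <- NA_real_
  pmin(pmax(r2, 0), 1)
}

index_matrix <- function(r, form, weight) {
  switch(form,
    ndvi  = outer(r, r, "-") / outer(r, r, "+"),
    rvi   = outer(r, r, "/"),
    wdrvi = outer(weight * r, r, "-") / outer(weight * r, r, "+"),
    evi2  = 2.5 * outer(r, r, "-") / (outer(r, 2.4 * r, "+") + 1)
  )
}

#' Exhaustive two-band index optimisation against canopy chlorophyll
#'
#' For every ordered pair of distinct wavelengths on the search grid and
#' each requested index form, computes the index per sample and the R2 of
#' regressing CCC on it (linear: `ccc ~ a*VI + b`; exponential:
#' log-linearised `ccc ~ a*exp(b*VI)`). Index values are taken at single
#' wavelengths (`rho1` at the row wavelength, `rho2` at the column
#' wavelength). A pair is dropped (`NA`) if the index is undefined for any
#' sample or constant across samples, so `n` is identical for every stored
#' R2. The diagonal (equal wavelengths) is always `NA`. The NDVI map is
#' symmetric under band swap (the swap is a pure sign flip, absorbed by
#' the regression slope), so its upper triangle is mirrored onto the
#' lower; RVI, EVI2 and WDRVI lack that symmetry (WDRVI only reduces to a
#' sign flip at weight 1) and both triangles are computed.
#'
#' @param spectra List of `refl_spectrum` objects covering the grid.
#' @param ccc Canopy chlorophyll content per spectrum (g m-2); must be
#'   `> 0` when an exponential regression is requested.
#' @param lo,hi,step Search grid in nm (default 400-1300 at 1 nm).
#' @param forms Index forms, subset of `c("ndvi", "rvi", "wdrvi", "evi2")`.
#' @param regressions Subset of `c("linear", "exponential")`.
#' @param wdrvi_weight WDRVI weight (see [two_band_index()]).
#' @return An object of class `r2_map_set`: a named list
#'   (`"<form>_<regression>"`) of `r2_map` objects, each holding the
#'   wavelength axis and the square R2 matrix.
#' @export
band_search <- function(spectra, ccc, lo = 400, hi = 1300, step = 1,
                        forms = c("ndvi", "rvi", "wdrvi", "evi2"),
                        regressions = c("linear", "exponential"),
                        wdrvi_weight = 0.2) {
  forms <- match.arg(forms, several.ok = TRUE)
  regressions <- match.arg(regressions, several.ok = TRUE)
  n <- length(spectra)
  if (n != length(ccc)) {
    stop("one CCC value per spectrum is required", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if ("exponential" %in% regressions && any(ccc <= 0)) {
    stop("exponential regression requires all ccc > 0", call. = FALSE)
  }
  wl <- seq(lo, hi, by = step)
  refm <- vapply(spectra, function(sp) refl_at(sp, wl), numeric(length(wl)))

  ys <- list()
  if ("linear" %in% regressions) ys$linear <- ccc
  if ("exponential" %in% regressions) ys$exponential <- log(ccc)

  out <- list()
  nw <- length(wl)
  for (form in forms) {
    sx <- matrix(0, nw, nw); sxx <- matrix(0, nw, nw)
    bad <- matrix(0L, nw, nw)
    sxy <- lapply(ys, function(y) matrix(0, nw, nw))
    for (s in seq_len(n)) {
      xm <- index_matrix(refm[, s], form, wdrvi_weight)
      nf <- !is.finite(xm)
      if (any(nf)) {
        xm[nf] <- 0
        bad <- bad + nf
      }
      sx <- sx + xm
      sxx <- sxx + xm * xm
      for (reg in names(ys)) sxy[[reg]] <- sxy[[reg]] + xm * ys[[reg]][s]
    }
    for (reg in names(ys)) {
      y <- ys[[reg]]
      r2 <- r2_from_moments(n, sx, sxx, sxy[[reg]], sum(y), sum(y * y), bad)
      diag(r2) <- NA_real_
      if (form == "ndvi" || (form == "wdrvi" && wdrvi_weight == 1)) {
        # swap symmetry is exact only when the swap is a pure sign flip
        r2[lower.tri(r2)] <- t(r2)[lower.tri(r2)]
      }
      out[[paste(form, reg, sep = "_")]] <- structure(
        list(wavelength = wl, r2 = r2, form = form, regression = reg, n = n),
        class = "r2_map"
      )
    }
  }
  structure(out, class = "r2_map_set")
}

#' @export
print.r2_map <- function(x, ...) {
  cat(sprintf("<r2_map> %s / %s: %d x %d pairs (%g-%g nm), max R2 = %.4f\n",
              x$form, x$regression, length(x$wavelength), length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              max(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.r2_map_set <- function(x, ...) {
  cat(sprintf("<r2_map_set> %d maps:\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' Top-ranked band pairs from an R2 map
#'
#' @param map An `r2_map` from [band_search()].
#' @param k Number of pairs to return; must not exceed the finite entries.
#' @return Tibble sorted by descending R2 (ties broken by lower `lambda1`,
#'   then lower `lambda2`) with columns `lambda1`, `lambda2`, `r2`,
#'   `form`, `regression`.
#' @export
best_pairs <- function(map, k = 10) {
  stopifnot(inherits(map, "r2_map"))
  fin <- which(is.finite(map$r2), arr.ind = TRUE)
  if (k > nrow(fin)) {
    stop(sprintf("k = %d exceeds the %d finite entries", k, nrow(fin)),
         call. = FALSE)
  }
  df <- tibble::tibble(
    lambda1 = map$wavelength[fin[, 1]],
    lambda2 = map$wavelength[fin[, 2]],
    r2 = map$r2[fin]
  )
  df <- df[order(-df$r2, df$lambda1, df$lambda2), ]
  df <- head(df, k)
  df$form <- map$form
  df$regression <- map$regression
  df
}
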