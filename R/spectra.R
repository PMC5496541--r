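#' Reflectance spectrum for one canopy sample
#'
#' Container for a single hyperspectral reflectance measurement: a strictly
#' increasing wavelength grid (nm) and reflectance fractions in \[0, 1\].
#' Most index operations assume a uniform 1-nm grid; use
#' [resample_to_1nm()] first for irregular field exports.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance Numeric vector of reflectance fractions, same length.
#' @param sample_id Optional sample identifier.
#' @param date Optional measurement date (`Date` or coercible).
#'
#' @return An object of class `refl_spectrum`.
#' @export
#' @examples
#' sp <- reflectance_spectrum(400:900, rep(0.3, 501), sample_id = "s1")
#' band_average(sp, 620, 670)
reflectance_spectrum <- function(wavelength, reflectance, sample_id = NA_character_,
                                 date = as.Date(NA)) {
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength) != length(reflectance)) {
    stop("`wavelength` and `reflectance` must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 2) {
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  }
  if (anyNA(wavelength) || is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be strictly increasing and free of NA", call. = FALSE)
  }
  if (any(!is.finite(reflectance)) ||
      any(reflectance < -1e-9) || any(reflectance > 1 + 1e-9)) {
    stop("`reflectance` must be finite and within [0, 1]", call. = FALSE)
  }
  structure(
    list(
      wavelength = wavelength,
      reflectance = pmin(pmax(reflectance, 0), 1),
      sample_id = as.character(sample_id),
      date = as.Date(date)
    ),
    class = "refl_spectrum"
  )
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat(sprintf(
    "<refl_spectrum> %s %s: %d bands, %.0f-%.0f nm, reflectance %.3f-%.3f\n",
    x$sample_id, format(x$date), length(x$wavelength),
    min(x$wavelength), max(x$wavelength),
    min(x$reflectance), max(x$reflectance)
  ))
  invisible(x)
}

is_unit_grid <- function(spectrum) {
  w <- spectrum$wavelength
  all(w == round(w)) && all(diff(w) == 1)
}

assert_unit_grid <- function(spectrum) {
  if (!is_unit_grid(spectrum)) {
    stop("spectrum is not on a uniform 1-nm grid; call resample_to_1nm() first",
         call. = FALSE)
  }
  invisible(spectrum)
}

# reflectance at exact integer wavelengths (vectorised); errors on misses
refl_at <- function(spectrum, lambda) {
  idx <- match(lambda, spectrum$wavelength)
  if (anyNA(idx)) {
    stop(sprintf("spectrum does not cover wavelength(s): %s",
                 paste(lambda[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  spectrum$reflectance[idx]
}

#' Resample a spectrum onto the integer 1-nm grid
#'
#' Linear interpolation onto the integer-nm grid spanning the input range.
#' Values at original integer-nm wavelengths are preserved exactly.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @return A `refl_spectrum` on a 1-nm grid.
#' @export
resample_to_1nm <- function(spectrum) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  grid <- seq(ceiling(min(spectrum$wavelength)), floor(max(spectrum$wavelength)))
  vals <- approx(spectrum$wavelength, spectrum$reflectance, xout = grid,
                 method = "linear", ties = "ordered")$y
  reflectance_spectrum(grid, vals, sample_id = spectrum$sample_id,
                       date = spectrum$date)
}

#' Mean reflectance over an inclusive waveband
#'
#' Arithmetic mean of reflectance at the integer wavelengths in
#' `[lo, hi]`, the convention used for MODIS-style broadband values
#' (e.g. red 620-670 nm, NIR 841-876 nm).
#'
#' @param spectrum A `refl_spectrum` on a 1-nm grid.
#' @param lo,hi Band limits in nm, `lo <= hi`, inside the spectrum range.
#' @return Mean reflectance (fraction).
#' @export
band_average <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  assert_unit_grid(spectrum)
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  if (lo < min(spectrum$wavelength) || hi > max(spectrum$wavelength)) {
    stop(sprintf("band [%s, %s] outside spectrum range [%s, %s]",
                 lo, hi, min(spectrum$wavelength), max(spectrum$wavelength)),
         call. = FALSE)
  }
  mean(refl_at(spectrum, seq(ceiling(lo), floor(hi))))
}

#' First-derivative reflectance at a wavelength
#'
#' Central first difference on the 1-nm grid,
#' `(rho(lambda + 1) - rho(lambda - 1)) / 2`, in reflectance per nm.
#' Used by the derivative-based canopy chlorophyll index (D720/D700).
#'
#' @param spectrum A `refl_spectrum` on a 1-nm grid.
#' @param lambda Wavelength(s) in nm, interior to the grid.
#' @return Slope(s) in reflectance per nm.
#' @export
derivative_at <- function(spectrum, lambda) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  assert_unit_grid(spectrum)
  (refl_at(spectrum, lambda + 1) - refl_at(spectrum, lambda - 1)) / 2
}

#' Red edge position
#'
#' The red edge position (REP) is the wavelength of maximum reflectance
#' slope between 680 and 750 nm, located here as the argmax of the central
#' first difference on the 1-nm grid. Ties break toward the shorter
#' wavelength. When the maximum slope does not exceed `slope_floor`
#' (flat or vegetationless spectra) the REP is undefined and `NA` is
#' returned.
#'
#' @param spectrum A `refl_spectrum` on a 1-nm grid covering 679-751 nm.
#' @param slope_floor Minimum slope (per nm) for a defined red edge.
#' @return REP in nm, or `NA_real_` when undefined.
#' @export
compute_rep <- function(spectrum, slope_floor = 1e-5) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  assert_unit_grid(spectrum)
  if (min(spectrum$wavelength) > 679 || max(spectrum$wavelength) < 751) {
    stop("spectrum must cover 679-751 nm to locate the red edge", call. = FALSE)
  }
  candidates <- 680:750
  slopes <- derivative_at(spectrum, candidates)
  if (max(slopes) <= slope_floor) {
    return(NA_real_)
  }
  as.numeric(candidates[which.max(slopes)])
}

#' Generalised two-band vegetation index
#'
#' Computes one of the four two-band index forms used in the exhaustive
#' band-pair optimisation, from the two reflectances directly:
#' \describe{
#'   \item{ndvi}{`(rho1 - rho2) / (rho1 + rho2)`}
#'   \item{rvi}{`rho1 / rho2`}
#'   \item{wdrvi}{`(w * rho1 - rho2) / (w * rho1 + rho2)`}
#'   \item{evi2}{`2.5 * (rho1 - rho2) / (rho1 + 2.4 * rho2 + 1)`}
#' }
#' Undefined values (zero denominators) propagate as `NA`, never as errors.
#'
#' @param rho1,rho2 Reflectance fractions in \[0, 1\] (vectorised).
#' @param form One of `"ndvi"`, `"rvi"`, `"wdrvi"`, `"evi2"`.
#' @param weight Positive weight on `rho1` for WDRVI; the conventional
#'   range is 0.1-0.2. Distinct from the light-use coefficient alpha of the
#'   GPP model.
#' @return Index value(s); `NA` where undefined.
#' @export
#' @examples
#' two_band_index(0.5, 0.1, "ndvi")
#' two_band_index(0.5, 0.1, "wdrvi", weight = 0.2)
two_band_index <- function(rho1, rho2, form = c("ndvi", "rvi", "wdrvi", "evi2"),
                           weight = 0.2) {
  form <- match.arg(form)
  if (any(rho1 < 0 | rho1 > 1, na.rm = TRUE) ||
      any(rho2 < 0 | rho2 > 1, na.rm = TRUE)) {
    stop("reflectances must lie in [0, 1]", call. = FALSE)
  }
  if (form == "wdrvi" && (!is.numeric(weight) || length(weight) != 1 || weight <= 0)) {
    stop("`weight` must be a single positive number", call. = FALSE)
  }
  out <- switch(form,
    ndvi  = (rho1 - rho2) / (rho1 + rho2),
    rvi   = rho1 / rho2,
    wdrvi = (weight * rho1 - rho2) / (weight * rho1 + rho2),
    evi2  = 2.5 * (rho1 - rho2) / (rho1 + 2.4 * rho2 + 1)
  )
  out[!is.finite(out)] <- NA_real_
  out
}

# MODIS-style broadband limits used for rho_nir / rho_red / rho_blue / rho_swir1
broadband_limits <- function(blue = c(459, 479)) {
  list(
    red = c(620, 670),
    nir = c(841, 876),
    blue = blue,
    swir1 = c(1628, 1652)
  )
}

#' Names of the supported chlorophyll-related vegetation indices
#'
#' @return Character vector of index names accepted by [compute_index()].
#' @export
list_indices <- function() {
  c("NDVI", "EVI", "RVI", "RedEdgeNDVI", "PRI", "MCARI710",
    "CIgreen", "CIrededge", "MTCI", "CCI", "WDRVI")
}

#' Chlorophyll-related vegetation indices from a spectrum
#'
#' Computes one of eleven common chlorophyll-related indices. Broadband
#' `rho_nir`, `rho_red` and `rho_blue` are band averages over the MODIS
#' ranges (841-876, 620-670 and 459-479 nm); single-wavelength terms
#' (e.g. `rho_750`) are read at the stated nm; `D720`/`D700` are central
#' first differences. Zero denominators yield `NA`.
#'
#' @param spectrum A `refl_spectrum` on a 1-nm grid covering the index bands.
#' @param index One of [list_indices()].
#' @param wdrvi_weight Weight for WDRVI (see [two_band_index()]).
#' @param blue_band Length-2 band limits for `rho_blue` in the EVI.
#' @return Index value, or `NA_real_` where undefined.
#' @export
compute_index <- function(spectrum, index, wdrvi_weight = 0.2,
                          blue_band = c(459, 479)) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  assert_unit_grid(spectrum)
  if (!is.character(index) || length(index) != 1 || !(index %in% list_indices())) {
    stop(sprintf("unknown index '%s'; see list_indices()", paste(index, collapse = ",")),
         call. = FALSE)
  }
  bb <- broadband_limits(blue = blue_band)
  safe <- function(num, den) {
    v <- num / den
    if (!is.finite(v)) NA_real_ else v
  }
  switch(index,
    NDVI = {
      nir <- band_average(spectrum, bb$nir[1], bb$nir[2])
      red <- band_average(spectrum, bb$red[1], bb$red[2])
      safe(nir - red, nir + red)
    },
    EVI = {
      nir <- band_average(spectrum, bb$nir[1], bb$nir[2])
      red <- band_average(spectrum, bb$red[1], bb$red[2])
      blue <- band_average(spectrum, bb$blue[1], bb$blue[2])
      safe(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1)
    },
    RVI = {
      nir <- band_average(spectrum, bb$nir[1], bb$nir[2])
      red <- band_average(spectrum, bb$red[1], bb$red[2])
      safe(nir, red)
    },
    RedEdgeNDVI = {
      r750 <- refl_at(spectrum, 750); r710 <- refl_at(spectrum, 710)
      safe(r750 - r710, r750 + r710)
    },
    PRI = {
      r531 <- refl_at(spectrum, 531); r570 <- refl_at(spectrum, 570)
      safe(r531 - r570, r531 + r570)
    },
    MCARI710 = {
      r750 <- refl_at(spectrum, 750); r710 <- refl_at(spectrum, 710)
      r550 <- refl_at(spectrum, 550)
      ratio <- safe(r750, r710)
      if (is.na(ratio)) NA_real_ else ((r750 - r710) - 0.2 * (r750 - r550)) * ratio
    },
    CIgreen = {
      r750 <- refl_at(spectrum, 750); r550 <- refl_at(spectrum, 550)
      v <- safe(r750, r550)
      if (is.na(v)) NA_real_ else v - 1
    },
    CIrededge = {
      r750 <- refl_at(spectrum, 750); r710 <- refl_at(spectrum, 710)
      v <- safe(r750, r710)
      if (is.na(v)) NA_real_ else v - 1
    },
    MTCI = {
      r753 <- refl_at(spectrum, 753); r708 <- refl_at(spectrum, 708)
      r681 <- refl_at(spectrum, 681)
      safe(r753 - r708, r708 - r681)
    },
    CCI = {
      safe(derivative_at(spectrum, 720), derivative_at(spectrum, 700))
    },
    WDRVI = {
      nir <- band_average(spectrum, bb$nir[1], bb$nir[2])
      red <- band_average(spectrum, bb$red[1], bb$red[2])
      safe(wdrvi_weight * nir - red, wdrvi_weight * nir + red)
    }
  )
}

#' Per-sample table of vegetation indices and red edge position
#'
#' @param spectra List of `refl_spectrum` objects.
#' @param indices Character vector of index names (default all).
#' @param include_rep Add a `REP` column from [compute_rep()]?
#' @param wdrvi_weight,blue_band Passed to [compute_index()].
#' @return A tibble with `sample_id`, `date` and one column per index.
#' @export
compute_index_table <- function(spectra, indices = list_indices(),
                                include_rep = TRUE, wdrvi_weight = 0.2,
                                blue_band = c(459, 479)) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  rows <- lapply(spectra, function(sp) {
    vals <- vapply(indices, function(ix) {
      compute_index(sp, ix, wdrvi_weight = wdrvi_weight, blue_band = blue_band)
    }, numeric(1))
    out <- tibble::tibble(sample_id = sp$sample_id, date = sp$date)
    out[indices] <- as.list(vals)
    if (include_rep) out$REP <- compute_rep(sp)
    out
  })
  dplyr::bind_rows(rows)
}
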