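# wavelength grid the generator emits (covers the 400-1300 nm search range
# plus the MODIS NIR band and both planted pairs)
GEN_GRID <- 400:1350

# bare-soil line: monotone, featureless, with slope below the REP slope
# floor so vegetationless spectra flag the red edge undefined
soil_line <- function(wl) {
  0.18 + 8e-6 * (wl - 400)
}

# compactly supported raised-cosine bump: 1 at `center`, 0 beyond radius
cos_bump <- function(wl, center, radius) {
  u <- abs(wl - center) / radius
  ifelse(u < 1, cos(pi * u / 2)^2, 0)
}

# smooth window that is exactly 1 on [flat_lo, flat_hi] and exactly 0
# outside [lo, hi]
flat_window <- function(wl, lo, flat_lo, flat_hi, hi) {
  out <- numeric(length(wl))
  out[wl >= flat_lo & wl <= flat_hi] <- 1
  left <- wl > lo & wl < flat_lo
  out[left] <- sin(pi / 2 * (wl[left] - lo) / (flat_lo - lo))^2
  right <- wl > flat_hi & wl < hi
  out[right] <- cos(pi / 2 * (wl[right] - flat_hi) / (hi - flat_hi))^2
  out
}

#' Generate a synthetic canopy reflectance spectrum
#'
#' Builds a 1-nm reflectance spectrum on 400-1350 nm as a gap-fraction
#' mixture of a bare-soil line and a vegetation spectrum with: a red
#' trough (660-680 nm) deepening with canopy chlorophyll content, a
#' red-edge sigmoid whose inflection moves as
#' `700 + 40 * ccc / (ccc + 1)` nm (saturating inside the 680-750 nm
#' red-edge window), a NIR plateau rising with LAI, and water-absorption
#' dips near 970 and 1200 nm. For vegetated canopies the spectrum is then
#' adjusted so the planted index-CCC relations of [planted_relations()]
#' hold exactly: the 620-670 nm region is rescaled to pin the broadband
#' NDVI, and narrow raised-cosine features pin the two planted EVI2
#' pairs. Additive Gaussian noise (truncated to keep reflectance in
#' \[0, 1\]) is applied last; with `noise_sd = 0` the output is a
#' deterministic function of `(ccc, lai)`.
#'
#' @param ccc Canopy chlorophyll content, g m-2, `>= 0`.
#' @param lai Leaf area index, `>= 0`. `ccc = lai = 0` gives bare soil.
#' @param noise_sd Additive reflectance noise sd, `>= 0`.
#' @param seed Optional integer seed for the noise draw; with `NULL` the
#'   current RNG stream is used.
#' @param sample_id,date Passed to [reflectance_spectrum()].
#' @param planting Planted relations (see [planted_relations()]), or
#'   `NULL` to skip the exact-index adjustment.
#' @return A `refl_spectrum` on the 1-nm grid 400-1350 nm.
#' @export
generate_spectrum <- function(ccc, lai, noise_sd = 0, seed = NULL,
                              sample_id = NA_character_, date = as.Date(NA),
                              planting = planted_relations()) {
  if (!is.finite(ccc) || ccc < 0) stop("`ccc` must be finite and >= 0", call. = FALSE)
  if (!is.finite(lai) || lai < 0) stop("`lai` must be finite and >= 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be finite and >= 0", call. = FALSE)
  }
  wl <- GEN_GRID
  soil <- soil_line(wl)

  # vegetation endmember
  trough_floor <- 0.035 + 0.17 * exp(-1.1 * ccc)
  green_amp <- 0.06 * (0.25 + 0.75 * exp(-0.8 * ccc))
  vis <- trough_floor + green_amp * exp(-((wl - 550) / 30)^2)
  lambda_infl <- 700 + 40 * ccc / (ccc + 1)
  sig <- plogis((wl - lambda_infl) / 3)
  plateau <- 0.30 + 0.18 * (1 - exp(-0.45 * lai))
  nir <- plateau * (1 - 0.10 * exp(-((wl - 970) / 22)^2)
                      - 0.16 * exp(-((wl - 1200) / 32)^2))
  veg <- vis * (1 - sig) + nir * sig

  gap <- exp(-0.6 * lai)
  refl <- gap * soil + (1 - gap) * veg

  if (!is.null(planting) && ccc > 0.02 && lai > 0.05) {
    refl <- plant_index_relations(wl, refl, ccc, planting)
  }

  if (noise_sd > 0) {
    draw <- function() refl + rnorm(length(refl), 0, noise_sd)
    refl <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    refl <- pmin(pmax(refl, 0), 1)
  }
  reflectance_spectrum(wl, refl, sample_id = sample_id, date = date)
}

# deform the base spectrum so the planted NDVI and EVI2 relations hold
# exactly; all adjustments stay clear of the 680-750 nm red-edge window
# and of the MODIS NIR band (841-876 nm)
plant_index_relations <- function(wl, refl, ccc, planting) {
  # broadband NDVI: rescale the red region (support 610-680 nm, flat over
  # the full 620-670 nm MODIS red band so the band mean is pinned exactly)
  nir_mean <- mean(refl[wl >= 841 & wl <= 876])
  ndvi_t <- planted_ndvi(ccc, planting)
  red_t <- nir_mean * (1 - ndvi_t) / (1 + ndvi_t)
  red_now <- mean(refl[wl >= 620 & wl <= 670])
  k <- red_t / red_now
  refl <- refl * (1 + (k - 1) * flat_window(wl, 610, 618, 672, 680))

  # single-wavelength EVI2 pairs: solve rho1 from the target index and the
  # current rho2, then pin it with a narrow bump (pair2 solved after pair1;
  # supports are disjoint from each other and from every other band used)
  for (pr in list(planting$pair1, planting$pair2)) {
    e_t <- (ccc - pr$intercept) / pr$slope
    rho2 <- refl[wl == pr$bands[2]]
    rho1_t <- (2.5 * rho2 + e_t * (2.4 * rho2 + 1)) / (2.5 - e_t)
    rho1_now <- refl[wl == pr$bands[1]]
    refl <- refl + (rho1_t - rho1_now) * cos_bump(wl, pr$bands[1], 8)
  }
  refl
}

#' Plant a CCC label as an exponential function of one band pair
#'
#' Recovery-test scaffolding for the exhaustive band search: given a set
#' of spectra, defines canopy chlorophyll labels
#' `ccc = a * exp(b * EVI2[pair])` from each spectrum's measured EVI2 at
#' the designated pair, plus small multiplicative noise, so that the pair
#' is by construction the maximally informative wavelength combination.
#' Use spectra generated with `planting = NULL`, otherwise the generator's
#' own exact index relations compete with the planted label relation; keep
#' the label noise small against the pair's EVI2 dynamic range (about
#' 0.05 across a season) so the pair stays recoverable.
#'
#' @param spectra List of `refl_spectrum` objects.
#' @param pair Length-2 wavelength pair in nm (inside 400-1300).
#' @param a,b Coefficients of the planted exponential relation.
#' @param label_sd Relative sd of the multiplicative label noise.
#' @param seed Optional integer seed.
#' @return Numeric vector of planted CCC labels (g m-2).
#' @export
plant_ccc_from_pair <- function(spectra, pair = c(1214, 1259), a = 0.5, b = 3,
                                label_sd = 0.002, seed = NULL) {
  if (length(pair) != 2 || any(pair < 400) || any(pair > 1300)) {
    stop("`pair` must be two wavelengths inside 400-1300 nm", call. = FALSE)
  }
  e <- vapply(spectra, function(sp) {
    two_band_index(refl_at(sp, pair[1]), refl_at(sp, pair[2]), "evi2")
  }, numeric(1))
  labels <- a * exp(b * e)
  if (label_sd > 0) {
    draw <- function() labels * (1 + rnorm(length(labels), 0, label_sd))
    labels <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  pmax(labels, 1e-6)
}
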