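# Independent oracles: plain-arithmetic re-implementations used to
# cross-check the package's vectorised/registry code paths. They share no
# code with the implementation beyond base R.

oracle_mean_band <- function(wl, refl, lo, hi) {
  sel <- wl >= lo & wl <= hi
  sum(refl[sel]) / sum(sel)
}

oracle_at <- function(wl, refl, lambda) refl[which(wl == lambda)]

oracle_deriv <- function(wl, refl, lambda) {
  (oracle_at(wl, refl, lambda + 1) - oracle_at(wl, refl, lambda - 1)) / 2
}

# Table of chlorophyll-related index formulas, written out one by one
oracle_index <- function(sp, name, wdrvi_weight = 0.2) {
  wl <- sp$wavelength; r <- sp$reflectance
  nir <- oracle_mean_band(wl, r, 841, 876)
  red <- oracle_mean_band(wl, r, 620, 670)
  blue <- oracle_mean_band(wl, r, 459, 479)
  val <- switch(name,
    NDVI = (nir - red) / (nir + red),
    EVI = 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1),
    RVI = nir / red,
    RedEdgeNDVI = (oracle_at(wl, r, 750) - oracle_at(wl, r, 710)) /
      (oracle_at(wl, r, 750) + oracle_at(wl, r, 710)),
    PRI = (oracle_at(wl, r, 531) - oracle_at(wl, r, 570)) /
      (oracle_at(wl, r, 531) + oracle_at(wl, r, 570)),
    MCARI710 = ((oracle_at(wl, r, 750) - oracle_at(wl, r, 710)) -
                  0.2 * (oracle_at(wl, r, 750) - oracle_at(wl, r, 550))) *
      (oracle_at(wl, r, 750) / oracle_at(wl, r, 710)),
    CIgreen = oracle_at(wl, r, 750) / oracle_at(wl, r, 550) - 1,
    CIrededge = oracle_at(wl, r, 750) / oracle_at(wl, r, 710) - 1,
    MTCI = (oracle_at(wl, r, 753) - oracle_at(wl, r, 708)) /
      (oracle_at(wl, r, 708) - oracle_at(wl, r, 681)),
    CCI = oracle_deriv(wl, r, 720) / oracle_deriv(wl, r, 700),
    WDRVI = (wdrvi_weight * nir - red) / (wdrvi_weight * nir + red)
  )
  if (!is.finite(val)) NA_real_ else val
}

# maximum-slope red edge by explicit loop
oracle_rep <- function(sp, slope_floor = 1e-5) {
  best <- -Inf; best_wl <- NA_real_
  for (lam in 680:750) {
    s <- oracle_deriv(sp$wavelength, sp$reflectance, lam)
    if (s > best) { best <- s; best_wl <- as.numeric(lam) }
  }
  if (best <= slope_floor) NA_real_ else best_wl
}

# closed-form OLS via normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - sy / n)^2)
  list(slope = b, intercept = a, r2 = r2)
}

# a smooth vegetated spectrum with randomised state, for oracle sweeps
random_spectrum <- function() {
  generate_spectrum(runif(1, 0.1, 2.5), runif(1, 0.3, 4.5),
                    noise_sd = runif(1, 0, 0.005))
}
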