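campaign_dates <- function(config) {
  as.Date(round(seq(as.numeric(config$campaign_start),
                    as.numeric(config$campaign_end),
                    length.out = config$n_campaigns)),
          origin = "1970-01-01")
}

#' Simulate the biweekly measurement campaigns of a season
#'
#' Draws the campaign dates evenly across the campaign window, evaluates
#' the planted CCC/LAI truth on those dates, inverts the SPAD calibration
#' chain to obtain the true SPAD value, adds independent per-plant SPAD
#' noise, and generates one canopy reflectance spectrum per campaign from
#' the true CCC and LAI. Campaign dates and truth values depend only on
#' the configuration, never on the RNG, so changing the seed changes only
#' the noise realisations.
#'
#' @param config A [season_config()].
#' @param truth Optional truth bundle from [season_truth()] (recomputed
#'   when omitted).
#' @return A list with `campaigns` (per-plant tibble: `date`, `plant_id`,
#'   `spad`, `lai`), `samples` (per-campaign chain table from
#'   [campaign_ccc()]), `spectra` (list of `refl_spectrum`), and `truth`.
#' @export
simulate_campaigns <- function(config, truth = season_truth(config)) {
  stopifnot(inherits(config, "season_config"))
  dates <- campaign_dates(config)
  idx <- match(dates, truth$daily$date)
  ccc <- truth$daily$ccc[idx]
  lai <- truth$daily$lai[idx]
  m_true <- ccc_to_spad(ccc, lai)

  campaigns <- tibble::tibble(
    date = rep(dates, each = config$n_plants),
    plant_id = rep(seq_len(config$n_plants), times = length(dates)),
    spad = pmax(rep(m_true, each = config$n_plants) +
                  rnorm(length(dates) * config$n_plants, 0, config$spad_sd), 0),
    lai = rep(lai, each = config$n_plants)
  )
  spectra <- lapply(seq_along(dates), function(i) {
    generate_spectrum(ccc[i], lai[i], noise_sd = config$spectral_sd,
                      sample_id = sprintf("campaign_%02d", i), date = dates[i],
                      planting = config$planting)
  })
  list(campaigns = campaigns, samples = campaign_ccc(campaigns),
       spectra = spectra, truth = truth)
}

# deterministic diurnal/seasonal micromet drivers (Kelvin for temperatures)
par_clear_sky <- function(doy, hour) {
  pmax_day <- 1600 + 350 * cos(2 * pi * (doy - 172) / 365)
  ifelse(hour > 6 & hour < 18, pmax_day * sin(pi * (hour - 6) / 12), 0)
}

soil_temperature <- function(doy, hour) {
  284 + 7 * cos(2 * pi * (doy - 215) / 365) + 2.5 * sin(2 * pi * (hour - 9) / 24)
}

air_temperature <- function(doy, hour) {
  283.5 + 10 * cos(2 * pi * (doy - 208) / 365) + 5 * sin(2 * pi * (hour - 9) / 24)
}

#' Simulate the half-hourly flux and micromet series of a season
#'
#' Forward model over every half hour of the season: PAR follows a
#' clipped diurnal sinusoid (exactly zero at night) with multiplicative
#' log-normal cloud noise; soil and air temperature follow
#' diurnal-plus-seasonal sinusoids; ecosystem respiration follows the
#' Lloyd-Taylor model with the planted `rref` and `e0`; GPP follows
#' `PAR * fAPAR_green * alpha * CCC` with the daily planted truth; and
#' `NEE = Reco - GPP` (positive when CO2 is emitted) with multiplicative
#' and additive noise. Relative humidity, vapour pressure deficit and
#' soil water content are plausible deterministic drivers carried along
#' for format completeness.
#'
#' @param config A [season_config()].
#' @param truth Optional truth bundle from [season_truth()].
#' @return Tibble with half-hourly `timestamp` (UTC), `nee`, `par`,
#'   `t_air`, `t_soil` (K), `rh`, `vpd`, `swc`, plus the noise-free truth
#'   columns `reco_true` and `gpp_true` (mg CO2 m-2 s-1).
#' @export
simulate_flux <- function(config, truth = season_truth(config)) {
  stopifnot(inherits(config, "season_config"))
  daily <- truth$daily
  n_days <- nrow(daily)
  hour <- rep(seq(0, 23.5, by = 0.5), times = n_days)
  doy <- rep(daily$doy, each = 48)
  ccc <- rep(daily$ccc, each = 48)
  fapar <- rep(daily$fapar, each = 48)
  timestamp <- rep(as.POSIXct(daily$date, tz = "UTC"), each = 48) + hour * 3600

  par <- par_clear_sky(doy, hour)
  if (config$cloud_sd > 0) {
    par <- par * exp(rnorm(length(par), 0, config$cloud_sd) -
                       config$cloud_sd^2 / 2)
  }
  t_soil <- soil_temperature(doy, hour)
  t_air <- air_temperature(doy, hour)

  reco <- lloyd_taylor(t_soil, truth$rref, truth$e0)
  gpp_umol <- par * fapar * truth$alpha * ccc
  gpp_mg <- gpp_umol * MG_PER_UMOL_CO2
  nee <- reco - gpp_mg
  if (config$nee_rel_sd > 0) {
    nee <- nee * (1 + rnorm(length(nee), 0, config$nee_rel_sd))
  }
  if (config$nee_add_sd > 0) {
    nee <- nee + rnorm(length(nee), 0, config$nee_add_sd)
  }

  rh <- pmin(95, 60 + 25 * exp(-((doy - 210) / 40)^2) -
               8 * sin(2 * pi * (hour - 15) / 24))
  vpd <- pmax(0.05, 1.4 - 0.012 * rh + 0.4 * sin(2 * pi * (hour - 15) / 24))
  swc <- 25 + 4 * cos(2 * pi * (doy - 230) / 365)

  tibble::tibble(
    timestamp = timestamp, nee = nee, par = par, t_air = t_air,
    t_soil = t_soil, rh = rh, vpd = vpd, swc = swc,
    reco_true = reco, gpp_true = gpp_mg
  )
}

#' Simulate a complete synthetic season
#'
#' Runs [simulate_campaigns()] and [simulate_flux()] under the
#' configuration's master seed, so repeated calls with the same
#' configuration are bit-reproducible.
#'
#' @param config A [season_config()].
#' @return A list of class `season_sim` with elements `campaigns`,
#'   `samples`, `spectra`, `flux`, `truth` and `config`.
#' @export
simulate_season <- function(config = season_config()) {
  stopifnot(inherits(config, "season_config"))
  truth <- season_truth(config)
  withr::with_seed(config$seed, {
    camp <- simulate_campaigns(config, truth)
    flux <- simulate_flux(config, truth)
  })
  structure(
    list(campaigns = camp$campaigns, samples = camp$samples,
         spectra = camp$spectra, flux = flux, truth = truth, config = config),
    class = "season_sim"
  )
}

#' @export
print.season_sim <- function(x, ...) {
  cat(sprintf(
    "<season_sim> %s to %s: %d campaigns, %d spectra, %d half-hourly flux records\n",
    x$config$season_start, x$config$season_end,
    length(unique(x$campaigns$date)), length(x$spectra), nrow(x$flux)
  ))
  invisible(x)
}
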