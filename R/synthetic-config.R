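#' Configuration of a synthetic maize growing season
#'
#' Defines the study conditions the generator emulates: a single growing
#' season with nine biweekly measurement campaigns, a single-peak canopy
#' chlorophyll (CCC) and leaf area index (LAI) trajectory peaking between
#' late July and early August, five standard plants per campaign, and
#' half-hourly CO2 flux and micromet series driven by a Lloyd-Taylor
#' respiration and a chlorophyll-based light-use-efficiency GPP with a
#' planted coefficient `alpha`.
#'
#' The default noise levels describe a realistic field campaign: SPAD-502
#' repeatability of about 1 SPAD unit, field-spectrometer reflectance
#' noise of 0.002, 10 percent relative random error on half-hourly NEE,
#' and log-normal cloud modulation of PAR. Set the sds to zero (see
#' [zero_noise()]) for planted-truth recovery runs.
#'
#' @param season_start,season_end Season limits (`Date`).
#' @param n_campaigns Number of measurement campaigns (>= 2).
#' @param campaign_start,campaign_end First and last campaign dates.
#' @param n_plants Standard plants measured per campaign.
#' @param ccc_peak Peak canopy chlorophyll content, g m-2.
#' @param ccc_peak_doy Day of year of the CCC peak (inside the season).
#' @param ccc_rise,ccc_fall Rise and senescence widths of the CCC
#'   double-logistic, days.
#' @param lai_peak,lai_peak_doy,lai_rise,lai_fall LAI trajectory
#'   parameters (same meaning).
#' @param rref Planted respiration at 10 C, mg CO2 m-2 s-1.
#' @param e0 Planted Lloyd-Taylor temperature sensitivity, K.
#' @param alpha Planted light-use coefficient, umol CO2 per
#'   (umol photons m-2 s-1) per (g Chl m-2); must be > 0.
#' @param spad_sd Per-plant SPAD observation noise sd (SPAD units).
#' @param spectral_sd Additive reflectance noise sd (fraction).
#' @param nee_rel_sd Relative (multiplicative) NEE noise sd.
#' @param nee_add_sd Additive NEE noise sd, mg CO2 m-2 s-1.
#' @param cloud_sd Log-scale sd of the multiplicative PAR cloud factor.
#' @param wdrvi_weight WDRVI weight used by the pipeline.
#' @param seed Integer master seed.
#' @return An object of class `season_config`.
#' @export
season_config <- function(season_start = as.Date("2011-05-01"),
                          season_end = as.Date("2011-09-30"),
                          n_campaigns = 9,
                          campaign_start = as.Date("2011-05-25"),
                          campaign_end = as.Date("2011-09-20"),
                          n_plants = 5,
                          ccc_peak = 2.5, ccc_peak_doy = 210,
                          ccc_rise = 30, ccc_fall = 40,
                          lai_peak = 4.5, lai_peak_doy = 210,
                          lai_rise = 33, lai_fall = 55,
                          rref = 0.08, e0 = 14, alpha = 0.008,
                          spad_sd = 1, spectral_sd = 0.002,
                          nee_rel_sd = 0.10, nee_add_sd = 0.01,
                          cloud_sd = 0.15,
                          wdrvi_weight = 0.2,
                          seed = 42L) {
  season_start <- as.Date(season_start); season_end <- as.Date(season_end)
  campaign_start <- as.Date(campaign_start); campaign_end <- as.Date(campaign_end)
  if (season_end <= season_start) stop("season_end must follow season_start", call. = FALSE)
  if (campaign_start < season_start || campaign_end > season_end ||
      campaign_end <= campaign_start) {
    stop("campaign dates must lie inside the season", call. = FALSE)
  }
  if (n_campaigns < 2) stop("need at least 2 campaigns", call. = FALSE)
  if (n_plants < 1) stop("need at least 1 plant per campaign", call. = FALSE)
  doys <- as.POSIXlt(c(season_start, season_end))$yday + 1
  for (pd in c(ccc_peak_doy, lai_peak_doy)) {
    if (pd < doys[1] || pd > doys[2]) {
      stop("trajectory peak day must fall within the season", call. = FALSE)
    }
  }
  sds <- c(spad_sd = spad_sd, spectral_sd = spectral_sd,
           nee_rel_sd = nee_rel_sd, nee_add_sd = nee_add_sd,
           cloud_sd = cloud_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise sds must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (ccc_peak <= 0 || lai_peak <= 0 || ccc_rise <= 0 || ccc_fall <= 0 ||
      lai_rise <= 0 || lai_fall <= 0) {
    stop("trajectory peaks and widths must be > 0", call. = FALSE)
  }
  if (rref <= 0) stop("`rref` must be > 0", call. = FALSE)
  structure(
    list(
      season_start = season_start, season_end = season_end,
      n_campaigns = as.integer(n_campaigns),
      campaign_start = campaign_start, campaign_end = campaign_end,
      n_plants = as.integer(n_plants),
      ccc_peak = ccc_peak, ccc_peak_doy = ccc_peak_doy,
      ccc_rise = ccc_rise, ccc_fall = ccc_fall,
      lai_peak = lai_peak, lai_peak_doy = lai_peak_doy,
      lai_rise = lai_rise, lai_fall = lai_fall,
      rref = rref, e0 = e0, alpha = alpha,
      spad_sd = spad_sd, spectral_sd = spectral_sd,
      nee_rel_sd = nee_rel_sd, nee_add_sd = nee_add_sd, cloud_sd = cloud_sd,
      wdrvi_weight = wdrvi_weight,
      seed = as.integer(seed),
      planting = planted_relations()
    ),
    class = "season_config"
  )
}

#' @export
print.season_config <- function(x, ...) {
  cat(sprintf(
    paste0("<season_config> %s to %s, %d campaigns (%s to %s)\n",
           "  CCC peak %.2f g m-2 (DOY %d), LAI peak %.2f (DOY %d)\n",
           "  rref %.3f mg m-2 s-1, e0 %.1f K, alpha %.4f\n",
           "  noise: spad %.2f, spectral %.4f, nee rel %.2f / add %.3f, cloud %.2f; seed %d\n"),
    x$season_start, x$season_end, x$n_campaigns, x$campaign_start,
    x$campaign_end, x$ccc_peak, x$ccc_peak_doy, x$lai_peak, x$lai_peak_doy,
    x$rref, x$e0, x$alpha, x$spad_sd, x$spectral_sd, x$nee_rel_sd,
    x$nee_add_sd, x$cloud_sd, x$seed
  ))
  invisible(x)
}

#' Zero out every noise source of a season configuration
#'
#' @param config A [season_config()].
#' @return The configuration with all noise sds set to 0 (trajectories,
#'   planted parameters and dates unchanged).
#' @export
zero_noise <- function(config) {
  stopifnot(inherits(config, "season_config"))
  config$spad_sd <- 0
  config$spectral_sd <- 0
  config$nee_rel_sd <- 0
  config$nee_add_sd <- 0
  config$cloud_sd <- 0
  config
}

#' Index relations planted by the synthetic spectrum generator
#'
#' The generator shapes each spectrum so that three index-CCC relations
#' hold exactly at zero noise, giving every downstream estimator a
#' recoverable truth: the MODIS-broadband NDVI satisfies
#' `CCC = ndvi_a * exp(ndvi_b * NDVI)` (coefficients matching a published
#' maize calibration), and two single-wavelength EVI2 pairs satisfy
#' `CCC = slope * EVI2 + intercept`. Both planted pairs sit on the NIR
#' side of the spectrum, clear of the 680-750 nm red-edge window so the
#' planted REP map stays untouched.
#'
#' @return A list with elements `ndvi` (`a`, `b`), `pair1` and `pair2`
#'   (`bands`, `slope`, `intercept`).
#' @export
planted_relations <- function() {
  list(
    ndvi = list(a = 0.0067, b = 6.6986),
    pair1 = list(bands = c(1214, 1259), slope = 25, intercept = -0.5),
    pair2 = list(bands = c(820, 1248), slope = -20, intercept = 1.6)
  )
}

# unimodal double-logistic (rise times senescence), normalised to `peak`
# at its seasonal maximum over the integer days of the season
double_logistic <- function(doy, peak, peak_doy, rise, fall, doy_grid) {
  g <- function(t) {
    plogis((t - (peak_doy - rise)) / (rise / 3)) *
      plogis(-(t - (peak_doy + fall)) / (fall / 3))
  }
  peak * g(doy) / max(g(doy_grid))
}

#' Daily planted truth for a synthetic season
#'
#' Evaluates the CCC and LAI double-logistic trajectories for every day of
#' the season, together with the planted broadband NDVI (from the exact
#' NDVI-CCC relation of [planted_relations()]) and the green-canopy fAPAR
#' derived from it (`1.235 * NDVI - 0.211`, clamped to \[0, 1\]).
#'
#' @param config A [season_config()].
#' @return A list (the truth bundle) with elements `daily` (tibble:
#'   `date`, `doy`, `ccc`, `lai`, `ndvi`, `fapar`), `rref`, `e0`, `alpha`
#'   and `planting`.
#' @export
season_truth <- function(config) {
  stopifnot(inherits(config, "season_config"))
  dates <- seq(config$season_start, config$season_end, by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  ccc <- double_logistic(doy, config$ccc_peak, config$ccc_peak_doy,
                         config$ccc_rise, config$ccc_fall, doy)
  lai <- double_logistic(doy, config$lai_peak, config$lai_peak_doy,
                         config$lai_rise, config$lai_fall, doy)
  ndvi <- planted_ndvi(ccc, config$planting)
  fapar <- fapar_green(ndvi)
  list(
    daily = tibble::tibble(date = dates, doy = doy, ccc = ccc, lai = lai,
                           ndvi = ndvi, fapar = fapar),
    rref = config$rref, e0 = config$e0, alpha = config$alpha,
    planting = config$planting
  )
}

# the NDVI value the generator plants for a given CCC (clamped so the
# spectrum stays physical at near-zero chlorophyll)
planted_ndvi <- function(ccc, planting = planted_relations()) {
  nd <- log(pmax(ccc, 1e-12) / planting$ndvi$a) / planting$ndvi$b
  pmin(pmax(nd, 0.02), 0.95)
}
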