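# grams CO2 per mmol; converts mg CO2 m-2 s-1 <-> umol CO2 m-2 s-1
MG_PER_UMOL_CO2 <- 0.04401

#' Net ecosystem exchange as an eddy covariance
#'
#' NEE is the mean covariance between fluctuations in vertical wind speed
#' and CO2 density: the mean of their elementwise products (the series are
#' already fluctuations about zero, so no re-centring is applied).
#' Provided for completeness; the pipeline's primary input is half-hourly
#' NEE.
#'
#' @param w_prime Vertical wind speed fluctuations, m s-1.
#' @param c_prime CO2 density fluctuations, mg m-3.
#' @return NEE in mg CO2 m-2 s-1, positive when CO2 is emitted.
#' @export
covariance_nee <- function(w_prime, c_prime) {
  if (length(w_prime) != length(c_prime)) {
    stop("`w_prime` and `c_prime` must have the same length", call. = FALSE)
  }
  if (length(w_prime) < 2) stop("need at least two paired samples", call. = FALSE)
  mean(w_prime * c_prime)
}

#' Lloyd-Taylor ecosystem respiration
#'
#' `Reco = rref * exp(e0 * (1 / (t_ref - t0) - 1 / (t - t0)))` with all
#' temperatures in Kelvin, `t0 = 273.15` K and reference temperature
#' 10 degrees C (`t_ref = 283.15` K), so `t - t0` reproduces the Celsius
#' soil temperature. In this parameterisation `e0` carries units of K and
#' a value near 14 corresponds to a Q10 of about 2 between 10 and 20
#' degrees C. Temperatures at or below freezing (`t <= t0`) are outside
#' the model's domain and return `NA`.
#'
#' @param t_k Soil temperature(s) in Kelvin.
#' @param rref Respiration at 10 degrees C, mg CO2 m-2 s-1.
#' @param e0 Temperature sensitivity (K).
#' @param t_ref,t0 Reference and base temperatures in Kelvin.
#' @return Respiration in mg CO2 m-2 s-1; `NA` where `t_k <= t0`.
#' @export
#' @examples
#' lloyd_taylor(283.15, rref = 2, e0 = 14)  # equals rref at 10 C
lloyd_taylor <- function(t_k, rref, e0, t_ref = 283.15, t0 = 273.15) {
  out <- rref * exp(e0 * (1 / (t_ref - t0) - 1 / (t_k - t0)))
  out[t_k <= t0] <- NA_real_
  out
}

# nighttime definition: PAR below threshold (generated data use PAR = 0 at night)
is_night <- function(par, night_par = 10) {
  par < night_par
}

#' Windowed Lloyd-Taylor respiration parameterisation
#'
#' For every calendar day, fits `rref` and `e0` by nonlinear least squares
#' of the Lloyd-Taylor model against nighttime NEE (at night GPP = 0, so
#' NEE equals respiration) within a centred window (91 days by default,
#' truncated at the season edges). Days whose window holds fewer than
#' `min_night_points` nighttime records inherit the nearest valid day's
#' parameters and are flagged `carried`.
#'
#' @param flux Tibble with columns `timestamp` (POSIXct), `nee`
#'   (mg CO2 m-2 s-1), `par` (umol m-2 s-1) and `t_soil` (K).
#' @param window_days Width of the centred window in days.
#' @param min_night_points Minimum nighttime records for a fit.
#' @param night_par PAR threshold (umol m-2 s-1) defining night.
#' @param init_e0 Deterministic starting value for `e0`.
#' @return Tibble with one row per day: `date`, `rref`, `e0`, `n_night`,
#'   `rmse`, `carried`, `source_date`.
#' @export
fit_respiration <- function(flux, window_days = 91, min_night_points = 20,
                            night_par = 10, init_e0 = 14) {
  req <- c("timestamp", "nee", "par", "t_soil")
  if (!all(req %in% names(flux))) {
    stop("`flux` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  date <- as.Date(flux$timestamp, tz = "UTC")
  days <- sort(unique(date))
  keep <- is_night(flux$par, night_par) & is.finite(flux$nee) &
    is.finite(flux$t_soil) & flux$t_soil > 273.15
  night <- data.frame(date = date[keep], nee = flux$nee[keep],
                      t_soil = flux$t_soil[keep])
  half <- (window_days - 1) / 2

  fits <- vector("list", length(days))
  start <- NULL
  for (i in seq_along(days)) {
    d <- days[i]
    w <- night[night$date >= d - half & night$date <= d + half, ]
    if (nrow(w) < min_night_points) {
      fits[[i]] <- list(rref = NA_real_, e0 = NA_real_, n_night = nrow(w),
                        rmse = NA_real_)
      next
    }
    if (is.null(start)) {
      start <- list(rref = max(mean(w$nee), 1e-3), e0 = init_e0)
    }
    fit <- try(minpack.lm::nlsLM(
      nee ~ rref * exp(e0 * (1 / 10 - 1 / (t_soil - 273.15))),
      data = w, start = start,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-15, ptol = 1e-15
      )
    ), silent = TRUE)
    if (inherits(fit, "try-error")) {
      fits[[i]] <- list(rref = NA_real_, e0 = NA_real_, n_night = nrow(w),
                        rmse = NA_real_)
      start <- NULL
      next
    }
    cf <- coef(fit)
    fits[[i]] <- list(rref = unname(cf["rref"]), e0 = unname(cf["e0"]),
                      n_night = nrow(w),
                      rmse = sqrt(mean(residuals(fit)^2)))
    start <- as.list(cf)  # warm start for the next (heavily overlapping) window
  }

  out <- tibble::tibble(
    date = days,
    rref = vapply(fits, `[[`, numeric(1), "rref"),
    e0 = vapply(fits, `[[`, numeric(1), "e0"),
    n_night = vapply(fits, `[[`, numeric(1), "n_night"),
    rmse = vapply(fits, `[[`, numeric(1), "rmse"),
    carried = FALSE,
    source_date = days
  )
  valid <- which(is.finite(out$rref))
  if (length(valid) == 0) {
    stop("no day has enough valid nighttime records to fit respiration",
         call. = FALSE)
  }
  invalid <- which(!is.finite(out$rref))
  for (i in invalid) {
    j <- valid[which.min(abs(valid - i))]  # nearest valid day; earlier on ties
    out$rref[i] <- out$rref[j]
    out$e0[i] <- out$e0[j]
    out$rmse[i] <- out$rmse[j]
    out$carried[i] <- TRUE
    out$source_date[i] <- out$date[j]
  }
  out
}

#' Partition NEE into GPP and ecosystem respiration
#'
#' Per record: `Reco` from the Lloyd-Taylor model with that day's fitted
#' parameters; in the daytime `GPP = -NEE + Reco`; at night GPP is 0 and
#' `Reco` stays the modelled value. NEE is positive when CO2 is emitted;
#' GPP and Reco are positive fluxes.
#'
#' @param flux Tibble as in [fit_respiration()].
#' @param fits Respiration parameter table from [fit_respiration()].
#' @param night_par PAR threshold (umol m-2 s-1) defining night.
#' @return `flux` with added columns `night`, `reco`, `gpp`
#'   (mg CO2 m-2 s-1).
#' @export
partition_flux <- function(flux, fits, night_par = 10) {
  date <- as.Date(flux$timestamp, tz = "UTC")
  idx <- match(date, fits$date)
  if (anyNA(idx)) {
    stop(sprintf("no respiration fit for day(s): %s",
                 paste(unique(date[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  out <- flux
  out$night <- is_night(flux$par, night_par)
  out$reco <- lloyd_taylor(flux$t_soil, fits$rref[idx], fits$e0[idx])
  out$gpp <- ifelse(out$night, 0, -flux$nee + out$reco)
  out
}

#' Midday GPP aggregation
#'
#' Daily mean of half-hourly GPP for records between 11:00 (inclusive) and
#' 14:00 (exclusive) local time, the window matched to the spectral
#' campaigns, with conversion from mg CO2 m-2 s-1 to umol CO2 m-2 s-1
#' (divide by 0.04401 mg per umol).
#'
#' @param flux Partitioned flux tibble (from [partition_flux()]).
#' @param dates Optional `Date` vector; errors if a requested date has no
#'   records in the window. Default: all days present.
#' @return Tibble with `date`, `gpp_mg` (mg CO2 m-2 s-1), `gpp_umol`
#'   (umol CO2 m-2 s-1), `par` (mean PAR over the window), `n`.
#' @export
midday_gpp <- function(flux, dates = NULL) {
  if (!("gpp" %in% names(flux))) {
    stop("`flux` has no `gpp` column; run partition_flux() first", call. = FALSE)
  }
  hr <- as.numeric(format(flux$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(flux$timestamp, "%M", tz = "UTC")) / 60
  mid <- flux[hr >= 11 & hr < 14, ]
  mid$date <- as.Date(mid$timestamp, tz = "UTC")
  out <- mid |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      gpp_mg = mean(.data$gpp),
      par = mean(.data$par),
      n = dplyr::n(),
      .groups = "drop"
    )
  out$gpp_umol <- out$gpp_mg / MG_PER_UMOL_CO2
  out <- out[, c("date", "gpp_mg", "gpp_umol", "par", "n")]
  if (!is.null(dates)) {
    idx <- match(as.Date(dates), out$date)
    if (anyNA(idx)) {
      stop(sprintf("no midday records on: %s",
                   paste(as.Date(dates)[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    out <- out[idx, ]
  }
  out
}
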