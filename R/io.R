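#' Read and write long-format spectra CSV
#'
#' The interchange format for field-spectrometer exports: one row per
#' (sample, wavelength) with columns `sample_id`, `date`,
#' `wavelength_nm`, `reflectance`.
#'
#' @param path CSV file path.
#' @return `read_spectra_csv()`: a list of `refl_spectrum` objects.
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("sample_id", "date", "wavelength_nm", "reflectance")
  if (!all(req %in% names(df))) {
    stop("spectra CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  spectra_from_long(df)
}

#' @rdname read_spectra_csv
#' @param spectra List of `refl_spectrum` objects.
#' @export
write_spectra_csv <- function(spectra, path) {
  readr::write_csv(spectra_to_long(spectra), path)
  invisible(path)
}

#' Convert between spectrum lists and the long table format
#'
#' @param spectra List of `refl_spectrum` objects.
#' @return A tibble with columns `sample_id`, `date`, `wavelength_nm`,
#'   `reflectance`.
#' @export
spectra_to_long <- function(spectra) {
  dplyr::bind_rows(lapply(spectra, function(sp) {
    tibble::tibble(sample_id = sp$sample_id, date = sp$date,
                   wavelength_nm = sp$wavelength, reflectance = sp$reflectance)
  }))
}

#' @rdname spectra_to_long
#' @param long Long-format tibble (see [spectra_to_long()]).
#' @export
spectra_from_long <- function(long) {
  ids <- unique(long$sample_id)
  lapply(ids, function(id) {
    sub <- long[long$sample_id == id, ]
    sub <- sub[order(sub$wavelength_nm), ]
    reflectance_spectrum(sub$wavelength_nm, sub$reflectance, sample_id = id,
                         date = sub$date[1])
  })
}

#' Read a per-plant campaign CSV
#'
#' Columns: `date`, `plant_id`, `spad`, `lai`.
#'
#' @param path CSV file path.
#' @return Tibble ready for [campaign_ccc()].
#' @export
read_campaign_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("date", "plant_id", "spad", "lai")
  if (!all(req %in% names(df))) {
    stop("campaign CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df$date <- as.Date(df$date)
  df
}

#' Read a half-hourly flux CSV
#'
#' Columns: `timestamp`, `nee` (mg CO2 m-2 s-1, positive = emission),
#' `par` (umol m-2 s-1), `t_air`, `t_soil` (Kelvin), `rh`, `vpd`, `swc`.
#'
#' @param path CSV file path.
#' @return Tibble ready for [fit_respiration()].
#' @export
read_flux_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("timestamp", "nee", "par", "t_soil")
  if (!all(req %in% names(df))) {
    stop("flux CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df
}

#' Write a simulated season to disk
#'
#' Emits the three tabular inputs the pipeline consumes (long-format
#' spectra CSV, per-plant campaign CSV, half-hourly flux CSV) plus a JSON
#' truth file with the planted parameters and daily trajectories.
#'
#' @param sim A `season_sim` from [simulate_season()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "season_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra_csv(sim$spectra, file.path(dir, "spectra.csv"))
  readr::write_csv(sim$campaigns, file.path(dir, "campaigns.csv"))
  flux_cols <- c("timestamp", "nee", "par", "t_air", "t_soil", "rh", "vpd", "swc")
  readr::write_csv(sim$flux[, flux_cols], file.path(dir, "flux.csv"))
  truth <- list(
    rref = sim$truth$rref, e0 = sim$truth$e0, alpha = sim$truth$alpha,
    planting = sim$truth$planting,
    daily = sim$truth$daily
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
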