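#' Aggregate per-plant SPAD readings
#'
#' Field protocol: SPAD is read on the same standard plants (five by
#' default) on each campaign date and the campaign value is their
#' arithmetic mean.
#'
#' @param readings Numeric vector of SPAD readings, all `>= 0`.
#' @return Mean SPAD value.
#' @export
aggregate_spad <- function(readings) {
  if (length(readings) < 1) stop("need at least one SPAD reading", call. = FALSE)
  if (any(!is.finite(readings)) || any(readings < 0)) {
    stop("SPAD readings must be finite and >= 0", call. = FALSE)
  }
  mean(readings)
}

#' Convert a SPAD reading to leaf chlorophyll content
#'
#' SPAD-502 calibration `Chl = 10^(M^0.265)` in micromol per square metre.
#' The alternative product reading `10^(0.265 * M)` of the same printed
#' calibration is available via `form = "product"` for fidelity
#' experiments; it yields physically implausible values (about 1e10 at
#' M = 40) and is not used by the pipeline.
#'
#' @param m SPAD reading(s), `>= 0`.
#' @param form `"power"` (default) or `"product"`.
#' @return Chlorophyll content in micromol per square metre.
#' @export
#' @examples
#' spad_to_chl(40)
spad_to_chl <- function(m, form = c("power", "product")) {
  form <- match.arg(form)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("SPAD values must be finite and >= 0", call. = FALSE)
  }
  switch(form,
    power = 10^(m^0.265),
    product = 10^(0.265 * m)
  )
}

#' Convert chlorophyll content to leaf chlorophyll mass
#'
#' `LCC = Chl * 897.01 * 1e-3`, converting micromol per square metre to
#' milligram per square metre with the 897.01 g/mol chlorophyll molar mass.
#'
#' @param chl Chlorophyll content(s) in micromol per square metre, `>= 0`.
#' @return Leaf chlorophyll content in mg per square metre.
#' @export
chl_to_lcc <- function(chl) {
  if (any(!is.finite(chl)) || any(chl < 0)) {
    stop("chlorophyll content must be finite and >= 0", call. = FALSE)
  }
  chl * 897.01 * 1e-3
}

#' Canopy chlorophyll content from LAI and leaf chlorophyll
#'
#' `CCC = LAI * LCC * 1e-3` in gram chlorophyll per square metre of
#' ground area.
#'
#' @param lai Leaf area index(es), `>= 0` (square metre per square metre).
#' @param lcc Leaf chlorophyll content(s) in mg per square metre, `>= 0`.
#' @return Canopy chlorophyll content in g per square metre.
#' @export
canopy_ccc <- function(lai, lcc) {
  if (any(!is.finite(lai)) || any(lai < 0)) {
    stop("`lai` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(lcc)) || any(lcc < 0)) {
    stop("`lcc` must be finite and >= 0", call. = FALSE)
  }
  lai * lcc * 1e-3
}

# invert the SPAD -> CCC chain; used by the synthetic generator to plant
# per-plant SPAD readings whose zero-noise mean reproduces the truth CCC
ccc_to_spad <- function(ccc, lai) {
  lcc <- 1000 * ccc / lai                 # mg m-2
  chl <- lcc / (897.01 * 1e-3)            # umol m-2
  if (any(chl <= 1)) {
    stop("CCC/LAI combination below the invertible range of the SPAD calibration",
         call. = FALSE)
  }
  (log10(chl))^(1 / 0.265)
}

#' Campaign-level canopy chlorophyll table
#'
#' Aggregates per-plant SPAD readings by date and runs the full
#' SPAD -> Chl -> LCC -> CCC chain.
#'
#' @param campaigns Tibble with columns `date`, `plant_id`, `spad`, `lai`
#'   (LAI constant within a date).
#' @return Tibble with one row per date: `date`, `spad`, `lai`, `chl`
#'   (micromol m-2), `lcc` (mg m-2), `ccc` (g m-2).
#' @export
campaign_ccc <- function(campaigns) {
  req <- c("date", "plant_id", "spad", "lai")
  if (!all(req %in% names(campaigns))) {
    stop("`campaigns` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  out <- campaigns |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      spad = aggregate_spad(.data$spad),
      lai = .data$lai[1],
      .groups = "drop"
    )
  out$chl <- spad_to_chl(out$spad)
  out$lcc <- chl_to_lcc(out$chl)
  out$ccc <- canopy_ccc(out$lai, out$lcc)
  out
}
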