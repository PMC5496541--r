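test_that("season configuration validates its invariants", {
  expect_s3_class(season_config(), "season_config")
  expect_error(season_config(n_campaigns = 1), "at least 2")
  expect_error(season_config(spad_sd = -0.1), ">= 0")
  expect_error(season_config(alpha = 0), "> 0")
  expect_error(season_config(ccc_peak_doy = 400), "within the season")
  expect_error(season_config(campaign_end = as.Date("2011-12-01")),
               "inside the season")
})

test_that("generated spectra are physical and deterministic at zero noise", {
  sp1 <- generate_spectrum(1.5, 3)
  sp2 <- generate_spectrum(1.5, 3)
  expect_identical(sp1$reflectance, sp2$reflectance)
  expect_true(all(sp1$reflectance >= 0 & sp1$reflectance <= 1))
  expect_true(all(sp1$wavelength == 400:1350))
  # seeded noise is reproducible; different seeds differ
  n1 <- generate_spectrum(1.5, 3, noise_sd = 0.003, seed = 5)
  n2 <- generate_spectrum(1.5, 3, noise_sd = 0.003, seed = 5)
  n3 <- generate_spectrum(1.5, 3, noise_sd = 0.003, seed = 6)
  expect_identical(n1$reflectance, n2$reflectance)
  expect_false(identical(n1$reflectance, n3$reflectance))
  expect_error(generate_spectrum(-1, 3), ">= 0")
})

test_that("bare soil is monotone and featureless with undefined red edge", {
  soil <- generate_spectrum(0, 0)
  expect_true(all(diff(soil$reflectance) >= 0))
  expect_true(is.na(compute_rep(soil)))
})

test_that("red edge position is non-decreasing in canopy chlorophyll", {
  ccc_grid <- seq(0.5, 2.5, by = 0.25)
  reps <- vapply(ccc_grid, function(cc) compute_rep(generate_spectrum(cc, 3)),
                 numeric(1))
  expect_false(anyNA(reps))
  expect_true(all(reps >= 680 & reps <= 750))
  expect_false(is.unsorted(reps))
  expect_gt(reps[length(reps)], reps[1])
})

test_that("red trough deepens with chlorophyll and NIR rises with LAI", {
  red <- vapply(c(0.5, 1, 1.5, 2, 2.5),
                function(cc) band_average(generate_spectrum(cc, 3), 620, 670),
                numeric(1))
  expect_true(all(diff(red) < 0))
  nir <- vapply(c(0.5, 1.5, 2.5, 3.5, 4.5),
                function(l) band_average(generate_spectrum(1.5, l), 760, 1100),
                numeric(1))
  expect_true(all(diff(nir) > 0))
  # water-absorption dips: local minima near 970 and 1200 nm
  sp <- generate_spectrum(1.5, 3)
  expect_lt(refl_at_970 <- band_average(sp, 965, 975), band_average(sp, 900, 910))
  expect_lt(band_average(sp, 1195, 1205), band_average(sp, 1120, 1130))
})

test_that("planted index relations hold exactly at zero noise", {
  pl <- planted_relations()
  for (cc in c(0.1, 0.8, 2.2)) {
    sp <- generate_spectrum(cc, 2.5)
    ndvi <- compute_index(sp, "NDVI")
    expect_equal(pl$ndvi$a * exp(pl$ndvi$b * ndvi), cc, tolerance = 1e-10)
    for (pr in list(pl$pair1, pl$pair2)) {
      e <- two_band_index(refl_at(sp, pr$bands[1]), refl_at(sp, pr$bands[2]),
                          "evi2")
      expect_equal(pr$slope * e + pr$intercept, cc, tolerance = 1e-10)
    }
  }
})

test_that("the planted CCC trajectory has exactly one local maximum", {
  truth <- season_truth(season_config())
  ccc <- truth$daily$ccc
  sign_changes <- sum(diff(sign(diff(ccc))) != 0)
  expect_equal(sign_changes, 1)
  expect_true(all(is.finite(ccc)) && all(is.finite(truth$daily$lai)))
  expect_true(all(truth$daily$fapar >= 0 & truth$daily$fapar <= 1))
})

test_that("campaigns: one sample and spectrum per date, seed isolates noise", {
  cfg <- season_config(seed = 1)
  sim1 <- simulate_season(cfg)
  expect_equal(nrow(sim1$samples), 9)
  expect_length(sim1$spectra, 9)
  expect_equal(nrow(sim1$campaigns), 9 * 5)

  sim1b <- simulate_season(cfg)
  expect_identical(sim1b$campaigns$spad, sim1$campaigns$spad)  # reproducible

  sim2 <- simulate_season(season_config(seed = 2))
  expect_identical(sim1$campaigns$date, sim2$campaigns$date)
  expect_identical(sim1$samples$lai, sim2$samples$lai)
  expect_false(identical(sim1$campaigns$spad, sim2$campaigns$spad))
})

test_that("night flux equals Lloyd-Taylor respiration at zero noise", {
  sim <- simulate_season(zero_noise(season_config()))
  night <- sim$flux[sim$flux$par == 0, ]
  expect_equal(night$nee,
               lloyd_taylor(night$t_soil, sim$truth$rref, sim$truth$e0))
  expect_true(all(sim$flux$par >= 0))
})

test_that("a zero light-use coefficient degenerates NEE to pure respiration", {
  cfg <- zero_noise(season_config())
  cfg$alpha <- 1e-12  # alpha must be > 0; use a numerically negligible value
  truth <- season_truth(cfg)
  truth$alpha <- 0
  flux <- simulate_flux(cfg, truth)
  expect_equal(flux$gpp_true, rep(0, nrow(flux)))
  expect_equal(flux$nee, flux$reco_true)
})

test_that("partitioning a noise-free season recovers the planted GPP", {
  sim <- simulate_season(zero_noise(season_config()))
  fits <- fit_respiration(sim$flux)
  part <- partition_flux(sim$flux, fits)
  day <- !part$night
  expect_lt(max(abs(part$gpp[day] - sim$flux$gpp_true[day])), 1e-6)
})

test_that("planted pair labels follow the declared exponential relation", {
  spectra <- lapply(seq(0.3, 2.4, length.out = 6),
                    function(cc) generate_spectrum(cc, 3, planting = NULL))
  labels <- plant_ccc_from_pair(spectra, pair = c(1215, 1260), a = 0.5, b = 3,
                                label_sd = 0)
  e <- vapply(spectra, function(sp) {
    two_band_index(refl_at(sp, 1215), refl_at(sp, 1260), "evi2")
  }, numeric(1))
  expect_equal(labels, 0.5 * exp(3 * e))
  expect_error(plant_ccc_from_pair(spectra, pair = c(300, 900)), "400-1300")
})
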