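test_that("resampling preserves 1-nm input and interpolates linearly", {
  sp <- reflectance_spectrum(400:500, seq(0.1, 0.3, length.out = 101))
  expect_identical(resample_to_1nm(sp)$reflectance, sp$reflectance)

  two <- reflectance_spectrum(c(400, 402), c(0.1, 0.3))
  expect_equal(refl_at <- resample_to_1nm(two)$reflectance[2], 0.2)

  # jittered grid against an independent piecewise-linear oracle
  set.seed(11)
  w <- sort(400 + cumsum(runif(60, 0.3, 2.5)))
  r <- runif(60, 0.05, 0.6)
  rs <- resample_to_1nm(reflectance_spectrum(w, r))
  manual <- sapply(rs$wavelength, function(g) {
    i <- max(which(w <= g))
    if (w[i] == g) r[i] else r[i] + (r[i + 1] - r[i]) * (g - w[i]) / (w[i + 1] - w[i])
  })
  expect_equal(rs$reflectance, manual, tolerance = 1e-12)
})

test_that("spectrum construction rejects malformed input", {
  expect_error(reflectance_spectrum(c(400, 400, 401), c(0.1, 0.2, 0.3)),
               "strictly increasing")
  expect_error(reflectance_spectrum(400:402, c(0.1, 1.5, 0.2)), "\\[0, 1\\]")
  expect_error(reflectance_spectrum(400:402, c(0.1, 0.2)), "same length")
})

test_that("band averages follow the inclusive integer-band convention", {
  flat <- reflectance_spectrum(400:900, rep(0.3, 501))
  expect_equal(band_average(flat, 620, 670), 0.3)
  ramp <- reflectance_spectrum(400:900, seq(0, 0.5, length.out = 501))
  expect_equal(band_average(ramp, 750, 750), ramp$reflectance[351])
  # linear ramp: mean equals the midpoint of the endpoints
  expect_equal(band_average(ramp, 620, 670),
               (oracle_at(ramp$wavelength, ramp$reflectance, 620) +
                  oracle_at(ramp$wavelength, ramp$reflectance, 670)) / 2)
  expect_error(band_average(flat, 300, 500), "outside")
  expect_error(band_average(flat, 700, 650), "lo")
})

test_that("central-difference derivative matches analytic slopes", {
  flat <- reflectance_spectrum(400:900, rep(0.3, 501))
  expect_equal(derivative_at(flat, 600), 0)
  ramp <- reflectance_spectrum(400:900, 0.001 * (0:500))
  expect_equal(derivative_at(ramp, 600), 0.001)
  # quadratic: central difference is exact for polynomials of degree <= 2
  quad <- reflectance_spectrum(400:900, 1e-6 * ((400:900) - 400)^2)
  expect_equal(derivative_at(quad, 600), 2e-6 * 200, tolerance = 1e-12)
  expect_error(derivative_at(ramp, 400), "cover")
})

test_that("red edge position finds the logistic inflection and honours ties", {
  wl <- 400:900
  logi <- reflectance_spectrum(wl, 0.05 + 0.4 * plogis((wl - 720) / 6))
  expect_equal(compute_rep(logi), 720)

  lin <- reflectance_spectrum(wl, 0.001 * (wl - 400))  # constant slope: tie
  expect_equal(compute_rep(lin), 680)

  flat <- reflectance_spectrum(wl, rep(0.2, length(wl)))
  expect_true(is.na(compute_rep(flat)))

  short <- reflectance_spectrum(700:900, rep(0.2, 201))
  expect_error(compute_rep(short), "679-751")
})

test_that("two-band index forms match hand arithmetic and reduce correctly", {
  expect_equal(two_band_index(0.5, 0.5, "ndvi"), 0)
  expect_equal(two_band_index(0.5, 0.5, "evi2"), 0)
  expect_equal(two_band_index(0.5, 0.1, "ndvi"), 0.4 / 0.6)
  expect_equal(two_band_index(0.1, 0.5, "ndvi"), -0.4 / 0.6)
  # WDRVI numerator cancellation at weight * rho1 == rho2
  expect_equal(two_band_index(0.5, 0.1, "wdrvi", weight = 0.2), 0)
  expect_true(is.na(two_band_index(0, 0, "ndvi")))
  expect_true(is.na(two_band_index(0.3, 0, "rvi")))
  expect_error(two_band_index(1.2, 0.1, "ndvi"), "\\[0, 1\\]")
})

test_that("two-band antisymmetry and reduction identities hold on random pairs", {
  set.seed(7)
  r1 <- runif(1000); r2 <- runif(1000)
  expect_equal(two_band_index(r1, r2, "ndvi"), -two_band_index(r2, r1, "ndvi"))
  expect_equal(two_band_index(r1, r2, "rvi"), 1 / two_band_index(r2, r1, "rvi"))
  expect_equal(two_band_index(r1, r2, "wdrvi", weight = 1),
               two_band_index(r1, r2, "ndvi"))
  w <- 0.2  # band swap with reciprocal weight flips the sign
  expect_equal(two_band_index(r1, r2, "wdrvi", weight = w),
               -two_band_index(r2, r1, "wdrvi", weight = 1 / w))
  expect_true(all(abs(two_band_index(r1, r2, "ndvi")) <= 1))
  expect_true(all(abs(two_band_index(r1, r2, "wdrvi")) <= 1))
})

test_that("index registry collapses correctly on a constant spectrum", {
  flat <- reflectance_spectrum(400:1400, rep(0.25, 1001))
  expect_equal(compute_index(flat, "NDVI"), 0)
  expect_equal(compute_index(flat, "RVI"), 1)
  expect_equal(compute_index(flat, "RedEdgeNDVI"), 0)
  expect_true(is.na(compute_index(flat, "MTCI")))  # zero denominator
  expect_true(is.na(compute_index(flat, "CCI")))   # 0 / 0
  expect_error(compute_index(flat, "NOPE"), "unknown index")
})

test_that("MTCI follows its three-band formula directly", {
  wl <- 400:900
  r <- rep(0.1, length(wl))
  r[wl == 753] <- 0.5; r[wl == 708] <- 0.3; r[wl == 681] <- 0.2
  sp <- reflectance_spectrum(wl, r)
  expect_equal(compute_index(sp, "MTCI"), 2.0)
})

test_that("all indices and REP match the formula-by-formula oracle", {
  set.seed(101)
  for (i in 1:30) {
    sp <- random_spectrum()
    for (nm in list_indices()) {
      expect_equal(compute_index(sp, nm), oracle_index(sp, nm),
                   tolerance = 1e-10, label = nm)
    }
    expect_identical(compute_rep(sp), oracle_rep(sp))
  }
})

test_that("indices are invariant to resampling an already 1-nm spectrum", {
  set.seed(5)
  sp <- random_spectrum()
  rs <- resample_to_1nm(sp)
  for (nm in list_indices()) {
    expect_identical(compute_index(sp, nm), compute_index(rs, nm))
  }
})

test_that("index table collects one row per spectrum", {
  set.seed(3)
  spl <- replicate(4, random_spectrum(), simplify = FALSE)
  tab <- compute_index_table(spl, indices = c("NDVI", "MTCI"))
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("sample_id", "date", "NDVI", "MTCI", "REP"))
})
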