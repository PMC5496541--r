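test_that("linear fits match exact lines and the normal-equations oracle", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$a, 2); expect_equal(f$b, 1); expect_equal(f$r2, 1)

  fc <- fit_linear(x, rep(3, 10))
  expect_true(is.na(fc$r2))

  fx <- fit_linear(rep(2, 10), rnorm(10))
  expect_true(is.na(fx$r2))

  set.seed(21)
  x <- rnorm(50); y <- 1.3 * x + rnorm(50)
  f <- fit_linear(x, y)
  o <- oracle_ols(x, y)
  expect_equal(f$a, o$slope, tolerance = 1e-10)
  expect_equal(f$b, o$intercept, tolerance = 1e-10)
  expect_equal(f$r2, o$r2, tolerance = 1e-10)
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("exponential fits log-linearise and guard their domain", {
  x <- seq(0, 2, length.out = 8)
  f <- fit_exponential(x, 3 * exp(2 * x))
  expect_equal(f$a, 3, tolerance = 1e-10)
  expect_equal(f$b, 2, tolerance = 1e-10)
  expect_equal(f$r2, 1)

  expect_error(fit_exponential(x, c(3, 0, rep(1, 6))), "offending sample")

  set.seed(22)
  y <- exp(1.5 * x + rnorm(8, 0, 0.1))
  f <- fit_exponential(x, y)
  o <- oracle_ols(x, log(y))
  expect_equal(f$b, o$slope, tolerance = 1e-10)
  expect_equal(f$a, exp(o$intercept), tolerance = 1e-10)
  expect_equal(predict(f, 0.5), f$a * exp(f$b * 0.5))
})

toy_setup <- function(n = 7) {
  ccc <- seq(0.3, 2.4, length.out = n)
  spectra <- lapply(seq_len(n), function(i) generate_spectrum(ccc[i], 3,
                                                              planting = NULL))
  list(spectra = spectra, ccc = ccc)
}

test_that("search matrices equal a brute-force double-loop oracle", {
  toy <- toy_setup()
  wl <- seq(700, 740, by = 10)  # 5-wavelength toy grid
  maps <- band_search(toy$spectra, toy$ccc, lo = 700, hi = 740, step = 10)
  refm <- vapply(toy$spectra, function(sp) refl_at(sp, wl),
                 numeric(length(wl)))
  for (form in c("ndvi", "rvi", "wdrvi", "evi2")) {
    for (reg in c("linear", "exponential")) {
      got <- maps[[paste(form, reg, sep = "_")]]$r2
      want <- matrix(NA_real_, 5, 5)
      for (i in 1:5) for (j in 1:5) {
        if (i == j) next
        x <- two_band_index(refm[i, ], refm[j, ], form)
        if (anyNA(x)) next
        fit <- if (reg == "linear") fit_linear(x, toy$ccc) else
          fit_exponential(x, toy$ccc)
        want[i, j] <- fit$r2
      }
      expect_equal(got, want, tolerance = 1e-12,
                   label = paste(form, reg))
      expect_true(all(is.na(diag(got))))
      expect_true(all(got[!is.na(got)] >= 0 & got[!is.na(got)] <= 1))
    }
  }
})

test_that("swap symmetry: exact for NDVI, for WDRVI only at weight 1", {
  toy <- toy_setup()
  maps <- band_search(toy$spectra, toy$ccc, lo = 650, hi = 850, step = 25,
                      forms = c("ndvi", "wdrvi"))
  for (nm in c("ndvi_linear", "ndvi_exponential")) {
    m <- maps[[nm]]$r2
    expect_identical(m, t(m), label = nm)
  }
  # weight 0.2: swap is not a sign flip, so the map is genuinely asymmetric
  expect_false(isTRUE(all.equal(maps$wdrvi_linear$r2, t(maps$wdrvi_linear$r2))))
  maps1 <- band_search(toy$spectra, toy$ccc, lo = 650, hi = 850, step = 25,
                       forms = "wdrvi", wdrvi_weight = 1)
  m1 <- maps1$wdrvi_linear$r2
  expect_identical(m1, t(m1))
})

test_that("search validates its inputs", {
  toy <- toy_setup(3)
  expect_error(band_search(toy$spectra, toy$ccc[1:2]), "one CCC value")
  expect_error(band_search(toy$spectra[1:2], toy$ccc[1:2]), "at least 3")
  expect_error(band_search(toy$spectra, c(-1, 1, 2), lo = 700, hi = 710),
               "ccc > 0")
})

test_that("best_pairs ranks by R2 with deterministic tie order", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- 0.5
  map1 <- structure(list(wavelength = c(500, 510, 520), r2 = m,
                         form = "evi2", regression = "linear", n = 5),
                    class = "r2_map")
  bp <- best_pairs(map1, 1)
  expect_equal(c(bp$lambda1, bp$lambda2, bp$r2), c(500, 510, 0.5))

  m[3, 1] <- 0.5  # equal maximum: lower-wavelength pair must come first
  map2 <- structure(list(wavelength = c(500, 510, 520), r2 = m,
                         form = "evi2", regression = "linear", n = 5),
                    class = "r2_map")
  bp2 <- best_pairs(map2, 2)
  expect_equal(bp2$lambda1, c(500, 520))
  expect_error(best_pairs(map2, 5), "exceeds")

  # ranked prefix equals a full-sort oracle on a real map
  toy <- toy_setup()
  map <- band_search(toy$spectra, toy$ccc, lo = 700, hi = 800, step = 10,
                     forms = "evi2", regressions = "linear")$evi2_linear
  bp10 <- best_pairs(map, 10)
  fin <- which(is.finite(map$r2), arr.ind = TRUE)
  ord <- order(-map$r2[fin], map$wavelength[fin[, 1]], map$wavelength[fin[, 2]])
  expect_equal(bp10$r2, map$r2[fin][ord][1:10])
  expect_equal(bp10$lambda1, map$wavelength[fin[, 1]][ord][1:10])
})

test_that("a planted informative pair is recovered by the search", {
  pair <- c(1215, 1260)
  toy <- toy_setup(9)
  set.seed(31)
  noisy <- lapply(toy$spectra, function(sp) {
    reflectance_spectrum(sp$wavelength,
                         pmin(pmax(sp$reflectance + rnorm(length(sp$reflectance), 0, 0.005), 0), 1))
  })
  ccc <- plant_ccc_from_pair(noisy, pair = pair, seed = 99)
  map <- band_search(noisy, ccc, step = 5, forms = "evi2",
                     regressions = "exponential")$evi2_exponential
  bp <- best_pairs(map, 1)
  expect_true(all(abs(sort(c(bp$lambda1, bp$lambda2)) - sort(pair)) <= 10))
})
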