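test_that("inner filter correction follows the 10^((Aex+Aem)/2) law", {
  expect_equal(inner_filter_correct(123.4, 0, 0), 123.4)
  expect_equal(inner_filter_correct(0, 0.7, 1.2), 0)
  expect_equal(inner_filter_correct(100, 0.2, 0.1), 100 * 10^0.15)
  expect_error(inner_filter_correct(10, -0.1, 0), "negative absorbance")

  # monotone in each absorbance, factor >= 1
  a <- seq(0, 1, 0.1)
  out <- inner_filter_correct(1, a, 0.3)
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= 1))

  # elementwise on a spectrum
  s <- spectrum(500:510, rep(2, 11), kind = "emission")
  cs <- inner_filter_correct(s, 0.2, 0.1)
  expect_s3_class(cs, "spectrum")
  expect_equal(cs$values, rep(2 * 10^0.15, 11))
})

test_that("band_descriptor matches the Gaussian FWHM closed form", {
  w <- seq(300, 600, 1)
  sigma <- 40.3
  s <- spectrum(w, 0.8 * exp(-(w - 438)^2 / (2 * sigma^2)),
                kind = "absorbance")
  bd <- band_descriptor(s)
  expect_equal(bd$lambda_max, 438, tolerance = 0.05)
  expect_equal(bd$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.5)

  # fwhm invariant under intensity rescaling
  s10 <- spectrum(w, 10 * s$values, kind = "absorbance")
  expect_equal(band_descriptor(s10)$fwhm, bd$fwhm, tolerance = 1e-9)
})

test_that("band_descriptor handles symmetric and degenerate peaks", {
  # symmetric triangle: apex exactly on a grid point
  w <- seq(440, 460, 1)
  y <- 10 - abs(w - 450)
  bd <- band_descriptor(spectrum(w, y, kind = "emission"))
  expect_equal(bd$lambda_max, 450)

  mono <- spectrum(400:420, seq(0, 2, 0.1), kind = "absorbance")
  expect_error(band_descriptor(mono), "edge")
})

test_that("find_isosbestic recovers the constructed crossing", {
  tit <- gen_absorbance_titration(noise_sd = 0, seed = 1)
  iso_true <- attr(tit, "isosbestic")
  iso <- find_isosbestic(tit)
  expect_length(iso, 1)
  expect_equal(iso, iso_true, tolerance = 0.5)

  # invariant under entry order (constructor sorts, so feed reversed input)
  tit_rev <- titration_series(rev(tit$concentrations), rev(tit$entries),
                              unit = "mg/mL")
  expect_equal(find_isosbestic(tit_rev), iso)
})

test_that("find_isosbestic flags degenerate and crossing-free series", {
  w <- seq(400, 500, 1)
  s <- spectrum(w, exp(-(w - 450)^2 / 800), kind = "absorbance")
  same <- titration_series(c(0.1, 0.5, 1), list(s, s, s), unit = "mg/mL")
  expect_warning(iso <- find_isosbestic(same), "degenerate")
  expect_length(iso, 0)

  # bound spectrum proportional to free: no wavelength where they are equal
  base <- exp(-(w - 450)^2 / 800)
  mix <- function(th) spectrum(w, (1 - th) * base + th * 0.5 * base,
                               kind = "absorbance")
  prop <- titration_series(c(0.1, 0.5, 1, 2),
                           lapply(c(0.1, 0.4, 0.7, 0.95), mix),
                           unit = "mg/mL")
  expect_length(find_isosbestic(prop), 0)
})

test_that("shift_profile spans the constructed red shift", {
  concs <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1, 1.5, 2, 5, 15, 75)
  tit <- gen_absorbance_titration(noise_sd = 0, concentrations = concs,
                                  seed = 1)
  prof <- shift_profile(tit)
  expect_equal(nrow(prof), length(concs))
  span <- max(prof$lambda_max) - min(prof$lambda_max)
  expect_equal(span, 11, tolerance = 0.5)
  expect_true(is.finite(attr(prof, "saturation")))

  # constant spectra: flat profile, saturation at the first concentration
  w <- seq(400, 500, 1)
  s <- spectrum(w, exp(-(w - 450)^2 / 800), kind = "absorbance")
  flat <- titration_series(c(0.1, 0.5, 1), list(s, s, s), unit = "mg/mL")
  pf <- shift_profile(flat)
  expect_equal(unique(pf$lambda_max), 450, tolerance = 1e-6)
  expect_equal(attr(pf, "saturation"), 0.1)

  # two-point series: profile only, no saturation estimate
  two <- titration_series(c(0.1, 1), tit$entries[c(1, 12)], unit = "mg/mL")
  p2 <- shift_profile(two)
  expect_equal(nrow(p2), 2)
  expect_true(is.na(attr(p2, "saturation")))
})
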