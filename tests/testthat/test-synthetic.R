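test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_absorbance_titration(seed = 5),
                   gen_absorbance_titration(seed = 5))
  expect_identical(gen_quench_series(seed = 5), gen_quench_series(seed = 5))
  expect_identical(gen_decay(channels = 256, channel_width = 0.4, seed = 5),
                   gen_decay(channels = 256, channel_width = 0.4, seed = 5))
  expect_identical(gen_pyrene_ratio(seed = 5), gen_pyrene_ratio(seed = 5))
  expect_identical(gen_height_map(seed = 5), gen_height_map(seed = 5))
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(gen_decay(channels = 256, channel_width = 0.4,
                                   seed = 99)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("absorbance titration generator honors its two-state limits", {
  tit <- gen_absorbance_titration(noise_sd = 0,
                                  concentrations = c(0, 0.5, 1, 2, 75),
                                  seed = 1)
  w <- tit$entries[[1]]$wavelengths
  k <- 2 * sqrt(2 * log(2))  # fwhm = k * sigma for a Gaussian
  s_free <- 0.8 * exp(-(w - 438)^2 / (2 * (95 / k)^2))
  s_bound <- 0.5 * exp(-(w - 449)^2 / (2 * (117 / k)^2))
  # c = 0: exactly the free spectrum
  expect_lt(max(abs(tit$entries[[1]]$values - s_free)), 1e-12)
  # c = 100*kd: bound spectrum within 1%
  expect_lt(max(abs(tit$entries[[5]]$values - s_bound)), 0.01 * max(s_bound))

  # non-overlapping bands warn about a missing isosbestic point
  expect_warning(gen_absorbance_titration(free_band = c(380, 10, 1),
                                          bound_band = c(550, 10, 0.5),
                                          noise_sd = 0),
                 "do not cross")
})

test_that("quench generator matches the closed-form van't Hoff K", {
  qs <- gen_quench_series(noise_sd = 0, seed = 1)
  K303 <- exp(467.17 / 8.314 - 117.06 * 1000 / (8.314 * 303.15))
  expect_rel_equal(attr(qs[[2]], "K_true"), K303, 1e-12)
  # q = 0 row carries F0 exactly
  ts <- qs[[1]]
  expect_equal(ts$entries[ts$concentrations == 0], 1000)
  # noiseless round trip through the Stern-Volmer fit
  q <- ts$concentrations; F <- ts$entries
  sv <- stern_volmer_fit(q[q > 0], F[q == 0], F[q > 0])
  expect_rel_equal(sv$K_sv, attr(ts, "K_true"), 1e-10)
})

test_that("decay generator respects count targets and limits", {
  # realized totals within 3 sigma of the Poisson sum over several seeds
  totals <- vapply(1:5, function(s) {
    sum(gen_decay(channels = 512, channel_width = 0.2, total_counts = 1e5,
                  seed = s)$counts)
  }, numeric(1))
  expect_true(all(abs(totals - 1e5) < 3 * sqrt(1e5)))

  # delta IRF, no noise: exact discretized exponential
  d <- gen_decay(taus = 5, alphas = 1, irf_sigma = 0, poisson = FALSE,
                 total_counts = 1e6, channels = 512, channel_width = 0.1)
  t <- d$times
  expected <- exp(-t / 5) * 1e6 / sum(exp(-t / 5))
  expect_rel_equal(d$counts, expected, 1e-10)

  expect_warning(gen_decay(taus = c(1, 30), alphas = c(0.5, 0.5),
                           channels = 256, channel_width = 0.2, seed = 1),
                 "truncated")
})

test_that("pyrene generator plateaus and map generator hits Rq exactly", {
  p <- gen_pyrene_ratio(noise_sd = 0,
                        concentrations = c(0.01, 0.02, 0.05, 1.5, 2, 3))
  expect_equal(p$ratio[1], 0.95, tolerance = 1e-4)

  hm <- gen_height_map(seed = 31)
  r <- roughness(hm)
  expect_lt(abs(r$Rq - 51.1), 1e-9)
  ratios <- vapply(1:20, function(s) {
    rr <- roughness(gen_height_map(seed = s))
    rr$Ra / rr$Rq
  }, numeric(1))
  expect_true(all(ratios > 0.7 & ratios < 0.85))
})
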