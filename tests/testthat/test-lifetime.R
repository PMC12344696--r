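test_that("average_lifetime reproduces the displacement-series table", {
  tb <- ans_lifetime_table
  # point targets for the first and the +12 uM rows
  expect_equal(average_lifetime(c(0.51, 7.67, 18.86), c(0.39, 0.20, 0.41)),
               9.4, tolerance = 0.1)
  expect_equal(average_lifetime(c(0.65, 6.15, 17.9), c(0.53, 0.24, 0.23)),
               5.9, tolerance = 0.1)
  # full-table regression: every printed tau_av within 0.1 ns
  for (i in seq_len(nrow(tb))) {
    got <- average_lifetime(c(tb$tau1[i], tb$tau2[i], tb$tau3[i]),
                            c(tb$alpha1[i], tb$alpha2[i], tb$alpha3[i]))
    expect_equal(got, tb$tau_av[i], tolerance = 0.1,
                 label = sprintf("row %s", tb$label[i]))
  }
})

test_that("average_lifetime contracts", {
  expect_equal(average_lifetime(7, 1), 7)
  expect_equal(average_lifetime(c(2, 8), c(0.5, 0.5)),
               average_lifetime(c(2, 8), c(5, 5)))
  expect_error(average_lifetime(c(1, 2), 1), "length")
  expect_error(average_lifetime(c(1, 2), c(0, 0)), "not all zero")
})

test_that("multiexp_fit is exact on a noiseless single exponential", {
  d <- gen_decay(taus = 5, alphas = 1, irf_sigma = 0, poisson = FALSE,
                 total_counts = 1e6, channels = 1024, channel_width = 0.05)
  fit <- multiexp_fit(d, m = 1, mode = "tail")
  expect_rel_equal(fit$taus, 5, 1e-6)
  expect_lt(fit$chi2_red, 1e-8)
  expect_equal(fit$alphas, 1)
})

test_that("multiexp_fit recovers the tri-exponential reference decay", {
  truth_tau <- c(0.51, 7.67, 18.86)
  truth_alpha <- c(0.39, 0.20, 0.41)
  d <- gen_decay(taus = truth_tau, alphas = truth_alpha, irf_sigma = 0.05,
                 total_counts = 1e6, seed = 7)
  fit <- multiexp_fit(d, m = 3, mode = "reconvolution")
  expect_true(all(abs(fit$taus - truth_tau) / truth_tau < 0.05))
  expect_true(all(abs(fit$alphas - truth_alpha) < 0.03))
  expect_gt(fit$chi2_red, 0.9)
  expect_lt(fit$chi2_red, 1.2)
  expect_true(all(diff(fit$taus) > 0))
  expect_gte(fit$tau_av, min(fit$taus))
  expect_lte(fit$tau_av, max(fit$taus))
})

test_that("multiexp_fit is deterministic and seed-stable", {
  d1 <- gen_decay(channels = 1024, channel_width = 0.0976, seed = 12)
  d2 <- gen_decay(channels = 1024, channel_width = 0.0976, seed = 12)
  expect_identical(d1$counts, d2$counts)
  f1 <- multiexp_fit(d1, m = 3, mode = "reconvolution")
  f2 <- multiexp_fit(d2, m = 3, mode = "reconvolution")
  expect_rel_equal(f1$taus, f2$taus, 1e-12)
  expect_rel_equal(f1$alphas, f2$alphas, 1e-12)
})

test_that("over-parameterized fits raise an unidentifiable warning", {
  d <- gen_decay(taus = 5, alphas = 1, irf_sigma = 0, poisson = FALSE,
                 total_counts = 1e5, channels = 512, channel_width = 0.1)
  expect_warning(fit <- multiexp_fit(d, m = 3, mode = "tail"),
                 "unidentifiable|over-parameterized|correlation")
  expect_true(fit$unidentifiable)
})

test_that("lifetime_stern_volmer recovers a constructed dynamic constant", {
  tau0 <- 3.0
  q <- c(5e-6, 1e-5, 2e-5, 4e-5)
  taus <- tau0 / (1 + 3500 * q)
  fit <- lifetime_stern_volmer(tau0, q, taus)
  expect_rel_equal(fit$K_D, 3500, 1e-10)

  # no lifetime change: zero constant
  flat <- lifetime_stern_volmer(tau0, q, rep(tau0, 4))
  expect_equal(flat$K_D, 0, tolerance = 1e-12)

  # lengthening lifetimes: negative constant plus warning
  expect_warning(neg <- lifetime_stern_volmer(tau0, q, tau0 * (1 + 100 * q)),
                 "anti-quenching")
  expect_lt(neg$K_D, 0)

  expect_error(lifetime_stern_volmer(tau0, 1e-5, 2.9), "at least 2")
})
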