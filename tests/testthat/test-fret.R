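test_that("efficiency_from_quenching implements 1 - F_DA/F_D", {
  expect_equal(efficiency_from_quenching(100, 100), 0)
  expect_equal(efficiency_from_quenching(50, 100), 0.5)
  expect_equal(efficiency_from_quenching(0.4281 * 321, 321), 0.5719,
               tolerance = 1e-12)
  expect_error(efficiency_from_quenching(110, 100), "enhancement")
  expect_error(efficiency_from_quenching(0, 100), "positive")
})

test_that("overlap_integral matches the flat-spectrum closed form", {
  w <- seq(400, 500, 1)
  don <- spectrum(w, rep(2, length(w)), kind = "emission")
  eps0 <- 1000
  eps <- spectrum(w, rep(eps0, length(w)), kind = "absorbance")
  J <- overlap_integral(don, eps)
  Jexact <- eps0 * (500^5 - 400^5) / 5 / 100
  expect_rel_equal(J, Jexact, 1e-4)  # 0.01%

  # zero absorptivity
  expect_equal(overlap_integral(don, spectrum(w, rep(0, length(w)),
                                              kind = "absorbance")), 0)
  # disjoint ranges
  far <- spectrum(seq(600, 700, 1), rep(1000, 101), kind = "absorbance")
  expect_warning(J0 <- overlap_integral(don, far), "disjoint")
  expect_equal(J0, 0)
  expect_error(overlap_integral(don, spectrum(w, rep(-1, length(w)),
                                              kind = "absorbance")),
               "negative")
})

test_that("overlap_integral is grid-converged and scale-invariant", {
  gauss <- function(w, c0, s, a) a * exp(-(w - c0)^2 / (2 * s^2))
  w1 <- seq(300, 450, 1)
  don <- spectrum(w1, gauss(w1, 340, 25, 1e4), kind = "emission")
  eps <- spectrum(w1, gauss(w1, 400, 30, 5e4), kind = "absorbance")
  J1 <- overlap_integral(don, eps)

  w2 <- seq(300, 450, 0.5)
  don2 <- spectrum(w2, gauss(w2, 340, 25, 1e4), kind = "emission")
  eps2 <- spectrum(w2, gauss(w2, 400, 30, 5e4), kind = "absorbance")
  J2 <- overlap_integral(don2, eps2)
  expect_lt(abs(J2 - J1) / J1, 1e-4)

  # donor normalization cancels any intensity scale
  don_scaled <- spectrum(w1, 37.5 * don$values, kind = "emission")
  expect_rel_equal(overlap_integral(don_scaled, eps), J1, 1e-12)
})

test_that("forster_radius follows the sixth-root law", {
  cst <- fret_constants(q_donor = 0.515, kappa2 = 2 / 3, n_ri = 1.33)
  expect_warning(r0 <- forster_radius(0, cst), "no spectral overlap")
  expect_equal(r0, 0)

  J <- 9.31e13
  R0 <- forster_radius(J, cst)
  expect_rel_equal(forster_radius(64 * J, cst), 2 * R0, 1e-12)

  # back-solved constants product 0.183 reproduces the reported radius
  cst2 <- fret_constants(q_donor = 0.183, kappa2 = 1, n_ri = 1)
  expect_equal(forster_radius(9.31e13, cst2), 33.8, tolerance = 0.05)

  # strictly increasing in kappa2, Q_D, J
  expect_gt(forster_radius(J, fret_constants(0.6, kappa2 = 1)),
            forster_radius(J, fret_constants(0.6, kappa2 = 2 / 3)))
  expect_gt(forster_radius(J, fret_constants(0.9)),
            forster_radius(J, fret_constants(0.5)))
  expect_gt(forster_radius(2 * J, cst), R0)
})

test_that("distance/efficiency are exact inverses with the right anchors", {
  expect_equal(distance_from_efficiency(0.5719, 33.82), 32.23,
               tolerance = 0.02)
  expect_equal(distance_from_efficiency(0.5, 20), 20)
  for (E in c(0.05, 0.3, 0.5719, 0.9)) {
    r <- distance_from_efficiency(E, 33.82)
    expect_rel_equal(efficiency_from_distance(r, 33.82), E, 1e-12)
  }
  # strictly decreasing in E
  Es <- seq(0.05, 0.95, 0.05)
  rs <- vapply(Es, distance_from_efficiency, numeric(1), R0 = 30)
  expect_true(all(diff(rs) < 0))
  expect_error(distance_from_efficiency(0, 30), "strictly between")
  expect_error(distance_from_efficiency(1, 30), "strictly between")
})

test_that("rate operations follow their defining ratios", {
  expect_equal(energy_transfer_rate(2, 30, 30), 1 / 2e-9)
  k1 <- energy_transfer_rate(3.57, 33.82, 32.23)
  expect_equal(k1, 3.74e8, tolerance = 0.01e8)
  expect_rel_equal(energy_transfer_rate(3.57, 33.82, 2 * 32.23),
                   k1 / 64, 1e-12)

  expect_equal(radiative_rate(0.5, 5), 1e8)
  expect_equal(radiative_rate(1, 1), 1e9)
  expect_rel_equal(radiative_rate(0.4, 5), 2 * radiative_rate(0.2, 5),
                   1e-12)

  expect_equal(as.numeric(decompose_rates(0.5, 2e8, 0)), 2e8)
  # with the printed-rounded inputs the residual rate comes out ~1.40e8
  s <- decompose_rates(0.5719, 3.74e8, 1.4e8)
  expect_equal(as.numeric(s), 1.40e8, tolerance = 0.02e8)
  expect_false(attr(s, "inconsistent"))
  # negative budget clamps with a flag
  expect_warning(cl <- decompose_rates(0.9, 1e8, 1e9), "clamped")
  expect_equal(as.numeric(cl), 0)
  expect_true(attr(cl, "inconsistent"))

  expect_equal(total_nonradiative(1.27e8, 3.74e8), 5.01e8)
})

test_that("the efficiency balance closes for randomized rate budgets", {
  set.seed(99)
  for (i in 1:1000) {
    tau_D <- runif(1, 0.5, 10)
    R0 <- runif(1, 15, 60)
    r <- runif(1, 0.4, 2.5) * R0
    k_r <- 10^runif(1, 6, 9)
    E <- efficiency_from_distance(r, R0)
    k_ET <- energy_transfer_rate(tau_D, R0, r)
    s <- suppressWarnings(as.numeric(decompose_rates(E, k_ET, k_r)))
    E_back <- k_ET / (k_r + k_ET + s)
    if (s > 0) expect_lt(abs(E_back - E), 1e-9)
  }
})

test_that("fret_chain wires the full rate budget consistently", {
  gauss <- function(w, c0, s, a) a * exp(-(w - c0)^2 / (2 * s^2))
  w <- seq(300, 480, 1)
  don <- spectrum(w, gauss(w, 340, 28, 1e4), kind = "emission")
  eps <- spectrum(w, gauss(w, 440, 35, 4.5e4), kind = "absorbance")
  fr <- fret_chain(F_DA = 42.81, F_D = 100, donor_em = don,
                   acceptor_eps = eps,
                   constants = fret_constants(q_donor = 0.15),
                   tau_D = 3.57, phi_DA = 0.05, tau_DA = 1.8)
  expect_equal(fr$E, 0.5719, tolerance = 1e-10)
  expect_rel_equal(fr$r, distance_from_efficiency(fr$E, fr$R0), 1e-12)
  expect_rel_equal(fr$total_k_nr, fr$sum_k_nr + fr$k_ET, 1e-12)
  # Eq-2 closure on the chain outputs
  expect_lt(abs(fr$E - fr$k_ET / (fr$k_r + fr$k_ET + fr$sum_k_nr)), 1e-9)
})
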