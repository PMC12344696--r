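# Seeded synthetic-data generators emulating the data structure of each
# experiment, so every analysis stage can be exercised and verified at desk
# scale. Band shapes are Gaussian: real titration spectra are asymmetric,
# but Gaussians give closed-form widths and a constructible isosbestic
# crossing, which is what the analysis contracts need.

# run code under a temporary RNG state so generators never disturb the
# caller's stream and identical seeds give bit-identical output
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.gauss_band <- function(lambda, center, fwhm, amplitude) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(lambda - center)^2 / (2 * sigma^2))
}

#' Generate a two-state absorbance titration
#'
#' Builds spectra as concentration-weighted mixtures of a "free" and a
#' "bound" Gaussian band,
#' \deqn{A(\lambda, c) = f_{free}(c)\,S_{free}(\lambda) +
#'   (1 - f_{free}(c))\,S_{bound}(\lambda)}
#' with the bound fraction following the Hill law
#' \eqn{\theta(c) = c^n / (k_D^n + c^n)}. Because every spectrum is a convex
#' combination of the same two shapes, all spectra cross exactly where
#' \eqn{S_{free} = S_{bound}}: the constructed isosbestic point, returned as
#' attribute `isosbestic`. Defaults mirror a ligand band red-shifting
#' 438 to 449 nm with broadening 95 to 117 nm upon encapsulation, with
#' half-saturation at 0.75 mg/mL and Hill coefficient 1.32.
#'
#' @param free_band,bound_band Numeric `c(center, fwhm, amplitude)` of the
#'   free and bound species bands (nm, nm, AU).
#' @param kd Half-saturation concentration (mg/mL).
#' @param n_hill Hill coefficient.
#' @param concentrations Titrant concentrations (mg/mL).
#' @param wavelengths Wavelength grid (nm).
#' @param noise_sd Additive Gaussian noise sd relative to the maximum
#'   amplitude (default 0.005, i.e. 0.5 percent).
#' @param seed RNG seed.
#' @return A [titration_series()] of absorbance spectra with attributes
#'   `isosbestic` (constructed crossing, nm; NA when the bands do not
#'   cross) and `truth` (generator parameters).
#' @export
gen_absorbance_titration <- function(free_band = c(438, 95, 0.8),
                                     bound_band = c(449, 117, 0.5),
                                     kd = 0.75, n_hill = 1.32,
                                     concentrations = c(0.05, 0.1, 0.2, 0.3,
                                                        0.5, 0.75, 1, 1.25,
                                                        1.5, 2, 2.5, 3),
                                     wavelengths = seq(330, 620, by = 1),
                                     noise_sd = 0.005, seed = 1) {
  s_free <- .gauss_band(wavelengths, free_band[1], free_band[2],
                        free_band[3])
  s_bound <- .gauss_band(wavelengths, bound_band[1], bound_band[2],
                         bound_band[3])
  # constructed crossing red of both band centers (where analyses look for
  # the isosbestic point of an encapsulation red-shift)
  diff_fun <- function(l) {
    .gauss_band(l, free_band[1], free_band[2], free_band[3]) -
      .gauss_band(l, bound_band[1], bound_band[2], bound_band[3])
  }
  lo <- max(free_band[1], bound_band[1])
  hi <- max(wavelengths)
  iso <- NA_real_
  if (diff_fun(lo) * diff_fun(hi) < 0) {
    iso <- stats::uniroot(diff_fun, c(lo, hi), tol = 1e-10)$root
  } else {
    warning("free and bound bands do not cross: no isosbestic point")
  }
  theta <- concentrations^n_hill / (kd^n_hill + concentrations^n_hill)
  entries <- .with_seed(seed, lapply(seq_along(concentrations), function(i) {
    a <- (1 - theta[i]) * s_free + theta[i] * s_bound
    if (noise_sd > 0) {
      a <- a + stats::rnorm(length(a), 0,
                            noise_sd * max(free_band[3], bound_band[3]))
    }
    spectrum(wavelengths, a, kind = "absorbance",
             label = sprintf("c=%g", concentrations[i]))
  }))
  out <- titration_series(concentrations, entries, unit = "mg/mL")
  attr(out, "isosbestic") <- iso
  attr(out, "truth") <- list(free_band = free_band, bound_band = bound_band,
                             kd = kd, n_hill = n_hill, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate Stern-Volmer quenching series at one or more temperatures
#'
#' Intensities follow \eqn{F(q) = F_0 / (1 + K q)} with the quenching
#' constant either supplied per temperature or derived from a van't Hoff
#' parameterization \eqn{K(T) = e^{\Delta S / R - \Delta H / (R T)}}
#' (`delta_H` in kJ/mol, `delta_S` in J/(mol K), R = 8.314). Noise is
#' multiplicative Gaussian.
#'
#' @param K Quenching/association constant(s) in M^-1, one per temperature;
#'   or `NULL` to derive from `delta_H`/`delta_S`.
#' @param delta_H,delta_S van't Hoff parameters (used when `K` is NULL).
#' @param temperatures Temperatures in K.
#' @param q_grid Quencher concentrations in M (0 allowed).
#' @param F0 Unquenched intensity.
#' @param noise_sd Relative Gaussian noise sd (default 0.005).
#' @param seed RNG seed.
#' @return A list of [titration_series()] (scalar intensities, unit M), one
#'   per temperature, each with attribute `K_true`; the list carries
#'   attribute `truth`.
#' @export
gen_quench_series <- function(K = NULL, delta_H = 117.06, delta_S = 467.17,
                              temperatures = c(293.15, 303.15, 313.15),
                              q_grid = seq(0, 40e-6, length.out = 9),
                              F0 = 1000, noise_sd = 0.005, seed = 1) {
  if (any(q_grid < 0)) stop("quencher concentrations must be >= 0",
                            call. = FALSE)
  if (is.null(K)) {
    K <- exp(delta_S / .R_GAS - delta_H * 1000 / (.R_GAS * temperatures))
  } else {
    K <- rep_len(K, length(temperatures))
  }
  out <- .with_seed(seed, lapply(seq_along(temperatures), function(i) {
    f <- F0 / (1 + K[i] * q_grid)
    if (noise_sd > 0) {
      f <- f * (1 + stats::rnorm(length(f), 0, noise_sd))
    }
    ts <- titration_series(q_grid, f, unit = "M",
                           temperature = temperatures[i],
                           response_label = "fluorescence intensity")
    attr(ts, "K_true") <- K[i]
    ts
  }))
  attr(out, "truth") <- list(K = K, temperatures = temperatures, F0 = F0,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a TCSPC decay histogram
#'
#' Expected counts are the discrete convolution of a Gaussian instrument
#' response with \eqn{\sum_i \alpha_i e^{-t/\tau_i}}, scaled to
#' `total_counts`, then Poisson-sampled per channel. `irf_sigma = 0` uses a
#' delta IRF (pure discretized exponential). The IRF histogram is attached
#' to the output.
#'
#' @param taus Lifetimes, ns, strictly increasing.
#' @param alphas Amplitudes, positive; normalized internally.
#' @param irf_sigma Gaussian IRF width (sd), ns.
#' @param irf_t0 IRF center, ns (default `max(10 * irf_sigma, 0)`).
#' @param total_counts Target total photon count.
#' @param channels Number of channels.
#' @param channel_width Channel width, ns.
#' @param poisson Apply Poisson noise? `FALSE` returns expected counts.
#' @param seed RNG seed.
#' @return A [decay_histogram()] with attribute `truth`.
#' @export
gen_decay <- function(taus = c(0.51, 7.67, 18.86),
                      alphas = c(0.39, 0.20, 0.41),
                      irf_sigma = 0.05, irf_t0 = NULL, total_counts = 1e6,
                      channels = 4096, channel_width = 0.0244,
                      poisson = TRUE, seed = 1) {
  if (length(taus) != length(alphas)) stop("taus/alphas length mismatch",
                                           call. = FALSE)
  if (any(taus <= 0) || any(alphas <= 0)) {
    stop("taus and alphas must be positive", call. = FALSE)
  }
  if (is.unsorted(taus, strictly = TRUE)) {
    stop("taus must be strictly increasing", call. = FALSE)
  }
  alphas <- alphas / sum(alphas)
  t <- (seq_len(channels) - 1L) * channel_width
  span <- channels * channel_width
  if (span < 5 * max(taus)) {
    warning(sprintf("channel span %.3g ns < 5 x max lifetime %.3g ns: ",
                    span, max(taus)),
            "decay is truncated")
  }
  d <- Reduce(`+`, lapply(seq_along(taus),
                          function(i) alphas[i] * exp(-t / taus[i])))
  if (irf_sigma > 0) {
    if (is.null(irf_t0)) irf_t0 <- 10 * irf_sigma
    irf <- stats::dnorm(t, irf_t0, irf_sigma)
    irf <- irf / sum(irf)
    model <- .convolve_irf(irf, d)
  } else {
    irf <- c(1, rep(0, channels - 1L))
    model <- d
  }
  model[model < 0] <- 0
  expected <- model * total_counts / sum(model)
  counts <- if (poisson) {
    .with_seed(seed, stats::rpois(channels, expected))
  } else {
    expected
  }
  out <- decay_histogram(t, counts, irf = irf * total_counts / 10,
                         channel_width = channel_width)
  attr(out, "truth") <- list(taus = taus, alphas = alphas,
                             irf_sigma = irf_sigma, irf_t0 = irf_t0,
                             total_counts = total_counts, seed = seed)
  out
}

#' Generate a sigmoidal pyrene ratio series
#'
#' Boltzmann sigmoid
#' \eqn{ratio(c) = lower + (upper - lower)/(1 + e^{(cmc - c)/slope})}
#' plus multiplicative Gaussian noise.
#'
#' @param cmc Sigmoid midpoint (mg/mL).
#' @param lower,upper Plateau ratios, `lower < upper`.
#' @param slope Transition width (mg/mL).
#' @param concentrations Concentrations (mg/mL).
#' @param noise_sd Relative Gaussian noise sd (default 0.005).
#' @param seed RNG seed.
#' @return A `ratio_series` data.frame with attribute `truth`.
#' @export
gen_pyrene_ratio <- function(cmc = 0.84, lower = 0.95, upper = 1.35,
                             slope = 0.08,
                             concentrations = seq(0.05, 3,
                                                  length.out = 24),
                             noise_sd = 0.005, seed = 1) {
  if (lower >= upper) stop("lower plateau must be below upper",
                           call. = FALSE)
  r <- lower + (upper - lower) / (1 + exp((cmc - concentrations) / slope))
  if (noise_sd > 0) {
    r <- .with_seed(seed,
                    r * (1 + stats::rnorm(length(r), 0, noise_sd)))
  }
  out <- data.frame(concentration = concentrations, ratio = r)
  attr(out, "unit") <- "mg/mL"
  attr(out, "truth") <- list(cmc = cmc, lower = lower, upper = upper,
                             slope = slope, noise_sd = noise_sd,
                             seed = seed)
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Generate a correlated random AFM height map
#'
#' White Gaussian noise smoothed with a Gaussian kernel (a stationary random
#' field with the requested correlation length), mean-centered and rescaled
#' so that the root-mean-square roughness Rq equals `target_rq` exactly.
#' For such Gaussian fields Ra/Rq is close to sqrt(2/pi) ~ 0.798.
#'
#' @param grid_size Edge length in pixels (>= 16).
#' @param correlation_length Gaussian smoothing sd, pixels.
#' @param target_rq Target Rq, nm.
#' @param pixel_size Pixel edge, nm.
#' @param seed RNG seed.
#' @return A [height_map()] with attribute `truth`.
#' @export
gen_height_map <- function(grid_size = 64, correlation_length = 4,
                           target_rq = 51.1, pixel_size = 78, seed = 1) {
  if (grid_size < 16) stop("grid must be at least 16 x 16", call. = FALSE)
  z <- .with_seed(seed, matrix(stats::rnorm(grid_size^2), grid_size))
  # circular convolution with a Gaussian kernel via FFT keeps the field
  # stationary (no edge roll-off biasing Ra/Rq)
  ax <- c(0:(grid_size %/% 2), -((grid_size - grid_size %/% 2 - 1):1))
  k <- exp(-outer(ax^2, ax^2, `+`) / (2 * correlation_length^2))
  k <- k / sum(k)
  z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    grid_size^2
  z <- z - mean(z)
  rq <- sqrt(mean(z^2))
  z <- z * target_rq / rq
  out <- height_map(z, pixel_size = pixel_size)
  attr(out, "truth") <- list(grid_size = grid_size,
                             correlation_length = correlation_length,
                             target_rq = target_rq, seed = seed)
  out
}
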