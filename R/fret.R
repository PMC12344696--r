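# Forster resonance energy transfer: efficiency, overlap integral, Forster
# radius, donor-acceptor distance, and the radiative/nonradiative rate budget.

#' FRET constants bundle
#'
#' @param kappa2 Orientation factor, 0 < kappa2 <= 4. Default 2/3, the
#'   isotropic dynamic average.
#' @param n_ri Refractive index of the intervening medium, >= 1. Default
#'   1.33 (aqueous buffer).
#' @param q_donor Donor fluorescence quantum yield in the absence of
#'   acceptor, 0 < Q_D <= 1. No default: it must be supplied, because it is
#'   system specific and R0 depends on it to the sixth root.
#' @return A list of class `fret_constants`.
#' @export
fret_constants <- function(q_donor, kappa2 = 2 / 3, n_ri = 1.33) {
  if (kappa2 <= 0 || kappa2 > 4) stop("kappa2 must be in (0, 4]",
                                      call. = FALSE)
  if (n_ri < 1) stop("refractive index must be >= 1", call. = FALSE)
  if (q_donor <= 0 || q_donor > 1) stop("q_donor must be in (0, 1]",
                                        call. = FALSE)
  structure(list(kappa2 = kappa2, n_ri = n_ri, q_donor = q_donor),
            class = "fret_constants")
}

#' FRET efficiency from steady-state quenching
#'
#' \deqn{E = 1 - F_{DA}/F_D}
#' where `F_D` is the donor intensity alone and `F_DA` its intensity in the
#' presence of the acceptor.
#'
#' @param F_DA Donor intensity with acceptor, 0 < F_DA <= F_D.
#' @param F_D Donor intensity without acceptor.
#' @return Efficiency in `[0, 1)`.
#' @export
efficiency_from_quenching <- function(F_DA, F_D) {
  if (F_D <= 0 || F_DA <= 0) stop("intensities must be positive",
                                  call. = FALSE)
  if (F_DA > F_D) stop("F_DA > F_D: enhancement is not FRET quenching",
                       call. = FALSE)
  1 - F_DA / F_D
}

#' Spectral overlap integral J
#'
#' \deqn{J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
#'   d\lambda}{\int F_D(\lambda)\, d\lambda}}
#' evaluated on the intersection of the two wavelength ranges: both spectra
#' are linearly interpolated onto the finer of the two grids and integrated
#' by the trapezoidal rule. The donor normalization cancels any intensity
#' scale, so `J` depends only on the donor line shape.
#'
#' @param donor_em Donor emission [spectrum()] (arbitrary units, >= 0).
#' @param acceptor_eps Acceptor molar absorptivity [spectrum()], values
#'   epsilon(lambda) in M^-1 cm^-1, >= 0.
#' @return Overlap integral in nm^4 M^-1 cm^-1 (0 with a warning when the
#'   ranges are disjoint).
#' @export
overlap_integral <- function(donor_em, acceptor_eps) {
  stopifnot(inherits(donor_em, "spectrum"), inherits(acceptor_eps,
                                                     "spectrum"))
  if (any(donor_em$values < 0)) stop("donor emission must be non-negative",
                                     call. = FALSE)
  if (any(acceptor_eps$values < 0)) stop("negative molar absorptivity",
                                         call. = FALSE)
  lo <- max(min(donor_em$wavelengths), min(acceptor_eps$wavelengths))
  hi <- min(max(donor_em$wavelengths), max(acceptor_eps$wavelengths))
  if (hi - lo < 2) {
    warning("donor emission and acceptor absorption ranges are disjoint ",
            "(or overlap < 2 nm); J = 0")
    return(0)
  }
  step <- min(min(diff(donor_em$wavelengths)),
              min(diff(acceptor_eps$wavelengths)))
  grid <- seq(lo, hi, by = step)
  fd <- stats::approx(donor_em$wavelengths, donor_em$values, grid)$y
  ea <- stats::approx(acceptor_eps$wavelengths, acceptor_eps$values, grid)$y
  num <- .trapz(grid, fd * ea * grid^4)
  den <- .trapz(grid, fd)
  if (den <= 0) {
    warning("donor emission vanishes on the overlap range; J = 0")
    return(0)
  }
  num / den
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)

#' Forster radius from the overlap integral
#'
#' \deqn{R_0 = \left(8.79\times 10^{-5}\, \kappa^2\, n^{-4}\, Q_D\, J
#'   \right)^{1/6}\ \mathrm{\AA}}
#' with `J` in nm^4 M^-1 cm^-1 — the standard convention that returns the
#' radius directly in Angstrom.
#'
#' @param J Overlap integral, nm^4 M^-1 cm^-1, >= 0.
#' @param constants A [fret_constants()] bundle.
#' @return Forster radius in Angstrom (0 with a warning when `J = 0`).
#' @export
forster_radius <- function(J, constants) {
  stopifnot(inherits(constants, "fret_constants"))
  if (J < 0) stop("J must be non-negative", call. = FALSE)
  if (J == 0) {
    warning("J = 0: no spectral overlap, R0 = 0")
    return(0)
  }
  (8.79e-5 * constants$kappa2 * constants$n_ri^-4 * constants$q_donor *
     J)^(1 / 6)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts \eqn{E = R_0^6 / (R_0^6 + r^6)}:
#' \deqn{r = R_0 \left(\frac{1 - E}{E}\right)^{1/6}}
#'
#' @param E Efficiency, strictly between 0 and 1.
#' @param R0 Forster radius, Angstrom, > 0.
#' @return Distance r in Angstrom.
#' @export
#' @examples
#' distance_from_efficiency(0.5719, 33.82)  # ~32.23 A
distance_from_efficiency <- function(E, R0) {
  if (E <= 0 || E >= 1) stop("E must be strictly between 0 and 1",
                             call. = FALSE)
  if (R0 <= 0) stop("R0 must be positive", call. = FALSE)
  R0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency from donor-acceptor distance
#'
#' \deqn{E = \frac{R_0^6}{R_0^6 + r^6}}
#'
#' @param r Donor-acceptor distance, Angstrom, > 0.
#' @param R0 Forster radius, Angstrom, > 0.
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, R0) {
  if (r <= 0 || R0 <= 0) stop("distances must be positive", call. = FALSE)
  R0^6 / (R0^6 + r^6)
}

#' Energy-transfer rate
#'
#' \deqn{k_{ET} = \frac{1}{\tau_D}\left(\frac{R_0}{r}\right)^6}
#' where `tau_D` is the donor lifetime in the absence of acceptor.
#'
#' @param tau_D Donor-only lifetime, ns.
#' @param R0 Forster radius, Angstrom.
#' @param r Donor-acceptor distance, Angstrom.
#' @return Rate in s^-1.
#' @export
energy_transfer_rate <- function(tau_D, R0, r) {
  if (tau_D <= 0 || R0 <= 0 || r <= 0) stop("all inputs must be positive",
                                            call. = FALSE)
  (1 / (tau_D * 1e-9)) * (R0 / r)^6
}

#' Radiative decay rate from quantum yield and lifetime
#'
#' \deqn{k_r = \phi / \tau}
#' with the (quenched) quantum yield and the matching fluorescence lifetime.
#'
#' @param phi_DA Quantum yield, in (0, 1].
#' @param tau_DA Lifetime, ns.
#' @return Rate in s^-1.
#' @export
radiative_rate <- function(phi_DA, tau_DA) {
  if (phi_DA <= 0 || phi_DA > 1) stop("phi must be in (0, 1]", call. = FALSE)
  if (tau_DA <= 0) stop("lifetime must be positive", call. = FALSE)
  phi_DA / (tau_DA * 1e-9)
}

#' Residual nonradiative rate from the efficiency balance
#'
#' The efficiency balance
#' \eqn{E = k_{ET} / (k_r + k_{ET} + \sum k_{nr})} solved for the remaining
#' nonradiative channels:
#' \deqn{\sum k_{nr} = k_{ET}\frac{1-E}{E} - k_r}
#' A small negative result (possible when rounded inputs are combined) is
#' clamped to 0 and flagged via attribute `inconsistent`.
#'
#' @param E Efficiency, in (0, 1).
#' @param k_ET Energy-transfer rate, s^-1.
#' @param k_r Radiative rate, s^-1.
#' @return `sum_k_nr` in s^-1 (attribute `inconsistent` = TRUE when
#'   clamped).
#' @export
decompose_rates <- function(E, k_ET, k_r) {
  if (E <= 0 || E >= 1) stop("E must be strictly between 0 and 1",
                             call. = FALSE)
  if (k_ET < 0 || k_r < 0) stop("rates must be non-negative", call. = FALSE)
  out <- k_ET * (1 - E) / E - k_r
  if (out < 0) {
    warning("rate budget inconsistent (rounded inputs?): ",
            "sum_k_nr clamped to 0")
    return(structure(0, inconsistent = TRUE))
  }
  structure(out, inconsistent = FALSE)
}

#' Total nonradiative rate
#'
#' Energy transfer is itself a nonradiative channel, so the total
#' nonradiative rate is \eqn{\sum k_{nr} + k_{ET}}.
#'
#' @param sum_k_nr Residual nonradiative rate, s^-1.
#' @param k_ET Energy-transfer rate, s^-1.
#' @return Total nonradiative rate, s^-1.
#' @export
total_nonradiative <- function(sum_k_nr, k_ET) {
  if (sum_k_nr < 0 || k_ET < 0) stop("rates must be non-negative",
                                     call. = FALSE)
  as.numeric(sum_k_nr) + as.numeric(k_ET)
}

#' Run the full FRET chain
#'
#' Convenience wrapper executing efficiency, overlap integral, Forster
#' radius, distance, transfer rate and the rate budget in one call, echoing
#' every intermediate and constant so the chain is auditable.
#'
#' @param F_DA,F_D Donor intensities with and without acceptor.
#' @param donor_em Donor emission [spectrum()].
#' @param acceptor_eps Acceptor molar absorptivity [spectrum()].
#' @param constants A [fret_constants()].
#' @param tau_D Donor-only lifetime, ns.
#' @param phi_DA Quenched donor quantum yield (for `k_r`); optional.
#' @param tau_DA Donor lifetime with acceptor, ns (for `k_r`); optional.
#' @return A list of class `fret_result` with `E`, `J`, `R0`, `r`, `tau_D`,
#'   `k_ET`, `k_r`, `sum_k_nr`, `total_k_nr`, `phi_DA`, `tau_DA`,
#'   `constants`.
#' @export
fret_chain <- function(F_DA, F_D, donor_em, acceptor_eps, constants, tau_D,
                       phi_DA = NA_real_, tau_DA = NA_real_) {
  E <- efficiency_from_quenching(F_DA, F_D)
  J <- overlap_integral(donor_em, acceptor_eps)
  R0 <- forster_radius(J, constants)
  r <- distance_from_efficiency(E, R0)
  k_ET <- energy_transfer_rate(tau_D, R0, r)
  k_r <- if (is.na(phi_DA) || is.na(tau_DA)) NA_real_ else
    radiative_rate(phi_DA, tau_DA)
  sum_k_nr <- if (is.na(k_r)) NA_real_ else
    as.numeric(decompose_rates(E, k_ET, k_r))
  structure(list(E = E, J = J, R0 = R0, r = r, tau_D = tau_D, k_ET = k_ET,
                 k_r = k_r, sum_k_nr = sum_k_nr,
                 total_k_nr = if (is.na(sum_k_nr)) NA_real_ else
                   total_nonradiative(sum_k_nr, k_ET),
                 phi_DA = phi_DA, tau_DA = tau_DA, constants = constants),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat("<fret_result>\n")
  cat(sprintf("  E = %.4f, J = %.4g nm^4 M^-1 cm^-1\n", x$E, x$J))
  cat(sprintf("  R0 = %.2f A, r = %.2f A (kappa2 = %.3f, n = %.3f, Q_D = %.3f)\n",
              x$R0, x$r, x$constants$kappa2, x$constants$n_ri,
              x$constants$q_donor))
  cat(sprintf("  k_ET = %.4g s^-1, k_r = %.4g s^-1, sum_k_nr = %.4g s^-1\n",
              x$k_ET, x$k_r, x$sum_k_nr))
  if (!is.na(x$total_k_nr)) {
    cat(sprintf("  total nonradiative = %.4g s^-1\n", x$total_k_nr))
  }
  invisible(x)
}
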