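#' @keywords internal
.R_GAS <- 8.314  # J mol^-1 K^-1, fixed for determinism

#' Gibbs free energy from enthalpy and entropy
#'
#' \deqn{\Delta G = \Delta H - T \Delta S}
#' with `delta_H` in kJ/mol and `delta_S` in J/(mol K); the entropy term is
#' divided by 1000 so the result is in kJ/mol.
#'
#' @param delta_H Enthalpy change, kJ/mol.
#' @param delta_S Entropy change, J/(mol K).
#' @param T Temperature(s) in K, > 0.
#' @return Gibbs free energy change(s), kJ/mol.
#' @export
#' @examples
#' gibbs(117.06, 467.17, 303.15)  # about -24.56 kJ/mol
gibbs <- function(delta_H, delta_S, T) {
  if (any(T <= 0)) stop("temperature must be positive", call. = FALSE)
  delta_H - T * delta_S / 1000
}

#' Classify dominant binding forces from thermodynamic signs
#'
#' The Ross-Subramanian sign rules for protein-ligand association:
#' positive enthalpy and entropy changes indicate hydrophobic interactions;
#' both negative indicate van der Waals forces and hydrogen bonding;
#' negative enthalpy with positive entropy indicates electrostatic
#' interactions. Exact zeros are indeterminate.
#'
#' @param delta_H Enthalpy change, kJ/mol.
#' @param delta_S Entropy change, J/(mol K).
#' @return One of `"hydrophobic"`, `"vdw_hbond"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @export
classify_forces <- function(delta_H, delta_S) {
  if (delta_H > 0 && delta_S > 0) return("hydrophobic")
  if (delta_H < 0 && delta_S < 0) return("vdw_hbond")
  if (delta_H < 0 && delta_S > 0) return("electrostatic")
  "indeterminate"
}

#' van't Hoff analysis of temperature-dependent association constants
#'
#' Ordinary least squares of \eqn{\ln K_a} on \eqn{1/T}:
#' \deqn{\ln K_a = -\frac{\Delta H}{R T} + \frac{\Delta S}{R}}
#' so \eqn{\Delta H = -slope \cdot R} and \eqn{\Delta S = intercept \cdot R}
#' (R = 8.314 J/(mol K)). Gibbs energies at each input temperature are then
#' taken from the van't Hoff route `delta_H - T * delta_S`, which matches how
#' the quantity is conventionally tabulated; `-RT ln Ka` is also computed and
#' reported alongside so any discrepancy (e.g. from rounded inputs) is
#' visible.
#'
#' @param ka_table Named numeric vector or data.frame/list mapping
#'   temperature (K) to association constant K_a (M^-1): either
#'   `c("293.15" = 4310, ...)` or `data.frame(T, Ka)`.
#' @return A list of class `thermo_result` with `delta_H` (kJ/mol),
#'   `delta_S` (J/(mol K)), `delta_G` (named, kJ/mol, van't Hoff route),
#'   `delta_G_rtlnk` (named, kJ/mol, `-RT ln Ka` route), `ka_table`,
#'   `r_squared`, `force_class`.
#' @export
#' @examples
#' vant_hoff_fit(data.frame(T = c(293.15, 303.15, 313.15),
#'                          Ka = c(4310, 10100, 116000)))
vant_hoff_fit <- function(ka_table) {
  if (is.data.frame(ka_table) || is.list(ka_table)) {
    T <- as.numeric(ka_table[[1L]])
    ka <- as.numeric(ka_table[[2L]])
  } else {
    T <- as.numeric(names(ka_table))
    ka <- as.numeric(ka_table)
  }
  if (length(T) < 3L) stop("need at least 3 temperatures", call. = FALSE)
  if (any(!is.finite(T)) || any(T <= 0)) stop("invalid temperatures",
                                              call. = FALSE)
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    stop("association constants must be positive", call. = FALSE)
  }
  ord <- order(T)
  T <- T[ord]; ka <- ka[ord]
  x <- 1 / T
  y <- log(ka)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  delta_H <- -unname(co[2L]) * .R_GAS / 1000  # kJ/mol
  delta_S <- unname(co[1L]) * .R_GAS          # J/(mol K)
  dG <- gibbs(delta_H, delta_S, T)
  dG_rtlnk <- -.R_GAS * T * y / 1000
  names(dG) <- names(dG_rtlnk) <- format(T, trim = TRUE)
  kt <- ka
  names(kt) <- format(T, trim = TRUE)
  structure(list(delta_H = delta_H, delta_S = delta_S, delta_G = dG,
                 delta_G_rtlnk = dG_rtlnk, ka_table = kt,
                 r_squared = .lm_r2(fit),
                 force_class = classify_forces(delta_H, delta_S)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/(mol K), R2 = %.4f\n",
              x$delta_H, x$delta_S, x$r_squared))
  cat(sprintf("  force class: %s\n", x$force_class))
  for (nm in names(x$delta_G)) {
    cat(sprintf("  T = %s K: dG = %.2f kJ/mol (-RT ln Ka: %.2f)\n",
                nm, x$delta_G[[nm]], x$delta_G_rtlnk[[nm]]))
  }
  invisible(x)
}
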