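#' Fit a Hill binding isotherm ("Hill1" form)
#'
#' Fits the saturation model
#' \deqn{y = start + (end - start) \frac{x^n}{k_D^n + x^n}}
#' to a dose-response curve by nonlinear least squares. `k_D` is the
#' half-saturation (apparent dissociation) concentration in the units of
#' `x`; `n` is the Hill coefficient, read as the apparent number of binding
#' sites. Initial values follow the usual convention: `start` from the
#' lowest-concentration response, `end` from the highest, `k_D` at the
#' half-range response, `n = 1`.
#'
#' @param x Concentrations (>= 0, strictly increasing, >= 5 points).
#' @param y Responses, same length.
#' @return A list of class `hill1_fit` with `start`, `end`, `k_D`, `n_hill`,
#'   `r_squared`, `K_b_molar` (NA until [convert_kd_to_molar()] is applied),
#'   and logical `kd_outside_range`.
#' @export
#' @examples
#' x <- c(0.05, 0.1, 0.2, 0.4, 0.75, 1, 1.5, 2, 3)
#' y <- 0.8 + (0.5 - 0.8) * x^1.32 / (0.75^1.32 + x^1.32)
#' hill1_fit(x, y)
hill1_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 5L) stop("need at least 5 points", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (diff(range(y)) == 0) {
    stop("fit failure: constant response, k_D unidentifiable", call. = FALSE)
  }
  start0 <- y[1L]
  end0 <- y[length(y)]
  half <- (start0 + end0) / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(x[x > 0])
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    stats::nls(y ~ start + (end - start) * x^n / (kd^n + x^n),
               data = dat,
               start = list(start = start0, end = end0, kd = kd0, n = 1),
               lower = c(start = -Inf, end = -Inf, kd = 1e-12, n = 1e-3),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12,
                                            warnOnly = FALSE)),
    error = function(e) {
      stop(sprintf("fit failure: %s", conditionMessage(e)), call. = FALSE)
    })
  p <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  kd_out <- p[["kd"]] < min(x) || p[["kd"]] > max(x)
  if (kd_out) warning("fitted k_D lies outside the data range")
  structure(list(start = p[["start"]], end = p[["end"]], k_D = p[["kd"]],
                 n_hill = p[["n"]], r_squared = r2, K_b_molar = NA_real_,
                 kd_outside_range = kd_out),
            class = "hill1_fit")
}

#' @export
print.hill1_fit <- function(x, ...) {
  cat(sprintf(
    "<hill1_fit> k_D = %.4g, n = %.3f, start = %.4g, end = %.4g, R2 = %.4f\n",
    x$k_D, x$n_hill, x$start, x$end, x$r_squared))
  if (!is.na(x$K_b_molar)) {
    cat(sprintf("  K_b = %.4g M^-1\n", x$K_b_molar))
  }
  invisible(x)
}

#' Convert a mass-unit dissociation constant to a molar association constant
#'
#' A `k_D` in mg/mL inverts to an association constant in (mg/mL)^-1; since
#' mg/mL equals g/L, multiplying by the molar mass in Da (g/mol) yields the
#' association constant in M^-1:
#' \deqn{K_b = \frac{MW}{k_D}}
#'
#' @param k_D Dissociation constant in mg/mL (> 0).
#' @param mw Molar mass in Da (> 0).
#' @return Association constant in M^-1.
#' @export
#' @examples
#' convert_kd_to_molar(0.75, 22500)  # 3e4 M^-1
convert_kd_to_molar <- function(k_D, mw) {
  if (any(k_D <= 0)) stop("k_D must be positive", call. = FALSE)
  if (any(mw <= 0)) stop("molar mass must be positive", call. = FALSE)
  (1 / k_D) * mw
}

#' Stern-Volmer quenching fit
#'
#' Ordinary least squares of \eqn{(F_0 - F)/F} on quencher concentration.
#' The slope is the Stern-Volmer constant `K_sv` (M^-1); dividing by the
#' unquenched fluorophore lifetime `tau0` gives the bimolecular quenching
#' rate constant `k_q = K_sv / tau0` (M^-1 s^-1). An intercept is fitted and
#' reported; for well-behaved quenching data it should be near zero.
#'
#' @param q Quencher concentrations in M (the `q = 0` point may be included;
#'   its F must then equal `F0`).
#' @param F0 Unquenched intensity (scalar).
#' @param F Quenched intensities, same length as `q`, all > 0.
#' @param tau0 Unquenched lifetime in seconds; required for `k_q`, may be NA
#'   to skip the rate constant.
#' @return A list of class `stern_volmer_fit` with `K_sv`, `k_q`, `tau0`,
#'   `intercept`, `r_squared`.
#' @export
stern_volmer_fit <- function(q, F0, F, tau0 = NA_real_) {
  q <- as.numeric(q); F <- as.numeric(F)
  if (length(q) != length(F)) stop("q and F lengths differ", call. = FALSE)
  if (length(q) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(F <= 0)) stop("intensities must be positive", call. = FALSE)
  if (F0 <= 0) stop("F0 must be positive", call. = FALSE)
  yy <- (F0 - F) / F
  fit <- stats::lm(yy ~ q)
  co <- stats::coef(fit)
  r2 <- .lm_r2(fit)
  ksv <- unname(co[2L])
  structure(list(K_sv = ksv,
                 k_q = if (is.na(tau0)) NA_real_ else ksv / tau0,
                 tau0 = tau0, intercept = unname(co[1L]), r_squared = r2),
            class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf("<stern_volmer_fit> K_sv = %.4g M^-1, intercept = %.3g, R2 = %.4f\n",
              x$K_sv, x$intercept, x$r_squared))
  if (!is.na(x$k_q)) cat(sprintf("  k_q = %.4g M^-1 s^-1 (tau0 = %.3g s)\n",
                                 x$k_q, x$tau0))
  invisible(x)
}

#' Double-logarithmic Hill association fit
#'
#' Regression of \eqn{\log_{10}((F_0 - F)/F)} on \eqn{\log_{10} [Q]}. The
#' slope is the Hill coefficient `n`. Two intercept conventions circulate in
#' the quenching literature; the classical form
#' \eqn{\log((F_0-F)/F) = \log K_a + n \log [Q]} (intercept = log10 K_a) is
#' the default, and `convention = "n_logK"` interprets the intercept as
#' `n * log10 K_a` instead.
#'
#' @param q Quencher concentrations in M, > 0.
#' @param F0 Unquenched intensity (scalar).
#' @param F Quenched intensities; points with `F >= F0` (enhancement) are
#'   dropped with a warning.
#' @param convention `"logK"` (default) or `"n_logK"`.
#' @return A list of class `log_hill_fit` with `K_a` (M^-1), `n`,
#'   `r_squared`, `convention`, `n_used` points.
#' @export
double_log_hill_fit <- function(q, F0, F,
                                convention = c("logK", "n_logK")) {
  convention <- match.arg(convention)
  q <- as.numeric(q); F <- as.numeric(F)
  if (length(q) != length(F)) stop("q and F lengths differ", call. = FALSE)
  if (any(q <= 0)) stop("quencher concentrations must be positive",
                        call. = FALSE)
  if (any(F <= 0)) stop("intensities must be positive", call. = FALSE)
  keep <- F < F0
  if (!all(keep)) {
    warning(sprintf("%d point(s) with F >= F0 excluded (no quenching)",
                    sum(!keep)))
  }
  q <- q[keep]; F <- F[keep]
  if (length(q) < 3L) stop("fewer than 3 usable quenching points",
                           call. = FALSE)
  lx <- log10(q)
  ly <- log10((F0 - F) / F)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  n <- unname(co[2L])
  ka <- if (convention == "logK") 10^unname(co[1L]) else
    10^(unname(co[1L]) / n)
  structure(list(K_a = ka, n = n, r_squared = .lm_r2(fit),
                 convention = convention, n_used = length(q)),
            class = "log_hill_fit")
}

#' @export
print.log_hill_fit <- function(x, ...) {
  cat(sprintf("<log_hill_fit> K_a = %.4g M^-1, n = %.3f, R2 = %.4f (%s)\n",
              x$K_a, x$n, x$r_squared, x$convention))
  invisible(x)
}

# R^2 without summary.lm's "essentially perfect fit" chatter on noiseless
# oracle data
.lm_r2 <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  ss <- sum((y - mean(y))^2)
  if (ss <= 0) return(NA_real_)
  1 - sum(stats::resid(fit)^2) / ss
}
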