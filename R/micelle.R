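# Micellization and morphology: pyrene I335/I332 ratiometry, CMC from a
# Boltzmann sigmoid, AFM surface roughness.

#' Pyrene excitation ratio I335/I332
#'
#' Pyrene's excitation peak shifts from 332 nm (aqueous) to 335 nm when the
#' probe partitions into a hydrophobic micellar core; the intensity ratio at
#' these two wavelengths therefore tracks micelle formation. Intensities are
#' read off each spectrum by linear interpolation at exactly 335 and 332 nm.
#'
#' @param series A [titration_series()] of excitation spectra covering at
#'   least 325-345 nm.
#' @param lambda_hydrophobic,lambda_aqueous Probe wavelengths in nm
#'   (defaults 335 and 332).
#' @return A data.frame of class `ratio_series` with columns
#'   `concentration` and `ratio`, plus the concentration `unit` attribute.
#' @export
pyrene_ratio <- function(series, lambda_hydrophobic = 335,
                         lambda_aqueous = 332) {
  stopifnot(inherits(series, "titration_series"))
  sps <- series$entries
  if (is.numeric(sps)) stop("pyrene_ratio needs spectra", call. = FALSE)
  ratio <- vapply(sps, function(s) {
    if (min(s$wavelengths) > min(lambda_aqueous, lambda_hydrophobic) ||
        max(s$wavelengths) < max(lambda_aqueous, lambda_hydrophobic)) {
      stop("spectrum does not cover the 332-335 nm probe window",
           call. = FALSE)
    }
    i335 <- stats::approx(s$wavelengths, s$values, lambda_hydrophobic)$y
    i332 <- stats::approx(s$wavelengths, s$values, lambda_aqueous)$y
    i335 / i332
  }, numeric(1))
  out <- data.frame(concentration = series$concentrations, ratio = ratio)
  attr(out, "unit") <- series$unit
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Critical micelle concentration from a sigmoidal ratio series
#'
#' Fits the Boltzmann sigmoid
#' \deqn{ratio(c) = lower + \frac{upper - lower}{1 + e^{(x_0 - c)/slope}}}
#' to the pyrene ratio curve. The default `"inflection"` method reports the
#' CMC as the sigmoid midpoint `x0`; the `"intersection"` method reports the
#' crossing of the low-concentration plateau with the tangent at `x0`
#' (`cmc = x0 - 2 * slope`), which some of the surfactant literature uses
#' instead and which always sits below the inflection.
#'
#' @param series A `ratio_series` (from [pyrene_ratio()]) or data.frame with
#'   columns `concentration` and `ratio`; >= 6 points spanning the
#'   transition.
#' @param method `"inflection"` or `"intersection"`.
#' @return A list of class `cmc_result` with `cmc`, `fit_params`
#'   (lower, upper, x0, slope), `method`, `r_squared`.
#' @export
cmc_fit <- function(series, method = c("inflection", "intersection")) {
  method <- match.arg(method)
  x <- as.numeric(series$concentration)
  y <- as.numeric(series$ratio)
  if (length(x) < 6L) stop("need at least 6 points", call. = FALSE)
  lower0 <- min(y); upper0 <- max(y)
  if (upper0 - lower0 <= 0) stop("no transition: flat ratio series",
                                 call. = FALSE)
  x0_0 <- x[which.min(abs(y - (lower0 + upper0) / 2))]
  dat <- data.frame(x = x, y = y)
  # multi-start over transition widths: a slope narrower than the grid
  # spacing is a step-function local minimum the optimizer cannot leave
  best <- NULL
  for (slope0 in diff(range(x)) / c(5, 10, 20, 50)) {
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ lower + (upper - lower) / (1 + exp((x0 - x) / slope)),
                 data = dat,
                 start = list(lower = lower0, upper = upper0, x0 = x0_0,
                              slope = slope0),
                 lower = c(lower = -Inf, upper = -Inf, x0 = min(x),
                           slope = 1e-6),
                 algorithm = "port",
                 # warnOnly: zero-residual (noiseless) data trips "singular
                 # convergence" at the true optimum; fit quality is judged
                 # by SSR and the R^2 gate instead
                 control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                              minFactor = 1e-12,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    stop("no-transition error: sigmoid fit failed from every start",
         call. = FALSE)
  }
  fit <- best$fit
  p <- as.list(stats::coef(fit))
  r2 <- 1 - best$ssr / sum((y - mean(y))^2)
  if (r2 < 0.8) {
    stop(sprintf("no-transition error: sigmoid fit R^2 = %.3f < 0.8", r2),
         call. = FALSE)
  }
  cmc <- if (method == "inflection") p$x0 else p$x0 - 2 * p$slope
  structure(list(cmc = cmc,
                 fit_params = list(lower = p$lower, upper = p$upper,
                                   x0 = p$x0, slope = p$slope),
                 method = method, r_squared = r2),
            class = "cmc_result")
}

#' @export
print.cmc_result <- function(x, ...) {
  cat(sprintf("<cmc_result> CMC = %.3g (%s method), R2 = %.4f\n", x$cmc,
              x$method, x$r_squared))
  invisible(x)
}

#' AFM surface roughness
#'
#' With \eqn{\bar z} the mean height of the map:
#' \deqn{R_a = \mathrm{mean}\,|z - \bar z|, \qquad
#'       R_q = \sqrt{\mathrm{mean}\,(z - \bar z)^2}}
#' `Rq >= Ra` always (quadratic vs absolute mean). Optional least-squares
#' plane detrending removes sample tilt before the statistics are taken;
#' it is off by default.
#'
#' @param map A [height_map()].
#' @param detrend Subtract the least-squares plane first? Default `FALSE`.
#' @return A list of class `roughness_result` with `Ra` and `Rq` in nm.
#' @export
#' @examples
#' roughness(height_map(matrix(c(0, 0, 3, 3), 2)))  # Ra = Rq = 1.5
roughness <- function(map, detrend = FALSE) {
  stopifnot(inherits(map, "height_map"))
  z <- map$heights
  if (detrend) {
    idx <- expand.grid(row = seq_len(nrow(z)), col = seq_len(ncol(z)))
    fit <- stats::lm(as.vector(z) ~ idx$row + idx$col)
    z <- matrix(stats::resid(fit), nrow(z), ncol(z))
  }
  d <- z - mean(z)
  structure(list(Ra = mean(abs(d)), Rq = sqrt(mean(d^2))),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("<roughness_result> Ra = %.3g nm, Rq = %.3g nm\n", x$Ra, x$Rq))
  invisible(x)
}
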