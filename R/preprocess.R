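#' Inner-filter correction of fluorescence intensities
#'
#' Re-absorption of excitation and emission light by the sample attenuates the
#' observed fluorescence. The standard first-order correction multiplies the
#' observed signal by `10^((A_ex + A_em)/2)`, where `A_ex` and `A_em` are the
#' sample absorbances at the excitation and emission wavelengths.
#'
#' @param f_obs Observed fluorescence (scalar, vector, or [spectrum()]).
#' @param a_ex Absorbance at the excitation wavelength (AU), >= 0.
#' @param a_em Absorbance at the emission wavelength (AU), >= 0. May be a
#'   vector matching `f_obs` when correcting a full spectrum.
#' @return Corrected fluorescence, same shape as `f_obs`.
#' @export
#' @examples
#' inner_filter_correct(100, 0.2, 0.1)  # 100 * 10^0.15
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0)) {
    stop("negative absorbance: baseline-correct absorbance upstream",
         call. = FALSE)
  }
  factor <- 10^((a_ex + a_em) / 2)
  if (inherits(f_obs, "spectrum")) {
    out <- f_obs
    out$values <- f_obs$values * factor
    return(out)
  }
  f_obs * factor
}

#' Peak position and width of a spectral band
#'
#' Locates the band maximum by parabolic interpolation through the three
#' points around the discrete maximum (so 1 nm sampling does not quantize
#' sub-nm shifts), and measures the full width at half maximum by linear
#' interpolation of the half-height crossings. The half-height baseline is
#' the spectrum minimum, not zero, so constant offsets do not inflate the
#' width.
#'
#' @param sp A [spectrum()] with a unique global maximum away from the grid
#'   edges.
#' @return A list of class `band_descriptor` with `lambda_max` (nm), `fwhm`
#'   (nm) and `peak_value` (spectrum units, baseline included).
#' @export
band_descriptor <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  w <- sp$wavelengths
  y <- sp$values
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    stop("band maximum lies at the grid edge", call. = FALSE)
  }
  # parabola through (w[i-1..i+1], y[i-1..i+1]); uniform grid not assumed
  x1 <- w[i - 1L]; x2 <- w[i]; x3 <- w[i + 1L]
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (a < 0) {
    lambda_max <- -b / (2 * a)
    c0 <- y2 - (a * x2^2 + b * x2)
    peak_value <- a * lambda_max^2 + b * lambda_max + c0
  } else {
    lambda_max <- x2
    peak_value <- y2
  }
  baseline <- min(y)
  half <- baseline + (peak_value - baseline) / 2
  # half-height crossings left and right of the peak index
  cross <- function(side) {
    idx <- if (side == "left") seq_len(i) else seq(i, length(y))
    yy <- y[idx]; ww <- w[idx]
    below <- yy < half
    runs <- which(diff(below) != 0L)
    if (!length(runs)) return(NA_real_)
    # crossing segments; pick the one nearest the peak
    if (side == "left") {
      if (length(runs) > 1L) {
        warning("multiple half-height crossings left of the peak; ",
                "using the one nearest the peak")
      }
      k <- runs[length(runs)]
    } else {
      if (length(runs) > 1L) {
        warning("multiple half-height crossings right of the peak; ",
                "using the one nearest the peak")
      }
      k <- runs[1L]
    }
    ww[k] + (half - yy[k]) * (ww[k + 1L] - ww[k]) / (yy[k + 1L] - yy[k])
  }
  left <- cross("left")
  right <- cross("right")
  if (is.na(left) || is.na(right)) {
    stop("half-height level is not crossed on both sides of the peak",
         call. = FALSE)
  }
  structure(list(lambda_max = lambda_max, fwhm = right - left,
                 peak_value = peak_value),
            class = "band_descriptor")
}

#' @export
print.band_descriptor <- function(x, ...) {
  cat(sprintf("<band_descriptor> lambda_max = %.2f nm, fwhm = %.2f nm\n",
              x$lambda_max, x$fwhm))
  invisible(x)
}

#' Locate isosbestic points in an absorbance titration
#'
#' An isosbestic point is a wavelength where all spectra of a two-state
#' titration cross: the absorbance stays constant while the band reshapes,
#' signalling equilibrium between exactly two absorbing species. The
#' detector flags wavelengths where the coefficient of variation of
#' absorbance across the series falls below `rel_tol` while the mean
#' absorbance exceeds 10 percent of the series maximum (excluding flat
#' baseline), then collapses contiguous runs to their centroid.
#'
#' @param series A [titration_series()] of at least 3 absorbance spectra on a
#'   common wavelength grid.
#' @param rel_tol Relative-variation threshold (coefficient of variation);
#'   default 0.02.
#' @return Numeric vector of isosbestic wavelengths (nm); empty if none.
#' @export
find_isosbestic <- function(series, rel_tol = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  sps <- series$entries
  if (is.numeric(sps) || length(sps) < 3L) {
    stop("need at least 3 spectra", call. = FALSE)
  }
  grid <- sps[[1L]]$wavelengths
  same <- vapply(sps, function(s) {
    length(s$wavelengths) == length(grid) &&
      all(abs(s$wavelengths - grid) < 1e-9)
  }, logical(1))
  if (!all(same)) stop("spectra do not share a common wavelength grid",
                       call. = FALSE)
  mat <- vapply(sps, function(s) s$values, numeric(length(grid)))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  cv <- ifelse(abs(mu) > 0, sdv / abs(mu), Inf)
  signal <- mu > 0.10 * max(mat)
  flag <- cv < rel_tol & signal
  if (any(signal) && all(flag[signal])) {
    warning("whole signal range is invariant: series is degenerate, ",
            "no isolated isosbestic point")
    return(numeric(0))
  }
  if (!any(flag)) return(numeric(0))
  # collapse contiguous runs, weighting each wavelength by 1/cv so the
  # centroid sits at the true crossing
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- numeric(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    wgt <- 1 / pmax(cv[idx], 1e-12)
    out <- c(out, sum(grid[idx] * wgt) / sum(wgt))
  }
  out
}

#' Band-shift profile of a titration
#'
#' Tracks the band maximum of each spectrum against titrant concentration,
#' giving the red-shift profile of an encapsulation titration, and estimates
#' the saturation concentration as the first concentration whose peak
#' position is within `plateau_tol` of the final plateau value.
#'
#' @param series A [titration_series()] of spectra.
#' @param plateau_tol Plateau tolerance in nm (default 0.5).
#' @return A data.frame with columns `concentration` and `lambda_max`, plus
#'   attribute `saturation` (NA for series shorter than 3).
#' @export
shift_profile <- function(series, plateau_tol = 0.5) {
  stopifnot(inherits(series, "titration_series"))
  sps <- series$entries
  if (is.numeric(sps)) stop("shift_profile needs spectra", call. = FALSE)
  lm <- vapply(sps, function(s) band_descriptor(s)$lambda_max, numeric(1))
  out <- data.frame(concentration = series$concentrations, lambda_max = lm)
  saturation <- NA_real_
  if (nrow(out) >= 3L) {
    plateau <- lm[length(lm)]
    hit <- which(abs(lm - plateau) <= plateau_tol)
    if (length(hit)) saturation <- out$concentration[hit[1L]]
  }
  attr(out, "saturation") <- saturation
  out
}
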