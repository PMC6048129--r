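#' Gaussian distance components
#'
#' One row per population of the sum-of-Gaussians distance model: a Gaussian
#' in inter-spin distance with center \eqn{R_j} (nm), full width at half
#' maximum FWHM\eqn{_j} (nm) and mole fraction \eqn{x_j}. The standard
#' deviation is derived as \eqn{\sigma_j = FWHM_j / (2\sqrt{2\ln 2})}.
#'
#' @param center centers, nm (vector)
#' @param fwhm full widths at half maximum, nm (recycled)
#' @param fraction mole fractions (recycled); must sum to 1 within 1e-6
#'   unless `normalize = TRUE`
#' @param normalize if TRUE, fractions are rescaled to sum to exactly 1
#' @return a `gaussian_components` data frame with columns `center`, `fwhm`,
#'   `fraction`, `sigma`
#' @examples
#' gaussian_components(c(2.6, 4.3), 1.0, c(0.15, 0.85))
#' @export
gaussian_components <- function(center, fwhm = 1.0, fraction = NULL,
                                normalize = FALSE) {
  n <- length(center)
  if (n == 0) stop("at least one component is required")
  fwhm <- rep_len(fwhm, n)
  if (is.null(fraction)) fraction <- rep(1 / n, n)
  fraction <- rep_len(fraction, n)
  if (any(center <= 0)) stop("component centers must be positive")
  if (any(fwhm <= 0)) stop("component widths must be positive")
  if (any(fraction < 0) || any(fraction > 1))
    stop("fractions must lie in [0, 1]")
  s <- sum(fraction)
  if (normalize) {
    fraction <- fraction / s
  } else if (abs(s - 1) > 1e-6) {
    stop(sprintf("fractions sum to %.8f, not 1 (use normalize = TRUE)", s))
  } else {
    fraction <- fraction / s
  }
  out <- data.frame(center = center, fwhm = fwhm, fraction = fraction,
                    sigma = fwhm_to_sigma(fwhm))
  class(out) <- c("gaussian_components", "data.frame")
  out
}

#' Convert FWHM to Gaussian standard deviation
#'
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}.
#' @param fwhm full width at half maximum
#' @return standard deviation, same units
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Convert Gaussian standard deviation to FWHM
#' @param sigma standard deviation
#' @return full width at half maximum, same units
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

#' @export
print.gaussian_components <- function(x, ...) {
  cat("Gaussian distance components:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Distance distribution on a uniform grid
#'
#' Probability density P(r) over inter-spin distance, normalized so the
#' trapezoidal integral over the grid equals 1.
#'
#' @param r strictly increasing uniform distance grid, nm
#' @param density non-negative density values, per nm
#' @param normalize renormalize to unit trapezoidal area (default TRUE)
#' @return a `distance_distribution` object (list with `r`, `density`)
#' @export
distance_distribution <- function(r, density, normalize = TRUE) {
  if (length(r) != length(density)) stop("r and density lengths differ")
  if (length(r) < 3) stop("distance grid too short")
  dr <- diff(r)
  if (any(dr <= 0)) stop("distance grid must be strictly increasing")
  if (max(abs(dr - dr[1])) > 1e-9) stop("distance grid must be uniform")
  if (any(density < -1e-12)) stop("density must be non-negative")
  density <- pmax(density, 0)
  area <- trapz_int(r, density)
  if (normalize) {
    if (area <= 0) stop("density has zero mass; cannot normalize")
    density <- density / area
  }
  structure(list(r = r, density = density),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  pk <- find_peaks(x)
  cat(sprintf("Distance distribution: %d points, %.2f-%.2f nm\n",
              length(x$r), min(x$r), max(x$r)))
  if (nrow(pk)) {
    cat("Modes:\n")
    print.data.frame(pk, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Homogeneous intermolecular background model
#'
#' Describes the DEER background \eqn{B(t) = \exp(-k t^{d/3})} from randomly
#' distributed remote spins (d = 3 gives a simple exponential) together with
#' the modulation depth \eqn{\lambda}, the fraction of the echo modulated by
#' the pumped partner spin.
#'
#' @param k decay rate, per us (per us^(d/3) when d != 3); >= 0
#' @param lambda modulation depth in [0, 1]
#' @param d background dimensionality in [1, 6]; default 3
#' @return a `background_model` object
#' @export
background_model <- function(k = 0.05, lambda = 0.3, d = 3) {
  if (k < 0) stop("decay rate k must be non-negative")
  if (lambda < 0 || lambda > 1) stop("modulation depth must be in [0, 1]")
  if (d < 1 || d > 6) stop("background dimension must be in [1, 6]")
  structure(list(k = k, lambda = lambda, d = d),
            class = "background_model")
}

#' Evaluate the background decay B(t)
#' @param bg a [background_model()]
#' @param t time, us
#' @return B(t) = exp(-k t^(d/3))
#' @export
background_decay <- function(bg, t) exp(-bg$k * t^(bg$d / 3))

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "Background model: k = %.4g /us, lambda = %.3f, dimension = %.2f\n",
    x$k, x$lambda, x$d))
  invisible(x)
}

#' DEER dipolar evolution trace
#'
#' @param time uniform time grid starting at 0, us
#' @param amplitude echo amplitude (normalized so amplitude at t = 0 is 1 for
#'   raw simulated traces, or the form factor for corrected traces)
#' @param stage "raw" or "corrected"
#' @param metadata free-form list of acquisition annotations
#' @return a `deer_trace` object
#' @export
deer_trace <- function(time, amplitude, stage = c("raw", "corrected"),
                       metadata = list()) {
  stage <- match.arg(stage)
  if (length(time) != length(amplitude)) stop("time/amplitude length mismatch")
  if (length(time) < 4) stop("trace too short")
  if (any(!is.finite(time)) || any(!is.finite(amplitude)))
    stop("non-finite values in trace")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time grid must be increasing")
  if (max(abs(dt - dt[1])) > 1e-9) stop("time grid must be uniform")
  if (abs(time[1]) > 1e-12) stop("time grid must start at t = 0")
  structure(list(time = time, amplitude = amplitude, stage = stage,
                 metadata = metadata),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("DEER trace (%s): %d points, dt = %.4g us, t_max = %.3f us\n",
              x$stage, length(x$time), x$time[2] - x$time[1], max(x$time)))
  invisible(x)
}

#' Continuous-wave EPR spectrum
#'
#' First-derivative absorption spectrum on a uniform magnetic-field grid.
#'
#' @param field field axis, Gauss, uniform
#' @param intensity first-derivative intensity
#' @param normalized logical; TRUE once the spectrum has been divided by its
#'   double integral (see [normalize_double_integral()])
#' @return a `cw_spectrum` object
#' @export
cw_spectrum <- function(field, intensity, normalized = FALSE) {
  if (length(field) != length(intensity)) stop("field/intensity mismatch")
  if (length(field) < 8) stop("spectrum too short")
  db <- diff(field)
  if (any(db <= 0)) stop("field grid must be increasing")
  if (max(abs(db - db[1])) > 1e-9) stop("field grid must be uniform")
  structure(list(field = field, intensity = intensity,
                 normalized = isTRUE(normalized)),
            class = "cw_spectrum")
}

#' @export
print.cw_spectrum <- function(x, ...) {
  cat(sprintf("CW spectrum: %d points, %.1f-%.1f G%s\n", length(x$field),
              min(x$field), max(x$field),
              if (x$normalized) ", double-integral normalized" else ""))
  invisible(x)
}
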