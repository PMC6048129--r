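#' Physical constants and unit conventions
#'
#' All internal computation uses nanometres for distance, microseconds for
#' time and Gauss for magnetic field; conversions happen only at I/O
#' boundaries.
#'
#' @section Dipolar constant:
#' The electron-electron dipolar coupling for a pair of free-electron-like
#' spins (g close to 2.0023) is \eqn{\nu_{dd}(r) = D / r^3} with
#' \eqn{D = 52.04} MHz nm\eqn{^3}. This single constant drives both the DEER
#' kernel and the CW Pake broadening and is defined in exactly one place.
#'
#' @name deerfit-constants
#' @keywords internal
NULL

# Dipolar constant, MHz * nm^3, for a free-electron-like spin pair.
DIPOLAR_MHZ_NM3 <- 52.04

# Isotropic nitroxide g value used for field <-> frequency conversion.
G_NITROXIDE <- 2.0056

# Bohr magneton / Planck constant, MHz per Gauss per unit g.
MHZ_PER_GAUSS_PER_G <- 1.3996245

#' Dipolar coupling frequency for an inter-spin distance
#'
#' @param r distance, nm (vector ok)
#' @return coupling \eqn{\nu_{dd} = D/r^3} in MHz
#' @keywords internal
dipolar_nu <- function(r) DIPOLAR_MHZ_NM3 / r^3

# Angular dipolar frequency in rad/us (MHz and us are reciprocal units).
dipolar_omega <- function(r) 2 * pi * dipolar_nu(r)

#' Convert a frequency in MHz to a field offset in Gauss
#'
#' Uses the isotropic nitroxide g value (2.0056).
#' @param mhz frequency, MHz
#' @return field offset, Gauss
#' @keywords internal
mhz_to_gauss <- function(mhz) mhz / (G_NITROXIDE * MHZ_PER_GAUSS_PER_G)

#' Trapezoidal quadrature weights for a uniform grid
#' @keywords internal
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("grid needs at least 2 points")
  h <- diff(x)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Trapezoidal integral
#' @keywords internal
trapz_int <- function(x, y) sum(trapz_weights(x) * y)
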