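#' Default distance and time grids
#'
#' The default distance grid spans 1-10 nm in 0.02 nm steps (forward
#' simulation); the default time step is 16 ns, matching typical four-pulse
#' DEER acquisition granularity.
#'
#' @param r_min,r_max,dr grid limits and step, nm
#' @return numeric grid
#' @export
default_r_grid <- function(r_min = 1, r_max = 10, dr = 0.02) {
  seq(r_min, r_max, by = dr)
}

#' @param t_max evolution time, us
#' @param dt time step, us (default 0.016 us = 16 ns)
#' @rdname default_r_grid
#' @export
default_time_grid <- function(t_max = 5, dt = 0.016) seq(0, t_max, by = dt)

#' Sum-of-Gaussians distance distribution on a grid
#'
#' Evaluates \eqn{P(R) = \sum_j x_j \rho_j(R)} with each \eqn{\rho_j} a
#' unit-area Gaussian of center \eqn{R_j} and width \eqn{\sigma_j} derived
#' from the FWHM, then renormalizes on the grid. If the grid clips more than
#' 0.1\% of the analytic mass a warning is issued before renormalizing.
#'
#' @param components a [gaussian_components()] table
#' @param r_grid uniform distance grid, nm
#' @return a [distance_distribution()]
#' @examples
#' gm <- gaussian_mixture(gaussian_components(4.3, 1.0, 1), default_r_grid())
#' gm$r[which.max(gm$density)]  # 4.3
#' @export
gaussian_mixture <- function(components, r_grid = default_r_grid()) {
  if (!inherits(components, "gaussian_components"))
    components <- gaussian_components(components$center, components$fwhm,
                                      components$fraction)
  dens <- rep(0, length(r_grid))
  mass_in <- 0
  for (j in seq_len(nrow(components))) {
    cj <- components$center[j]
    sj <- components$sigma[j]
    xj <- components$fraction[j]
    dens <- dens + xj * stats::dnorm(r_grid, cj, sj)
    mass_in <- mass_in +
      xj * (stats::pnorm(max(r_grid), cj, sj) - stats::pnorm(min(r_grid), cj, sj))
  }
  if (mass_in < 1 - 1e-3)
    warning(sprintf(
      "distance grid truncates %.2f%% of the mixture mass; renormalizing",
      100 * (1 - mass_in)))
  distance_distribution(r_grid, dens, normalize = TRUE)
}

#' Four-pulse DEER dipolar kernel
#'
#' Kernel matrix of the orientation-averaged dipolar modulation,
#' \deqn{K(t, r) = \int_0^1 \cos[(1 - 3z^2)\,\omega_{dd}(r)\,t]\,dz,}
#' with \eqn{\omega_{dd}(r) = 2\pi D / r^3} and D = 52.04 MHz nm^3. The
#' closed form uses Fresnel integrals; `method = "quadrature"` evaluates the
#' angular average by 1001-point Gauss-Legendre quadrature instead (the two
#' agree to better than 1e-6 and the quadrature route serves as a check).
#'
#' @param time time values, us (non-negative)
#' @param r_grid distances, nm (positive)
#' @param method "fresnel" (default) or "quadrature"
#' @return matrix of dim `length(time) x length(r_grid)`; every column is 1
#'   at t = 0
#' @export
dipolar_kernel <- function(time, r_grid, method = c("fresnel", "quadrature")) {
  method <- match.arg(method)
  if (!length(time) || !length(r_grid)) stop("empty time or distance grid")
  if (any(!is.finite(time))) stop("non-finite time values")
  if (any(r_grid <= 0)) stop("distances must be positive")
  K <- matrix(0, length(time), length(r_grid))
  if (method == "fresnel") {
    for (j in seq_along(r_grid)) {
      K[, j] <- kernel_column_fresnel(time, r_grid[j])
    }
  } else {
    gq <- pracma::gaussLegendre(1001, 0, 1)
    for (j in seq_along(r_grid)) {
      w <- dipolar_omega(r_grid[j])
      # cos((1 - 3 z^2) w t) averaged over z in [0, 1]
      phase <- outer(time * w, 1 - 3 * gq$x^2)
      K[, j] <- as.vector(cos(phase) %*% gq$w)
    }
  }
  dimnames(K) <- NULL
  K
}

# Closed-form kernel column via Fresnel integrals:
#   K(t) = [cos(wt) C(x) + sin(wt) S(x)] / x,  x = sqrt(6 w t / pi)
kernel_column_fresnel <- function(time, r) {
  w <- dipolar_omega(r)
  out <- numeric(length(time))
  tt <- abs(time)
  z <- tt < 1e-12
  out[z] <- 1
  if (any(!z)) {
    x <- sqrt(6 * w * tt[!z] / pi)
    out[!z] <- (cos(w * tt[!z]) * pracma::fresnelC(x) +
                sin(w * tt[!z]) * pracma::fresnelS(x)) / x
  }
  out
}

#' Simulate a DEER trace from a distance distribution
#'
#' Computes the form factor \eqn{F(t) = \int K(t,r) P(r)\,dr} and the full
#' signal \eqn{V(t) = [1 - \lambda + \lambda F(t)] B(t)} with the
#' homogeneous background \eqn{B(t) = \exp(-k t^{d/3})}.
#'
#' @param dist a [distance_distribution()]
#' @param time time grid, us, starting at 0
#' @param bg a [background_model()]
#' @param kernel optional precomputed kernel for (time, dist$r)
#' @return a raw-stage [deer_trace()], with the noiseless form factor stored
#'   in `metadata$form_factor`
#' @export
simulate_deer <- function(dist, time = default_time_grid(),
                          bg = background_model(), kernel = NULL) {
  stopifnot(inherits(dist, "distance_distribution"))
  if (abs(time[1]) > 1e-12) stop("time grid must start at 0")
  if (is.null(kernel)) kernel <- dipolar_kernel(time, dist$r)
  if (ncol(kernel) != length(dist$r) || nrow(kernel) != length(time))
    stop("kernel dimensions do not match distribution/time grids")
  Fm <- form_factor(kernel, dist)
  V <- (1 - bg$lambda + bg$lambda * Fm) * background_decay(bg, time)
  deer_trace(time, V, stage = "raw",
             metadata = list(form_factor = Fm, background = bg))
}

#' Form factor from a kernel and a distribution
#' @keywords internal
form_factor <- function(kernel, dist) {
  w <- trapz_weights(dist$r)
  as.vector(kernel %*% (w * dist$density))
}
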