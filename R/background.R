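#' Fit the intermolecular background of a raw DEER trace
#'
#' At times past the decay of the intramolecular form factor the signal
#' approaches \eqn{V(t) \approx (1-\lambda)\exp(-k t^{d/3})}, so both the
#' modulation depth and the decay rate are obtained by linear least squares
#' on the log amplitude over the tail window `[fit_start, t_max]` for fixed
#' dimension d. With `fit_dimension = TRUE` the dimensionality is profiled
#' over a grid and the best (d, k, lambda) returned.
#'
#' @param trace a raw [deer_trace()]
#' @param fit_start start of the fit window, us; default 1/3 of t_max
#'   (the latest 2/3 of the trace is fitted)
#' @param d background dimension held fixed (default 3)
#' @param fit_dimension profile d over `d_grid` instead of fixing it
#' @param d_grid dimensions scanned when `fit_dimension = TRUE`
#' @return a [background_model()] with attributes `fit_start`, `residual`
#'   (RMS of the log-domain residual) and `n_fit`
#' @export
fit_background <- function(trace, fit_start = NULL, d = 3,
                           fit_dimension = FALSE,
                           d_grid = seq(2, 4, by = 0.1)) {
  stopifnot(inherits(trace, "deer_trace"))
  t_max <- max(trace$time)
  if (is.null(fit_start)) fit_start <- t_max / 3
  if (fit_start <= 0 || fit_start >= t_max)
    stop("fit_start must lie strictly inside (0, t_max)")
  sel <- trace$time >= fit_start
  if (sum(sel) < 10) stop("fewer than 10 points in the background window")
  tt <- trace$time[sel]
  # normalize to the echo amplitude at t = 0 so the fit is scale-invariant
  vv <- trace$amplitude[sel] / trace$amplitude[1]
  if (any(vv <= 0))
    stop("non-positive amplitudes in fit window; cannot fit log background")

  fit_one <- function(dd) {
    x <- tt^(dd / 3)
    fit <- stats::lm.fit(cbind(1, x), log(vv))
    list(d = dd, k = max(0, -fit$coefficients[2]),
         lambda = min(1, max(0, 1 - exp(fit$coefficients[1]))),
         rss = sum(fit$residuals^2))
  }
  best <- if (fit_dimension) {
    cands <- lapply(d_grid, fit_one)
    cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
  } else {
    fit_one(d)
  }
  bg <- background_model(k = best$k, lambda = best$lambda, d = best$d)
  attr(bg, "fit_start") <- fit_start
  attr(bg, "residual") <- sqrt(best$rss / sum(sel))
  attr(bg, "n_fit") <- sum(sel)
  bg
}

#' Background-correct a DEER trace to its form factor
#'
#' Divides out the fitted background and removes the unmodulated fraction:
#' \eqn{\hat F(t) = (V(t)/B(t) - (1-\lambda))/\lambda}, rescaled so
#' \eqn{\hat F(0) = 1}.
#'
#' @param trace raw [deer_trace()]
#' @param bg fitted or supplied [background_model()]; `lambda` must be > 0
#' @return corrected-stage [deer_trace()] whose amplitude is the form factor
#' @export
correct_background <- function(trace, bg) {
  stopifnot(inherits(trace, "deer_trace"), inherits(bg, "background_model"))
  if (bg$lambda <= 0)
    stop("modulation depth is zero: no dipolar modulation to extract")
  B <- background_decay(bg, trace$time)
  Fhat <- (trace$amplitude / B - (1 - bg$lambda)) / bg$lambda
  if (abs(Fhat[1]) < 1e-12) stop("corrected form factor vanishes at t = 0")
  Fhat <- Fhat / Fhat[1]
  deer_trace(trace$time, Fhat, stage = "corrected",
             metadata = c(trace$metadata, list(correction_bg = bg)))
}

#' Estimate the noise level of a corrected trace
#'
#' Standard deviation of the residual after a second-order local polynomial
#' (Savitzky-Golay-style) smooth of the last-third tail, where the form
#' factor is nearly flat. Used for BIC scaling and uncertainty estimates.
#'
#' @param trace corrected [deer_trace()]
#' @param window odd smoothing window length (points)
#' @return noise standard deviation estimate
#' @export
estimate_noise <- function(trace, window = 11) {
  y <- trace$amplitude
  n <- length(y)
  tail_idx <- seq(max(1, floor(2 * n / 3)), n)
  yt <- y[tail_idx]
  if (length(yt) < window + 2) window <- max(5, (length(yt) %/% 2) * 2 - 1)
  sm <- sg_smooth(yt, window)
  stats::sd(yt - sm)
}

# Second-order Savitzky-Golay smooth by local quadratic regression.
sg_smooth <- function(y, window = 11) {
  n <- length(y)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    x <- (lo:hi) - i
    fit <- stats::lm.fit(cbind(1, x, x^2), y[lo:hi])
    out[i] <- fit$coefficients[1]
  }
  out
}
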