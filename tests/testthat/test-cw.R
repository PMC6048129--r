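field_grid_test <- function(step = 0.2) seq(3300, 3500, by = step)

test_that("double-integral normalization is scale invariant and exact", {
  fg <- field_grid_test()
  absorb <- dnorm(fg, 3400, 5)
  spec <- cw_spectrum(fg, pracma::gradient(absorb, fg[2] - fg[1]))
  n1 <- normalize_double_integral(spec)
  n2 <- normalize_double_integral(cw_spectrum(fg, 37 * spec$intensity))
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-12)
  expect_equal(double_integral(n1), 1, tolerance = 1e-6)
  expect_true(n1$normalized)
})

test_that("Pake kernel geometry: singularities at D/2, support to D", {
  fg <- field_grid_test(0.05)
  k <- pake_broadening(gaussian_components(1.2, 0.01, 1), fg,
                       n_theta = 8000, n_r = 3)
  D <- deerfit:::mhz_to_gauss(52.04 / 1.2^3)
  # maxima (perpendicular singularities) near +/- D/2
  peak_off <- abs(k$offset[which.max(k$value)])
  expect_equal(peak_off, D / 2, tolerance = 0.05 * D)
  # support ends at the parallel extreme D (plus binning width)
  w <- deerfit:::trapz_weights(k$offset)
  mass_beyond <- sum((w * k$value)[abs(k$offset) > 1.05 * D])
  expect_lt(mass_beyond, 1e-6)
  expect_equal(sum(w * k$value), 1, tolerance = 1e-6)
})

test_that("Pake second moment scales as r^-6", {
  fg <- field_grid_test(0.05)
  m2 <- function(r) {
    k <- pake_broadening(gaussian_components(r, 0.05, 1), fg,
                         n_theta = 4000, n_r = 5)
    sum(deerfit:::trapz_weights(k$offset) * k$value * k$offset^2)
  }
  expect_equal(m2(1.2) / m2(2.4), 64, tolerance = 0.01)
})

test_that("large distances collapse the kernel toward a delta", {
  fg <- field_grid_test(0.2)
  expect_warning(k <- pake_broadening(gaussian_components(5, 0.05, 1), fg),
                 "validity")
  w <- deerfit:::trapz_weights(k$offset)
  expect_gt(sum((w * k$value)[abs(k$offset) <= 0.4]), 0.999)
  expect_error(pake_broadening(gaussian_components(1.2, 0.05, 1),
                               fg, n_theta = 100)$value, NA)
})

test_that("dipolar convolution: identity, smoothing, conservation", {
  fx <- make_cw_fixture(gaussian_components(1.5, 0.2, 1), 0.6, snr = Inf)
  ref <- fx$noninteracting
  db <- ref$field[2] - ref$field[1]
  # delta kernel reproduces the input
  half <- 40
  delta <- structure(list(offset = seq(-half, half) * db,
                          value = c(rep(0, half), 1 / db, rep(0, half))),
                     class = "pake_kernel")
  ident <- convolve_dipolar(ref, delta)
  # integrate-then-differentiate applies a discrete [1,2,1]/4 smoothing, so
  # the identity holds to second order in the grid step
  expect_lt(max(abs(ident$intensity - ref$intensity)),
            0.02 * diff(range(ref$intensity)))

  k <- pake_broadening(gaussian_components(1.3, 0.2, 1), ref$field)
  br <- convolve_dipolar(ref, k)
  # broadening reduces the peak-to-peak derivative amplitude
  expect_lt(diff(range(br$intensity)), diff(range(ref$intensity)))
  # and conserves the double integral
  expect_equal(double_integral(br), double_integral(ref), tolerance = 1e-6)
})

test_that("CW distance fit recovers a planted coupled population", {
  # noiseless round trip is exact
  fx0 <- make_cw_fixture(gaussian_components(1.5, 0.2, 1), 0.6, snr = Inf)
  fit0 <- fit_cw_distance(fx0$coupled, fx0$noninteracting, 1,
                          n_restarts = 4, rng_seed = 1)
  expect_equal(fit0$components$center, 1.5, tolerance = 0.02)
  expect_equal(fit0$coupled_fraction, 0.6, tolerance = 0.02)

  # at SNR 100 the recovery holds across seeds on average
  runs <- vapply(1:5, function(s) {
    fx <- make_cw_fixture(gaussian_components(1.5, 0.2, 1), 0.6, snr = 100,
                          seed = s)
    fit <- fit_cw_distance(fx$coupled, fx$noninteracting, 1, n_restarts = 6,
                           rng_seed = s)
    c(fit$components$center, fit$coupled_fraction)
  }, numeric(2))
  expect_equal(mean(runs[1, ]), 1.5, tolerance = 0.1)
  expect_equal(mean(runs[2, ]), 0.6, tolerance = 0.1)
})

test_that("identical spectra yield a non-coupled result with a warning", {
  fx <- make_cw_fixture(gaussian_components(1.5, 0.2, 1), 0, snr = Inf)
  expect_warning(fit <- fit_cw_distance(fx$coupled, fx$noninteracting, 1,
                                        n_restarts = 2, rng_seed = 1),
                 "non-coupled")
  expect_equal(fit$coupled_fraction, 0)
})

test_that("minimal broadening is still distinguishable by SSR ratio", {
  fx <- make_cw_fixture(gaussian_components(1.9, 0.2, 1), 0.2, snr = 500,
                        seed = 3)
  fit <- fit_cw_distance(fx$coupled, fx$noninteracting, 1, n_restarts = 4,
                         rng_seed = 3)
  ssr_null <- sum((fx$coupled$intensity - fx$noninteracting$intensity)^2)
  expect_gt(ssr_null / fit$ssr, 1.05)
})

test_that("rotational correlation time follows the calibrated power law", {
  expect_equal(rotational_correlation_time(0, 32), 0.54, tolerance = 1e-12)
  expect_equal(rotational_correlation_time(16, 32), 0.54 * 2^1.36,
               tolerance = 1e-12)
  # strictly increasing in the splitting ratio
  taus <- vapply(seq(0.05, 0.95, by = 0.1) * 32,
                 rotational_correlation_time, 0, T_par_rigid = 32)
  expect_true(all(diff(taus) > 0))
  expect_warning(tau <- rotational_correlation_time(32, 32), "diverges")
  expect_identical(tau, Inf)
  expect_error(rotational_correlation_time(33, 32), "T_par_prime")
})

test_that("order parameter interpolates between motional limits", {
  expect_equal(order_parameter(32, 32, 8), 1)
  expect_equal(order_parameter(8, 32, 8), 0)
  expect_equal(order_parameter(20, 32, 8), 0.5)
  expect_warning(s <- order_parameter(6, 32, 8), "clipped")
  expect_equal(s, 0)
  expect_error(order_parameter(20, 8, 8), "fast-limit")
})
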