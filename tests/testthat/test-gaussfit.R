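test_that("noiseless single component is recovered to caption precision", {
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1), snr = Inf))
  bg <- background_model(k = 0.05, lambda = 0.3)
  ff <- correct_background(fx$trace, bg)
  fit <- fit_sum_of_gaussians(ff, 1, n_restarts = 4, rng_seed = 1)
  expect_equal(fit$components$center, 4.3, tolerance = 0.02 / 4.3)
  expect_equal(fit$components$fwhm, 1.0, tolerance = 0.02)
})

test_that("two-component fractions are recovered within 0.05 at SNR 50", {
  for (s in c(1, 2)) {
    fx <- make_deer_fixture(condition_fixture("apoCaM", snr = 50, seed = s))
    a <- analyze_deer(fx$trace, n_components = 2, n_restarts = 16,
                      rng_seed = s)
    cc <- a$fit$components
    expect_equal(cc$fraction[which.max(cc$center)], 0.85, tolerance = 0.05)
  }
})

test_that("nested models: one component fits two-component data worse", {
  fx <- make_deer_fixture(condition_fixture("apoCaM", snr = Inf))
  ff <- correct_background(fx$trace, background_model(k = 0.05, lambda = 0.3))
  f1 <- fit_sum_of_gaussians(ff, 1, n_restarts = 4, rng_seed = 1)
  f2 <- fit_sum_of_gaussians(ff, 2, n_restarts = 8, rng_seed = 1)
  expect_gt(f1$ssr, f2$ssr)
})

test_that("BIC model selection prefers the true order and matches the
           arithmetic definition", {
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1), snr = Inf))
  ff <- correct_background(fx$trace, background_model(k = 0.05, lambda = 0.3))
  fits <- lapply(1:2, function(nc)
    suppressWarnings(fit_sum_of_gaussians(ff, nc, n_restarts = 6,
                                          rng_seed = nc)))
  best <- select_model_bic(fits)
  expect_equal(best$n_components, 1)
  # independent BIC arithmetic
  for (f in fits) {
    p <- 3 * f$n_components - 1 + 2  # + depth scale and baseline slope
    bic_oracle <- f$n_points * log(f$ssr / f$n_points) + p * log(f$n_points)
    expect_equal(f$bic, bic_oracle, tolerance = 1e-10)
  }
  expect_error(select_model_bic(fits[1]), "at least 2")
})

test_that("fits are exchange-symmetric and bit-reproducible", {
  mk <- function(ord) {
    cond <- condition_fixture(
      "custom",
      components = gaussian_components(c(2.6, 4.3)[ord], 1,
                                       c(0.3, 0.7)[ord]),
      snr = Inf)
    fx <- make_deer_fixture(cond)
    ff <- correct_background(fx$trace,
                             background_model(k = 0.05, lambda = 0.3))
    fit_sum_of_gaussians(ff, 2, n_restarts = 6, rng_seed = 9)
  }
  f12 <- mk(1:2)
  f21 <- mk(2:1)
  expect_equal(f12$components$center, f21$components$center,
               tolerance = 1e-6)
  expect_equal(f12$components$fraction, f21$components$fraction,
               tolerance = 1e-6)
  # identical seed gives identical results
  f12b <- mk(1:2)
  expect_identical(f12$components, f12b$components)
  expect_identical(f12$ssr, f12b$ssr)
})

test_that("tiny components are pruned with a log entry", {
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1), snr = Inf))
  ff <- correct_background(fx$trace, background_model(k = 0.05, lambda = 0.3))
  fit <- suppressWarnings(fit_sum_of_gaussians(ff, 2, n_restarts = 8,
                                               rng_seed = 2))
  if (fit$n_components < 2) expect_match(paste(fit$log, collapse = " "),
                                         "pruned")
  expect_equal(sum(fit$components$fraction), 1, tolerance = 1e-6)
})

test_that("error surface: noiseless intervals are tight and match a brute
           force profile for one component", {
  dist <- gaussian_mixture(gaussian_components(4.0, 1, 1))
  bg <- background_model(k = 0, lambda = 0.5)
  tr <- simulate_deer(dist, default_time_grid(2.5, 0.032), bg)
  ff <- correct_background(tr, bg)
  seed_dist <- tikhonov_solve(ff, alpha = 0.05)
  fit <- fit_sum_of_gaussians(ff, 1, seed_dist, n_restarts = 4, rng_seed = 1,
                              fit_depth = FALSE)
  expect_lt(fit$ssr, 1e-6)
  es <- error_surface(fit, ff, n_steps = 6)
  cen <- es[es$parameter == "center", ]
  expect_lt(cen$upper - cen$lower, 0.5)
  expect_true(cen$bounded_lower && cen$bounded_upper)

  # brute-force check: SSR along the center profile crosses the threshold
  # outside the reported interval
  rg <- default_r_grid(dr = 0.05)
  K <- dipolar_kernel(ff$time, rg)
  w <- deerfit:::trapz_weights(rg)
  ssr_at <- function(cen_val, fwhm_val) {
    d <- deerfit:::mixture_density(list(center = cen_val, fwhm = fwhm_val,
                                        fraction = 1), rg)
    sum((ff$amplitude - as.vector(K %*% (w * d)))^2)
  }
  n <- fit$n_points; p <- 2
  thresh <- fit$ssr * (1 + qf(0.68, 1, n - p) / (n - p))
  # the profile scan step is 0.2 nm; probe safely beyond it
  fw_grid <- seq(0.7, 1.3, by = 0.05)
  outside <- min(vapply(fw_grid, function(fv)
    ssr_at(cen$upper + 0.3, fv), 0))
  expect_gt(outside, thresh)
})

test_that("near-limit short components carry wider center uncertainty", {
  run_one <- function(center) {
    cond <- condition_fixture(
      "custom", components = gaussian_components(center, 1, 1), snr = 20,
      seed = 5)
    fx <- suppressWarnings(make_deer_fixture(cond, default_time_grid(3.5)))
    ff <- correct_background(fx$trace,
                             background_model(k = 0.05, lambda = 0.3))
    fit <- fit_sum_of_gaussians(ff, 1, n_restarts = 4, rng_seed = 5)
    es <- error_surface(fit, ff, n_steps = 20, max_span = 0.67)
    cen <- es[es$parameter == "center", ]
    cen$upper - cen$lower
  }
  expect_gt(run_one(2.1), run_one(4.3))
})

test_that("time-domain fit and Tikhonov inversion agree on the mode center", {
  ff <- quick_form_factor(3.8, 1, 1, t_max = 4, dt = 0.016)
  rg <- default_r_grid(dr = 0.05)
  tik <- tikhonov_solve(ff, rg, alpha = 0.05)
  fit <- fit_sum_of_gaussians(ff, 1, tik, n_restarts = 4, rng_seed = 1)
  expect_lte(abs(rg[which.max(tik$density)] - fit$components$center), 0.1)
})
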