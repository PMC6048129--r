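test_that("background fit recovers a pure exponential exactly", {
  time <- default_time_grid(4)
  tr <- deer_trace(time, exp(-0.2 * time))
  bg <- fit_background(tr)
  expect_equal(bg$k, 0.2, tolerance = 1e-6)
  expect_equal(bg$lambda, 0, tolerance = 1e-6)
})

test_that("background fit round-trips the generator within 5%", {
  cond <- condition_fixture("custom",
                            components = gaussian_components(3.2, 0.8, 1),
                            background = background_model(k = 0.15,
                                                          lambda = 0.3),
                            snr = Inf)
  fx <- make_deer_fixture(cond, default_time_grid(5))
  bg <- fit_background(fx$trace, fit_start = 2)  # past the form-factor decay
  expect_equal(bg$k, 0.15, tolerance = 0.05)
  expect_equal(bg$lambda, 0.3, tolerance = 0.05 * 0.3)
})

test_that("background fit is scale-invariant and rejects short windows", {
  time <- default_time_grid(4)
  fx <- make_deer_fixture(condition_fixture("apoCaM", snr = Inf), time)
  bg1 <- fit_background(fx$trace)
  scaled <- deer_trace(time, 7.3 * fx$trace$amplitude)
  bg2 <- fit_background(scaled)
  expect_equal(bg1$k, bg2$k, tolerance = 1e-12)
  expect_equal(bg1$lambda, bg2$lambda, tolerance = 1e-12)

  short <- deer_trace(seq(0, 0.064, by = 0.016), rep(1, 5))
  expect_error(fit_background(short, fit_start = 0.01), "fewer than 10")
})

test_that("background correction inverts the forward model", {
  bg <- background_model(k = 0.1, lambda = 0.35)
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1),
    background = bg, snr = Inf))
  ff <- correct_background(fx$trace, bg)
  expect_equal(ff$stage, "corrected")
  expect_lt(max(abs(ff$amplitude - fx$truth$form_factor)), 1e-9)

  expect_error(correct_background(fx$trace, background_model(lambda = 0)),
               "modulation depth")
})

test_that("noisy correction round-trip keeps the form factor RMSE small", {
  bg <- background_model(k = 0.05, lambda = 0.6)
  dist <- gaussian_mixture(gaussian_components(4.3, 1, 1))
  time <- default_time_grid(4)
  clean <- simulate_deer(dist, time, bg)
  set.seed(42)
  noisy <- deer_trace(time, clean$amplitude + rnorm(length(time), sd = 0.005))
  ff <- correct_background(noisy, bg)
  rmse <- sqrt(mean((ff$amplitude - clean$metadata$form_factor)^2))
  expect_lt(rmse, 0.01)
})

test_that("correction then re-simulation reproduces the raw trace", {
  fx <- make_deer_fixture(condition_fixture("apoCaM", snr = 200, seed = 3))
  bg <- fit_background(fx$trace)
  ff <- correct_background(fx$trace, bg)
  resim <- (1 - bg$lambda + bg$lambda * ff$amplitude) *
    background_decay(bg, ff$time)
  noise_level <- 0.3 / 200
  expect_lt(sqrt(mean((resim - fx$trace$amplitude)^2)), 3 * noise_level)
})

test_that("noise estimate tracks the injected noise level", {
  fx <- make_deer_fixture(condition_fixture("apoCaM", snr = 50, seed = 5))
  bg <- background_model(k = 0.05, lambda = 0.3)
  ff <- correct_background(fx$trace, bg)
  est <- estimate_noise(ff)
  # corrected-domain noise is sigma_V / (lambda B(t)); compare at the tail
  expected <- (0.3 / 50) / (0.3 * exp(-0.05 * 4.2))
  expect_equal(est, expected, tolerance = 0.35)
})

test_that("stability validation passes a clean trace and needs >= 3 starts", {
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1), snr = Inf))
  rep <- validate_background(fx$trace,
                             fit_starts = seq(5 / 3, 3.75, length.out = 4))
  expect_s3_class(rep, "bg_stability_report")
  expect_false(any(rep$unstable))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$center, 4.3, tolerance = 0.1)

  expect_error(validate_background(fx$trace, fit_starts = c(2, 3)),
               "at least 3")
})

test_that("a mis-modeled background dimension flags unstable populations", {
  # truth is a sub-3D (d = 2.5) background; the d = 3 analysis model
  # cannot represent it, leaving slowly-decaying residue that shows up as
  # fit-start-dependent long-distance artifact mass
  cond <- condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1),
    background = background_model(k = 0.1, lambda = 0.3, d = 2.5),
    snr = Inf)
  fx <- make_deer_fixture(cond)
  rep <- validate_background(fx$trace,
                             fit_starts = seq(5 / 3, 3.75, length.out = 5),
                             min_fraction = 0.03)
  expect_true(any(rep$unstable))
  # the real 4.3 nm population stays stable; the artifacts sit beyond it
  expect_false(rep$unstable[which.min(abs(rep$center - 4.3))])
  expect_true(all(rep$center[rep$unstable] > 5))
})

test_that("suppression folds well-separated artifacts into the background", {
  # no flagged peaks: suppression is the plain correction
  fx <- make_deer_fixture(condition_fixture(
    "custom", components = gaussian_components(4.3, 1, 1), snr = Inf))
  bg <- fit_background(fx$trace)
  rep0 <- structure(
    data.frame(center = 4.3, center_sd = 0, fraction = 1,
               fraction_rel_range = 0, n_seen = 3, sd = 0.42,
               unstable = FALSE),
    class = c("bg_stability_report", "data.frame"))
  expect_equal(suppress_unstable(fx$trace, rep0, bg)$amplitude,
               correct_background(fx$trace, bg)$amplitude)

  # injected spurious long-distance component, flagged for suppression
  cond <- condition_fixture(
    "custom",
    components = gaussian_components(c(4.3, 8), c(1, 0.8), c(0.85, 0.15)),
    snr = Inf)
  fx2 <- make_deer_fixture(cond)
  bg2 <- background_model(k = 0.05, lambda = 0.3)
  rep <- structure(
    data.frame(center = c(4.3, 8), center_sd = c(0, 0.3),
               fraction = c(0.85, 0.15), fraction_rel_range = c(0.05, 2),
               n_seen = c(5, 5), sd = c(0.42, 0.34),
               unstable = c(FALSE, TRUE)),
    class = c("bg_stability_report", "data.frame"))
  ff <- suppress_unstable(fx2$trace, rep, bg2)
  fit <- fit_sum_of_gaussians(ff, 1, n_restarts = 4, rng_seed = 1)
  expect_equal(fit$components$center, 4.3, tolerance = 0.02)

  # flagged peak overlapping a stable peak is refused
  rep_bad <- structure(
    data.frame(center = c(4.3, 4.5), center_sd = c(0, 0.3),
               fraction = c(0.9, 0.1), fraction_rel_range = c(0.05, 2),
               n_seen = c(5, 5), sd = c(0.4, 0.4),
               unstable = c(FALSE, TRUE)),
    class = c("bg_stability_report", "data.frame"))
  expect_error(suppress_unstable(fx2$trace, rep_bad, bg2), "overlaps")
})
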