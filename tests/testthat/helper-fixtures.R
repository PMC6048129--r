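# Shared helpers for the test suite. All fixtures are generated in code.

# brute-force angular average of the dipolar modulation, midpoint rule
kernel_bruteforce <- function(time, r, n_z = 1e4) {
  w <- 2 * pi * 52.04 / r^3
  z <- (seq_len(n_z) - 0.5) / n_z
  vapply(time, function(t) mean(cos((1 - 3 * z^2) * w * t)), 0)
}

# short noiseless corrected form factor for fast unit tests
quick_form_factor <- function(centers = 4.3, fwhm = 1, fractions = 1,
                              t_max = 3, dt = 0.032, lambda = 0.4) {
  dist <- gaussian_mixture(gaussian_components(centers, fwhm, fractions,
                                               normalize = TRUE))
  bg <- background_model(k = 0.05, lambda = lambda)
  tr <- simulate_deer(dist, default_time_grid(t_max, dt), bg)
  correct_background(tr, bg)
}

# coarse grids keeping matrix sizes small
r_coarse <- function() default_r_grid(1.5, 8, dr = 0.1)

# run one condition fixture through the standard pipeline
run_condition <- function(name, seed, n_components = NULL,
                          max_components = 3, t_max = 5, snr = 50,
                          n_restarts = 16) {
  fx <- make_deer_fixture(condition_fixture(name, snr = snr, seed = seed),
                          default_time_grid(t_max))
  analyze_deer(fx$trace, n_components = n_components,
               max_components = max_components, n_restarts = n_restarts,
               rng_seed = seed)
}

# total mole fraction assigned to the state whose center is nearest
# (components may split one physical state into two sub-Gaussians)
state_fraction <- function(components, state_center, other_centers) {
  d_self <- abs(components$center - state_center)
  d_other <- sapply(components$center, function(cc)
    min(abs(cc - other_centers)))
  sum(components$fraction[d_self < d_other])
}
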