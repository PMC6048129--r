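#' Built-in experimental condition fixtures
#'
#' The four calmodulin conditions used throughout the package's validation,
#' each a mixture of the compact (2.6 nm), closed (4.3 nm) and open (5.7 nm)
#' lobe-to-lobe states with the reported mole fractions:
#' \itemize{
#'   \item `apoCaM`: closed 85% / compact 15%
#'   \item `CaCaM`: compact 29% / closed 28% / open 44% (renormalized to 1)
#'   \item `apoCaM_RyRp`: compact 75% / closed 25%
#'   \item `CaCaM_RyRp`: compact 97% / closed 3%
#' }
#' All components default to FWHM 1.0 nm. The `CaCaM` fractions as reported
#' sum to 1.01 and are renormalized (noted in the fixture's `note` field).
#'
#' @param name one of "apoCaM", "CaCaM", "apoCaM_RyRp", "CaCaM_RyRp", or
#'   "custom" (then `components` must be given)
#' @param components [gaussian_components()] for `name = "custom"`, or to
#'   override the built-in set
#' @param background a [background_model()]; default lambda 0.3,
#'   k 0.05 /us, d 3
#' @param snr amplitude-to-noise-sigma ratio (Inf = noiseless)
#' @param seed integer RNG seed stored with the fixture
#' @param fwhm width applied to built-in components, nm
#' @return a `condition_fixture` list: `name`, `components`, `background`,
#'   `snr`, `seed`, `note`
#' @export
condition_fixture <- function(name = c("apoCaM", "CaCaM", "apoCaM_RyRp",
                                       "CaCaM_RyRp", "custom"),
                              components = NULL,
                              background = background_model(k = 0.05,
                                                            lambda = 0.3),
                              snr = 50, seed = 1, fwhm = 1.0) {
  name <- match.arg(name)
  if (snr <= 0) stop("snr must be positive (use Inf for noiseless)")
  note <- NULL
  if (is.null(components)) {
    components <- switch(name,
      apoCaM = gaussian_components(c(2.6, 4.3), fwhm, c(0.15, 0.85)),
      CaCaM = {
        note <- "reported fractions 29/28/44 sum to 1.01; renormalized"
        gaussian_components(c(2.6, 4.3, 5.7), fwhm, c(0.29, 0.28, 0.44),
                            normalize = TRUE)
      },
      apoCaM_RyRp = gaussian_components(c(2.6, 4.3), fwhm, c(0.75, 0.25)),
      CaCaM_RyRp = gaussian_components(c(2.6, 4.3), fwhm, c(0.97, 0.03)),
      custom = stop("custom condition requires a components table"))
  }
  structure(list(name = name, components = components,
                 background = background, snr = snr, seed = seed,
                 note = note),
            class = "condition_fixture")
}

#' @export
print.condition_fixture <- function(x, ...) {
  cat(sprintf("Condition fixture '%s' (SNR %s, seed %d)\n", x$name,
              format(x$snr), x$seed))
  print(x$components)
  print(x$background)
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' Generate a synthetic raw DEER trace with known ground truth
#'
#' Simulates the forward model for the condition's Gaussian mixture and
#' background, then adds white Gaussian noise. The SNR is quoted against the
#' dipolar modulation amplitude (the part of the echo that carries distance
#' information): the noise standard deviation is
#' `lambda * V(0) / snr` (falling back to `V(0)/snr` when lambda = 0).
#' Deterministic for a fixed seed.
#'
#' @param condition a [condition_fixture()]
#' @param time time grid, us (default 5 us evolution, 16 ns steps)
#' @param r_grid distance grid for the forward simulation
#' @return list with `trace` (raw [deer_trace()]) and `truth` (the
#'   condition plus the noiseless signal and form factor)
#' @export
make_deer_fixture <- function(condition, time = default_time_grid(),
                              r_grid = default_r_grid()) {
  stopifnot(inherits(condition, "condition_fixture"))
  dist <- gaussian_mixture(condition$components, r_grid)
  clean <- simulate_deer(dist, time, condition$background)
  amp <- clean$amplitude
  if (is.finite(condition$snr)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(condition$seed)
    lam <- condition$background$lambda
    noise_ref <- if (lam > 0) lam * amp[1] else amp[1]
    amp <- amp + stats::rnorm(length(amp), sd = noise_ref / condition$snr)
  }
  trace <- deer_trace(time, amp, stage = "raw",
                      metadata = list(condition = condition$name,
                                      seed = condition$seed,
                                      snr = condition$snr))
  list(trace = trace,
       truth = list(condition = condition, distribution = dist,
                    clean_signal = clean$amplitude,
                    form_factor = clean$metadata$form_factor))
}

#' Generate a synthetic dipolar CW-EPR fixture with known ground truth
#'
#' Builds a rigid-limit nitroxide-like reference spectrum (three Gaussian
#' absorption lines at 0 and +/- 35.2 G from the sweep center, widths
#' 1.4/1.1/1.6 G — fixed synthetic parameters chosen so the intrinsic
#' linewidth does not mask the Pake splitting, not a slow-motion
#' simulation), broadens it with the Pake kernel of the requested distance
#' components, mixes broadened and unbroadened populations, adds white
#' noise, and double-integral normalizes both spectra.
#'
#' @param r_components [gaussian_components()] in the 0.8-2.5 nm CW range
#' @param coupled_fraction fraction of spins experiencing the dipolar
#'   coupling, in [0, 1]
#' @param snr peak-signal to noise-sigma ratio (Inf = noiseless)
#' @param seed integer RNG seed
#' @param field_grid field axis, Gauss (default 200 G sweep, 0.25 G step)
#' @return list with `coupled`, `noninteracting` (both normalized
#'   [cw_spectrum()]) and `truth`
#' @export
make_cw_fixture <- function(r_components, coupled_fraction, snr = 100,
                            seed = 1,
                            field_grid = seq(3300, 3500, by = 0.25)) {
  if (coupled_fraction < 0 || coupled_fraction > 1)
    stop("coupled_fraction must be in [0, 1]")
  if (any(r_components$center < 0.8 | r_components$center > 2.5))
    stop("CW fixture distances must lie in 0.8-2.5 nm")
  center_b <- mean(range(field_grid))
  # synthetic rigid-limit-like triplet (documented fixed parameters)
  absorb <- 0.35 * stats::dnorm(field_grid, center_b - 35.2, 1.4) +
    0.30 * stats::dnorm(field_grid, center_b, 1.1) +
    0.35 * stats::dnorm(field_grid, center_b + 35.2, 1.6)
  db <- field_grid[2] - field_grid[1]
  ref <- cw_spectrum(field_grid, pracma::gradient(absorb, db))
  ref <- normalize_double_integral(ref)
  kern <- pake_broadening(r_components, field_grid)
  broadened <- convolve_dipolar(ref, kern)
  mixed <- (1 - coupled_fraction) * ref$intensity +
    coupled_fraction * broadened$intensity
  if (is.finite(snr)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
    sdn <- max(abs(mixed)) / snr
    mixed <- mixed + stats::rnorm(length(mixed), sd = sdn)
    refn <- ref$intensity +
      stats::rnorm(length(mixed), sd = max(abs(ref$intensity)) / snr)
  } else {
    refn <- ref$intensity
  }
  coupled <- normalize_double_integral(cw_spectrum(field_grid, mixed))
  nonint <- normalize_double_integral(cw_spectrum(field_grid, refn))
  list(coupled = coupled, noninteracting = nonint,
       truth = list(components = r_components,
                    coupled_fraction = coupled_fraction,
                    snr = snr, seed = seed))
}

#' Write a DEER fixture to disk
#'
#' Emits the ASCII trace (see [write_trace()]) and a JSON ground-truth
#' sidecar `<path>.truth.json`.
#'
#' @param fixture result of [make_deer_fixture()]
#' @param path output trace path
#' @return invisibly, the two paths written
#' @export
write_deer_fixture <- function(fixture, path) {
  write_trace(fixture$trace, path)
  truth <- fixture$truth
  side <- paste0(path, ".truth.json")
  jsonlite::write_json(list(
    condition = truth$condition$name,
    components = as.data.frame(truth$condition$components),
    background = truth$condition$background[c("k", "lambda", "d")],
    snr = truth$condition$snr, seed = truth$condition$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
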