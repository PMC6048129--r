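#' Multistart sum-of-Gaussians fit of a DEER form factor
#'
#' Fits the corrected waveform in the time domain: the model form factor is
#' the kernel image of a sum-of-Gaussians distance distribution, and the
#' component centers, FWHMs and mole fractions are optimized by
#' Levenberg-Marquardt least squares. Robustness against local minima comes
#' from multistart: the initialization is taken from the (typically
#' Tikhonov) seed distribution and re-drawn `n_restarts` times with 10%
#' Gaussian perturbations; the best-of-restarts fit is returned. Fractions
#' are parameterized on the simplex (stick-breaking), centers are bounded to
#' [1.5, 9] nm and FWHMs to [0.2, 3] nm.
#'
#' @param form_factor corrected-stage [deer_trace()]
#' @param n_components number of Gaussian components (1-5)
#' @param seed_distribution [distance_distribution()] used to initialize
#'   centers/widths/fractions (its modes); optional
#' @param n_restarts number of perturbed restarts (default 32)
#' @param rng_seed integer seed making the whole fit reproducible
#' @param r_grid distance grid on which the model distribution is evaluated
#' @param kernel optional precomputed kernel for (time, r_grid)
#' @param prune_below components with fraction below this are removed and
#'   the rest renormalized (logged in `$log`)
#' @param fit_depth also float a modulation-depth rescale \eqn{\Lambda} and
#'   a linear baseline slope c, i.e. fit
#'   \eqn{1 - \Lambda + \Lambda (K P)(t) + c t}: to first order these two
#'   nuisance parameters absorb residual errors in the background-stage
#'   modulation depth and decay rate without biasing the Gaussian shape
#'   parameters (default TRUE)
#' @return a `gaussian_fit` object: list with `components`
#'   ([gaussian_components()], sorted by ascending center, ties broken wider
#'   first), `rmsd`, `ssr`, `bic`, `n_restarts`, `seed`, `fitted` (model
#'   form factor), `log`
#' @export
fit_sum_of_gaussians <- function(form_factor, n_components,
                                 seed_distribution = NULL, n_restarts = 32,
                                 rng_seed = 1,
                                 r_grid = default_r_grid(dr = 0.05),
                                 kernel = NULL, prune_below = 0.01,
                                 fit_depth = TRUE) {
  stopifnot(inherits(form_factor, "deer_trace"))
  if (form_factor$stage != "corrected")
    stop("fit_sum_of_gaussians expects a background-corrected trace")
  if (n_components < 1 || n_components > 5)
    stop("n_components must be between 1 and 5")
  if (is.null(kernel)) kernel <- dipolar_kernel(form_factor$time, r_grid)
  Fobs <- form_factor$amplitude
  w_r <- trapz_weights(r_grid)
  log_msgs <- character(0)

  # initial physical parameters from the seed distribution's modes
  init <- gaussfit_init(seed_distribution, n_components, r_grid)
  if (!is.null(seed_distribution)) {
    npk <- nrow(find_peaks(seed_distribution, threshold = 0.05))
    if (n_components > npk) {
      warning(sprintf("n_components (%d) exceeds seed peak count (%d)",
                      n_components, npk))
      log_msgs <- c(log_msgs, "n_components exceeds seed peak count")
    }
  }

  n_shape <- 3 * n_components - 1
  resid_fn <- function(p) {
    ph <- unpack_params(p, n_components)
    dens <- mixture_density(ph, r_grid)
    Fm <- as.vector(kernel %*% (w_r * dens))
    if (fit_depth)
      Fm <- 1 - p[n_shape + 1] + p[n_shape + 1] * Fm +
        p[n_shape + 2] * form_factor$time
    Fobs - Fm
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(rng_seed)

  lower <- pack_bounds(n_components)$lower
  upper <- pack_bounds(n_components)$upper
  if (fit_depth) { lower <- c(lower, 0.3, -0.2); upper <- c(upper, 3, 0.2) }
  best <- NULL
  n_fail <- 0
  for (s in seq_len(max(1, n_restarts))) {
    p0 <- pack_params(perturb_init(init, relative = if (s == 1) 0 else 0.1),
                      lower[seq_len(n_shape)], upper[seq_len(n_shape)])
    if (fit_depth)
      p0 <- c(p0, if (s == 1) 1 else
        min(max(1 + 0.1 * stats::rnorm(1), 0.3), 3), 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1; next }
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-14)
      best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("all restarts failed to converge")
  ph <- unpack_params(best$par[seq_len(n_shape)], n_components)
  depth_scale <- if (fit_depth) best$par[n_shape + 1] else 1
  baseline_slope <- if (fit_depth) best$par[n_shape + 2] else 0

  # prune negligible components and renormalize
  keep <- ph$fraction >= prune_below
  if (!all(keep)) {
    log_msgs <- c(log_msgs, sprintf(
      "pruned %d component(s) below fraction %.3g", sum(!keep), prune_below))
    ph <- lapply(ph, `[`, keep)
    ph$fraction <- ph$fraction / sum(ph$fraction)
  }
  # sort ascending by center; ties broken wider first
  ord <- order(ph$center, -ph$fwhm)
  comps <- gaussian_components(ph$center[ord], ph$fwhm[ord],
                               ph$fraction[ord], normalize = TRUE)
  dens <- mixture_density(ph, r_grid)
  fitted <- as.vector(kernel %*% (w_r * dens))
  fitted <- 1 - depth_scale + depth_scale * fitted +
    baseline_slope * form_factor$time
  n <- length(Fobs)
  p_free <- 3 * nrow(comps) - 1 + 2 * as.integer(fit_depth)
  ssr <- sum((Fobs - fitted)^2)
  structure(list(components = comps, ssr = ssr, rmsd = sqrt(ssr / n),
                 bic = bic_from_ssr(ssr, n, p_free),
                 n_components = nrow(comps), n_restarts = n_restarts,
                 depth_scale = depth_scale, baseline_slope = baseline_slope,
                 fit_depth = fit_depth,
                 seed = rng_seed, n_points = n, fitted = fitted,
                 r_grid = r_grid, failed_restarts = n_fail, log = log_msgs),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Sum-of-Gaussians fit: %d component(s), RMSD %.3e, BIC %.1f\n",
              x$n_components, x$rmsd, x$bic))
  print(x$components)
  invisible(x)
}

#' Bayesian information criterion from a residual sum of squares
#'
#' \eqn{BIC = n \ln(SSR/n) + p \ln n} for a Gaussian-error least-squares fit
#' with p free parameters.
#'
#' @param ssr residual sum of squares
#' @param n number of data points
#' @param p number of free parameters (3 per Gaussian component minus 1 for
#'   the fraction constraint)
#' @return BIC value
#' @export
bic_from_ssr <- function(ssr, n, p) n * log(ssr / n) + p * log(n)

#' Select the model order by BIC
#'
#' Among fits of the same data with consecutive component counts, returns
#' the fit minimizing the BIC. If a Tikhonov RMSD is supplied, fits whose
#' RMSD exceeds `rmsd_factor` times it are rejected first (the parametric
#' model must do about as well as the model-free inversion).
#'
#' @param fits list of `gaussian_fit` objects on identical data
#' @param tikhonov_rmsd optional model-free reference RMSD
#' @param rmsd_factor acceptance factor (default 1.1)
#' @return the selected `gaussian_fit`, with a `bic_table` attribute
#' @export
select_model_bic <- function(fits, tikhonov_rmsd = NULL, rmsd_factor = 1.1) {
  if (length(fits) < 2) stop("need at least 2 candidate model orders")
  n_pts <- vapply(fits, `[[`, 0, "n_points")
  if (length(unique(n_pts)) != 1) stop("fits are not on identical data")
  tab <- data.frame(
    n_components = vapply(fits, `[[`, 0, "n_components"),
    rmsd = vapply(fits, `[[`, 0, "rmsd"),
    bic = vapply(fits, `[[`, 0, "bic"))
  tab$accepted <- if (is.null(tikhonov_rmsd)) TRUE else
    tab$rmsd <= rmsd_factor * tikhonov_rmsd
  cand <- which(tab$accepted)
  if (!length(cand)) {
    warning("no fit reaches the Tikhonov RMSD criterion; using best BIC overall")
    cand <- seq_len(nrow(tab))
  }
  best <- cand[which.min(tab$bic[cand])]
  out <- fits[[best]]
  attr(out, "bic_table") <- tab
  out
}

#' Error-surface uncertainty intervals for a Gaussian fit
#'
#' For each parameter (center, FWHM, fraction of every component) profiles
#' the residual sum of squares: the parameter is stepped over a grid about
#' its optimum, all other parameters refit, and the interval reported where
#' \eqn{SSR \le SSR_{min}(1 + \Delta)} with
#' \eqn{\Delta = F(level; 1, n-p)/(n-p)}. Intervals are asymmetric; a side
#' that reaches its bound before crossing the threshold is reported as
#' unbounded on that side.
#'
#' @param fit a converged `gaussian_fit`
#' @param form_factor the corrected trace that was fit
#' @param level confidence level (default 0.68)
#' @param n_steps profile steps per side
#' @param max_span scan span per side, as multiples of a heuristic scale
#' @return data frame with columns `component`, `parameter`, `estimate`,
#'   `lower`, `upper`, `bounded_lower`, `bounded_upper`
#' @export
error_surface <- function(fit, form_factor, level = 0.68, n_steps = 8,
                          max_span = 4) {
  stopifnot(inherits(fit, "gaussian_fit"))
  n <- fit$n_points
  p <- 3 * fit$n_components - 1 + 2 * as.integer(isTRUE(fit$fit_depth))
  dfree <- max(n - p, 1)
  thresh <- fit$ssr * (1 + stats::qf(level, 1, dfree) / dfree)
  r_grid <- fit$r_grid
  kernel <- dipolar_kernel(form_factor$time, r_grid)
  w_r <- trapz_weights(r_grid)
  Fobs <- form_factor$amplitude
  nc <- fit$n_components
  ph0 <- list(center = fit$components$center, fwhm = fit$components$fwhm,
              fraction = fit$components$fraction)
  use_nuis <- isTRUE(fit$fit_depth)
  nuis0 <- c(fit$depth_scale, fit$baseline_slope)

  profile_ssr <- function(which_par, j, value) {
    # fix one physical parameter of component j, refit all others; for a
    # fraction the component is permuted to the front so the fixed fraction
    # is exactly the first stick-breaking weight
    ph <- ph0
    if (which_par == "fraction") {
      perm <- c(j, setdiff(seq_len(nc), j))
      ph <- lapply(ph, `[`, perm)
      others <- seq_len(nc)[-1]
      ph$fraction[others] <- ph$fraction[others] /
        max(sum(ph$fraction[others]), 1e-12) * (1 - value)
      ph$fraction[1] <- value
      jj <- 1L
    } else {
      ph[[which_par]][j] <- value
      jj <- j
    }
    free <- free_param_spec(which_par, jj, nc)
    n_free_shape <- sum(free$keep)
    res_fn <- function(q) {
      ph2 <- apply_free_params(ph, q[seq_len(n_free_shape)], free,
                               which_par, jj)
      Fm <- as.vector(kernel %*% (w_r * mixture_density(ph2, r_grid)))
      if (use_nuis) {
        lam <- q[n_free_shape + 1]; slope <- q[n_free_shape + 2]
        Fm <- 1 - lam + lam * Fm + slope * form_factor$time
      }
      Fobs - Fm
    }
    q0 <- extract_free_params(ph, free)
    lo <- free$lower; hi <- free$upper
    if (use_nuis) {
      q0 <- c(q0, nuis0); lo <- c(lo, 0.3, -0.2); hi <- c(hi, 3, 0.2)
    }
    if (!length(q0)) return(sum(res_fn(numeric(0))^2))
    ft <- tryCatch(minpack.lm::nls.lm(q0, lower = lo, upper = hi,
                                      fn = res_fn,
                                      control = minpack.lm::nls.lm.control(maxiter = 100)),
                   error = function(e) NULL)
    if (is.null(ft)) Inf else sum(ft$fvec^2)
  }

  bounds <- list(center = c(1.5, 9), fwhm = c(0.2, 3), fraction = c(0, 1))
  scale0 <- list(center = 0.3, fwhm = 0.3, fraction = 0.15)
  rows <- list()
  for (par in c("center", "fwhm", "fraction")) {
    for (j in seq_len(nc)) {
      if (par == "fraction" && nc == 1) next
      est <- ph0[[par]][j]
      out <- c(lower = est, upper = est, blo = TRUE, bup = TRUE)
      for (side in c(-1, 1)) {
        lim <- if (side < 0) bounds[[par]][1] else bounds[[par]][2]
        grid <- est + side * seq_len(n_steps) / n_steps *
          min(max_span * scale0[[par]], abs(lim - est))
        grid <- grid[grid >= bounds[[par]][1] & grid <= bounds[[par]][2]]
        crossed <- FALSE
        last_ok <- est
        for (v in grid) {
          if (profile_ssr(par, j, v) > thresh) { crossed <- TRUE; break }
          last_ok <- v
        }
        if (side < 0) {
          out["lower"] <- last_ok; out["blo"] <- crossed
        } else {
          out["upper"] <- last_ok; out["bup"] <- crossed
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        component = j, parameter = par, estimate = est,
        lower = out[["lower"]], upper = out[["upper"]],
        bounded_lower = as.logical(out[["blo"]]),
        bounded_upper = as.logical(out[["bup"]]))
    }
  }
  do.call(rbind, rows)
}

## ---- internal parameterization helpers ----

# physical params <-> optimizer vector:
#   centers (nc), fwhms (nc), stick-breaking thetas (nc - 1), all box-bounded
pack_bounds <- function(nc) {
  list(lower = c(rep(1.5, nc), rep(0.2, nc), rep(1e-4, max(nc - 1, 0))),
       upper = c(rep(9, nc), rep(3, nc), rep(1 - 1e-4, max(nc - 1, 0))))
}

pack_params <- function(ph, lower, upper) {
  nc <- length(ph$center)
  th <- fractions_to_sticks(ph$fraction)
  p <- c(ph$center, ph$fwhm, th)
  pmin(pmax(p, lower), upper)
}

unpack_params <- function(p, nc) {
  center <- p[seq_len(nc)]
  fwhm <- p[nc + seq_len(nc)]
  th <- if (nc > 1) p[2 * nc + seq_len(nc - 1)] else numeric(0)
  list(center = center, fwhm = fwhm, fraction = sticks_to_fractions(th, nc))
}

fractions_to_sticks <- function(x) {
  nc <- length(x)
  if (nc == 1) return(numeric(0))
  th <- numeric(nc - 1)
  rem <- 1
  for (i in seq_len(nc - 1)) {
    th[i] <- if (rem > 1e-12) x[i] / rem else 0.5
    rem <- rem - x[i]
  }
  pmin(pmax(th, 1e-4), 1 - 1e-4)
}

sticks_to_fractions <- function(th, nc) {
  if (nc == 1) return(1)
  x <- numeric(nc)
  rem <- 1
  for (i in seq_len(nc - 1)) {
    x[i] <- th[i] * rem
    rem <- rem - x[i]
  }
  x[nc] <- rem
  x / sum(x)
}

mixture_density <- function(ph, r_grid) {
  dens <- rep(0, length(r_grid))
  for (j in seq_along(ph$center))
    dens <- dens + ph$fraction[j] *
      stats::dnorm(r_grid, ph$center[j], fwhm_to_sigma(ph$fwhm[j]))
  # renormalize on grid so F(0) = 1 holds even for edge components
  a <- trapz_int(r_grid, dens)
  if (a > 0) dens / a else dens
}

gaussfit_init <- function(seed_distribution, nc, r_grid = NULL) {
  if (!is.null(seed_distribution)) {
    pk <- find_peaks(seed_distribution, threshold = 0.02)
    # grid-edge maxima are classic inversion artifacts, not trustworthy seeds
    if (!is.null(r_grid) && nrow(pk)) {
      edge <- pk$center <= min(r_grid) + 0.25 | pk$center >= max(r_grid) - 0.25
      if (any(!edge)) pk <- pk[!edge, , drop = FALSE]
    }
    pk <- pk[order(-pk$fraction), , drop = FALSE]
  } else {
    pk <- data.frame(center = numeric(0), fraction = numeric(0),
                     sd = numeric(0))
  }
  n_have <- min(nrow(pk), nc)
  center <- fwhm <- fraction <- numeric(nc)
  if (n_have) {
    center[seq_len(n_have)] <- pk$center[seq_len(n_have)]
    fwhm[seq_len(n_have)] <- pmin(pmax(sigma_to_fwhm(pk$sd[seq_len(n_have)]),
                                       0.4), 2.5)
    fraction[seq_len(n_have)] <- pk$fraction[seq_len(n_have)]
  }
  if (n_have < nc) {
    extra <- seq(n_have + 1, nc)
    center[extra] <- seq(2.5, 6, length.out = length(extra))
    fwhm[extra] <- 1
    fraction[extra] <- if (n_have) max(0.5 * min(fraction[seq_len(n_have)]),
                                       0.05) else 1
  }
  fraction <- fraction / sum(fraction)
  list(center = center, fwhm = fwhm, fraction = fraction,
       n_seeded = n_have)
}

# Restart proposal: seeded components get 10% relative Gaussian jitter;
# components the seed did not supply are redrawn globally so the multistart
# explores the whole distance range, not just the seed neighborhood.
perturb_init <- function(init, relative = 0.1) {
  n_seeded <- if (is.null(init$n_seeded)) length(init$center) else init$n_seeded
  ph <- list(center = init$center, fwhm = init$fwhm,
             fraction = init$fraction)
  if (relative == 0) return(ph)
  nc <- length(ph$center)
  ph <- lapply(ph, function(v) v * (1 + relative * stats::rnorm(length(v))))
  if (n_seeded < nc) {
    extra <- seq(n_seeded + 1, nc)
    ph$center[extra] <- stats::runif(length(extra), 1.8, 6.5)
    ph$fwhm[extra] <- stats::runif(length(extra), 0.5, 1.5)
    ph$fraction[extra] <- stats::runif(length(extra), 0.05, 0.35)
  }
  ph$fraction <- pmax(ph$fraction, 1e-3)
  ph$fraction <- ph$fraction / sum(ph$fraction)
  ph$center <- pmin(pmax(ph$center, 1.5), 9)
  ph$fwhm <- pmin(pmax(ph$fwhm, 0.2), 3)
  ph
}

# free-parameter bookkeeping for profile refits: the full vector is
# (centers, fwhms, thetas); the profiled parameter is dropped from it
free_param_spec <- function(fixed_par, j, nc) {
  n_par <- 3 * nc - 1
  keep <- rep(TRUE, n_par)
  if (fixed_par == "center") keep[j] <- FALSE
  if (fixed_par == "fwhm") keep[nc + j] <- FALSE
  if (fixed_par == "fraction" && nc > 1) keep[2 * nc + 1] <- FALSE
  b <- pack_bounds(nc)
  list(keep = keep, lower = b$lower[keep], upper = b$upper[keep], nc = nc)
}

extract_free_params <- function(ph, free) {
  full <- c(ph$center, ph$fwhm, fractions_to_sticks(ph$fraction))
  pmin(pmax(full[free$keep], free$lower), free$upper)
}

apply_free_params <- function(ph, q, free, fixed_par, j) {
  nc <- free$nc
  full <- c(ph$center, ph$fwhm, fractions_to_sticks(ph$fraction))
  full[free$keep] <- q
  out <- unpack_params(full, nc)
  if (fixed_par == "center") out$center[j] <- ph$center[j]
  if (fixed_par == "fwhm") out$fwhm[j] <- ph$fwhm[j]
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
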