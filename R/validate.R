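#' Background-fit stability validation
#'
#' Repeats the background fit, correction and Tikhonov inversion over a set
#' of background fit-start times and tracks every distribution mode across
#' the runs. Modes whose mole fraction varies by more than
#' `fraction_threshold` (relative range), or that appear in only some runs,
#' are flagged unstable: their apparent population depends on the background
#' choice rather than on the dipolar signal.
#'
#' @param trace raw [deer_trace()]
#' @param fit_starts background-window start times, us; at least 3. Default:
#'   10 evenly spaced starts between 1/3 and 3/4 of t_max.
#' @param r_grid inversion distance grid
#' @param alpha regularization parameter; "loocv" (default) selects it once
#'   on the default correction and reuses it across fit_starts
#' @param fraction_threshold relative fraction-variation threshold (default
#'   0.5, i.e. 50%)
#' @param match_tol modes closer than this (nm) across runs are the same peak
#' @param min_fraction modes carrying less mass than this in a run are
#'   treated as inversion ripple and not tracked
#' @param d background dimension for the fits
#' @return a `bg_stability_report`: data frame of tracked peaks with columns
#'   `center`, `center_sd`, `fraction`, `fraction_rel_range`, `n_seen`,
#'   `sd` (mean RMS width), `unstable`; attributes carry the per-run detail
#' @export
validate_background <- function(trace, fit_starts = NULL,
                                r_grid = default_r_grid(dr = 0.05),
                                alpha = "loocv", fraction_threshold = 0.5,
                                match_tol = 0.4, min_fraction = 0.05,
                                d = 3) {
  stopifnot(inherits(trace, "deer_trace"))
  t_max <- max(trace$time)
  if (is.null(fit_starts))
    fit_starts <- seq(t_max / 3, 3 * t_max / 4, length.out = 10)
  if (length(fit_starts) < 3)
    stop("background validation needs at least 3 fit_start values")
  kernel <- dipolar_kernel(trace$time, r_grid)

  if (identical(alpha, "loocv")) {
    bg0 <- fit_background(trace, d = d)
    ff0 <- correct_background(trace, bg0)
    alpha <- select_alpha_loocv(ff0, r_grid, kernel = kernel)$alpha
  }

  runs <- lapply(fit_starts, function(fs) {
    res <- tryCatch({
      bg <- fit_background(trace, fit_start = fs, d = d)
      ff <- correct_background(trace, bg)
      dist <- tikhonov_solve(ff, r_grid, alpha = alpha, kernel = kernel)
      list(fit_start = fs, peaks = find_peaks(dist, threshold = 0.02),
           bg = bg)
    }, error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("background fit failed at fit_start = %.3f us: %s",
                   fs, conditionMessage(res)))
    res
  })

  all_pk <- do.call(rbind, lapply(seq_along(runs), function(i) {
    pk <- runs[[i]]$peaks
    pk <- pk[pk$fraction >= min_fraction, , drop = FALSE]
    if (nrow(pk)) pk$run <- i
    pk
  }))
  if (is.null(all_pk) || !nrow(all_pk))
    stop("no distribution peaks found in any validation run")

  # greedy clustering of peak centers across runs
  all_pk <- all_pk[order(all_pk$center), ]
  cl <- cumsum(c(1, diff(all_pk$center) > match_tol))
  rep_rows <- lapply(split(all_pk, cl), function(g) {
    rel_range <- if (nrow(g) > 1)
      (max(g$fraction) - min(g$fraction)) / max(mean(g$fraction), 1e-12)
    else Inf
    data.frame(center = mean(g$center), center_sd = stats::sd(g$center),
               fraction = mean(g$fraction),
               fraction_rel_range = rel_range,
               n_seen = nrow(g), sd = mean(g$sd))
  })
  rep <- do.call(rbind, rep_rows)
  rep$center_sd[is.na(rep$center_sd)] <- 0
  rep$unstable <- rep$fraction_rel_range > fraction_threshold |
    rep$n_seen < length(fit_starts)
  rownames(rep) <- NULL
  structure(rep, class = c("bg_stability_report", "data.frame"),
            fit_starts = fit_starts, alpha = alpha,
            runs = lapply(runs, `[`, c("fit_start", "peaks")))
}

#' @export
print.bg_stability_report <- function(x, ...) {
  cat(sprintf("Background stability report (%d fit starts, alpha = %.3g):\n",
              length(attr(x, "fit_starts")), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Suppress unstable, well-separated populations
#'
#' Folds the dipolar signal of the flagged unstable modes into the
#' background model — \eqn{B'(t) = B(t)[1 - \lambda_u + \lambda_u F_u(t)]}
#' with \eqn{\lambda_u = \lambda x_u} — and repeats the correction, so the
#' remaining form factor contains only the stable populations. Refuses if a
#' flagged mode overlaps a stable mode within 2 sigma (suppression would
#' distort real populations).
#'
#' @param trace raw [deer_trace()]
#' @param report a `bg_stability_report` from [validate_background()]
#' @param bg fitted [background_model()] for the homogeneous part; refit
#'   from `trace` when NULL
#' @return corrected-stage [deer_trace()] with the unstable components
#'   absorbed into the background (identity correction if nothing flagged)
#' @export
suppress_unstable <- function(trace, report, bg = NULL) {
  stopifnot(inherits(trace, "deer_trace"),
            inherits(report, "bg_stability_report"))
  if (is.null(bg)) bg <- fit_background(trace)
  unstable <- report[report$unstable, , drop = FALSE]
  stable <- report[!report$unstable, , drop = FALSE]
  if (!nrow(unstable)) return(correct_background(trace, bg))
  for (i in seq_len(nrow(unstable))) {
    gap <- abs(stable$center - unstable$center[i])
    sep <- 2 * (stable$sd + unstable$sd[i])
    if (any(gap < sep))
      stop(sprintf(
        "unstable mode at %.2f nm overlaps a stable mode; refusing to suppress",
        unstable$center[i]))
  }
  x_u <- sum(unstable$fraction)
  comps_u <- gaussian_components(unstable$center,
                                 pmax(sigma_to_fwhm(unstable$sd), 0.3),
                                 unstable$fraction, normalize = TRUE)
  F_u <- form_factor(dipolar_kernel(trace$time, default_r_grid()),
                     gaussian_mixture(comps_u, default_r_grid()))
  lambda_u <- bg$lambda * x_u
  B2 <- background_decay(bg, trace$time) * (1 - lambda_u + lambda_u * F_u)
  lambda_s <- (bg$lambda - lambda_u) / (1 - lambda_u)
  if (lambda_s <= 0) stop("all modulation flagged unstable; nothing remains")
  Fhat <- (trace$amplitude / B2 - (1 - lambda_s)) / lambda_s
  Fhat <- Fhat / Fhat[1]
  deer_trace(trace$time, Fhat, stage = "corrected",
             metadata = c(trace$metadata,
                          list(suppressed = comps_u, correction_bg = bg)))
}
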