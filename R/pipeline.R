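#' Full DEER analysis pipeline
#'
#' Runs the complete analysis chain on a raw trace: background fit and
#' correction (optionally with stability validation and suppression of
#' unstable populations), Tikhonov inversion with automatic smoothing
#' selection, and a multistart sum-of-Gaussians parameterization seeded
#' from the Tikhonov distribution, with BIC model-order selection when
#' `n_components` is not fixed.
#'
#' @param trace raw [deer_trace()]
#' @param r_grid inversion distance grid, nm
#' @param alphas regularization-parameter grid
#' @param alpha_select "loocv" (default), "lcurve", or a numeric alpha
#' @param n_components fixed component count; when NULL, orders
#'   `1:max_components` are fit and BIC selects
#' @param max_components largest model order tried (default 4)
#' @param bg_fit_start background window start, us (default t_max/3)
#' @param bg_validate run [validate_background()] and suppress unstable
#'   modes before inversion
#' @param n_restarts multistart restarts per model order
#' @param rng_seed seed for the Monte-Carlo multistart
#' @param compute_uncertainty also run [error_surface()] on the chosen fit
#' @return a `deer_analysis` list: `background`, `form_factor`, `tikhonov`,
#'   `fits` (all orders), `fit` (selected), `noise`, `bic_table`,
#'   `stability` (report or NULL)
#' @export
analyze_deer <- function(trace, r_grid = default_r_grid(dr = 0.05),
                         alphas = default_alpha_grid(),
                         alpha_select = "loocv", n_components = NULL,
                         max_components = 4, bg_fit_start = NULL,
                         bg_validate = FALSE, n_restarts = 32, rng_seed = 1,
                         compute_uncertainty = FALSE) {
  stopifnot(inherits(trace, "deer_trace"))
  bg <- fit_background(trace, fit_start = bg_fit_start)
  stability <- NULL
  if (bg_validate) {
    stability <- validate_background(trace, r_grid = r_grid)
    ff <- suppress_unstable(trace, stability, bg)
  } else {
    ff <- correct_background(trace, bg)
  }
  kernel <- dipolar_kernel(trace$time, r_grid)
  tik <- tikhonov_scan(ff, r_grid, alphas, select = alpha_select,
                       kernel = kernel)
  tik_rmsd <- tik$residual_norm / sqrt(length(ff$amplitude))
  orders <- if (is.null(n_components)) seq_len(max_components)
            else n_components
  fits <- lapply(orders, function(nc)
    suppressWarnings(fit_sum_of_gaussians(
      ff, nc, seed_distribution = tik$distribution, n_restarts = n_restarts,
      rng_seed = rng_seed + nc, r_grid = r_grid, kernel = kernel)))
  if (length(fits) > 1) {
    fit <- select_model_bic(fits, tikhonov_rmsd = tik_rmsd)
    bic_table <- attr(fit, "bic_table")
  } else {
    fit <- fits[[1]]
    bic_table <- data.frame(n_components = fit$n_components, rmsd = fit$rmsd,
                            bic = fit$bic, accepted = TRUE)
  }
  uncertainty <- if (compute_uncertainty) error_surface(fit, ff) else NULL
  structure(list(background = bg, form_factor = ff, tikhonov = tik,
                 fits = fits, fit = fit, noise = estimate_noise(ff),
                 bic_table = bic_table, stability = stability,
                 uncertainty = uncertainty, rng_seed = rng_seed),
            class = "deer_analysis")
}

#' @export
print.deer_analysis <- function(x, ...) {
  cat("DEER analysis\n=============\n")
  print(x$background)
  cat(sprintf("Noise estimate: %.2e\n", x$noise))
  print(x$tikhonov)
  cat("\nModel selection:\n")
  print(x$bic_table, row.names = FALSE, digits = 4)
  cat("\nSelected fit:\n")
  print(x$fit)
  invisible(x)
}
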