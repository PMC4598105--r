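# broom-style tidiers for the package's fitted objects.

#' Tidy a Gaussian mixture fit
#'
#' One row per mixture component: weight, mean and sd on the log scale,
#' and the back-transformed mean in mm.
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `weight`, `mean_log`,
#'   `sd_log`, `mean_mm`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights, mean_log = x$means,
         sd_log = x$sds, mean_mm = exp(x$means))
}

#' @rdname tidy.mixture_fit
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = x$bic, aic = x$aic,
         converged = x$converged, n_obs = x$n_obs)
}

#' Tidy a mode analysis
#'
#' `tidy()` returns the merged modes of the selected fit (one row per
#' mode, with the ratio to the previous mode); `glance()` returns a
#' one-row summary.
#'
#' @param x A `mode_analysis` from [select_best_mixture()] or
#'   [analyze_ratio_modes()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mode_analysis
#' @export
tidy.mode_analysis <- function(x, ...) {
  tibble(
    mode = seq_along(x$modes),
    location_log = x$modes,
    location_mm = x$modes_mm,
    ratio_to_previous = c(NA_real_, x$peak_to_peak_ratios)
  )
}

#' @rdname tidy.mode_analysis
#' @method glance mode_analysis
#' @export
glance.mode_analysis <- function(x, ...) {
  best <- x$best_fit
  tibble(best_k = x$best_k, n_modes = length(x$modes),
         criterion = x$criterion, score = min(x$scan[[x$criterion]]),
         loglik = best$loglik, converged = best$converged, n_obs = x$n_obs)
}

#' Tidy a niche simulation
#'
#' `tidy()` returns the surviving community (one row per species);
#' `glance()` a one-row run summary.
#'
#' @param x A `niche_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy niche_sim
#' @export
tidy.niche_sim <- function(x, ...) {
  st <- x$final_state
  tibble(species = seq_along(st$x), x = st$x, N = st$N)
}

#' @rdname tidy.niche_sim
#' @method glance niche_sim
#' @export
glance.niche_sim <- function(x, ...) {
  st <- x$final_state
  tibble(n_initial = x$params$n_species, n_surviving = length(st$x),
         total_abundance = sum(st$N), t_final = st$t,
         sigma_alpha = x$params$sigma_alpha,
         evolution_mode = x$params$evolution_mode)
}
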