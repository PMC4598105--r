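# Gaussian-mixture ("latent class") and kernel-density mode detection for
# log body-size and log size-ratio distributions.

SD_FLOOR <- 1e-4  # log-scale floor preventing EM collapse on tied values

#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `k`-component Gaussian mixture to `values` (log body lengths or
#' log ratios) by expectation-maximisation, taking the best of `n_init`
#' seeded random restarts by log-likelihood (ties go to the earliest
#' restart). Component standard deviations are floored at `1e-4` on the log
#' scale so that tied observations (catalogue lengths are typically rounded)
#' cannot collapse a component to a zero-variance spike.
#'
#' @param values Numeric vector of observations (natural-log scale).
#' @param k Number of components (>= 1). Requires `length(values) >= 2k`.
#' @param n_init Number of EM restarts.
#' @param seed Integer seed for the restarts, or `NULL`.
#' @param tol Convergence tolerance: EM stops when the relative
#'   log-likelihood change drops below `tol`.
#' @param max_iter Maximum EM iterations per restart.
#' @param init Optional extra starting point, a list with `weights`,
#'   `means`, `sds` of length `k`; used as an additional restart (this is
#'   how [select_best_mixture()] warm-starts `k` from the `k - 1` fit).
#'
#' @return An object of class `"mixture_fit"`: list with `k`, `weights`,
#'   `means`, `sds`, `loglik`, `bic`, `aic`, `converged`, `n_obs`.
#' @examples
#' x <- c(rnorm(100, log(2), 0.05), rnorm(100, log(2.7), 0.05))
#' fit <- fit_gaussian_mixture(x, k = 2, seed = 1)
#' tidy(fit)
#' @export
fit_gaussian_mixture <- function(values, k, n_init = 10, seed = NULL,
                                 tol = 1e-6, max_iter = 500, init = NULL) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric observations.")
  }
  k <- check_count(k, "k")
  n <- length(values)
  if (n < 2 * k) {
    abort(sprintf(
      "insufficient observations for k classes: need n >= %d, got %d.",
      2 * k, n
    ))
  }
  if (length(unique(values)) == 1L) {
    abort("All values are identical; a mixture fit is degenerate (zero variance).")
  }
  starts <- derive_seeds(seed, n_init)
  best <- NULL
  for (i in seq_len(n_init)) {
    th0 <- with_seed_if(starts[[i]], em_init_random(values, k))
    cand <- em_run(values, th0, tol, max_iter)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (!is.null(init)) {
    stopifnot(length(init$means) == k)
    cand <- em_run(values, list(weights = init$weights, means = init$means,
                                sds = pmax(init$sds, SD_FLOOR)),
                   tol, max_iter)
    if (cand$loglik > best$loglik) best <- cand
  }
  new_mixture_fit(best, n)
}

em_init_random <- function(values, k) {
  list(weights = rep(1 / k, k),
       means = sample(values, k, replace = length(values) < k),
       sds = rep(max(sd(values), SD_FLOOR), k))
}

new_mixture_fit <- function(fit, n) {
  o <- order(fit$means)
  p <- 3L * length(fit$means) - 1L
  structure(
    list(k = length(fit$means), weights = fit$weights[o], means = fit$means[o],
         sds = fit$sds[o], loglik = fit$loglik,
         bic = -2 * fit$loglik + p * log(n),
         aic = -2 * fit$loglik + 2 * p,
         converged = fit$converged, n_obs = n),
    class = "mixture_fit"
  )
}

# Log density matrix (n x k) of each observation under each weighted
# component, written as matrix ops to keep the EM loop fast.
em_log_resp <- function(values, th) {
  n <- length(values)
  k <- length(th$means)
  const <- log(th$weights) - log(th$sds) - 0.5 * log(2 * pi)
  z <- outer(values, th$means, "-") /
    matrix(th$sds, n, k, byrow = TRUE)
  matrix(const, n, k, byrow = TRUE) - 0.5 * z^2
}

# Row-wise log-sum-exp via max.col (C-level, no apply loop).
row_lse <- function(lp) {
  m <- lp[cbind(seq_len(nrow(lp)), max.col(lp, ties.method = "first"))]
  m + log(rowSums(exp(lp - m)))
}

em_run <- function(values, th, tol, max_iter) {
  n <- length(values)
  k <- length(th$means)
  if (k == 1L) {
    m <- mean(values)
    s <- max(sqrt(sum((values - m)^2) / n), SD_FLOOR)
    ll <- sum(dnorm(values, m, s, log = TRUE))
    return(list(weights = 1, means = m, sds = s, loglik = ll,
                converged = TRUE))
  }
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lp <- em_log_resp(values, th)
    lse <- row_lse(lp)
    ll <- sum(lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    th$weights <- nk / n
    th$means <- colSums(resp * values) / nk
    th$sds <- pmax(sqrt(colSums(resp * outer(values, th$means, "-")^2) / nk),
                   SD_FLOOR)
  }
  ll <- sum(row_lse(em_log_resp(values, th)))
  list(weights = th$weights, means = th$means, sds = th$sds, loglik = ll,
       converged = converged)
}

# Merge components whose means are closer than half the sum of their sds;
# near-duplicate components would otherwise create spurious ratios near 1.
merge_modes <- function(weights, means, sds) {
  o <- order(means)
  weights <- weights[o]; means <- means[o]; sds <- sds[o]
  repeat {
    if (length(means) < 2L) break
    gap <- diff(means)
    lim <- 0.5 * (head(sds, -1) + tail(sds, -1))
    j <- which(gap < lim)
    if (!length(j)) break
    j <- j[1]
    w <- weights[j] + weights[j + 1]
    means[j] <- (weights[j] * means[j] + weights[j + 1] * means[j + 1]) / w
    sds[j] <- (weights[j] * sds[j] + weights[j + 1] * sds[j + 1]) / w
    weights[j] <- w
    means <- means[-(j + 1)]; sds <- sds[-(j + 1)]; weights <- weights[-(j + 1)]
  }
  list(weights = weights, means = means, sds = sds)
}

#' Fit mixtures over a range of class counts and select the best
#'
#' Fits Gaussian mixtures for every feasible `k` in `kmin:kmax` (a `k`
#' needing more than `n / 2` observations is skipped and recorded) and
#' selects `best_k` by the information criterion (default BIC; lower is
#' better; ties go to the smaller `k`). Each `k` is warm-started from the
#' best `k - 1` fit (splitting the heaviest component) in addition to its
#' random restarts, which keeps the maximised log-likelihood non-decreasing
#' in `k`. Components of the selected fit whose means are closer than half
#' the sum of their sds are merged before modes are reported.
#'
#' @inheritParams fit_gaussian_mixture
#' @param kmin,kmax Range of class counts to scan (default 1-10).
#' @param criterion `"bic"` (default) or `"aic"`.
#'
#' @return An object of class `"mode_analysis"`: list with `fits` (one
#'   `mixture_fit` per attempted `k`), `scan` (tibble of `k`, `loglik`,
#'   `bic`, `aic`, `converged`), `best_k`, `best_fit`, `modes` (merged
#'   component means, log scale, increasing), `modes_mm` (`exp(modes)`),
#'   `peak_to_peak_ratios`, `skipped_k`, `criterion`, `n_obs`.
#' @examples
#' x <- c(rnorm(300, log(2), 0.04), rnorm(300, log(2.7), 0.04))
#' res <- select_best_mixture(x, kmax = 5, seed = 1)
#' res$best_k
#' res$peak_to_peak_ratios
#' @export
select_best_mixture <- function(values, kmin = 1, kmax = 10,
                                criterion = c("bic", "aic"), n_init = 10,
                                seed = NULL, tol = 1e-6, max_iter = 500) {
  criterion <- match.arg(criterion)
  kmin <- check_count(kmin, "kmin")
  kmax <- check_count(kmax, "kmax", lower = kmin)
  ks <- kmin:kmax
  feasible <- ks[2 * ks <= length(values)]
  skipped <- setdiff(ks, feasible)
  if (!length(feasible)) {
    abort(sprintf(
      "No feasible class count in %d:%d for %d observations.",
      kmin, kmax, length(values)
    ))
  }
  kseeds <- derive_seeds(seed, length(feasible))
  fits <- vector("list", length(feasible))
  prev <- NULL
  for (i in seq_along(feasible)) {
    k <- feasible[i]
    warm <- if (!is.null(prev) && prev$k == k - 1L) split_heaviest(prev)
    fits[[i]] <- fit_gaussian_mixture(values, k, n_init = n_init,
                                      seed = kseeds[[i]], tol = tol,
                                      max_iter = max_iter, init = warm)
    prev <- fits[[i]]
  }
  names(fits) <- paste0("k", feasible)
  scan <- tibble(
    k = feasible,
    loglik = map_dbl(fits, "loglik"),
    bic = map_dbl(fits, "bic"),
    aic = map_dbl(fits, "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  score <- scan[[criterion]]
  best_i <- which(score == min(score))[1]  # ties -> smaller k (ks ascending)
  best <- fits[[best_i]]
  merged <- merge_modes(best$weights, best$means, best$sds)
  structure(
    list(fits = fits, scan = scan, best_k = best$k, best_fit = best,
         modes = merged$means, modes_mm = exp(merged$means),
         peak_to_peak_ratios = peak_to_peak_ratios(merged$means),
         skipped_k = skipped, criterion = criterion,
         n_obs = length(values), values = values),
    class = "mode_analysis"
  )
}

split_heaviest <- function(fit) {
  j <- which.max(fit$weights)
  list(
    weights = c(fit$weights[-j], fit$weights[j] / 2, fit$weights[j] / 2),
    means = c(fit$means[-j], fit$means[j] - 0.5 * fit$sds[j],
              fit$means[j] + 0.5 * fit$sds[j]),
    sds = c(fit$sds[-j], fit$sds[j], fit$sds[j])
  )
}

#' Gaussian kernel density of a size distribution
#'
#' Kernel-smoothed density on an even grid spanning
#' `[min(values) - 3h, max(values) + 3h]` with `h` from Silverman's
#' rule-of-thumb (or given explicitly), renormalised to integrate to 1.
#'
#' @param values Numeric observations (log scale); at least two distinct
#'   values.
#' @param bandwidth `"silverman"` or a positive number (log-scale width).
#' @param grid_size Number of grid points.
#' @return A tibble of class `"density_curve"` with columns `grid`,
#'   `density` and attribute `bandwidth`.
#' @export
kernel_density <- function(values, bandwidth = "silverman", grid_size = 512) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric observations.")
  }
  if (length(unique(values)) < 2L) {
    abort("Need at least 2 distinct values for a density estimate.")
  }
  grid_size <- check_count(grid_size, "grid_size", lower = 16L)
  h <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
       else check_number(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  d <- stats::density(values, bw = h, kernel = "gaussian", n = grid_size,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  dens <- d$y / trapezoid(d$x, d$y)
  out <- tibble(grid = d$x, density = dens)
  attr(out, "bandwidth") <- h
  class(out) <- c("density_curve", class(out))
  out
}

#' Locate peaks of a density curve
#'
#' Interior strict local maxima whose topographic prominence is at least
#' `min_prominence` times the curve maximum. Prominence of a peak is its
#' height minus the higher of the two valley floors separating it from
#' higher terrain (or from the curve ends).
#'
#' @param curve A [kernel_density()] result.
#' @param min_prominence Fraction of the maximum density (in \[0, 1\]).
#' @return Sorted numeric vector of peak locations (possibly empty).
#' @export
find_density_peaks <- function(curve, min_prominence = 0.05) {
  stopifnot(inherits(curve, "density_curve"))
  check_number(min_prominence, "min_prominence", lower = 0, upper = 1)
  y <- curve$density
  x <- curve$grid
  n <- length(y)
  if (n < 3L) return(numeric())
  is_pk <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (!length(is_pk)) return(numeric())
  prom <- vapply(is_pk, function(i) {
    left <- y[seq_len(i - 1)]
    hi_l <- which(left > y[i])
    base_l <- min(y[(if (length(hi_l)) max(hi_l) else 1L):(i - 1L)])
    right <- y[(i + 1L):n]
    hi_r <- which(right > y[i])
    end_r <- if (length(hi_r)) i + min(hi_r) else n
    base_r <- min(y[(i + 1L):end_r])
    y[i] - max(base_l, base_r)
  }, numeric(1))
  sort(x[is_pk[prom >= min_prominence * max(y)]])
}

#' Peak-to-peak size ratios
#'
#' Converts sorted log-scale mode locations into the body-length ratios
#' between consecutive modes: `exp(m[i+1] - m[i])`. All ratios are >= 1.
#'
#' @param modes Numeric vector of mode locations (log scale), sorted
#'   ascending.
#' @return Numeric vector of length `length(modes) - 1` (empty for a single
#'   mode).
#' @examples
#' peak_to_peak_ratios(log(c(2, 2.7, 3.645)))
#' @export
peak_to_peak_ratios <- function(modes) {
  if (is.unsorted(modes)) {
    abort("`modes` must be sorted in ascending order.")
  }
  if (length(modes) < 2L) return(numeric())
  exp(diff(modes))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, loglik = %.3f, BIC = %.3f (%s)\n",
              x$k, x$loglik, x$bic,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
print.mode_analysis <- function(x, ...) {
  cat(sprintf(
    "<mode_analysis> best k = %d by %s over k = %s (n = %d)\n",
    x$best_k, toupper(x$criterion),
    paste(range(x$scan$k), collapse = "-"), x$n_obs
  ))
  cat("modes (mm):", paste(signif(x$modes_mm, 4), collapse = ", "), "\n")
  if (length(x$peak_to_peak_ratios)) {
    cat("peak-to-peak ratios:",
        paste(signif(x$peak_to_peak_ratios, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
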