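test_that("the one-component fit equals its closed form", {
  set.seed(1)
  x <- rnorm(200, log(3), 0.1)
  fit <- fit_gaussian_mixture(x, k = 1)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))  # population convention
  expect_equal(fit$means, m)
  expect_equal(fit$sds, s)
  expect_equal(fit$loglik, sum(dnorm(x, m, s, log = TRUE)))
  expect_true(fit$converged)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(200))
})

test_that("mixture fitting rejects degenerate inputs", {
  expect_error(fit_gaussian_mixture(rnorm(5), k = 3), "insufficient observations")
  expect_error(fit_gaussian_mixture(rep(2.5, 50), k = 2), "identical")
  expect_error(fit_gaussian_mixture(c(1, NA, 2), k = 1), "finite")
})

test_that("a 2-component fit on unimodal data does not hard-split", {
  set.seed(2)
  x <- rnorm(500, log(3), 0.1)
  f1 <- fit_gaussian_mixture(x, k = 1)
  f2 <- fit_gaussian_mixture(x, k = 2, seed = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  # no spurious hard split: the fitted mixture density itself stays
  # unimodal (overlapping components), or one component is marginal
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- f2$weights[1] * dnorm(grid, f2$means[1], f2$sds[1]) +
    f2$weights[2] * dnorm(grid, f2$means[2], f2$sds[2])
  n_max <- sum(diff(sign(diff(dens))) == -2)
  expect_true(n_max <= 1 || min(f2$weights) < 0.2)
})

test_that("parameters are recovered on a clear two-lump sample", {
  set.seed(5)
  x <- c(rnorm(250, log(2), 0.05), rnorm(250, log(2.7), 0.05))
  fit <- fit_gaussian_mixture(x, k = 2, seed = 5)
  expect_lt(abs(fit$means[1] - log(2)), 0.03)
  expect_lt(abs(fit$means[2] - log(2.7)), 0.03)
  expect_true(all(abs(fit$weights - 0.5) < 0.08))
})

test_that("maximised log-likelihood is non-decreasing in k", {
  set.seed(3)
  x <- c(rnorm(150, log(2), 0.05), rnorm(150, log(3), 0.08))
  res <- select_best_mixture(x, kmax = 6, seed = 3)
  expect_true(all(diff(res$scan$loglik) > -1e-6))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(8)
  x <- c(rnorm(200, log(2), 0.05), rnorm(200, log(2.7), 0.06))
  ours <- fit_gaussian_mixture(x, k = 2, n_init = 20, seed = 8)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(sort(ours$means), sort(as.vector(ref$parameters$mean)),
               tolerance = 1e-3)
})

test_that("BIC selects three classes on a three-lump pool", {
  set.seed(6)
  x <- c(rnorm(200, log(2), 0.04), rnorm(200, log(2.7), 0.04),
         rnorm(200, log(3.645), 0.04))
  res <- select_best_mixture(x, kmax = 6, seed = 6)
  expect_equal(res$best_k, 3)
  expect_equal(length(res$peak_to_peak_ratios), 2)
  expect_true(all(abs(res$peak_to_peak_ratios - 1.35) / 1.35 < 0.05))
})

test_that("a single candidate class count is selected trivially", {
  set.seed(7)
  x <- rnorm(50, log(4), 0.2)
  res <- select_best_mixture(x, kmin = 1, kmax = 1)
  expect_equal(res$best_k, 1)
})

test_that("infeasible class counts are skipped and recorded", {
  set.seed(9)
  x <- rnorm(7, 0, 1)
  res <- select_best_mixture(x, kmin = 1, kmax = 10, seed = 9)
  expect_setequal(res$scan$k, 1:3)
  expect_setequal(res$skipped_k, 4:10)
  expect_error(select_best_mixture(rnorm(1), kmin = 1, kmax = 10),
               "No feasible")
})

test_that("mode analysis is equivariant under a log-scale shift", {
  set.seed(10)
  x <- c(rnorm(150, log(2), 0.05), rnorm(150, log(3), 0.05))
  a <- select_best_mixture(x, kmax = 4, seed = 10)
  b <- select_best_mixture(x + 1, kmax = 4, seed = 10)
  expect_equal(b$best_k, a$best_k)
  expect_equal(b$modes, a$modes + 1, tolerance = 1e-6)
  expect_equal(b$best_fit$sds, a$best_fit$sds, tolerance = 1e-6)
  expect_equal(b$best_fit$weights, a$best_fit$weights, tolerance = 1e-6)
  expect_equal(b$peak_to_peak_ratios, a$peak_to_peak_ratios,
               tolerance = 1e-6)
})

test_that("near-duplicate components merge before ratios are formed", {
  set.seed(11)
  x <- c(rnorm(300, log(2), 0.05), rnorm(300, log(2.7), 0.05))
  res <- select_best_mixture(x, kmax = 5, seed = 11)
  if (length(res$peak_to_peak_ratios)) {
    expect_true(all(res$peak_to_peak_ratios > 1.05))
  }
  expect_false(is.unsorted(res$modes, strictly = TRUE))
})

test_that("kernel density integrates to one and finds the right peaks", {
  set.seed(12)
  x <- rnorm(1000, log(3), 0.1)
  kd <- kernel_density(x)
  expect_true(all(kd$density >= 0))
  grid_int <- sum(diff(kd$grid) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_lt(abs(grid_int - 1), 0.01)
  expect_equal(length(find_density_peaks(kd, 0.05)), 1)

  spikes <- c(rep(log(2), 500), rep(log(4), 500)) + rnorm(1000, 0, 0.01)
  kd2 <- kernel_density(spikes, bandwidth = 0.05)
  peaks <- find_density_peaks(kd2, 0.05)
  expect_equal(length(peaks), 2)
  step <- diff(kd2$grid[1:2])
  expect_lt(abs(peaks[1] - log(2)), step + 0.01)
  expect_lt(abs(peaks[2] - log(4)), step + 0.01)

  expect_error(kernel_density(rep(1, 10)), "distinct")
})

test_that("monotone curves yield no interior peaks", {
  curve <- tibble::tibble(grid = seq(0, 1, length.out = 50),
                          density = seq(0, 2, length.out = 50))
  class(curve) <- c("density_curve", class(curve))
  expect_equal(length(find_density_peaks(curve)), 0)
})

test_that("peak-to-peak ratios are exp of consecutive log differences", {
  expect_equal(peak_to_peak_ratios(log(c(2, 2.7))), 1.35)
  expect_equal(peak_to_peak_ratios(log(2)), numeric())
  expect_equal(peak_to_peak_ratios(log(c(2, 2.7, 3.645))), c(1.35, 1.35))
  expect_error(peak_to_peak_ratios(c(1, 0.5)), "sorted")
})
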