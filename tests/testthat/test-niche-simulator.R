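test_that("competition kernel is Gaussian in niche distance and symmetric", {
  expect_equal(competition_coefficient(0.5, 0.5, 0.1), 1)
  expect_equal(competition_coefficient(0, 0.05, 0.05), exp(-0.5))
  set.seed(1)
  a <- runif(20); b <- runif(20)
  expect_equal(competition_coefficient(a, b, 0.07),
               competition_coefficient(b, a, 0.07))
  expect_true(all(competition_coefficient(a, b, 0.07) <= 1))
  expect_error(competition_coefficient(0, 1, 0), "sigma_alpha")
})

test_that("LV derivatives vanish at the known equilibria", {
  p <- niche_sim_params(n_species = 1, K0 = 5)
  expect_equal(lv_derivatives(community_state(0.5, 5), p), 0)
  expect_equal(lv_derivatives(community_state(0.5, 0), p), 0)

  # closed-form symmetric two-species equilibrium N* = K / (1 + alpha)
  set.seed(2)
  for (i in 1:20) {
    d <- runif(1, 0.01, 0.5); sigma <- runif(1, 0.02, 0.3)
    K0 <- runif(1, 0.5, 10)
    p2 <- niche_sim_params(n_species = 2, K0 = K0, sigma_alpha = sigma)
    nstar <- two_species_equilibrium(d, sigma, K0)
    st <- community_state(c(0.3, 0.3 + d), rep(nstar, 2))
    expect_lt(max(abs(lv_derivatives(st, p2))), 1e-10)
  }
})

test_that("derivatives reject mismatched state vectors", {
  p <- niche_sim_params()
  st <- community_state(c(0.1, 0.2), c(1, 1))
  st$N <- c(1, 1, 1)
  expect_error(lv_derivatives(st, p), "mismatched")
})

test_that("integration matches the logistic closed form within 1%", {
  r <- 1; K0 <- 1
  p <- niche_sim_params(n_species = 1, r = r, K0 = K0, dt = 0.1,
                        extinction_threshold = 0)
  st <- integrate_dynamics(community_state(0.5, 0.01 * K0), p, 20 / r)
  expect_lt(abs(st$N - K0) / K0, 0.01)
  expect_equal(st$N, logistic_closed_form(0.01 * K0, K0, r, 20), tolerance = 1e-6)
})

test_that("zero-duration integration is the identity", {
  p <- niche_sim_params(extinction_threshold = 0)
  st <- community_state(c(0.2, 0.8), c(0.3, 0.4))
  out <- integrate_dynamics(st, p, 0)
  expect_equal(out$x, st$x)
  expect_equal(out$N, st$N)
})

test_that("co-located species stay exchange-symmetric and sum to K0", {
  p <- niche_sim_params(n_species = 2, K0 = 2, dt = 0.05,
                        extinction_threshold = 0)
  st <- integrate_dynamics(community_state(c(0.5, 0.5), c(0.01, 0.01)), p, 40)
  expect_equal(st$N[1], st$N[2], tolerance = 1e-12)
  expect_lt(abs(sum(st$N) - 2) / 2, 0.01)
})

test_that("extinction pruning removes species only below the threshold", {
  p <- niche_sim_params(n_species = 2, extinction_threshold = 0.05, dt = 0.1)
  st <- integrate_dynamics(community_state(c(0.2, 0.8), c(0.04, 0.5)), p, 0)
  expect_equal(length(st$x), 1)
  expect_equal(st$x, 0.8)
})

test_that("evolution step obeys its identities and boundary rules", {
  p0 <- niche_sim_params(evolution_mode = "hill_climb", evolution_step_sd = 0)
  st <- community_state(c(0.3, 0.6), c(0.5, 0.5))
  expect_equal(evolution_step(st, p0)$x, st$x)

  # flat fitness landscape: a lone species stays put (sign-test tie)
  p1 <- niche_sim_params(evolution_mode = "hill_climb",
                         evolution_step_sd = 0.01)
  lone <- community_state(0.4, 0.7)
  expect_equal(evolution_step(lone, p1)$x, 0.4)

  # two close competitors repel under hill climbing
  sigma <- 0.1
  p2 <- niche_sim_params(evolution_mode = "hill_climb", sigma_alpha = sigma,
                         evolution_step_sd = 0.005)
  pair <- community_state(c(0.5, 0.5 + 0.5 * sigma), c(0.4, 0.4))
  out <- evolution_step(pair, p2)
  expect_gt(diff(out$x), diff(pair$x))

  # mutation mode keeps abundances and species count, respects the axis
  p3 <- niche_sim_params(evolution_mode = "mutation_selection",
                         evolution_step_sd = 0.05, seed = NULL)
  set.seed(9)
  big <- community_state(runif(50), runif(50, 0.1, 1))
  out3 <- evolution_step(big, p3)
  expect_equal(out3$N, big$N)
  expect_equal(length(out3$x), 50)
  expect_true(all(out3$x >= 0 & out3$x <= 1))

  p4 <- niche_sim_params(evolution_mode = "none")
  expect_error(evolution_step(st, p4), "skip")
})

test_that("run_simulation is deterministic under a fixed seed", {
  p <- niche_sim_params(n_species = 30, t_max = 20, seed = 11)
  expect_identical(run_simulation(p), run_simulation(p))
})

test_that("a kernel wider than the axis behaves as one logistic niche", {
  p <- niche_sim_params(n_species = 20, sigma_alpha = 5, K0 = 1,
                        evolution_mode = "none", t_max = 60, dt = 0.1,
                        extinction_threshold = 0, seed = 4)
  sim <- run_simulation(p)
  expect_lt(abs(sum(sim$final_state$N) - 1), 0.01)
})

test_that("abundances are non-negative at every recorded state", {
  p <- niche_sim_params(n_species = 50, t_max = 30, seed = 5)
  sim <- run_simulation(p, record_every = 5)
  expect_true(all(sim$trajectory$N >= 0))
  expect_false(is.unsorted(sim$trajectory$t))
})

test_that("lump_summary clusters positions by single linkage", {
  st <- community_state(c(0.10, 0.11, 0.50), c(1, 1, 2))
  L <- lump_summary(st, 0.05)
  expect_equal(nrow(L), 2)
  expect_equal(L$n_species, c(2, 1))
  expect_equal(L$center, c(0.105, 0.5))
  expect_equal(sum(L$abundance), sum(st$N))

  same <- community_state(rep(0.3, 4), rep(0.25, 4))
  L1 <- lump_summary(same, 0.05)
  expect_equal(nrow(L1), 1)
  expect_equal(L1$center, 0.3)

  expect_equal(nrow(lump_summary(community_state(numeric(), numeric()), 0.1)), 0)
})

test_that("niche positions map onto the stated body-length range", {
  lens <- niche_to_length(c(0, 0.5, 1), length_range_mm = c(1, 36))
  expect_equal(lens[c(1, 3)], c(1, 36))
  expect_equal(lens[2], sqrt(36), tolerance = 1e-12)
})
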