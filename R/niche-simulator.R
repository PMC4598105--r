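#' Parameters for the niche-competition simulator
#'
#' Lotka-Volterra competition of species on a one-dimensional niche axis.
#' Species `i` has niche position `x_i` and abundance `N_i`, with
#' \deqn{dN_i/dt = r N_i (K(x_i) - \sum_j \alpha(x_i, x_j) N_j) / K(x_i),}
#' where the competition coefficient is a Gaussian kernel of the niche
#' distance (see [competition_coefficient()]) and includes the self term
#' \eqn{\alpha(x_i, x_i) = 1}. Between bouts of ecological dynamics the
#' niche positions evolve (see [evolution_step()]), and species whose
#' abundance falls below `extinction_threshold` are removed. On a finite
#' axis this interplay collapses an initially scattered community into a
#' small number of distinct position clusters ("lumps").
#'
#' The niche axis is abstract; for body-size applications it is read as log
#' body length, so `exp()` of (an affine map of) positions gives lengths in
#' mm.
#'
#' @param n_species Initial number of species.
#' @param axis_range Closed interval of admissible niche values.
#' @param r Intrinsic growth rate (> 0), per unit time.
#' @param K0 Carrying-capacity scale (> 0), abundance units.
#' @param K_center,K_width Optional Gaussian carrying-capacity profile
#'   `K(x) = K0 exp(-(x - K_center)^2 / (2 K_width^2))`; both `NULL`
#'   (default) gives uniform `K(x) = K0`.
#' @param sigma_alpha Competition-kernel width in niche units (> 0).
#' @param extinction_threshold Abundance below which a species is removed
#'   (>= 0) at the end of each integration call.
#' @param evolution_mode `"mutation_selection"` (default; positions take
#'   Normal(0, `evolution_step_sd`) steps and selection acts through the
#'   ecological dynamics), `"hill_climb"` (each species moves
#'   `evolution_step_sd` towards higher per-capita growth by a
#'   finite-difference sign test), or `"none"`.
#' @param evolution_step_sd Niche-unit scale of evolutionary position
#'   changes (>= 0).
#' @param dt Integration step (> 0) for the fixed-step 4th-order
#'   Runge-Kutta scheme.
#' @param t_max Total simulated time (> 0).
#' @param evolution_interval Time between evolutionary updates (>= `dt`).
#' @param boundary `"reflecting"` (default) or `"clipping"`: how
#'   evolutionary moves beyond `axis_range` are handled.
#' @param seed Integer seed for initial positions and evolutionary noise,
#'   or `NULL`.
#'
#' @return A validated list of class `"niche_sim_params"`.
#' @seealso [run_simulation()]
#' @export
niche_sim_params <- function(n_species = 200, axis_range = c(0, 1), r = 1,
                             K0 = 1, K_center = NULL, K_width = NULL,
                             sigma_alpha = 0.05, extinction_threshold = 0.004,
                             evolution_mode = c("mutation_selection",
                                                "hill_climb", "none"),
                             evolution_step_sd = 0.001, dt = 0.1,
                             t_max = 1000, evolution_interval = 1,
                             boundary = c("reflecting", "clipping"),
                             seed = NULL) {
  evolution_mode <- match.arg(evolution_mode)
  boundary <- match.arg(boundary)
  n_species <- check_count(n_species, "n_species")
  if (length(axis_range) != 2L || !all(is.finite(axis_range)) ||
      axis_range[1] >= axis_range[2]) {
    abort("`axis_range` must be a finite interval c(lo, hi) with lo < hi.")
  }
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  check_number(K0, "K0", lower = 0, strict_lower = TRUE)
  if (xor(is.null(K_center), is.null(K_width))) {
    abort("Supply both `K_center` and `K_width`, or neither.")
  }
  if (!is.null(K_width)) check_number(K_width, "K_width", lower = 0, strict_lower = TRUE)
  check_number(sigma_alpha, "sigma_alpha", lower = 0, strict_lower = TRUE)
  check_number(extinction_threshold, "extinction_threshold", lower = 0)
  check_number(evolution_step_sd, "evolution_step_sd", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(t_max, "t_max", lower = 0, strict_lower = TRUE)
  check_number(evolution_interval, "evolution_interval", lower = dt)
  structure(
    list(n_species = n_species, axis_range = as.numeric(axis_range), r = r,
         K0 = K0, K_center = K_center, K_width = K_width,
         sigma_alpha = sigma_alpha,
         extinction_threshold = extinction_threshold,
         evolution_mode = evolution_mode,
         evolution_step_sd = evolution_step_sd, dt = dt, t_max = t_max,
         evolution_interval = evolution_interval, boundary = boundary,
         seed = seed),
    class = "niche_sim_params"
  )
}

#' Construct a community state
#'
#' @param x Niche positions.
#' @param N Abundances (>= 0), same length as `x`.
#' @param t Elapsed time.
#' @return A list of class `"community_state"` with elements `x`, `N`, `t`.
#' @export
community_state <- function(x, N, t = 0) {
  if (length(x) != length(N)) {
    abort(sprintf("`x` (%d) and `N` (%d) must have equal length.",
                  length(x), length(N)))
  }
  if (any(N < 0)) abort("Abundances must be non-negative.")
  structure(list(x = as.numeric(x), N = as.numeric(N), t = t),
            class = "community_state")
}

#' Gaussian competition coefficient
#'
#' Competitive effect between species at niche positions `x_i` and `x_j`:
#' `exp(-(x_i - x_j)^2 / (2 sigma_alpha^2))`. Symmetric, equal to 1 iff the
#' positions coincide, and decaying with niche distance, so that similar
#' species compete strongly and distant ones hardly at all. Vectorised over
#' `x_i`/`x_j`.
#'
#' @param x_i,x_j Niche positions.
#' @param sigma_alpha Kernel width (> 0).
#' @return Values in (0, 1].
#' @examples
#' competition_coefficient(0, 0.05, 0.05)  # one kernel width: exp(-0.5)
#' @export
competition_coefficient <- function(x_i, x_j, sigma_alpha) {
  check_number(sigma_alpha, "sigma_alpha", lower = 0, strict_lower = TRUE)
  exp(-(x_i - x_j)^2 / (2 * sigma_alpha^2))
}

# Full pairwise kernel matrix for a position vector.
alpha_matrix <- function(x, sigma_alpha) {
  exp(-outer(x, x, "-")^2 / (2 * sigma_alpha^2))
}

# Carrying capacity at positions x under the params' K profile.
carrying_capacity <- function(x, params) {
  if (is.null(params$K_center)) rep(params$K0, length(x))
  else params$K0 * exp(-(x - params$K_center)^2 / (2 * params$K_width^2))
}

#' Lotka-Volterra abundance derivatives
#'
#' `dN_i/dt = r N_i (K(x_i) - sum_j alpha_ij N_j) / K(x_i)`, with the self
#' term `alpha_ii = 1` included in the sum. Zero abundance is an absorbing
#' state (`dN_i/dt = 0` when `N_i = 0`).
#'
#' @param state A [community_state()].
#' @param params A [niche_sim_params()].
#' @return Numeric vector of `dN/dt`, one per species.
#' @export
lv_derivatives <- function(state, params) {
  stopifnot(inherits(state, "community_state"),
            inherits(params, "niche_sim_params"))
  if (length(state$x) != length(state$N)) {
    abort("State has mismatched position and abundance vectors.")
  }
  if (length(state$x) == 0L) return(numeric())
  A <- alpha_matrix(state$x, params$sigma_alpha)
  K <- carrying_capacity(state$x, params)
  lv_derivatives_impl(state$N, A, K, params$r)
}

lv_derivatives_impl <- function(N, A, K, r) {
  r * N * (K - as.vector(A %*% N)) / K
}

#' Integrate the ecological dynamics
#'
#' Advances abundances by fixed-step 4th-order Runge-Kutta at step
#' `params$dt` (a final shorter step covers any remainder), holding niche
#' positions fixed. Abundances are clamped at zero after every stage, and
#' species below `params$extinction_threshold` are removed at the end of
#' the call, never mid-step.
#'
#' @inheritParams lv_derivatives
#' @param duration Time to integrate (>= 0); `0` returns the state
#'   unchanged.
#' @return The advanced [community_state()].
#' @export
integrate_dynamics <- function(state, params, duration) {
  stopifnot(inherits(state, "community_state"),
            inherits(params, "niche_sim_params"))
  check_number(duration, "duration", lower = 0)
  if (duration == 0 || length(state$x) == 0L) {
    state$x <- state$x[state$N >= params$extinction_threshold]
    state$N <- state$N[state$N >= params$extinction_threshold]
    return(state)
  }
  A <- alpha_matrix(state$x, params$sigma_alpha)
  K <- carrying_capacity(state$x, params)
  r <- params$r
  N <- state$N
  n_full <- floor(duration / params$dt + 1e-9)
  steps <- c(rep(params$dt, n_full), duration - n_full * params$dt)
  steps <- steps[steps > 1e-12]
  for (i in seq_along(steps)) {
    h <- steps[i]
    k1 <- lv_derivatives_impl(N, A, K, r)
    k2 <- lv_derivatives_impl(pmax(N + h / 2 * k1, 0), A, K, r)
    k3 <- lv_derivatives_impl(pmax(N + h / 2 * k2, 0), A, K, r)
    k4 <- lv_derivatives_impl(pmax(N + h * k3, 0), A, K, r)
    N <- pmax(N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (any(!is.finite(N))) {
      abort(sprintf(
        "Non-finite abundance at integration step %d (t = %g); reduce `dt`.",
        i, state$t + sum(steps[seq_len(i)])
      ))
    }
  }
  keep <- N >= params$extinction_threshold
  community_state(state$x[keep], N[keep], state$t + duration)
}

#' One evolutionary update of niche positions
#'
#' In `"hill_climb"` mode each species' position moves by
#' `evolution_step_sd` in whichever direction increases its per-capita
#' growth rate against the current community (finite-difference sign test
#' at `x +- evolution_step_sd`; exact ties stay put). In
#' `"mutation_selection"` mode every position receives an independent
#' Normal(0, `evolution_step_sd`) perturbation; selection then acts through
#' the ecological dynamics. Abundances and species count are unchanged;
#' positions are kept inside `axis_range` by the params' boundary rule
#' (reflection or clipping).
#'
#' @inheritParams lv_derivatives
#' @return The state with updated positions.
#' @export
evolution_step <- function(state, params) {
  stopifnot(inherits(state, "community_state"),
            inherits(params, "niche_sim_params"))
  if (params$evolution_mode == "none") {
    abort("`evolution_mode` is \"none\"; skip evolution_step() entirely.")
  }
  if (length(state$x) == 0L || params$evolution_step_sd == 0) return(state)
  delta <- params$evolution_step_sd
  x <- state$x
  if (params$evolution_mode == "hill_climb") {
    percap <- function(y) {
      # per-capita growth of a species relocated to y, community held fixed
      load <- as.vector(
        exp(-outer(y, x, "-")^2 / (2 * params$sigma_alpha^2)) %*% state$N
      )
      Ky <- carrying_capacity(y, params)
      params$r * (Ky - load) / Ky
    }
    up <- percap(x + delta)
    dn <- percap(x - delta)
    move <- ifelse(up > dn, delta, ifelse(dn > up, -delta, 0))
    x_new <- x + move
  } else {
    x_new <- x + rnorm(length(x), 0, delta)
  }
  lo <- params$axis_range[1]; hi <- params$axis_range[2]
  if (params$boundary == "reflecting") {
    # single reflection suffices for steps much smaller than the axis
    x_new <- ifelse(x_new < lo, 2 * lo - x_new,
                    ifelse(x_new > hi, 2 * hi - x_new, x_new))
  }
  x_new <- pmin(pmax(x_new, lo), hi)
  community_state(x_new, state$N, state$t)
}

#' Run the full competition-evolution simulation
#'
#' Initialises `n_species` at uniform-random positions on the axis with
#' equal abundances `K0 / n_species` (the symmetric state whose instability
#' seeds the pattern), then alternates [integrate_dynamics()] over
#' `evolution_interval` with [evolution_step()] until `t_max`. Identical
#' params and seed give identical results.
#'
#' @param params A [niche_sim_params()].
#' @param record_every Optional time interval at which to snapshot the
#'   community into a trajectory tibble (`NULL` records nothing).
#' @return An object of class `"niche_sim"`: a list with `final_state`
#'   (a [community_state()]), `trajectory` (tibble `t`, `species`, `x`, `N`
#'   or `NULL`) and `params`.
#' @examples
#' sim <- run_simulation(niche_sim_params(n_species = 40, t_max = 50, seed = 1))
#' glance(sim)
#' @export
run_simulation <- function(params, record_every = NULL) {
  stopifnot(inherits(params, "niche_sim_params"))
  if (!is.null(record_every)) {
    check_number(record_every, "record_every", lower = params$evolution_interval)
  }
  with_seed_if(params$seed, {
    x0 <- runif(params$n_species, params$axis_range[1], params$axis_range[2])
    state <- community_state(sort(x0), rep(params$K0 / params$n_species,
                                           params$n_species))
    snaps <- list()
    snap <- function(st) {
      tibble(t = st$t, species = seq_along(st$x), x = st$x, N = st$N)
    }
    if (!is.null(record_every)) snaps[[1]] <- snap(state)
    next_record <- if (is.null(record_every)) Inf else record_every
    while (state$t < params$t_max - 1e-9) {
      chunk <- min(params$evolution_interval, params$t_max - state$t)
      state <- integrate_dynamics(state, params, chunk)
      if (params$evolution_mode != "none" && length(state$x) > 0L &&
          state$t < params$t_max - 1e-9) {
        state <- evolution_step(state, params)
      }
      if (state$t >= next_record - 1e-9) {
        snaps[[length(snaps) + 1L]] <- snap(state)
        next_record <- next_record + record_every
      }
    }
    structure(
      list(final_state = state,
           trajectory = if (length(snaps)) list_rbind(snaps) else NULL,
           params = params),
      class = "niche_sim"
    )
  })
}

#' Summarise a community into position lumps
#'
#' Single-linkage clustering of surviving niche positions: sorted positions
#' closer than `gap_threshold` join the same lump. Lump centres are
#' abundance-weighted mean positions.
#'
#' @param state A [community_state()] or a `niche_sim` result.
#' @param gap_threshold Minimum gap (niche units, > 0) separating lumps; a
#'   natural choice is `2 * sigma_alpha`.
#' @return A tibble with one row per lump: `lump`, `center`, `abundance`,
#'   `n_species`. Empty community gives zero rows.
#' @export
lump_summary <- function(state, gap_threshold) {
  if (inherits(state, "niche_sim")) state <- state$final_state
  stopifnot(inherits(state, "community_state"))
  check_number(gap_threshold, "gap_threshold", lower = 0, strict_lower = TRUE)
  if (length(state$x) == 0L) {
    return(tibble(lump = integer(), center = double(), abundance = double(),
                  n_species = integer()))
  }
  o <- order(state$x)
  x <- state$x[o]; N <- state$N[o]
  grp <- cumsum(c(1, diff(x) >= gap_threshold))
  tibble(
    lump = seq_len(max(grp)),
    center = as.vector(tapply(x * N, grp, sum) / tapply(N, grp, sum)),
    abundance = as.vector(tapply(N, grp, sum)),
    n_species = tabulate(grp)
  )
}

#' Map niche positions to body lengths
#'
#' The simulator's niche axis is interpreted as log body length. This maps
#' positions affinely from `axis_range` onto `log(length_range_mm)` and
#' exponentiates, giving lengths in mm for downstream mode analysis.
#'
#' @param x Niche positions.
#' @param axis_range The simulator axis interval.
#' @param length_range_mm Body lengths (mm) corresponding to the axis ends.
#' @return Body lengths in mm.
#' @export
niche_to_length <- function(x, axis_range = c(0, 1),
                            length_range_mm = c(1, 36)) {
  lo <- log(length_range_mm[1]); hi <- log(length_range_mm[2])
  exp(lo + (x - axis_range[1]) / diff(axis_range) * (hi - lo))
}

#' @export
print.niche_sim <- function(x, ...) {
  st <- x$final_state
  cat(sprintf(
    "<niche_sim> %d/%d species surviving at t = %g; total abundance %.4g\n",
    length(st$x), x$params$n_species, st$t, sum(st$N)
  ))
  invisible(x)
}
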