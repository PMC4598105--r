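# Small fixtures built in code, shared across test files.

zero_noise_pool <- function(n_lumps = 3, species_per_lump = 10,
                            spacing = 1.35, seed = 1) {
  generate_lumpy_pool(lumpy_pool_spec(
    n_lumps = n_lumps, base_length = 2, spacing_ratio = spacing,
    within_lump_sd = 0, species_per_lump = species_per_lump, seed = seed
  ))
}

tiny_occurrence <- function() {
  tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    species_id = c("a", "b", "c", "a", "d", "e"),
    length_mm = c(2, 2, 4, 2, 3, 5)
  )
}

# Two-species LV equilibrium N* = K / (1 + alpha): the closed-form oracle.
two_species_equilibrium <- function(d, sigma, K0) {
  K0 / (1 + exp(-d^2 / (2 * sigma^2)))
}

# Logistic growth closed form, the oracle for single-species integration.
logistic_closed_form <- function(N0, K, r, t) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}
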