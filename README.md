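# nichelumps

Communities of competing species often do not spread evenly over a niche
axis: body sizes cluster into a few regularly spaced groups ("lumps"),
with species inside a lump nearly identical and adjacent lumps separated
by a roughly constant length ratio. In diving-beetle communities that
ratio is about **1.35** (a 35% size difference), echoed by its multiples
≈ 1.8 and ≈ 2.4. nichelumps is an R package for ecologists who want to
simulate, detect and quantify this kind of size structure:

* **Simulator** — Lotka–Volterra competition on a one-dimensional niche
  axis with a Gaussian competition kernel and evolving trait positions:

  dN_i/dt = r N_i (K(x_i) − Σ_j α_ij N_j) / K(x_i),
  α_ij = exp(−(x_i − x_j)² / 2σ_α²),

  integrated by fixed-step RK4 with an extinction threshold and either a
  mutation–selection random walk or fitness hill-climbing for the
  evolutionary update (`run_simulation()`, `lump_summary()`).
* **Mode detection** — univariate Gaussian-mixture ("latent class") fits
  by EM with seeded restarts and a variance floor, scanned over 1–10
  classes and selected by BIC; plus Gaussian kernel densities with
  prominence-filtered peak finding (`select_best_mixture()`,
  `kernel_density()`, `find_density_peaks()`, `peak_to_peak_ratios()`).
* **Ratio pipeline** — the field analysis: filter co-occurrence samples
  to ≥ 3 species, form all within-sample pairwise length ratios
  (larger/smaller, so ratios ≥ 1), pool them across samples and run mode
  detection on the log ratios (`filter_samples_min_richness()`,
  `pool_ratios()`, `analyze_ratio_modes()`).
* **Synthetic data** — seeded generators for lumpy species pools,
  occurrence samples with fixed or truncated-Poisson richness,
  three-species "aquifer" communities and multi-region catalogues, so
  every stage is testable without external datasets.

Everything is tibble-first and pipe-friendly, with broom-style `tidy()` /
`glance()` methods and ggplot2 `autoplot()` methods for each result type.
A small CLI (`synth`, `simulate`, `fit-modes`, `ratios`) wraps the same
functions; see `inst/cli/nichelumps.R`.

## Worked example

Generate a three-lump species pool (spacing ratio 1.35), sample it the
way field surveys sample ditches, pool the within-sample pairwise ratios,
and ask the mixture stage what modes the ratio distribution contains:

```r
library(nichelumps)

pool <- generate_lumpy_pool(lumpy_pool_spec(
  n_lumps = 3, base_length = 2, spacing_ratio = 1.35,
  within_lump_sd = 0.03, species_per_lump = 15, seed = 1
))
occ <- generate_cooccurrence_samples(pool, sampling_spec(
  n_samples = 400, richness = 4, seed = 2
))
rs  <- pool_ratios(filter_samples_min_richness(occ, 3))
res <- analyze_ratio_modes(rs, kmax = 6, seed = 3)
res
#> <mode_analysis> best k = 5 by BIC over k = 1-6 (n = 3158)
#> modes (mm): 1.006, 1.027, 1.069, 1.35, 1.822
#> peak-to-peak ratios: 1.022, 1.04, 1.263, 1.349

tidy(res)
#> # A tibble: 5 × 4
#>    mode location_log location_mm ratio_to_previous
#>   <int>        <dbl>       <dbl>             <dbl>
#> 1     1      0.00580        1.01             NA
#> 2     2      0.0271         1.03              1.02
#> 3     3      0.0666         1.07              1.04
#> 4     4      0.300          1.35              1.26
#> 5     5      0.600          1.82              1.35
```

Reading the output: the pooled ratios split into a cluster at ≈ 1
(same-lump pairs — several overlapping components describe its folded,
one-sided shape) and sharp modes at **1.35** and **1.82** — the
fundamental lump spacing and its square, recovered end to end from the
sampled co-occurrence data. `autoplot(res)` overlays the fitted
components on the histogram; `autoplot(pool_ratios(occ))` shows the raw
ratio histogram.

The simulator side works the same way:

```r
sim <- run_simulation(niche_sim_params(
  n_species = 200, sigma_alpha = 0.05, dt = 1, t_max = 2e4, seed = 1
))
lump_summary(sim, gap_threshold = 0.1)   # one row per surviving lump
autoplot(sim)                            # abundance spikes on the axis
```

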