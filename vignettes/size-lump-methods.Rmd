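---
title: "Self-organized body-size lumps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organized body-size lumps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichelumps)
library(dplyr)
```

nichelumps studies a specific macroecological phenomenon: communities of
competing species whose body sizes cluster into a small number of
regularly spaced groups ("lumps"), with adjacent lumps separated by a
roughly constant length ratio. The package provides three connected tool
sets: a competition–evolution simulator that can produce such patterns, a
mode-detection stage for log size distributions, and a pipeline that turns
field co-occurrence samples into pooled pairwise body-length ratios. A
seeded synthetic-data module emulates the tabular inputs (species
catalogues and occurrence samples) so the whole chain is testable without
external data.

## The competition–evolution model

Species live on a one-dimensional niche axis, read as log body length.
Species $i$ has niche position $x_i$ and abundance $N_i$, with
Lotka–Volterra dynamics

$$\frac{dN_i}{dt} = r\,N_i\,
  \frac{K(x_i) - \sum_j \alpha(x_i, x_j)\, N_j}{K(x_i)},
  \qquad
  \alpha(x_i, x_j) = \exp\!\left(-\frac{(x_i - x_j)^2}
  {2\sigma_\alpha^2}\right).$$

The Gaussian kernel $\alpha$ makes similarly sized species compete
strongly ($\alpha \to 1$) and distantly sized species hardly at all. The
self term $\alpha_{ii} = 1$ is included in the sum, so a lone species
follows plain logistic growth — the closed form of which, together with
the two-species equilibrium $N^* = K/(1+\alpha)$, are the analytic oracles
used by the test suite.

Integration is fixed-step 4th-order Runge–Kutta (default `dt = 0.1`;
abundances clamped at zero after each stage). Species are pruned below
`extinction_threshold` only *between* integration calls, never mid-step.
Between ecological bouts of length `evolution_interval`, niche positions
evolve; `run_simulation()` starts from the symmetric state (uniform random
positions, equal abundances $K_0/n$) whose instability seeds the pattern.

### Why mutation–selection is the default evolutionary rule

Two evolutionary updates are implemented. `hill_climb` moves each species
by `evolution_step_sd` towards higher per-capita growth (a
finite-difference sign test on the invasion-fitness landscape);
`mutation_selection` applies an unbiased Normal(0, `evolution_step_sd`)
step to every position and lets selection act purely through the
ecological dynamics.

We made `mutation_selection` the default after characterising both rules.
With a uniform carrying capacity the invasion-fitness landscape generated
by a cluster of species *repels its own members* (each member gains by
stepping away from its neighbours' competitive load), so deterministic
hill-climbing relaxes the community towards classical limiting-similarity
*over*dispersion: single species spaced evenly at about one kernel width,
with no gaps wider than $2\sigma_\alpha$. The random-walk rule instead
keeps positions diffusing while slow near-neutral exclusion removes
species stranded between the surviving clusters, and reliably leaves a
final state with several distinct position clusters. `hill_climb` remains
available and is the right tool for studying trait divergence of small
communities (its pairwise-divergence behaviour is part of the test suite).

### What the simulator does and does not reproduce

A point we consider important enough to state explicitly: with a Gaussian
competition kernel and *uniform* $K$, the continuum model has no Turing
wavelength (the kernel's Fourier transform is positive everywhere), so
there is no deterministic length scale that could pin lump spacing. In
long runs the surviving clusters sit roughly $4$–$6\,\sigma_\alpha$ apart,
far enough that residual competition between them ($\alpha \sim 10^{-5}$)
cannot rearrange positions. Consequently:

* the *number* of lumps and the *increase* of mean spacing with
  $\sigma_\alpha$ are robust across seeds, but
* the *regularity* of the spacing is not: across many seeds the
  coefficient of variation of inter-lump spacings stabilises around
  0.35–0.5, because the spacings are frozen relics of a stochastic
  extinction transient.

Seed-robust regular spacing requires a non-uniform resource landscape; a
Gaussian $K(x)$ profile is available (`K_center`, `K_width`) for exactly
that purpose. The acceptance metrics report the uniform-$K$ behaviour as
measured.

Simulated problem sizes used in the tests and the acceptance script
(200 species, $t_{\max} = 2\times 10^4$ with `dt = 1` for the
pattern runs) were chosen as the smallest runs at which the pattern
metrics stop changing with longer time; the mutation noise dominates the
integration error at this step size.

## Mode detection

The mode stage asks: how many size classes does a log length (or log
ratio) distribution contain, and where are they?

`fit_gaussian_mixture()` fits a $k$-component univariate Gaussian mixture
by EM, taking the best of `n_init = 10` seeded restarts by log-likelihood
(ties to the earliest restart). Numerical choices:

* **Variance floor.** Component sds are floored at $10^{-4}$ (log scale).
  Catalogue lengths are rounded, so exact ties are common and would
  otherwise let a component collapse onto a spike of tied values with
  unbounded likelihood.
* **Feasibility.** A fit requires $n \ge 2k$; infeasible $k$ are skipped
  by the scan and recorded, not raised as errors.
* **Nesting.** `select_best_mixture()` warm-starts each $k$ from the best
  $k-1$ fit (splitting the heaviest component), so the maximised
  log-likelihood is non-decreasing in $k$ up to EM convergence noise.
* **Selection.** Default criterion is BIC (lower is better, ties to the
  smaller $k$), with AIC selectable. A pure-likelihood rule would always
  prefer more classes; BIC's $\tfrac{3k-1}{2}\log n$ penalty is the
  conventional univariate-mixture choice.
* **Mode merging.** Components of the selected fit whose means differ by
  less than half the sum of their sds are merged (weight-weighted) before
  peak-to-peak ratios are formed, so near-duplicate components cannot
  fabricate spurious ratios near 1.

Peak-to-peak ratios are `exp()` of consecutive mode differences: on the
log scale a geometric size ladder $\ell, \rho\ell, \rho^2\ell$ becomes
equally spaced modes with all consecutive ratios equal to $\rho$.

`kernel_density()` (Gaussian kernel, Silverman bandwidth by default, grid
spanning the data ± 3 bandwidths, renormalised to integrate to 1) and
`find_density_peaks()` (strict local maxima filtered by topographic
prominence) provide the non-parametric companion: mixture means and
density peaks are two defensible readings of "mode", and both paths are
exposed so the analyst can compare them.

```{r modes}
pool <- generate_lumpy_pool(lumpy_pool_spec(
  n_lumps = 3, base_length = 2, spacing_ratio = 1.35,
  within_lump_sd = 0.05, species_per_lump = 200, seed = 1
))
res <- select_best_mixture(log(pool$length_mm), kmax = 6, seed = 1)
glance(res)
res$peak_to_peak_ratios
```

## The co-occurrence ratio pipeline

Field samples (one row per sample × species, with the species' mean adult
body length in mm) are filtered to samples with at least
`min_species = 3` distinct species — pairs from two-species samples say
little about packing — and every within-sample unordered pair contributes
one ratio, larger length over smaller, so all ratios are $\ge 1$ and a
tied pair contributes exactly 1. Ratios are **not** deduplicated across
samples: the pooled set counts co-occurrence events, which is what makes
its modes interpretable as how often particular spacings are realised in
the field. Mixture fitting then runs on the log ratios and reports modes
back-transformed to the ratio scale.

```{r ratios}
occ <- generate_cooccurrence_samples(pool, sampling_spec(
  n_samples = 300, richness = 4, seed = 2
))
rs <- pool_ratios(filter_samples_min_richness(occ, 3))
analyze_ratio_modes(rs, kmax = 6, seed = 3)$modes_mm
```

## What the synthetic data emulate — and what they do not

`generate_lumpy_pool()` draws species pools with exactly geometric lump
spacing and Gaussian within-lump scatter on the log scale; the defaults
(spacing ratio 1.35, aquifer step ratio 1.6) mirror the empirical spacing
values reported for diving-beetle communities, so default runs produce
ratio histograms with the familiar 1 / 1.35 / 1.8 ladder.
`generate_cooccurrence_samples()` draws species without replacement with a
fixed or 1-truncated-Poisson richness law — the truncated Poisson is a
stated stand-in, not an inference, since real survey richness
distributions are protocol-dependent. `generate_aquifer_triplets()` builds
three-species communities (small/medium/large at a constant step ratio,
default base length lognormal around 1.2 mm, the scale of subterranean
diving beetles).

The generators deliberately omit much of what real data carry: taxonomy,
spatial autocorrelation between samples, detection covariance,
abundance-dependent catchability, and rounding of published lengths
(rounding is available as an option, default off, because granularity
visibly restructures ratio histograms near 1). Passing tests on synthetic
pools therefore demonstrate that the *pipeline* recovers known structure,
not that any particular field dataset has that structure.

All log-scale quantities use the natural log throughout, so sd parameters
and mixture means are directly comparable across the simulator, the
generators and the mode stage.

## Known limitations

* One niche dimension only; no explicit genetics, speciation bookkeeping,
  or spatial structure in the simulator.
* Uniform-$K$ lump spacing is irregular by nature of the model (above);
  use the Gaussian $K$ profile when a regular reference pattern is
  needed.
* Mixture selection by BIC is consistent but conservative at small $n$;
  with fewer than ~50 observations per true class, expect merged modes.
* The ratio pipeline weights every co-occurrence event equally; no
  abundance weighting or regional stratification is built in.
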