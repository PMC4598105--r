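# The co-occurrence size-ratio analysis: filter samples by richness, form
# all within-sample pairwise body-length ratios, pool them, and detect
# modes in the pooled log ratios.

check_occurrence <- function(samples, arg = "samples") {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "species_id", "length_mm") %in% names(samples))) {
    abort(sprintf(
      "`%s` must be a data frame with columns sample_id, species_id, length_mm.",
      arg
    ))
  }
  bad <- samples$length_mm <= 0 | !is.finite(samples$length_mm)
  if (any(bad)) {
    abort(sprintf(
      "Non-positive body length for species: %s.",
      paste(unique(samples$species_id[bad]), collapse = ", ")
    ))
  }
  invisible(samples)
}

#' Keep samples with at least a minimum species richness
#'
#' Pairwise ratio analyses are only informative for samples holding several
#' species; the conventional cut keeps samples where more than two species
#' were found (`min_species = 3`).
#'
#' @param samples Occurrence tibble (`sample_id`, `species_id`,
#'   `length_mm`), e.g. from [generate_cooccurrence_samples()] or
#'   [read_occurrence_table()].
#' @param min_species Minimum number of distinct species (>= 1).
#' @return The filtered tibble, sample order preserved.
#' @export
filter_samples_min_richness <- function(samples, min_species = 3) {
  check_occurrence(samples)
  min_species <- check_count(min_species, "min_species")
  keep <- samples |>
    group_by(.data$sample_id) |>
    filter(dplyr::n_distinct(.data$species_id) >= min_species) |>
    ungroup()
  keep
}

#' All within-sample pairwise body-length ratios
#'
#' For every sample, forms each unordered species pair and computes the
#' ratio of the larger to the smaller body length (>= 1). Pairs are
#' reported with species ids in lexicographic order. A sample with `n`
#' species contributes `n (n - 1) / 2` ratios; single-species samples
#' contribute none. Equal lengths give a ratio of exactly 1 and are kept:
#' near-identical co-occurring sizes are a signal, not an artefact.
#'
#' @inheritParams filter_samples_min_richness
#' @return A tibble with columns `sample_id`, `species_a`, `species_b`,
#'   `ratio`.
#' @examples
#' occ <- tibble::tibble(sample_id = "s1", species_id = c("a", "b", "c"),
#'                       length_mm = c(2, 2, 4))
#' pairwise_length_ratios(occ)
#' @export
pairwise_length_ratios <- function(samples) {
  check_occurrence(samples)
  empty <- tibble(sample_id = character(), species_a = character(),
                  species_b = character(), ratio = double())
  if (nrow(samples) == 0L) return(empty)
  out <- samples |>
    group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      if (n < 2L) return(NULL)
      idx <- utils::combn(n, 2L)
      a <- idx[1L, ]; b <- idx[2L, ]
      swap <- df$species_id[a] > df$species_id[b]
      sp_a <- ifelse(swap, df$species_id[b], df$species_id[a])
      sp_b <- ifelse(swap, df$species_id[a], df$species_id[b])
      tibble(
        sample_id = key$sample_id,
        species_a = sp_a,
        species_b = sp_b,
        ratio = pmax(df$length_mm[a], df$length_mm[b]) /
          pmin(df$length_mm[a], df$length_mm[b])
      )
    }) |>
    list_rbind()
  if (nrow(out) == 0L) empty else out
}

#' Pool pairwise ratios across samples
#'
#' Concatenates every sample's pairwise ratios with per-ratio provenance.
#' A species pair occurring in several samples contributes once per sample
#' — pooled ratios count co-occurrence events, not unique pairs.
#'
#' @inheritParams filter_samples_min_richness
#' @return A tibble of class `"ratio_set"` (`sample_id`, `species_a`,
#'   `species_b`, `ratio`) with attributes `n_samples_used` (samples
#'   contributing at least one pair) and `n_pairs`.
#' @export
pool_ratios <- function(samples) {
  ratios <- pairwise_length_ratios(samples)
  attr(ratios, "n_samples_used") <- dplyr::n_distinct(ratios$sample_id)
  attr(ratios, "n_pairs") <- nrow(ratios)
  class(ratios) <- c("ratio_set", class(ratios))
  ratios
}

#' Detect modes in pooled body-length ratios
#'
#' Runs [select_best_mixture()] on the natural log of the pooled ratios
#' (so a geometric ratio ladder 1, rho, rho^2, ... becomes equally spaced
#' modes) and reports the modes back-transformed to the ratio scale.
#'
#' @param ratio_set A [pool_ratios()] result (or any data frame with a
#'   `ratio` column of values >= 1).
#' @inheritParams select_best_mixture
#' @return A `mode_analysis` object (see [select_best_mixture()]); its
#'   `modes_mm` field holds the ratio-scale modes here.
#' @examples
#' pool <- generate_lumpy_pool(lumpy_pool_spec(within_lump_sd = 0.03, seed = 1))
#' occ <- generate_cooccurrence_samples(pool, sampling_spec(200, 4, seed = 2))
#' res <- analyze_ratio_modes(pool_ratios(occ), kmax = 6, seed = 3)
#' res$modes_mm
#' @export
analyze_ratio_modes <- function(ratio_set, kmin = 1, kmax = 10,
                                criterion = c("bic", "aic"), n_init = 10,
                                seed = NULL, tol = 1e-6, max_iter = 500) {
  if (!is.data.frame(ratio_set) || !"ratio" %in% names(ratio_set)) {
    abort("`ratio_set` must be a data frame with a `ratio` column.")
  }
  if (any(ratio_set$ratio < 1)) {
    abort("Ratios must follow the larger/smaller convention (all >= 1).")
  }
  select_best_mixture(log(ratio_set$ratio), kmin = kmin, kmax = kmax,
                      criterion = criterion, n_init = n_init, seed = seed,
                      tol = tol, max_iter = max_iter)
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf("<ratio_set> %d pairwise ratios from %d samples\n",
              attr(x, "n_pairs"), attr(x, "n_samples_used")))
  NextMethod()
}
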