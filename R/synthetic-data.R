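#' Specify a lumpy log-size species pool
#'
#' Describes a species pool whose log body lengths cluster into `n_lumps`
#' groups ("lumps") with geometrically spaced centers: lump `k` (k = 0, 1,
#' ...) is centred at `base_length * spacing_ratio^k` mm. Within a lump,
#' log lengths scatter around the centre with standard deviation
#' `within_lump_sd` (natural-log scale). This is the size structure that
#' limiting-similarity theory predicts for competing species on a body-size
#' niche axis, with adjacent lumps separated by a constant length ratio.
#'
#' @param n_lumps Number of lumps (positive integer).
#' @param base_length Centre of the smallest lump, in mm (> 0).
#' @param spacing_ratio Geometric ratio between consecutive lump centres
#'   (> 1). The default 1.35 is the canonical limiting-similarity spacing
#'   for diving-beetle body lengths.
#' @param within_lump_sd Standard deviation of log length within a lump
#'   (natural-log scale, >= 0).
#' @param species_per_lump Species count per lump: a single integer applied
#'   to every lump, or a vector of length `n_lumps`.
#' @param seed Integer seed, or `NULL` to use the ambient RNG stream.
#'
#' @return A validated list of class `"lumpy_pool_spec"`.
#' @seealso [generate_lumpy_pool()]
#' @export
lumpy_pool_spec <- function(n_lumps = 3, base_length = 2, spacing_ratio = 1.35,
                            within_lump_sd = 0.05, species_per_lump = 10,
                            seed = NULL) {
  n_lumps <- check_count(n_lumps, "n_lumps")
  check_number(base_length, "base_length", lower = 0, strict_lower = TRUE)
  check_number(spacing_ratio, "spacing_ratio", lower = 1, strict_lower = TRUE)
  check_number(within_lump_sd, "within_lump_sd", lower = 0)
  if (length(species_per_lump) == 1L) {
    species_per_lump <- rep(species_per_lump, n_lumps)
  }
  if (length(species_per_lump) != n_lumps) {
    abort("`species_per_lump` must have length 1 or `n_lumps`.")
  }
  species_per_lump <- vapply(seq_along(species_per_lump), function(i) {
    check_count(species_per_lump[[i]], sprintf("species_per_lump[%d]", i))
  }, integer(1))
  structure(
    list(n_lumps = n_lumps, base_length = base_length,
         spacing_ratio = spacing_ratio, within_lump_sd = within_lump_sd,
         species_per_lump = species_per_lump, seed = seed),
    class = "lumpy_pool_spec"
  )
}

#' Generate a lumpy species pool
#'
#' Draws a species pool from a [lumpy_pool_spec()]: species `i` in lump `k`
#' gets `log(length_mm) ~ Normal(log(base_length) + k * log(spacing_ratio),
#' within_lump_sd)`. Identical spec and seed give identical pools.
#'
#' @param spec A [lumpy_pool_spec()].
#' @param region Optional region tag stored in a `region` column.
#' @param round_to Optional rounding granularity in mm (e.g. `0.1` for
#'   catalogue-style lengths). Default `NULL` keeps full float precision,
#'   since rounding granularity affects downstream ratio histograms.
#'
#' @return A tibble of class `"species_pool"` with columns `species_id`,
#'   `region` (if given), `lump` (1-based lump index) and `length_mm`.
#' @examples
#' pool <- generate_lumpy_pool(lumpy_pool_spec(seed = 1))
#' dplyr::count(pool, lump)
#' @export
generate_lumpy_pool <- function(spec, region = NULL, round_to = NULL) {
  stopifnot(inherits(spec, "lumpy_pool_spec"))
  centers <- log(spec$base_length) +
    (seq_len(spec$n_lumps) - 1L) * log(spec$spacing_ratio)
  log_len <- with_seed_if(spec$seed, {
    unlist(lapply(seq_len(spec$n_lumps), function(k) {
      rnorm(spec$species_per_lump[k], centers[k], spec$within_lump_sd)
    }))
  })
  lump <- rep(seq_len(spec$n_lumps), spec$species_per_lump)
  len <- exp(log_len)
  if (!is.null(round_to)) len <- pmax(round(len / round_to) * round_to, round_to)
  out <- tibble(
    species_id = sprintf("sp%03d", seq_along(len)),
    lump = lump,
    length_mm = len
  )
  if (!is.null(region)) out <- mutate(out, region = as.character(region), .after = "species_id")
  class(out) <- c("species_pool", class(out))
  out
}

#' Specify a co-occurrence sampling design
#'
#' Describes how field-style occurrence samples are drawn from a species
#' pool: the number of samples and the per-sample richness law. Richness is
#' either a fixed count or a draw from a Poisson truncated below at 1
#' (every sample contains at least one species), mimicking richness
#' variation among field samples such as ditch macroinvertebrate surveys.
#'
#' @param n_samples Number of samples (positive integer).
#' @param richness Either a single fixed richness (integer >= 1) when
#'   `richness_law = "fixed"`, or the untruncated Poisson mean when
#'   `richness_law = "truncated_poisson"`.
#' @param richness_law `"fixed"` or `"truncated_poisson"`.
#' @param detection_bias Optional vector of relative per-lump detection
#'   weights (recycled over lumps); default equal weights.
#' @param seed Integer seed, or `NULL`.
#'
#' @return A validated list of class `"sampling_spec"`.
#' @export
sampling_spec <- function(n_samples = 100, richness = 4,
                          richness_law = c("truncated_poisson", "fixed"),
                          detection_bias = NULL, seed = NULL) {
  richness_law <- match.arg(richness_law)
  n_samples <- check_count(n_samples, "n_samples")
  if (richness_law == "fixed") {
    richness <- check_count(richness, "richness")
  } else {
    check_number(richness, "richness", lower = 0, strict_lower = TRUE)
  }
  if (!is.null(detection_bias)) {
    if (any(!is.finite(detection_bias)) || any(detection_bias < 0) ||
        all(detection_bias == 0)) {
      abort("`detection_bias` weights must be non-negative and not all zero.")
    }
  }
  structure(
    list(n_samples = n_samples, richness = richness,
         richness_law = richness_law, detection_bias = detection_bias,
         seed = seed),
    class = "sampling_spec"
  )
}

# Truncated-Poisson(lambda) on {1, 2, ...} by rejection; vectorised.
rtpois <- function(n, lambda) {
  out <- rpois(n, lambda)
  while (any(zero <- out == 0L)) out[zero] <- rpois(sum(zero), lambda)
  out
}

# Analytic mean of the 1-truncated Poisson; the test oracle lives here so
# the package and its tests share one closed form.
truncated_poisson_mean <- function(lambda) lambda / (1 - exp(-lambda))

#' Draw co-occurrence samples from a species pool
#'
#' Each sample is a without-replacement draw of species from `pool`, with
#' richness following the sampling spec's richness law (capped at the pool
#' size) and optional per-lump detection weights. The result is the long
#' occurrence format used throughout the ratio pipeline.
#'
#' @param pool A `species_pool` tibble from [generate_lumpy_pool()] (any
#'   data frame with `species_id` and `length_mm` works; a `lump` column is
#'   required only when the spec has `detection_bias`).
#' @param spec A [sampling_spec()].
#'
#' @return A tibble of class `"occurrence_tbl"` with columns `sample_id`,
#'   `species_id`, `length_mm`; one row per (sample, species).
#' @examples
#' pool <- generate_lumpy_pool(lumpy_pool_spec(seed = 1))
#' occ <- generate_cooccurrence_samples(pool, sampling_spec(20, 4, seed = 2))
#' @export
generate_cooccurrence_samples <- function(pool, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (!is.data.frame(pool) || nrow(pool) == 0L) {
    abort("`pool` must be a non-empty data frame of species.")
  }
  n_pool <- nrow(pool)
  if (spec$richness_law == "fixed" && spec$richness > n_pool) {
    abort(sprintf(
      "Fixed richness %d exceeds pool size %d.", spec$richness, n_pool
    ))
  }
  weights <- rep(1, n_pool)
  if (!is.null(spec$detection_bias)) {
    if (!"lump" %in% names(pool)) {
      abort("`detection_bias` requires a `lump` column in the pool.")
    }
    w <- rep_len(spec$detection_bias, max(pool$lump))
    weights <- w[pool$lump]
  }
  with_seed_if(spec$seed, {
    richness <- if (spec$richness_law == "fixed") {
      rep(spec$richness, spec$n_samples)
    } else {
      pmin(rtpois(spec$n_samples, spec$richness), n_pool)
    }
    rows <- lapply(seq_len(spec$n_samples), function(s) {
      idx <- sample.int(n_pool, richness[s], prob = weights)
      tibble(
        sample_id = sprintf("s%04d", s),
        species_id = pool$species_id[idx],
        length_mm = pool$length_mm[idx]
      )
    })
    out <- list_rbind(rows)
    class(out) <- c("occurrence_tbl", class(out))
    out
  })
}

#' Generate aquifer-style three-species samples
#'
#' Emulates isolated groundwater communities in which evolution repeatedly
#' produced a small, a medium and a large species: each "aquifer" sample
#' holds exactly three species with log lengths `log(base) + {0, 1, 2} *
#' log(step_ratio)` plus independent Normal(0, `ratio_noise_sd`) noise.
#' The default step ratio 1.6 is the wide niche spacing typical of such
#' species-poor communities (wider than the 1.35 of species-rich surface
#' communities, since fewer competitors leave more room on the niche axis).
#'
#' @param n_aquifers Number of aquifer samples (>= 1).
#' @param base_length_law Base (smallest-species) length law: either a
#'   single fixed length in mm, or `c(meanlog, sdlog)` of a lognormal.
#'   Default `c(log(1.2), 0.25)`.
#' @param step_ratio Length ratio between consecutive size classes (> 1).
#' @param ratio_noise_sd Log-scale sd of the noise on each species length
#'   (>= 0).
#' @param seed Integer seed, or `NULL`.
#'
#' @return An `occurrence_tbl` tibble (`sample_id`, `species_id`,
#'   `length_mm`) with three rows per aquifer and a `size_class` column
#'   (`"small"`, `"medium"`, `"large"`).
#' @examples
#' generate_aquifer_triplets(2, base_length_law = 1, ratio_noise_sd = 0, seed = 1)
#' @export
generate_aquifer_triplets <- function(n_aquifers,
                                      base_length_law = c(log(1.2), 0.25),
                                      step_ratio = 1.6, ratio_noise_sd = 0.03,
                                      seed = NULL) {
  n_aquifers <- check_count(n_aquifers, "n_aquifers")
  check_number(step_ratio, "step_ratio", lower = 1, strict_lower = TRUE)
  check_number(ratio_noise_sd, "ratio_noise_sd", lower = 0)
  with_seed_if(seed, {
    base <- if (length(base_length_law) == 1L) {
      check_number(base_length_law, "base_length_law", lower = 0,
                   strict_lower = TRUE)
      rep(base_length_law, n_aquifers)
    } else {
      rlnorm(n_aquifers, base_length_law[1], base_length_law[2])
    }
    steps <- 0:2
    rows <- lapply(seq_len(n_aquifers), function(a) {
      loglen <- log(base[a]) + steps * log(step_ratio) +
        rnorm(3, 0, ratio_noise_sd)
      tibble(
        sample_id = sprintf("aq%03d", a),
        species_id = sprintf("aq%03d_%s", a, c("S", "M", "L")),
        size_class = c("small", "medium", "large"),
        length_mm = exp(loglen)
      )
    })
    out <- list_rbind(rows)
    class(out) <- c("occurrence_tbl", class(out))
    out
  })
}

#' Generate a multi-region species catalogue
#'
#' Concatenates one lumpy pool per region into a catalogue table, the shape
#' of a per-region species checklist with mean adult body lengths.
#'
#' @param regions A named list of [lumpy_pool_spec()] objects; names are the
#'   region tags and must be unique.
#'
#' @return A tibble with columns `species_id`, `region`, `lump`,
#'   `length_mm`; species ids are unique across the catalogue. Empty input
#'   gives an empty catalogue.
#' @examples
#' cat2 <- generate_regional_catalogue(list(
#'   north = lumpy_pool_spec(species_per_lump = 10, seed = 1),
#'   south = lumpy_pool_spec(species_per_lump = 10, seed = 2)
#' ))
#' dplyr::count(cat2, region)
#' @export
generate_regional_catalogue <- function(regions) {
  if (length(regions) == 0L) {
    return(tibble(species_id = character(), region = character(),
                  lump = integer(), length_mm = double()))
  }
  tags <- names(regions)
  if (is.null(tags) || any(tags == "") || anyDuplicated(tags)) {
    dup <- if (!is.null(tags)) unique(tags[duplicated(tags)]) else character()
    abort(sprintf(
      "`regions` must be a named list with unique region tags%s.",
      if (length(dup)) paste0("; duplicated: ", paste(dup, collapse = ", "))
      else ""
    ))
  }
  out <- list_rbind(lapply(tags, function(tag) {
    generate_lumpy_pool(regions[[tag]], region = tag)
  }))
  mutate(out, species_id = sprintf("%s_%s", .data$region, .data$species_id))
}
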