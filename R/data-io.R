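# Readers and writers for the package's tabular formats. CSV is the
# canonical dialect; TSV is auto-detected on read. Lengths are always
# stored in mm; logging happens at analysis time, never in files.

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort(sprintf("Empty file: %s", path))
  if (grepl("\t", header)) "\t" else ","
}

read_table_checked <- function(path, required, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- detect_delim(path, delim)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) abort(sprintf("Empty file: %s", path))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s) in %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

check_lengths_col <- function(df, path) {
  if (nrow(df) == 0L) return(invisible(df))
  if (!is.numeric(df$length_mm)) {
    abort(sprintf("`length_mm` in %s must be numeric.", path))
  }
  bad <- which(!is.finite(df$length_mm) | df$length_mm <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Invalid length_mm (missing or non-positive) in %s at data row(s): %s",
      path, paste(bad, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read a species catalogue
#'
#' Reads a delimited table with columns `species_id`, `region`,
#' `length_mm` (comma or tab, auto-detected; override with `delim`).
#' Rows with missing or non-positive lengths and duplicated
#' `(species_id, region)` keys are rejected with row-numbered messages.
#'
#' @param path File path.
#' @param delim Optional explicit delimiter.
#' @return A tibble with columns `species_id`, `region`, `length_mm`.
#' @export
read_species_catalogue <- function(path, delim = NULL) {
  df <- read_table_checked(path, c("species_id", "region", "length_mm"), delim)
  check_lengths_col(df, path)
  if (any(is.na(df$species_id)) || any(df$species_id == "")) {
    abort(sprintf("Empty species_id in %s.", path))
  }
  key <- paste(df$species_id, df$region, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(sprintf(
      "Duplicated (species_id, region) in %s: %s", path,
      paste(gsub("\r", "/", dup), collapse = ", ")
    ))
  }
  as_tibble(df[c("species_id", "region", "length_mm")])
}

#' Read an occurrence table
#'
#' Reads a long-format table `sample_id, species_id, length_mm`, or
#' `sample_id, species_id` plus a separate species-length lookup table
#' (`species_id, length_mm`). A species repeated within a sample collapses
#' to one row with a warning. When lengths appear both inline and in the
#' lookup they must agree; a conflict is an error, not a silent precedence.
#'
#' @param path Occurrence file path.
#' @param lookup_path Optional species-length lookup file path.
#' @param delim Optional explicit delimiter.
#' @return An `occurrence_tbl` tibble (`sample_id`, `species_id`,
#'   `length_mm`).
#' @export
read_occurrence_table <- function(path, lookup_path = NULL, delim = NULL) {
  df <- read_table_checked(path, c("sample_id", "species_id"), delim)
  if (nrow(df) == 0L) {
    out <- tibble(sample_id = character(), species_id = character(),
                  length_mm = double())
    class(out) <- c("occurrence_tbl", class(out))
    return(out)
  }
  has_inline <- "length_mm" %in% names(df)
  if (!has_inline && is.null(lookup_path)) {
    abort(sprintf(
      "%s has no length_mm column and no lookup table was given.", path
    ))
  }
  if (!is.null(lookup_path)) {
    lk <- read_table_checked(lookup_path, c("species_id", "length_mm"), delim)
    check_lengths_col(lk, lookup_path)
    if (anyDuplicated(lk$species_id)) {
      abort(sprintf("Duplicated species_id in lookup %s.", lookup_path))
    }
    if (has_inline) {
      merged <- left_join(df, rename(lk, lookup_len = "length_mm"),
                          by = "species_id")
      clash <- !is.na(merged$length_mm) & !is.na(merged$lookup_len) &
        abs(merged$length_mm - merged$lookup_len) > 1e-9
      if (any(clash)) {
        abort(sprintf(
          "Conflicting inline and lookup lengths for species: %s",
          paste(unique(merged$species_id[clash]), collapse = ", ")
        ))
      }
      df$length_mm <- dplyr::coalesce(merged$length_mm, merged$lookup_len)
    } else {
      df <- left_join(df, lk[, c("species_id", "length_mm")],
                      by = "species_id")
    }
  }
  no_len <- is.na(df$length_mm)
  if (any(no_len)) {
    abort(sprintf(
      "No body length available for species: %s",
      paste(unique(df$species_id[no_len]), collapse = ", ")
    ))
  }
  check_lengths_col(df, path)
  dup <- duplicated(df[c("sample_id", "species_id")])
  if (any(dup)) {
    warn(sprintf(
      "%d repeated (sample_id, species_id) row(s) collapsed to one.",
      sum(dup)
    ))
    df <- df[!dup, ]
  }
  out <- as_tibble(df[c("sample_id", "species_id", "length_mm")])
  class(out) <- c("occurrence_tbl", class(out))
  out
}

check_writable <- function(path, force) {
  if (file.exists(path) && !force) {
    abort(sprintf(
      "%s already exists; use force = TRUE (or --force) to overwrite.", path
    ))
  }
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Tabular results (tibbles, occurrence tables, ratio sets, simulation
#' states) are written as CSV with 10 significant digits; `mode_analysis`
#' and `mixture_fit` objects are written as JSON documents carrying the
#' full fits table, the selected class count, modes on both scales, and
#' the peak-to-peak ratios. Existing files are never overwritten unless
#' `force = TRUE`.
#'
#' @param x The object to write.
#' @param path Destination file.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, force = FALSE) {
  UseMethod("write_results")
}

#' @export
write_results.data.frame <- function(x, path, force = FALSE) {
  check_writable(path, force)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 10))
  readr::write_csv(df, path)
  invisible(path)
}

#' @export
write_results.niche_sim <- function(x, path, force = FALSE) {
  st <- x$final_state
  write_results(tibble(x = st$x, N = st$N), path, force = force)
}

#' @export
write_results.mixture_fit <- function(x, path, force = FALSE) {
  check_writable(path, force)
  doc <- list(k = x$k, weights = x$weights, means_log = x$means,
              means_mm = exp(x$means), sds_log = x$sds, loglik = x$loglik,
              bic = x$bic, aic = x$aic, converged = x$converged,
              n_obs = x$n_obs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.mode_analysis <- function(x, path, force = FALSE) {
  check_writable(path, force)
  doc <- list(
    criterion = x$criterion,
    best_k = x$best_k,
    fits = lapply(seq_len(nrow(x$scan)), function(i) {
      as.list(x$scan[i, ])
    }),
    skipped_k = x$skipped_k,
    modes_log = x$modes,
    modes_mm = x$modes_mm,
    peak_to_peak_ratios = x$peak_to_peak_ratios,
    n_obs = x$n_obs
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an occurrence table or species catalogue
#'
#' Convenience wrappers around [write_results()] fixing the canonical
#' column orders.
#'
#' @param x The table to write.
#' @param path Destination file.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(x, path, force = FALSE) {
  check_occurrence(x, arg = "x")
  write_results(as_tibble(x)[c("sample_id", "species_id", "length_mm")],
                path, force = force)
}

#' @rdname write_occurrence_table
#' @export
write_species_catalogue <- function(x, path, force = FALSE) {
  cols <- intersect(c("species_id", "region", "length_mm"), names(x))
  if (!all(c("species_id", "length_mm") %in% cols)) {
    abort("`x` must have species_id and length_mm columns.")
  }
  write_results(as_tibble(x)[cols], path, force = force)
}
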