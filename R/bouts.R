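#' Bout sets: pooled dwell durations for one stage
#'
#' A bout set holds the dwell durations (integer epochs) of all bouts of a
#' single stage, pooled over one or more subjects, together with provenance.
#'
#' @param stage_label Stage label, e.g. `"WASO"`, `"N"`, `"R"`.
#' @param durations_epochs Integer durations, all >= 1 (may be empty).
#' @param n_subjects Number of subjects contributing.
#' @param group_label Optional cohort label.
#' @return An object of class `bout_set`.
#' @export
bout_set <- function(stage_label, durations_epochs, n_subjects = 1L,
                     group_label = NA_character_) {
  durations_epochs <- as.integer(durations_epochs)
  if (any(durations_epochs < 1L)) stop("bout durations must be >= 1 epoch")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  structure(list(stage_label = stage_label,
                 durations_epochs = durations_epochs,
                 n_subjects = as.integer(n_subjects),
                 group_label = group_label),
            class = "bout_set")
}

#' @export
print.bout_set <- function(x, ...) {
  cat("<bout_set> ", x$stage_label, ": ", length(x$durations_epochs),
      " bouts from ", x$n_subjects, " subject(s)",
      if (!is.na(x$group_label)) paste0(" [", x$group_label, "]"), "\n", sep = "")
  invisible(x)
}

#' Pool bout sets across subjects
#'
#' All bouts of a given stage from the contributing subjects are combined
#' into one multiset for statistical analysis; subject counts are summed.
#'
#' @param sets Non-empty list of [bout_set] objects sharing one stage label.
#' @param group_label Optional cohort label for the pooled set.
#' @return A pooled [bout_set].
#' @export
pool_bouts <- function(sets, group_label = NA_character_) {
  if (length(sets) == 0L) stop("cannot pool an empty list of bout sets")
  stopifnot(all(vapply(sets, inherits, logical(1), "bout_set")))
  labels <- unique(vapply(sets, function(s) s$stage_label, character(1)))
  if (length(labels) != 1L) {
    stop("cannot pool bout sets with mixed stage labels: ",
         paste(labels, collapse = ", "))
  }
  bout_set(labels,
           unlist(lapply(sets, function(s) s$durations_epochs)),
           n_subjects = sum(vapply(sets, function(s) s$n_subjects, integer(1))),
           group_label = group_label)
}

#' Build a normalized bout-duration frequency histogram
#'
#' Bin width is one epoch; bins run from 1 to the longest observed
#' duration, retaining zero-count bins by default. The relative frequency
#' (count / total) is then normalized to the maximal relative frequency, so
#' the tallest bin has height 1 — the form the curve-fitting routines
#' expect.
#'
#' @param b A non-empty [bout_set].
#' @param include_empty_bins Keep zero-count bins (default `TRUE`). Dropping
#'   them changes the fitted degrees of freedom.
#' @param normalize Divide by the maximal relative frequency (default
#'   `TRUE`).
#' @return An object of class `bout_histogram` with fields
#'   `bin_centers_epochs`, `counts`, `rel_freq`, `n_total`, `normalized`,
#'   `max_rel_freq` (the normalizing constant), and provenance labels.
#' @examples
#' h <- build_histogram(bout_set("R", c(1, 1, 1, 2, 3)))
#' h$rel_freq  # 1, 1/3, 1/3
#' @export
build_histogram <- function(b, include_empty_bins = TRUE, normalize = TRUE) {
  stopifnot(inherits(b, "bout_set"))
  if (length(b$durations_epochs) == 0L) stop("cannot histogram an empty bout set")
  counts <- tabulate(b$durations_epochs)
  bins <- seq_along(counts)
  if (!include_empty_bins) {
    keep <- counts > 0L
    bins <- bins[keep]
    counts <- counts[keep]
  }
  n_total <- sum(counts)
  rf <- counts / n_total
  mx <- max(rf)
  structure(list(bin_centers_epochs = as.integer(bins),
                 counts = as.integer(counts),
                 rel_freq = if (normalize) rf / mx else rf,
                 n_total = as.integer(n_total),
                 normalized = normalize,
                 max_rel_freq = mx,
                 stage_label = b$stage_label,
                 group_label = b$group_label),
            class = "bout_histogram")
}

#' Build a histogram object from known relative frequencies
#'
#' Constructs a `bout_histogram` directly from bin heights — e.g. an exact
#' model curve evaluated at integer bins — so the fitting routines can be
#' exercised on noiseless data. Counts are unavailable and set to `NA`.
#'
#' @param bin_centers_epochs Integer bin centers (epochs).
#' @param rel_freq Non-negative bin heights.
#' @param normalize Divide by the maximum (default `TRUE`).
#' @return A `bout_histogram`.
#' @export
histogram_from_rel_freq <- function(bin_centers_epochs, rel_freq,
                                    normalize = TRUE) {
  stopifnot(length(bin_centers_epochs) == length(rel_freq), all(rel_freq >= 0))
  mx <- max(rel_freq)
  structure(list(bin_centers_epochs = as.integer(bin_centers_epochs),
                 counts = rep(NA_integer_, length(rel_freq)),
                 rel_freq = if (normalize) rel_freq / mx else rel_freq,
                 n_total = NA_integer_,
                 normalized = normalize,
                 max_rel_freq = mx,
                 stage_label = "synthetic",
                 group_label = NA_character_),
            class = "bout_histogram")
}

#' @export
print.bout_histogram <- function(x, ...) {
  cat("<bout_histogram> ", x$stage_label, ": ", length(x$bin_centers_epochs),
      " bins, ", x$n_total, " bouts",
      if (x$normalized) ", max-normalized", "\n", sep = "")
  invisible(x)
}

#' Coerce a histogram to a data frame
#'
#' @param x A `bout_histogram`.
#' @param ... Unused.
#' @return Data frame with columns `bin`, `count`, `rel_freq`.
#' @export
as.data.frame.bout_histogram <- function(x, ...) {
  data.frame(bin = x$bin_centers_epochs, count = x$counts, rel_freq = x$rel_freq)
}

#' Serialize a histogram or bout set
#'
#' Histograms go to CSV (`bin, count, rel_freq`) or JSON; bout sets to a
#' one-column CSV of durations or JSON.
#'
#' @param x A `bout_histogram` or `bout_set`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_bout_data <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(x, "bout_histogram")) {
    df <- as.data.frame(x)
    if (ext == "json") {
      jsonlite::write_json(df, path, digits = NA)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(x, "bout_set")) {
    if (ext == "json") {
      jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(data.frame(duration_epochs = x$durations_epochs),
                       path, row.names = FALSE)
    }
  } else {
    stop("write_bout_data handles bout_histogram and bout_set objects")
  }
  invisible(path)
}
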