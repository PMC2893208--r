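#' Hypnogram objects
#'
#' A hypnogram is the per-epoch time series of scored sleep stages for one
#' recording. Epochs are 30 s by convention; stage codes come from the
#' canonical alphabet (`W`, `N1`-`N4`, `R`, or merged `N`).
#'
#' @param stages Character vector of canonical stage codes, one per epoch.
#' @param subject_id Subject identifier.
#' @param epoch_seconds Epoch duration in seconds (> 0, default 30).
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(c("W", "W", "N2", "N2", "R"), subject_id = "s1")
#' length(h$stages)
#' @export
hypnogram <- function(stages, subject_id = "unknown", epoch_seconds = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L || epoch_seconds <= 0)
    stop("epoch_seconds must be a single positive number")
  bad <- which(!stages %in% stage_alphabet())
  if (length(bad) > 0L) {
    stop("invalid stage code '", stages[bad[1L]], "' at epoch index ", bad[1L] - 1L)
  }
  structure(list(subject_id = subject_id,
                 epoch_seconds = as.numeric(epoch_seconds),
                 stages = stages),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> subject=", x$subject_id, ", ", length(x$stages),
      " epochs x ", x$epoch_seconds, " s\n", sep = "")
  invisible(x)
}

#' Read an epoch-coded hypnogram from a plain-text file
#'
#' One stage code per epoch, separated by whitespace, commas and/or
#' newlines. Codes are translated to the canonical alphabet through a
#' [stage_map]; unknown codes raise an error naming the offending token and
#' its (0-based) epoch index.
#'
#' @param path Path to the stage file.
#' @param map A [stage_map]; default is the SHHS numeric convention.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param epoch_seconds Epoch duration in seconds.
#' @return A [hypnogram].
#' @export
read_hypnogram <- function(path, map = stage_map_shhs(),
                           subject_id = NULL, epoch_seconds = 30) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  if (is.null(subject_id)) subject_id <- basename(path)
  raw <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(paste(raw, collapse = " "), "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty hypnogram file: ", path)
  translated <- unname(map$mapping[tokens])
  bad <- which(is.na(translated))
  if (length(bad) > 0L) {
    stop("unknown stage code '", tokens[bad[1L]], "' at epoch index ",
         bad[1L] - 1L, " in ", path)
  }
  if (any(translated == "UNSCORED")) {
    if (map$unscored == "wake") {
      translated[translated == "UNSCORED"] <- "W"
    } else {
      i <- which(translated == "UNSCORED")[1L]
      stop("unscored/movement code '", tokens[i], "' at epoch index ", i - 1L,
           " in ", path, " (stage_map has unscored='error')")
    }
  }
  hypnogram(translated, subject_id = subject_id, epoch_seconds = epoch_seconds)
}

#' Merge NREM sub-stages into a single NREM state
#'
#' Replaces `N1`-`N4` by the single code `N`, ignoring transitions within
#' NREM. Wake and REM epochs are untouched and sequence length is preserved.
#'
#' @param h A [hypnogram].
#' @return A [hypnogram] over the merged alphabet `W, N, R`.
#' @export
collapse_nrem <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  s <- h$stages
  s[s %in% c("N1", "N2", "N3", "N4")] <- "N"
  hypnogram(s, subject_id = h$subject_id, epoch_seconds = h$epoch_seconds)
}

#' Extract stage bouts by run-length encoding
#'
#' A bout is a maximal run of consecutive epochs in the same stage; its
#' length in epochs is the dwell time analysed throughout the package.
#'
#' @param h A [hypnogram].
#' @return A data frame with columns `stage`, `duration_epochs`, and
#'   `start_epoch_index` (0-based), in recording order. Durations sum to the
#'   hypnogram length.
#' @examples
#' h <- hypnogram(c("W", "W", "N", "N", "N", "R", "R", "W"))
#' extract_bouts(h)
#' @export
extract_bouts <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(h$stages)
  ends <- cumsum(r$lengths)
  data.frame(stage = r$values,
             duration_epochs = as.integer(r$lengths),
             start_epoch_index = as.integer(ends - r$lengths),
             stringsAsFactors = FALSE)
}

first_sleep_epoch <- function(h) {
  i <- which(h$stages != "W")
  if (length(i) == 0L) NA_integer_ else i[1L] - 1L  # 0-based
}

#' Select the bouts of one stage, applying WASO and censoring rules
#'
#' For wake, only bouts beginning at or after sleep onset (the first epoch
#' scored as any non-wake stage) are kept — wake after sleep onset, WASO.
#' Under the default censoring policy the recording's final bout is dropped
#' whenever it belongs to the requested stage, because its true duration is
#' right-censored by the end of the recording.
#'
#' @param bouts Data frame from [extract_bouts()].
#' @param stage Canonical stage code to select.
#' @param h The source [hypnogram] (needed for onset and censoring).
#' @param censoring_policy `"drop_final"` (default) or `"keep_final"`.
#' @return A [bout_set] for the stage (possibly empty, with a warning, for
#'   WASO when the recording contains no sleep).
#' @examples
#' h <- hypnogram(c("W", "W", "N", "W", "W", "N", "R", "W"))
#' select_stage_bouts(extract_bouts(h), "W", h)$durations_epochs  # 2
#' @export
select_stage_bouts <- function(bouts, stage, h,
                               censoring_policy = c("drop_final", "keep_final")) {
  censoring_policy <- match.arg(censoring_policy)
  stopifnot(inherits(h, "hypnogram"))
  if (!stage %in% stage_alphabet()) stop("unknown stage code: ", stage)
  label <- if (stage == "W") "WASO" else stage
  keep <- bouts$stage == stage
  if (stage == "W") {
    onset <- first_sleep_epoch(h)
    if (is.na(onset)) {
      warning("recording '", h$subject_id, "' contains no sleep epoch; WASO is empty")
      return(bout_set(label, integer(0), n_subjects = 1L))
    }
    keep <- keep & bouts$start_epoch_index >= onset
  }
  if (censoring_policy == "drop_final" && nrow(bouts) > 0L) {
    keep[nrow(bouts)] <- FALSE
  }
  bout_set(label, bouts$duration_epochs[keep], n_subjects = 1L)
}

#' Per-recording summary metrics
#'
#' Routine polysomnographic summary measures: stage percentages (of sleep
#' epochs), total sleep time, sleep latency, REM latency from sleep onset,
#' and sleep efficiency.
#'
#' @param h A [hypnogram].
#' @return A list with `stage_pct` (named percentages over sleep epochs),
#'   `tst_min`, `sleep_latency_min`, `rem_latency_min`,
#'   `sleep_efficiency_pct` and `no_sleep` (flag; latencies are `NA` when no
#'   sleep was scored).
#' @examples
#' summary_metrics(hypnogram(c("W", "W", "N2", "N2", "R", "R", "N2", "N2")))
#' @export
summary_metrics <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  epm <- h$epoch_seconds / 60  # minutes per epoch
  sleep <- h$stages != "W"
  n_sleep <- sum(sleep)
  onset <- first_sleep_epoch(h)
  no_sleep <- is.na(onset)
  sleep_stages <- setdiff(unique(h$stages), "W")
  stage_pct <- if (n_sleep > 0L) {
    100 * vapply(sleep_stages, function(s) sum(h$stages == s), integer(1)) / n_sleep
  } else {
    stats::setNames(numeric(0), character(0))
  }
  rem_lat <- NA_real_
  if (!no_sleep) {
    r1 <- which(h$stages == "R")
    if (length(r1) > 0L) rem_lat <- (r1[1L] - 1L - onset) * epm
  }
  if (no_sleep) warning("recording '", h$subject_id, "' contains no sleep; latencies undefined")
  list(subject_id = h$subject_id,
       stage_pct = stage_pct,
       tst_min = n_sleep * epm,
       sleep_latency_min = if (no_sleep) NA_real_ else onset * epm,
       rem_latency_min = rem_lat,
       sleep_efficiency_pct = 100 * n_sleep / length(h$stages),
       no_sleep = no_sleep)
}
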