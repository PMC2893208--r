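#' Run the full bout-dynamics pipeline over a cohort collection
#'
#' Reads (or simulates) per-subject hypnograms for each group, extracts
#' WASO/NREM/REM bouts with the chosen censoring policy, pools them, builds
#' max-normalized histograms, selects the optimal number of exponential
#' components sequentially, computes Y0-weighted time constants, and
#' (optionally) compares the selected exponential model with a power law.
#' All randomness flows from `seed`; the emitted tables are deterministic
#' given the same configuration and seed.
#'
#' @param manifest Cohort manifest: a data frame (or path to a CSV) with
#'   columns `subject_id`, `path`, `group`. Exactly one of `manifest` and
#'   `sim_specs` must be given.
#' @param sim_specs Named list of [cohort_spec] objects (name = group
#'   label) to simulate instead of reading files.
#' @param map A [stage_map] for reading manifest files.
#' @param nrem_mode `"merged"` (analyze NREM as one stage; default) or
#'   `"substages"` (analyze N1-N4 separately).
#' @param censoring Censoring policy for [select_stage_bouts()].
#' @param alpha F-test significance level.
#' @param max_components Cap on exponential components (default 4).
#' @param seed Optional integer seed.
#' @param out_dir If given, report tables are written there as CSV
#'   (`fit_parameters.csv`, `selection_log.csv`, `weighted_tau.csv`,
#'   `summary_metrics.csv`, `powerlaw_comparison.csv`).
#' @param compare_powerlaw Also fit and compare a power law per stage
#'   (default `TRUE`).
#' @return A list of class `bout_pipeline_report` with elements
#'   `fit_table`, `selection_table`, `weighted_tau_table`,
#'   `summary_metrics`, `powerlaw_table`, `selections` (nested
#'   `model_selection` objects by group/stage), and `histograms`.
#' @export
run_pipeline <- function(manifest = NULL, sim_specs = NULL,
                         map = stage_map_letters(),
                         nrem_mode = c("merged", "substages"),
                         censoring = c("drop_final", "keep_final"),
                         alpha = 0.05, max_components = 4, seed = NULL,
                         out_dir = NULL, compare_powerlaw = TRUE) {
  nrem_mode <- match.arg(nrem_mode)
  censoring <- match.arg(censoring)
  if (is.null(manifest) == is.null(sim_specs))
    stop("give exactly one of 'manifest' or 'sim_specs'")
  if (!is.null(seed)) set.seed(seed)

  cohorts <- if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                            stringsAsFactors = FALSE)
    need <- c("subject_id", "path", "group")
    if (!all(need %in% names(manifest)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    split(manifest, manifest$group) |>
      lapply(function(g) {
        lapply(seq_len(nrow(g)), function(i)
          read_hypnogram(g$path[i], map = map, subject_id = g$subject_id[i]))
      })
  } else {
    stopifnot(all(vapply(sim_specs, inherits, logical(1), "cohort_spec")))
    lapply(sim_specs, simulate_hypnogram)
  }
  if (length(cohorts) == 0L || any(vapply(cohorts, length, integer(1)) == 0L))
    stop("empty cohort: every group needs at least one recording")

  stages <- if (nrem_mode == "merged") c("W", "N", "R")
  else c("W", "N1", "N2", "N3", "N4", "R")

  fit_rows <- list(); sel_rows <- list(); wt_rows <- list()
  pl_rows <- list(); sm_rows <- list()
  selections <- list(); histograms <- list()

  for (group in names(cohorts)) {
    hyps <- cohorts[[group]]
    if (nrem_mode == "merged") hyps <- lapply(hyps, collapse_nrem)
    sm_rows[[group]] <- do.call(rbind, lapply(hyps, function(h) {
      m <- summary_metrics(h)
      pct <- m$stage_pct
      df <- data.frame(subject_id = m$subject_id, group = group,
                       tst_min = m$tst_min,
                       sleep_latency_min = m$sleep_latency_min,
                       rem_latency_min = m$rem_latency_min,
                       sleep_efficiency_pct = m$sleep_efficiency_pct,
                       stringsAsFactors = FALSE)
      for (s in setdiff(stages, "W")) {
        df[[paste0("pct_", s)]] <- if (s %in% names(pct)) pct[[s]] else 0
      }
      df
    }))
    selections[[group]] <- list()
    histograms[[group]] <- list()
    for (stage in stages) {
      sets <- lapply(hyps, function(h)
        select_stage_bouts(extract_bouts(h), stage, h, censoring_policy = censoring))
      sets <- Filter(function(s) length(s$durations_epochs) > 0L, sets)
      if (length(sets) == 0L) {
        warning("no ", stage, " bouts in group '", group, "'; stage skipped")
        next
      }
      pooled <- pool_bouts(sets, group_label = group)
      hist <- build_histogram(pooled)
      label <- pooled$stage_label
      histograms[[group]][[label]] <- hist
      sel <- select_model(hist, max_components = max_components, alpha = alpha)
      selections[[group]][[label]] <- sel
      fit <- sel$fits[[sel$selected]]
      contrib <- relative_contributions(fit)
      tau_ci <- fit$ci95[grepl("^k", fit$ci95$parameter), ]
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        group = group, stage = label, n_bouts = length(pooled$durations_epochs),
        component = seq_len(nrow(fit$components)),
        tau_epochs = fit$components$tau_epochs,
        # CI endpoints of tau = 1/k swap order relative to k
        tau_ci_lo = if (fit$ci_available) 1 / tau_ci$hi else NA_real_,
        tau_ci_hi = if (fit$ci_available) 1 / tau_ci$lo else NA_real_,
        contrib_pct = contrib,
        r_squared = fit$r_squared,
        stringsAsFactors = FALSE)
      if (nrow(sel$comparisons) > 0L) {
        sel_rows[[length(sel_rows) + 1L]] <-
          cbind(group = group, stage = label, sel$comparisons,
                selected = sel$selected, stop_reason = sel$stop_reason)
      }
      wt_rows[[length(wt_rows) + 1L]] <- data.frame(
        group = group, stage = label, selected = sel$selected,
        weighted_tau_epochs = weighted_tau(fit),
        mono_tau_epochs = sel$fits[[1L]]$components$tau_epochs[1L],
        mono_r_squared = sel$fits[[1L]]$r_squared,
        stringsAsFactors = FALSE)
      if (compare_powerlaw) {
        pl <- tryCatch(fit_powerlaw(hist), error = function(e) NULL)
        if (!is.null(pl)) {
          cmp <- compare_nonnested(fit, pl)
          pl_rows[[length(pl_rows) + 1L]] <- data.frame(
            group = group, stage = label, n_bouts = length(pooled$durations_epochs),
            exp_components = sel$selected,
            ss_exp = fit$ss_residual, ss_pl = pl$ss_residual,
            A = pl$A, B = pl$B, delta_aicc = cmp$delta_aicc,
            preferred_by_ss = cmp$preferred_by_ss,
            preferred_by_aicc = cmp$preferred_by_aicc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  bind <- function(rows) if (length(rows) > 0L) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL
  report <- structure(list(fit_table = bind(fit_rows),
                           selection_table = bind(sel_rows),
                           weighted_tau_table = bind(wt_rows),
                           summary_metrics = bind(unname(sm_rows)),
                           powerlaw_table = bind(pl_rows),
                           selections = selections,
                           histograms = histograms,
                           nrem_mode = nrem_mode, censoring = censoring,
                           alpha = alpha, seed = seed),
                      class = "bout_pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the pipeline report tables as CSV
#'
#' @param report A `bout_pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "bout_pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(fit_parameters = report$fit_table,
               selection_log = report$selection_table,
               weighted_tau = report$weighted_tau_table,
               summary_metrics = report$summary_metrics,
               powerlaw_comparison = report$powerlaw_table)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]]))
      utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.bout_pipeline_report <- function(x, ...) {
  cat("<bout_pipeline_report> nrem_mode=", x$nrem_mode,
      ", censoring=", x$censoring, "\n", sep = "")
  if (!is.null(x$weighted_tau_table)) print(x$weighted_tau_table)
  invisible(x)
}

#' Repeated random-subset refitting of one cohort
#'
#' Draws `k` subjects without replacement, reruns bout pooling and
#' sequential model selection on the subset, and records the selected
#' component count per stage per repeat — quantifying how model selection
#' degrades as the pooled sample shrinks.
#'
#' @param hyps List of [hypnogram] objects (one cohort).
#' @param k Subjects per subset (<= cohort size).
#' @param n_repeats Number of subsets.
#' @param seed Optional integer seed.
#' @param nrem_mode,censoring,alpha,max_components As in [run_pipeline()].
#' @return Data frame with columns `repeat_idx`, `stage`, `n_bouts`,
#'   `selected`, `stop_reason`.
#' @export
subsample_cohort <- function(hyps, k, n_repeats = 4, seed = NULL,
                             nrem_mode = c("merged", "substages"),
                             censoring = c("drop_final", "keep_final"),
                             alpha = 0.05, max_components = 4) {
  nrem_mode <- match.arg(nrem_mode)
  censoring <- match.arg(censoring)
  if (k > length(hyps)) stop("k (", k, ") exceeds cohort size (", length(hyps), ")")
  if (!is.null(seed)) set.seed(seed)
  if (nrem_mode == "merged") hyps <- lapply(hyps, collapse_nrem)
  stages <- if (nrem_mode == "merged") c("W", "N", "R")
  else c("W", "N1", "N2", "N3", "N4", "R")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    subset <- hyps[sample.int(length(hyps), k)]
    for (stage in stages) {
      sets <- lapply(subset, function(h)
        select_stage_bouts(extract_bouts(h), stage, h, censoring_policy = censoring))
      sets <- Filter(function(s) length(s$durations_epochs) > 0L, sets)
      if (length(sets) == 0L) next
      pooled <- pool_bouts(sets)
      res <- tryCatch({
        hist <- build_histogram(pooled)
        sel <- select_model(hist, max_components = max_components, alpha = alpha)
        data.frame(repeat_idx = r, stage = pooled$stage_label,
                   n_bouts = length(pooled$durations_epochs),
                   selected = sel$selected, stop_reason = sel$stop_reason,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(repeat_idx = r, stage = pooled$stage_label,
                   n_bouts = length(pooled$durations_epochs),
                   selected = NA_integer_, stop_reason = "fit_error",
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
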