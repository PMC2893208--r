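#' Exponential-mixture specification for bout dwell times
#'
#' A bout-duration mixture is defined by component time constants (tau, in
#' epochs) and either per-bout event probabilities or the Y0 "relative
#' contribution" percentages a histogram fit would report. The two
#' parameterizations are interconvertible: the histogram intercept of
#' component i scales as p_i / tau_i, so contributions c_i map to event
#' probabilities p_i = c_i tau_i / sum(c_j tau_j).
#'
#' @param taus_epochs Strictly increasing positive time constants.
#' @param event_probs Per-bout component membership probabilities (sum 1).
#' @param y0_contribs Alternative parameterization: Y0 contribution
#'   percentages; converted via [y0_contribs_to_event_probs()].
#' @return An object of class `mixture_spec` with fields `taus_epochs` and
#'   `event_probs`.
#' @examples
#' mixture_spec(c(1, 5, 25), y0_contribs = c(95, 4, 1))
#' @export
mixture_spec <- function(taus_epochs, event_probs = NULL, y0_contribs = NULL) {
  stopifnot(is.numeric(taus_epochs), all(taus_epochs > 0))
  if (length(taus_epochs) > 1L && any(diff(taus_epochs) <= 0))
    stop("taus must be strictly increasing")
  if (is.null(event_probs) == is.null(y0_contribs))
    stop("give exactly one of event_probs or y0_contribs")
  if (!is.null(y0_contribs))
    event_probs <- y0_contribs_to_event_probs(taus_epochs, y0_contribs)
  if (length(event_probs) != length(taus_epochs))
    stop("event_probs and taus_epochs lengths differ")
  if (any(event_probs < 0) || abs(sum(event_probs) - 1) > 1e-9)
    stop("event_probs must be non-negative and sum to 1")
  structure(list(taus_epochs = taus_epochs, event_probs = event_probs),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec> tau =", paste(signif(x$taus_epochs, 4), collapse = ", "),
      "epochs; event probs =", paste(signif(x$event_probs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Convert Y0 contribution percentages to per-bout event probabilities
#'
#' A component's fitted intercept reflects its event probability divided by
#' its time constant (slow components spread their events over many bins),
#' so the event probability is p_i proportional to c_i * tau_i. The number
#' of events behind a slow component can therefore far exceed its Y0
#' percentage.
#'
#' @param taus Component time constants (epochs).
#' @param contribs Y0 contribution percentages (any positive scale).
#' @return Event probabilities summing to 1.
#' @examples
#' y0_contribs_to_event_probs(c(1, 5, 25), c(95, 4, 1))
#' @export
y0_contribs_to_event_probs <- function(taus, contribs) {
  stopifnot(length(taus) == length(contribs), all(taus > 0), all(contribs >= 0))
  p <- contribs * taus
  p / sum(p)
}

#' Inverse of [y0_contribs_to_event_probs()]
#'
#' @param taus Component time constants (epochs).
#' @param event_probs Per-bout component probabilities.
#' @return Y0 contribution percentages summing to 100.
#' @export
event_probs_to_y0_contribs <- function(taus, event_probs) {
  stopifnot(length(taus) == length(event_probs), all(taus > 0))
  c0 <- event_probs / taus
  100 * c0 / sum(c0)
}

#' Draw i.i.d. exponential bout durations
#'
#' @param tau Time constant in epochs (> 0).
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of continuous durations.
#' @export
draw_exponential_bouts <- function(tau, n, seed = NULL) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(n, rate = 1 / tau)
}

#' Quantize continuous dwell times to integer epochs
#'
#' Ceiling with a minimum of one epoch, mirroring epoch-based scoring in
#' which no bout shorter than one epoch can be observed.
#'
#' @param d Continuous durations.
#' @return Integer durations >= 1.
#' @export
quantize_epochs <- function(d) {
  pmax(1L, as.integer(ceiling(d)))
}

#' Draw bout durations from an exponential mixture
#'
#' Two-stage sampling: a component is chosen by its event probability, then
#' the duration is drawn from that component's exponential distribution.
#'
#' @param spec A [mixture_spec].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param quantize If `TRUE`, return integer epochs via [quantize_epochs()].
#' @return Numeric (or integer, if quantized) vector of durations.
#' @export
draw_mixture_bouts <- function(spec, n, seed = NULL, quantize = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(spec$taus_epochs), n, replace = TRUE,
                     prob = spec$event_probs)
  d <- stats::rexp(n, rate = 1 / spec$taus_epochs[comp])
  if (quantize) quantize_epochs(d) else d
}

#' Published multi-exponential bout parameters by cohort and stage
#'
#' Reference decay time constants (epochs) and Y0 percentage contributions
#' for pooled WASO, NREM (merged) and REM bout-duration histograms in
#' control, mild-OSA and severe-OSA cohorts from a large home
#' polysomnography study. Used to parameterize the semi-Markov simulator
#' and the recovery experiments.
#'
#' @return Data frame with columns `group`, `stage`, `component`
#'   (`fast`/`medium`/`slow`), `tau_epochs`, `ci_lo`, `ci_hi`,
#'   `contrib_pct`.
#' @export
osa_cohort_params <- function() {
  df <- rbind(
    data.frame(group = "control", stage = "WASO",
               component = c("fast", "medium", "slow"),
               tau_epochs = c(0.60, 3.1, 16.1),
               ci_lo = c(0.59, 2.9, 14.1), ci_hi = c(0.61, 3.2, 18.7),
               contrib_pct = c(94.5, 5.4, 0.3)),
    data.frame(group = "mild", stage = "WASO",
               component = c("fast", "medium", "slow"),
               tau_epochs = c(0.53, 2.2, 14.6),
               ci_lo = c(0.53, 2.1, 13.8), ci_hi = c(0.54, 2.2, 15.5),
               contrib_pct = c(93.2, 6.5, 0.3)),
    data.frame(group = "severe", stage = "WASO",
               component = c("fast", "medium"),
               tau_epochs = c(0.53, 3.7),
               ci_lo = c(0.52, 3.6), ci_hi = c(0.53, 3.8),
               contrib_pct = c(97.9, 2.1)),
    data.frame(group = "control", stage = "NREM",
               component = c("fast", "medium", "slow"),
               tau_epochs = c(1.7, 7.8, 44.1),
               ci_lo = c(1.6, 6.9, 40.0), ci_hi = c(1.8, 9.0, 49.1),
               contrib_pct = c(77.3, 18.2, 4.4)),
    data.frame(group = "mild", stage = "NREM",
               component = c("fast", "medium", "slow"),
               tau_epochs = c(0.9, 5.2, 37.6),
               ci_lo = c(0.8, 4.9, 35.2), ci_hi = c(0.9, 5.5, 40.3),
               contrib_pct = c(75.3, 21.6, 3.1)),
    data.frame(group = "severe", stage = "NREM",
               component = c("fast", "medium", "slow"),
               tau_epochs = c(1.0, 4.8, 32.8),
               ci_lo = c(1.0, 4.6, 30.6), ci_hi = c(1.1, 5.1, 35.4),
               contrib_pct = c(82.8, 15.2, 2.0)),
    data.frame(group = "control", stage = "REM",
               component = c("fast", "slow"),
               tau_epochs = c(3.8, 19.0),
               ci_lo = c(2.8, 17.4), ci_hi = c(5.8, 20.9),
               contrib_pct = c(40.5, 59.5)),
    data.frame(group = "mild", stage = "REM",
               component = c("fast", "slow"),
               tau_epochs = c(2.6, 16.8),
               ci_lo = c(2.2, 15.8), ci_hi = c(3.0, 18.0),
               contrib_pct = c(57.5, 42.5)),
    data.frame(group = "severe", stage = "REM",
               component = c("fast", "slow"),
               tau_epochs = c(1.9, 16.3),
               ci_lo = c(1.8, 15.3), ci_hi = c(2.0, 17.6),
               contrib_pct = c(81.9, 18.1)))
  rownames(df) <- NULL
  df
}

#' Mixture specification for one cohort x stage from the reference table
#'
#' @param group `"control"`, `"mild"`, or `"severe"`.
#' @param stage `"WASO"`, `"NREM"`, or `"REM"`.
#' @return A [mixture_spec] with the published taus and contributions.
#' @export
cohort_mixture <- function(group, stage) {
  tab <- osa_cohort_params()
  row <- tab[tab$group == group & tab$stage == stage, ]
  if (nrow(row) == 0L) stop("no reference parameters for ", group, "/", stage)
  mixture_spec(row$tau_epochs, y0_contribs = row$contrib_pct)
}

#' Semi-Markov cohort architecture specification
#'
#' Defines the generator that stands in for a real cohort: per-stage dwell
#' mixtures, a stage-transition rule without self-transitions, recording
#' length, a leading wake run emulating sleep latency, and cohort size.
#'
#' @param waso,nrem,rem [mixture_spec] dwell-time mixtures per stage.
#' @param transition Named list of transition probability vectors:
#'   `W` (always to `N` by default), `N` over `c(R=, W=)`, `R` over
#'   `c(N=, W=)`. Self-transitions are forbidden.
#' @param n_epochs Recording length in epochs (default 840, i.e. 7 h of
#'   30-s epochs).
#' @param n_subjects Cohort size.
#' @param latency_mean_epochs Mean of the exponential leading-wake run
#'   (default 45 epochs, about 22.5 min).
#' @param seed Optional integer seed for the whole cohort.
#' @param group_label Cohort label carried into bout sets.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(waso, nrem, rem,
                        transition = list(W = c(N = 1),
                                          N = c(R = 0.3, W = 0.7),
                                          R = c(N = 0.5, W = 0.5)),
                        n_epochs = 840, n_subjects = 100,
                        latency_mean_epochs = 45, seed = NULL,
                        group_label = "sim") {
  stopifnot(inherits(waso, "mixture_spec"), inherits(nrem, "mixture_spec"),
            inherits(rem, "mixture_spec"))
  for (s in names(transition)) {
    pr <- transition[[s]]
    if (s %in% names(pr) && pr[[s]] > 0) stop("self-transition forbidden for ", s)
    if (abs(sum(pr) - 1) > 1e-9) stop("transition probabilities for ", s,
                                      " must sum to 1")
  }
  structure(list(mixtures = list(W = waso, N = nrem, R = rem),
                 transition = transition,
                 n_epochs = as.integer(n_epochs),
                 n_subjects = as.integer(n_subjects),
                 latency_mean_epochs = latency_mean_epochs,
                 seed = seed, group_label = group_label),
            class = "cohort_spec")
}

#' Cohort specification parameterized from the reference table
#'
#' @param group `"control"`, `"mild"`, or `"severe"`.
#' @param ... Overrides passed to [cohort_spec()] (`n_subjects`, `seed`, ...).
#' @return A `cohort_spec` whose dwell mixtures are the published
#'   parameters for that cohort.
#' @export
reference_cohort_spec <- function(group = c("control", "mild", "severe"), ...) {
  group <- match.arg(group)
  cohort_spec(waso = cohort_mixture(group, "WASO"),
              nrem = cohort_mixture(group, "NREM"),
              rem = cohort_mixture(group, "REM"),
              group_label = group, ...)
}

#' Simulate a cohort of hypnograms from a semi-Markov generator
#'
#' Each recording starts with a leading wake run (exponential, quantized)
#' emulating sleep latency, then alternates stages: the next stage is drawn
#' from the transition rule and its dwell from that stage's mixture
#' (quantized, >= 1 epoch), truncated at the recording length.
#'
#' @param spec A [cohort_spec].
#' @return List of [hypnogram] objects (merged `W/N/R` alphabet).
#' @export
simulate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(i) {
    stages <- character(0)
    lat <- quantize_epochs(stats::rexp(1, rate = 1 / spec$latency_mean_epochs))
    stages <- rep("W", min(lat, spec$n_epochs))
    state <- "N"  # W -> N always
    while (length(stages) < spec$n_epochs) {
      dwell <- quantize_epochs(draw_mixture_bouts(spec$mixtures[[state]], 1))
      stages <- c(stages, rep(state, dwell))
      pr <- spec$transition[[state]]
      state <- sample(names(pr), 1L, prob = pr)
    }
    hypnogram(stages[seq_len(spec$n_epochs)],
              subject_id = sprintf("%s_%03d", spec$group_label, i))
  })
}

#' Write a simulated cohort as per-epoch stage files plus a manifest
#'
#' Emits one whitespace-separated letter-coded stage file per subject and a
#' manifest CSV (`subject_id, path, group`) in the format [read_hypnogram()]
#' and [run_pipeline()] consume, closing the simulate-read loop.
#'
#' @param hyps List of [hypnogram] objects.
#' @param dir Output directory (created if needed).
#' @param group Group label recorded in the manifest.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(hyps, dir, group = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(hyps, function(h) {
    p <- file.path(dir, paste0(h$subject_id, ".txt"))
    writeLines(paste(h$stages, collapse = " "), p)
    data.frame(subject_id = h$subject_id, path = p, group = group,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
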