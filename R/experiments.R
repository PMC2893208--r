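#' Under-sampling experiment: spurious normality of small exponential samples
#'
#' Repeatedly draws small samples of continuous exponential bout durations
#' and counts how many pass a normality test — illustrating that a single
#' night's worth of bouts can masquerade as Gaussian. Draws are continuous
#' (no epoch quantization), matching random-variate simulation rather than
#' scored data.
#'
#' @param tau Exponential time constant (epochs; default 5). Pass rates are
#'   tau-invariant since the exponential is a scale family.
#' @param n_events_per_trial Sample size per trial.
#' @param n_trials Number of trials.
#' @param test Normality test name (default `"dagostino_pearson"`).
#' @param alpha Significance level; a trial passes when p > alpha.
#' @param seed Optional integer seed.
#' @return List with `n_pass` (count of passing trials), `pass_rate`,
#'   `p_values` (per trial), and the call parameters.
#' @examples
#' undersampling_experiment(n_events_per_trial = 10, n_trials = 10, seed = 1)$n_pass
#' @export
undersampling_experiment <- function(tau = 5, n_events_per_trial, n_trials,
                                     test = c("dagostino_pearson", "shapiro_wilk",
                                              "kolmogorov_smirnov_lilliefors"),
                                     alpha = 0.05, seed = NULL) {
  test <- match.arg(test)
  minimum <- normality_test_minimum[[test]]
  if (n_events_per_trial < minimum) {
    stop("the ", test, " test requires at least ", minimum,
         " events per trial (got ", n_events_per_trial, ")")
  }
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_values <- vapply(seq_len(n_trials), function(i) {
    x <- stats::rexp(n_events_per_trial, rate = 1 / tau)
    normality_tests(x, alpha = alpha, tests = test)$p_value
  }, numeric(1))
  n_pass <- sum(p_values > alpha)
  list(n_pass = n_pass, pass_rate = n_pass / n_trials, p_values = p_values,
       tau = tau, n_events_per_trial = n_events_per_trial,
       n_trials = n_trials, test = test, alpha = alpha)
}

#' Power-law mimicry experiment: multi-exponential data on log-log axes
#'
#' Draws samples of increasing size from a known exponential mixture,
#' histograms them, fits 1-3 exponential components and a power law, and
#' reports — per sample size — the selected exponential model plus the
#' power-law-versus-exponential verdicts by residual SS and by AICc (the
#' two may disagree). Both the selected-model comparator and the
#' 2-component comparator are reported.
#'
#' @param spec A [mixture_spec]; the classic configuration is taus 1, 5, 25
#'   with Y0 contributions of roughly 95/4/1 percent.
#' @param sample_sizes Vector of sample sizes (default 100, 1000, 10000).
#' @param seed Optional integer seed.
#' @param alpha F-test level for the exponential model selection.
#' @return Data frame with one row per sample size x comparator: `n`,
#'   `selected_exp`, `comparator_exp`, `ss_exp`, `ss_pl`, `delta_aicc`,
#'   `preferred_by_ss`, `preferred_by_aicc`, `loglog_r_squared` (r2 of a
#'   straight line through the log-log occupied bins).
#' @export
powerlaw_mimicry_experiment <- function(spec,
                                        sample_sizes = c(100, 1000, 10000),
                                        seed = NULL, alpha = 0.05) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (n in sample_sizes) {
    d <- draw_mixture_bouts(spec, n, quantize = TRUE)
    hist <- build_histogram(bout_set("sim", d))
    max_comp <- min(3L, floor(length(hist$bin_centers_epochs) / 2) - 1L)
    sel <- select_model(hist, max_components = max(1L, max_comp), alpha = alpha)
    pl <- fit_powerlaw(hist)
    ll <- loglog_view(hist)
    ll_r2 <- summary(stats::lm(log_y ~ log_x, data = ll))$r.squared
    comparators <- unique(c(sel$selected, 2L, 3L))
    comparators <- comparators[comparators <= length(sel$fits)]
    comparators <- comparators[!vapply(sel$fits[comparators], is.null, logical(1))]
    for (m in comparators) {
      cmp <- compare_nonnested(sel$fits[[m]], pl)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, selected_exp = sel$selected, comparator_exp = m,
        ss_exp = sel$fits[[m]]$ss_residual, ss_pl = pl$ss_residual,
        delta_aicc = cmp$delta_aicc,
        preferred_by_ss = cmp$preferred_by_ss,
        preferred_by_aicc = cmp$preferred_by_aicc,
        loglog_r_squared = ll_r2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
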