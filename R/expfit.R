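#' Small-sample corrected Akaike information criterion from residual SS
#'
#' AICc = N ln(SS/N) + 2K + 2K(K+1)/(N - K - 1), the least-squares form
#' used for both nested and non-nested model comparison.
#'
#' @param ss Residual sum of squares.
#' @param n Number of fitted points.
#' @param k Number of fitted parameters.
#' @return AICc value (`Inf` when the correction denominator is <= 0).
#' @export
aicc_from_ss <- function(ss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

multiexp_model <- function(k, y0, x) {
  as.vector(y0 %*% exp(-k %o% x))
}

# Prism-style parameter dependency at the solution: 1 - 1/VIF from the
# Jacobian correlation matrix. Values near 1 mean a parameter is redundant
# (its effect is reproducible by the others) — the signature of an
# over-parameterized sum of exponentials.
multiexp_dependency <- function(k, y0, x) {
  m <- length(k)
  E <- exp(-outer(k, x))
  J <- cbind(t(-(y0 * E) * rep(1, m) %o% x), t(E))  # d/dk_i, d/dy0_i
  C <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(C)) return(1)
  vif <- tryCatch(diag(solve(stats::cov2cor(C))), error = function(e) NULL)
  if (is.null(vif) || any(!is.finite(vif))) return(1)
  max(1 - 1 / vif)
}

#' Fit a sum of exponential decays to a normalized bout histogram
#'
#' Unweighted least squares of Y(X) = sum_i Y0_i exp(-k_i X) against the
#' max-normalized relative frequencies, with the plateau fixed at zero and
#' positivity enforced through bounds (k_i > 0, Y0_i >= 0). The optimizer
#' is bounded Levenberg-Marquardt restarted from a log-spaced grid of decay
#' time guesses (tau spanning 0.5 to the longest bin, amplitudes split
#' equally); the best start by residual SS wins. Residual weighting is
#' deliberately not offered: with these steeply decaying histograms,
#' Y-value weighting destabilizes convergence.
#'
#' @param hist A normalized [build_histogram()] result.
#' @param n_components Number of exponential components, 1-4.
#' @param max_iterations Iteration cap for the fit (default 3000, applied
#'   per start up to the optimizer's internal limit of 1024).
#' @param n_starts Number of multi-start windows (default 6).
#' @param dependency_limit Identifiability threshold: the fit is flagged
#'   non-identifiable (ambiguous) when any parameter's dependency
#'   (1 - 1/VIF at the solution) reaches this value (default 0.999).
#'   Redundant components in an over-parameterized exponential sum show
#'   dependencies essentially at 1.
#' @return An object of class `multiexp_fit`: `components` (data frame with
#'   `y0`, `tau_epochs`, `k`, sorted by ascending tau), `ss_residual`, `df`
#'   (bins - 2 x components), `r_squared`, `ci95` (per-parameter asymptotic
#'   95% intervals, or `NA` with `ci_available = FALSE` when the covariance
#'   is singular), `converged`, `max_dependency`, `identifiable`,
#'   `n_iterations`, `n_points`, `fitted`, `residuals`.
#' @export
fit_multiexp <- function(hist, n_components, max_iterations = 3000, n_starts = 6,
                         dependency_limit = 0.999) {
  stopifnot(inherits(hist, "bout_histogram"))
  if (!isTRUE(hist$normalized))
    stop("fit_multiexp expects a max-normalized histogram (normalize = TRUE)")
  if (!n_components %in% 1:4) stop("n_components must be between 1 and 4")
  x <- as.numeric(hist$bin_centers_epochs)
  y <- hist$rel_freq
  dof <- length(x) - 2L * n_components
  if (dof <= 0L) {
    stop("not enough bins (", length(x), ") to fit ", n_components,
         " components: df = ", dof)
  }
  m <- n_components
  tau_grid <- exp(seq(log(0.5), log(max(x)), length.out = max(m, 3) + n_starts - 1))
  lower <- c(rep(1e-8, m), rep(0, m))
  upper <- c(rep(50, m), rep(Inf, m))
  best <- NULL
  total_iter <- 0L
  for (s in seq_len(n_starts)) {
    tau0 <- tau_grid[seq(s, length.out = m)]
    par0 <- c(1 / tau0, rep(max(y) / m, m))
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper,
        fn = function(p) y - multiexp_model(p[1:m], p[m + 1:m], x),
        control = minpack.lm::nls.lm.control(
          maxiter = min(max_iterations, 1024L), ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f)) next
    total_iter <- total_iter + f$niter
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("all fitting starts failed for ", m, " component(s)")
  k <- best$par[1:m]
  y0 <- best$par[m + 1:m]
  ord <- order(1 / k)
  k <- k[ord]; y0 <- y0[ord]
  fitted <- multiexp_model(k, y0, x)
  ss <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  # asymptotic CIs from the (sorted) parameter covariance at the solution
  ci <- data.frame(parameter = c(paste0("k", seq_len(m)), paste0("y0", seq_len(m))),
                   estimate = c(k, y0), lo = NA_real_, hi = NA_real_)
  ci_available <- FALSE
  se <- tryCatch({
    cf <- summary(best)$coefficients
    unname(cf[, "Std. Error"])
  }, error = function(e) NULL)
  if (!is.null(se) && all(is.finite(se))) {
    se <- c(se[1:m][ord], se[m + 1:m][ord])
    tq <- stats::qt(0.975, dof)
    ci$lo <- ci$estimate - tq * se
    ci$hi <- ci$estimate + tq * se
    ci_available <- TRUE
  }
  dependency <- multiexp_dependency(k, y0, x)
  structure(list(components = data.frame(y0 = y0, tau_epochs = 1 / k, k = k),
                 ss_residual = ss,
                 df = dof,
                 r_squared = 1 - ss / ss_tot,
                 ci95 = ci,
                 ci_available = ci_available,
                 converged = best$info %in% 1:4,
                 max_dependency = dependency,
                 identifiable = dependency < dependency_limit,
                 n_iterations = total_iter,
                 n_points = length(x),
                 x = x, y = y,
                 fitted = fitted,
                 residuals = y - fitted),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  m <- nrow(x$components)
  cat("<multiexp_fit> ", m, " component(s), r2 = ", signif(x$r_squared, 4),
      ", SS = ", signif(x$ss_residual, 4),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  comp <- x$components
  contrib <- 100 * comp$y0 / sum(comp$y0)
  for (i in seq_len(m)) {
    cat(sprintf("  tau = %.3g epochs  (%.1f%% contribution)\n",
                comp$tau_epochs[i], contrib[i]))
  }
  invisible(x)
}

#' Extra sum-of-squares F-test between nested exponential fits
#'
#' F = ((SS1 - SS2)/(df1 - df2)) / (SS2/df2) for the simpler (1) versus
#' richer (2) model, with the p-value from the F distribution; the
#' small-sample corrected AICc difference is reported alongside. When the
#' richer model fails to improve the residual SS, F is reported as 0 and
#' the simpler model is preferred.
#'
#' @param simpler,richer `multiexp_fit` objects on the same histogram, the
#'   richer with more components.
#' @param n_points Number of fitted bins (defaults to the fits' own count).
#' @param alpha Significance level governing preference (default 0.05).
#' @return List with `F`, `p`, `delta_aicc` (AICc richer - simpler;
#'   negative favors the richer model), and `preferred` (component count).
#' @export
compare_nested <- function(simpler, richer, n_points = NULL, alpha = 0.05) {
  stopifnot(inherits(simpler, "multiexp_fit"), inherits(richer, "multiexp_fit"))
  m1 <- nrow(simpler$components); m2 <- nrow(richer$components)
  if (m2 <= m1) stop("'richer' must have more components than 'simpler'")
  if (is.null(n_points)) n_points <- simpler$n_points
  if (simpler$n_points != richer$n_points)
    stop("fits were not made to the same histogram (bin counts differ)")
  ss1 <- simpler$ss_residual; ss2 <- richer$ss_residual
  df1 <- simpler$df; df2 <- richer$df
  a1 <- aicc_from_ss(ss1, n_points, 2 * m1)
  a2 <- aicc_from_ss(ss2, n_points, 2 * m2)
  if (ss2 > ss1) {
    return(list(F = 0, p = 1, delta_aicc = a2 - a1, preferred = m1,
                simpler = m1, richer = m2))
  }
  Fval <- ((ss1 - ss2) / (df1 - df2)) / (ss2 / df2)
  p <- stats::pf(Fval, df1 - df2, df2, lower.tail = FALSE)
  list(F = Fval, p = p, delta_aicc = a2 - a1,
       preferred = if (p < alpha) m2 else m1,
       simpler = m1, richer = m2)
}

#' Select the number of exponential components sequentially
#'
#' Fits 1 component, then compares 1-vs-2, 2-vs-3, 3-vs-4 by the extra
#' sum-of-squares F-test, stopping as soon as the added component no longer
#' significantly improves the fit, a fit fails to converge, or the
#' component cap is reached. A richer fit whose parameters are ambiguous —
#' some dependency at the solution beyond the identifiability threshold,
#' meaning the added component is redundant and merely chases bin noise —
#' is treated as a failure to converge to an acceptable model. AICc
#' differences are recorded for every comparison; when AICc and the F-test
#' disagree the F-test governs and a message is emitted.
#'
#' @param hist A normalized [build_histogram()] result.
#' @param max_components Cap on components (default 4).
#' @param alpha F-test significance level (default 0.05).
#' @param max_iterations Iteration cap passed to [fit_multiexp()].
#' @return An object of class `model_selection`: `selected` (component
#'   count), `comparisons` (data frame of F, p, delta AICc per step),
#'   `stop_reason` (`"f_test_ns"`, `"no_convergence"`, or
#'   `"max_components"`), and `fits` (list of `multiexp_fit` by component
#'   count).
#' @export
select_model <- function(hist, max_components = 4, alpha = 0.05,
                         max_iterations = 3000) {
  fits <- list(fit_multiexp(hist, 1, max_iterations = max_iterations))
  selected <- 1L
  comparisons <- list()
  stop_reason <- "max_components"
  for (m in seq(2L, length.out = max_components - 1L)) {
    if (length(hist$bin_centers_epochs) - 2L * m <= 0L) {
      stop_reason <- "max_components"
      break
    }
    f <- tryCatch(fit_multiexp(hist, m, max_iterations = max_iterations),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged || !f$identifiable) {
      stop_reason <- "no_convergence"
      break
    }
    fits[[m]] <- f
    cmp <- compare_nested(fits[[selected]], f, alpha = alpha)
    comparisons[[length(comparisons) + 1L]] <-
      data.frame(simpler = cmp$simpler, richer = cmp$richer, F = cmp$F,
                 p = cmp$p, delta_aicc = cmp$delta_aicc, preferred = cmp$preferred)
    aicc_prefers_richer <- cmp$delta_aicc < 0
    f_prefers_richer <- cmp$preferred == cmp$richer
    if (aicc_prefers_richer != f_prefers_richer) {
      message("F-test and AICc disagree at ", cmp$simpler, " vs ", cmp$richer,
              " components (F-test governs selection)")
    }
    if (!f_prefers_richer) {
      stop_reason <- "f_test_ns"
      break
    }
    selected <- m
  }
  comparisons <- if (length(comparisons) > 0L) do.call(rbind, comparisons)
  else data.frame(simpler = integer(0), richer = integer(0), F = numeric(0),
                  p = numeric(0), delta_aicc = numeric(0), preferred = integer(0))
  structure(list(selected = selected, comparisons = comparisons,
                 stop_reason = stop_reason, fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> selected ", x$selected, " component(s), stop: ",
      x$stop_reason, "\n", sep = "")
  if (nrow(x$comparisons) > 0L) print(x$comparisons)
  invisible(x)
}

#' Y0-weighted mean decay time constant
#'
#' The component time constants weighted by their Y0 amplitudes,
#' sum_i (Y0_i / sum Y0) tau_i — the single-number summary comparable to a
#' forced mono-exponential fit.
#'
#' @param fit A `multiexp_fit`, or a data frame with columns `tau_epochs`
#'   and `y0` (e.g. published component tables; percent contributions are
#'   valid `y0` weights since only ratios matter).
#' @return Weighted tau in epochs.
#' @examples
#' weighted_tau(data.frame(tau_epochs = c(3.8, 19.0), y0 = c(40.5, 59.5)))
#' @export
weighted_tau <- function(fit) {
  comp <- if (inherits(fit, "multiexp_fit")) {
    if (!fit$converged) warning("weighted_tau on a non-converged fit")
    fit$components
  } else {
    stopifnot(is.data.frame(fit), all(c("tau_epochs", "y0") %in% names(fit)))
    fit
  }
  sum(comp$y0 * comp$tau_epochs) / sum(comp$y0)
}

#' Relative contribution of each exponential component
#'
#' 100 * Y0_i / sum(Y0): the percentage of the fitted intercept carried by
#' each component. This is not the component's event fraction (which scales
#' as Y0_i * tau_i) nor its area under the curve.
#'
#' @param fit A `multiexp_fit`.
#' @return Numeric vector of percentages summing to 100, in ascending-tau
#'   order.
#' @export
relative_contributions <- function(fit) {
  stopifnot(inherits(fit, "multiexp_fit"))
  if (!fit$converged) warning("relative_contributions on a non-converged fit")
  100 * fit$components$y0 / sum(fit$components$y0)
}

#' Goodness-of-fit diagnostics for an exponential fit
#'
#' @param fit A `multiexp_fit`.
#' @param hist The histogram it was fitted to (defaults to the data stored
#'   in the fit).
#' @return List with `r_squared`, `residuals` (data frame of bin, observed,
#'   fitted, residual), `ci95`, and `ci_available`.
#' @export
fit_diagnostics <- function(fit, hist = NULL) {
  stopifnot(inherits(fit, "multiexp_fit"))
  if (is.null(hist)) {
    x <- fit$x; y <- fit$y
  } else {
    x <- as.numeric(hist$bin_centers_epochs); y <- hist$rel_freq
  }
  fitted <- multiexp_model(fit$components$k, fit$components$y0, x)
  res <- y - fitted
  ss <- sum(res^2)
  list(r_squared = 1 - ss / sum((y - mean(y))^2),
       residuals = data.frame(bin = x, observed = y, fitted = fitted,
                              residual = res),
       ci95 = fit$ci95,
       ci_available = fit$ci_available)
}
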