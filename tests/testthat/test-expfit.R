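test_that("noiseless model-matched histograms are recovered exactly", {
  # single exponential, tau = 5: unit height at X = 1
  h1 <- histogram_from_rel_freq(1:60, exp(-(1:60 - 1) / 5))
  f1 <- fit_multiexp(h1, 1)
  expect_equal(f1$components$tau_epochs, 5, tolerance = 1e-6)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  # two and three components: oracle equivalence to <= 1e-6 relative error
  f2 <- fit_multiexp(noiseless_hist(c(2, 15), c(0.7, 0.3)), 2)
  expect_equal(f2$components$tau_epochs, c(2, 15), tolerance = 1e-6)
  expect_equal(f2$components$y0 / max(f2$components$y0), c(1, 3 / 7),
               tolerance = 1e-6)

  f3 <- fit_multiexp(noiseless_hist(c(1, 5, 25), c(0.95, 0.2, 0.05), n_bins = 120), 3)
  expect_equal(f3$components$tau_epochs, c(1, 5, 25), tolerance = 1e-5)
})

test_that("fit preconditions are enforced", {
  h <- build_histogram(bout_set("R", c(1, 1, 2, 3, 4, 5)))
  raw <- build_histogram(bout_set("R", c(1, 1, 2, 3, 4, 5)), normalize = FALSE)
  expect_error(fit_multiexp(raw, 1), "normalized")
  expect_error(fit_multiexp(h, 3), "df")
  expect_error(fit_multiexp(h, 5), "between 1 and 4")
})

test_that("components always come out sorted by ascending tau", {
  set.seed(13)
  for (i in 1:5) {
    taus <- sort(runif(2, 0.5, 30))
    h <- noiseless_hist(taus, runif(2, 0.1, 1))
    f <- fit_multiexp(h, 2)
    expect_false(is.unsorted(f$components$tau_epochs))
  }
})

test_that("residual SS is non-increasing in component count", {
  spec <- mixture_spec(c(1.7, 7.8, 44.1), y0_contribs = c(77.3, 18.2, 4.4))
  d <- draw_mixture_bouts(spec, 20000, seed = 5, quantize = TRUE)
  h <- build_histogram(bout_set("N", d))
  ss <- vapply(1:4, function(m) fit_multiexp(h, m)$ss_residual, numeric(1))
  expect_true(all(diff(ss) <= 1e-12))
})

test_that("nested F-test follows the extra sum-of-squares formula", {
  fake_fit <- function(m, ss, df, n) {
    structure(list(components = data.frame(y0 = rep(1, m),
                                           tau_epochs = seq_len(m), k = 1 / seq_len(m)),
                   ss_residual = ss, df = df, n_points = n, converged = TRUE),
              class = "multiexp_fit")
  }
  # SS1=10, SS2=5, df1=50, df2=48, N=52 -> F = ((10-5)/2)/(5/48) = 24
  cmp <- compare_nested(fake_fit(1, 10, 50, 52), fake_fit(2, 5, 48, 52))
  expect_equal(cmp$F, 24)
  expect_equal(cmp$p, pf(24, 2, 48, lower.tail = FALSE))
  expect_equal(cmp$preferred, 2)

  # identical SS: F = 0, simpler preferred
  cmp0 <- compare_nested(fake_fit(1, 5, 50, 52), fake_fit(2, 5, 48, 52))
  expect_equal(cmp0$F, 0)
  expect_equal(cmp0$preferred, 1)

  # richer fitting worse: F reported as 0, simpler preferred
  cmpw <- compare_nested(fake_fit(1, 5, 50, 52), fake_fit(2, 6, 48, 52))
  expect_equal(cmpw$F, 0)
  expect_equal(cmpw$preferred, 1)

  # AICc difference matches the stated small-sample formula
  aicc <- function(ss, n, k) n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(cmp$delta_aicc, aicc(5, 52, 4) - aicc(10, 52, 2))
  expect_equal(aicc_from_ss(5, 52, 4), aicc(5, 52, 4))
})

test_that("sequential selection stops at the first non-significant component", {
  # noiseless mono-exponential: nothing to improve
  sel1 <- select_model(histogram_from_rel_freq(1:60, exp(-(1:60) / 8)))
  expect_equal(sel1$selected, 1L)

  spec <- mixture_spec(c(3.8, 19.0), y0_contribs = c(40.5, 59.5))
  d <- draw_mixture_bouts(spec, 50000, seed = 31, quantize = TRUE)
  sel2 <- select_model(build_histogram(bout_set("R", d)))
  expect_equal(sel2$selected, 2L)
  # the third component is refused either as non-significant or as an
  # unidentifiable (redundant-parameter) fit
  expect_true(sel2$stop_reason %in% c("f_test_ns", "no_convergence"))
  # comparisons follow the (1,2),(2,3),... ladder
  expect_equal(sel2$comparisons$simpler, seq_len(nrow(sel2$comparisons)))
  expect_equal(sel2$comparisons$richer, sel2$comparisons$simpler + 1L)
})

test_that("weighted tau and relative contributions are Y0-weighted", {
  expect_equal(weighted_tau(data.frame(tau_epochs = 7, y0 = 0.4)), 7)
  expect_equal(weighted_tau(data.frame(tau_epochs = c(2, 10), y0 = c(1, 1))), 6)

  f <- fit_multiexp(noiseless_hist(c(2, 15), c(0.95, 0.05)), 2)
  rc <- relative_contributions(f)
  expect_equal(sum(rc), 100)
  expect_equal(rc, c(95, 5), tolerance = 1e-4)

  rc3 <- relative_contributions(fit_multiexp(noiseless_hist(c(1, 6, 30), rep(0.5, 3),
                                                            n_bins = 150), 3))
  expect_equal(rc3, rep(100 / 3, 3), tolerance = 1e-3)
})

test_that("diagnostics report residuals, r-squared and CIs", {
  h <- noiseless_hist(c(2, 15), c(0.7, 0.3))
  f <- fit_multiexp(h, 2)
  d <- fit_diagnostics(f, h)
  expect_equal(max(abs(d$residuals$residual)), 0, tolerance = 1e-8)
  expect_equal(d$r_squared, 1, tolerance = 1e-9)

  spec <- mixture_spec(c(3.8, 19.0), y0_contribs = c(40.5, 59.5))
  dd <- draw_mixture_bouts(spec, 50000, seed = 8, quantize = TRUE)
  f2 <- fit_multiexp(build_histogram(bout_set("R", dd)), 2)
  expect_true(f2$ci_available)
  ktab <- f2$ci95[grepl("^k", f2$ci95$parameter), ]
  expect_true(all(ktab$lo < ktab$estimate & ktab$estimate < ktab$hi))
})

test_that("a forced mono-exponential fit misses the fast decay yet keeps high r2", {
  spec <- mixture_spec(c(0.60, 3.1, 16.1), y0_contribs = c(94.5, 5.4, 0.3))
  d <- draw_mixture_bouts(spec, 50000, seed = 17, quantize = TRUE)
  h <- build_histogram(bout_set("WASO", d))
  f1 <- fit_multiexp(h, 1)
  expect_gte(f1$r_squared, 0.9)
  res <- fit_diagnostics(f1, h)$residuals
  # the systematic misfit concentrates at the short-duration bins
  short <- abs(res$residual[res$bin <= 5])
  long <- abs(res$residual[res$bin > 20])
  expect_gt(max(short), 10 * max(long))
})
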