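test_that("exponential draws are reproducible and calibrated", {
  a <- draw_exponential_bouts(5, 1000, seed = 99)
  b <- draw_exponential_bouts(5, 1000, seed = 99)
  expect_identical(a, b)

  big <- draw_exponential_bouts(5, 1e5, seed = 7)
  expect_gt(mean(big), 4.95)
  expect_lt(mean(big), 5.05)

  expect_length(draw_exponential_bouts(1, 1, seed = 1), 1)
  expect_gt(draw_exponential_bouts(1, 1, seed = 1), 0)
  expect_error(draw_exponential_bouts(-1, 10), "positive")
  expect_error(draw_exponential_bouts(5, 0), ">= 1")
})

test_that("Y0-contribution and event-probability parameterizations invert", {
  p <- y0_contribs_to_event_probs(c(1, 5, 25), c(95, 4, 1))
  expect_equal(p, c(0.95, 0.20, 0.25) / 1.40, tolerance = 1e-9)
  expect_equal(round(p, 3), c(0.679, 0.143, 0.179))

  expect_equal(y0_contribs_to_event_probs(3, 100), 1)
  # equal taus: probabilities proportional to contributions
  expect_equal(y0_contribs_to_event_probs(c(2, 2), c(80, 20)), c(0.8, 0.2))

  set.seed(55)
  for (i in 1:25) {
    m <- sample(1:4, 1)
    taus <- sort(runif(m, 0.2, 50))
    contribs <- runif(m, 0.01, 1)
    contribs <- 100 * contribs / sum(contribs)
    p <- y0_contribs_to_event_probs(taus, contribs)
    expect_equal(event_probs_to_y0_contribs(taus, p), contribs, tolerance = 1e-12)
  }
})

test_that("mixture draws honor the component structure", {
  one <- mixture_spec(4, event_probs = 1)
  d1 <- draw_mixture_bouts(one, 5e4, seed = 3)
  expect_equal(mean(d1), 4, tolerance = 0.05)

  spec <- mixture_spec(c(1, 5, 25), y0_contribs = c(95, 4, 1))
  expect_identical(draw_mixture_bouts(spec, 100, seed = 12),
                   draw_mixture_bouts(spec, 100, seed = 12))

  # conditional means: redo the two-stage sampling by hand under one seed
  set.seed(1001)
  comp <- sample.int(3, 2e5, replace = TRUE, prob = spec$event_probs)
  d <- rexp(2e5, rate = 1 / spec$taus_epochs[comp])
  for (i in 1:3) {
    expect_equal(mean(d[comp == i]), spec$taus_epochs[i], tolerance = 0.05)
  }

  q <- draw_mixture_bouts(spec, 1000, seed = 4, quantize = TRUE)
  expect_true(all(q >= 1L))
  expect_true(is.integer(q))
})

test_that("mixture_spec validates its invariants", {
  expect_error(mixture_spec(c(5, 1), event_probs = c(0.5, 0.5)), "increasing")
  expect_error(mixture_spec(c(1, 5), event_probs = c(0.6, 0.6)), "sum to 1")
  expect_error(mixture_spec(c(1, 5)), "exactly one")
  expect_error(mixture_spec(c(1, 5), event_probs = c(0.5, 0.5),
                            y0_contribs = c(50, 50)), "exactly one")
})

test_that("simulated hypnograms alternate stages and respect the length cap", {
  spec <- reference_cohort_spec("control", n_subjects = 12, seed = 2718)
  hyps <- simulate_hypnogram(spec)
  expect_length(hyps, 12)
  for (h in hyps) {
    expect_equal(length(h$stages), spec$n_epochs)
    b <- extract_bouts(h)
    # no self-transitions: consecutive bouts have distinct stages
    if (nrow(b) > 1) expect_true(all(b$stage[-1] != b$stage[-nrow(b)]))
    # recording starts with the latency wake run, then NREM (W -> N always)
    expect_equal(b$stage[1], "W")
    expect_equal(b$stage[2], "N")
  }
  # reproducibility of the whole cohort
  hyps2 <- simulate_hypnogram(spec)
  expect_identical(lapply(hyps, `[[`, "stages"), lapply(hyps2, `[[`, "stages"))
})

test_that("simulated dwell-time marginals match the generating mixture", {
  spec <- reference_cohort_spec("control", n_subjects = 120, seed = 31415)
  hyps <- simulate_hypnogram(spec)
  pooled <- pool_bouts(lapply(hyps, function(h)
    select_stage_bouts(extract_bouts(h), "R", h)))
  fresh <- draw_mixture_bouts(cohort_mixture("control", "REM"), 2e4,
                              seed = 27182, quantize = TRUE)
  ks <- suppressWarnings(ks.test(pooled$durations_epochs, fresh))
  expect_gt(ks$p.value, 0.01)
})

test_that("self-transitions and malformed transition rules are rejected", {
  m <- cohort_mixture("control", "REM")
  expect_error(cohort_spec(m, m, m, transition = list(W = c(N = 1),
                                                      N = c(N = 0.5, W = 0.5),
                                                      R = c(N = 1))),
               "self-transition")
  expect_error(cohort_spec(m, m, m, transition = list(W = c(N = 1),
                                                      N = c(R = 0.2, W = 0.2),
                                                      R = c(N = 1))),
               "sum to 1")
})

test_that("written cohorts round-trip through the manifest reader", {
  spec <- reference_cohort_spec("control", n_subjects = 4, seed = 777,
                                n_epochs = 200)
  hyps <- simulate_hypnogram(spec)
  dir <- file.path(tempdir(), "cohort_rt")
  manifest <- write_cohort(hyps, dir, group = "control")
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  expect_equal(nrow(man), 4)
  back <- lapply(seq_len(nrow(man)), function(i)
    read_hypnogram(man$path[i], stage_map_letters(), subject_id = man$subject_id[i]))
  expect_identical(lapply(back, `[[`, "stages"), lapply(hyps, `[[`, "stages"))
})

test_that("the under-sampling experiment counts passing trials", {
  r <- undersampling_experiment(tau = 5, n_events_per_trial = 10, n_trials = 10,
                                seed = 60)
  expect_length(r$p_values, 10)
  expect_equal(r$n_pass, sum(r$p_values > 0.05))
  r2 <- undersampling_experiment(tau = 5, n_events_per_trial = 10, n_trials = 10,
                                 seed = 60)
  expect_identical(r$p_values, r2$p_values)

  # p > 1 is impossible, so alpha = 1 passes nothing
  r3 <- undersampling_experiment(n_events_per_trial = 20, n_trials = 10,
                                 alpha = 1, seed = 2)
  expect_equal(r3$n_pass, 0)

  # scale family: pass rates do not depend on tau under a common seed
  ra <- undersampling_experiment(tau = 1, n_events_per_trial = 15, n_trials = 50,
                                 seed = 14)
  rb <- undersampling_experiment(tau = 40, n_events_per_trial = 15, n_trials = 50,
                                 seed = 14)
  expect_equal(ra$n_pass, rb$n_pass)
})
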