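test_that("reading translates SHHS numeric and letter codes", {
  f <- write_stage_file("0 0 2 2 5")
  h <- read_hypnogram(f, stage_map_shhs())
  expect_equal(h$stages, c("W", "W", "N2", "N2", "R"))
  expect_equal(h$epoch_seconds, 30)

  f2 <- write_stage_file("W,N1,R")
  h2 <- read_hypnogram(f2, stage_map_letters())
  expect_equal(h2$stages, c("W", "N1", "R"))
})

test_that("unknown codes and empty files are rejected with context", {
  f <- write_stage_file("0 9 0")
  expect_error(read_hypnogram(f, stage_map_shhs()), "'9'.*epoch index 1")
  f2 <- write_stage_file(character(0))
  expect_error(read_hypnogram(f2, stage_map_shhs()), "empty")
  expect_error(read_hypnogram(tempfile(), stage_map_shhs()), "not found")
})

test_that("collapse_nrem merges sub-stages and preserves W/R placement", {
  h <- hypnogram(c("W", "N1", "N2", "N2", "R"))
  expect_equal(collapse_nrem(h)$stages, c("W", "N", "N", "N", "R"))
  expect_equal(collapse_nrem(hypnogram(c("W", "R", "W")))$stages, c("W", "R", "W"))
  expect_equal(collapse_nrem(hypnogram(c("N3", "N4")))$stages, c("N", "N"))

  set.seed(71)
  for (i in 1:20) {
    s <- random_stages(sample(5:60, 1))
    cc <- collapse_nrem(hypnogram(s))$stages
    expect_equal(length(cc), length(s))
    expect_equal(which(cc == "W"), which(s == "W"))
    expect_equal(which(cc == "R"), which(s == "R"))
  }
})

test_that("bout extraction is run-length encoding and is invertible", {
  h <- hypnogram(c("W", "W", "N", "N", "N", "R", "R", "W"))
  b <- extract_bouts(h)
  expect_equal(b$stage, c("W", "N", "R", "W"))
  expect_equal(b$duration_epochs, c(2L, 3L, 2L, 1L))
  expect_equal(b$start_epoch_index, c(0L, 2L, 5L, 7L))

  expect_equal(extract_bouts(hypnogram("N1"))$duration_epochs, 1L)
  b3 <- extract_bouts(hypnogram(rep(c("W", "N2", "W"), each = 5)))
  expect_equal(b3$duration_epochs, c(5L, 5L, 5L))
})

test_that("bout extraction matches a brute-force scanner on random strings", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_stages(sample(1:80, 1))
    b <- extract_bouts(hypnogram(s))
    expect_equal(b, scan_bouts(s))
    # invertibility and duration conservation
    expect_equal(rep(b$stage, b$duration_epochs), s)
    expect_equal(sum(b$duration_epochs), length(s))
  }
})

test_that("WASO selection honors sleep onset and right-censoring", {
  h <- hypnogram(c("W", "W", "N", "W", "W", "N", "R", "W"))
  b <- extract_bouts(h)
  expect_equal(select_stage_bouts(b, "W", h)$durations_epochs, 2L)
  # keeping the final bout adds the trailing 1-epoch wake run
  expect_equal(sort(select_stage_bouts(b, "W", h, "keep_final")$durations_epochs),
               c(1L, 2L))

  h2 <- hypnogram(c("N", "W", "N"))
  expect_equal(select_stage_bouts(extract_bouts(h2), "W", h2)$durations_epochs, 1L)

  h3 <- hypnogram(rep("W", 6))
  expect_warning(ws <- select_stage_bouts(extract_bouts(h3), "W", h3), "no sleep")
  expect_length(ws$durations_epochs, 0)
})

test_that("pre-onset wake is excluded under every censoring policy", {
  set.seed(7)
  for (i in 1:25) {
    s <- c(rep("W", sample(1:8, 1)), random_stages(sample(5:40, 1)))
    h <- hypnogram(s)
    onset <- which(s != "W")[1] - 1L
    if (is.na(onset)) next
    pre_run <- if (onset > 0) s[1:onset] else character(0)
    for (pol in c("drop_final", "keep_final")) {
      ws <- select_stage_bouts(extract_bouts(h), "W", h, pol)
      # total WASO epochs can never include the pre-onset run
      expect_lte(sum(ws$durations_epochs), sum(s == "W") - length(pre_run))
    }
  }
})

test_that("sleep-stage selection drops only a censored final bout", {
  h <- hypnogram(c("W", "N", "N", "R", "N", "N", "N"))
  b <- extract_bouts(h)
  expect_equal(select_stage_bouts(b, "N", h)$durations_epochs, 2L)  # final N run censored
  expect_equal(select_stage_bouts(b, "N", h, "keep_final")$durations_epochs, c(2L, 3L))
  expect_equal(select_stage_bouts(b, "R", h)$durations_epochs, 1L)
})

test_that("summary metrics compute TST, latencies and efficiency", {
  m <- summary_metrics(hypnogram(c("W", "W", "N2", "N2", "R", "R", "N2", "N2")))
  expect_equal(m$tst_min, 3.0)
  expect_equal(m$sleep_latency_min, 1.0)
  expect_equal(m$rem_latency_min, 1.0)
  expect_equal(m$sleep_efficiency_pct, 75)
  expect_equal(unname(m$stage_pct[["N2"]]), 100 * 4 / 6)

  expect_equal(summary_metrics(hypnogram(rep("N2", 10)))$sleep_efficiency_pct, 100)

  m2 <- summary_metrics(hypnogram(c("W", "N1")))
  expect_equal(m2$tst_min, 0.5)
  expect_equal(m2$sleep_efficiency_pct, 50)

  expect_warning(m3 <- summary_metrics(hypnogram(rep("W", 4))), "no sleep")
  expect_true(m3$no_sleep)
  expect_true(is.na(m3$sleep_latency_min))
})
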