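test_that("lognormal moment matching reproduces the closed form", {
  p <- lognormal_from_median_iqr(119, 86, 180)
  expect_equal(p$mu, log(119))
  expect_equal(p$sigma, 0.5475, tolerance = 1e-3)
  p <- lognormal_from_median_iqr(51, 33, 85)
  expect_equal(p$mu, log(51))
  expect_equal(p$sigma, 0.7014, tolerance = 1e-3)
  # symmetric log-quartiles: sigma = 1 / qnorm(0.75)
  p <- lognormal_from_median_iqr(50, 50 * exp(-1), 50 * exp(1))
  expect_equal(p$sigma, 1 / qnorm(0.75))
  expect_error(lognormal_from_median_iqr(50, 60, 80), "q1 < median")

  # sampled median converges to the requested one
  set.seed(5)
  x <- rlnorm(20000, p$mu, p$sigma)
  expect_equal(median(x), 50, tolerance = 0.05)
})

test_that("planted events guarantee the prolonged-episode criterion", {
  n <- 600
  spo2 <- rep(93, n); occ <- rep(FALSE, n)
  pe <- plant_event(spo2, occ, 100, 120, 72)
  vals <- pe$spo2[100:219]
  expect_true(all(vals < 90))
  expect_gte(sum(vals < 80), 30)
  expect_equal(pe$truth$start, 100)
  expect_equal(pe$truth$end, 220)
  # below-80 range is consistent with the written values
  expect_true(all(pe$spo2[pe$truth$below80_start:
                            (pe$truth$below80_end - 1)] < 80))

  # minimal qualifying episode: 40 s at nadir 79
  pe2 <- plant_event(pe$spo2, pe$occupied, 400, 40, 79)
  expect_gte(sum(pe2$spo2[400:439] < 80), 30)

  # overlap is rejected
  expect_error(plant_event(pe$spo2, pe$occupied, 150, 60, 75), "overlaps")
  expect_error(plant_event(spo2, occ, 590, 60, 75), "outside")
})

test_that("planted SL respects containment, gaps and the protected nadir", {
  n <- 600
  spo2 <- rep(93, n); occ <- rep(FALSE, n)
  pe <- plant_event(spo2, occ, 100, 150, 74)
  valid <- rep(TRUE, n)
  ps <- plant_sl(valid, pe$truth, c(40, 20), "nadir")
  expect_equal(nrow(ps$periods), 2L)
  # inside the episode, first/last samples valid, >= 1 valid sample between
  expect_true(all(ps$periods[, 1] > pe$truth$start))
  expect_true(all(ps$periods[, 2] < pe$truth$end))
  expect_gte(ps$periods[2, 1], ps$periods[1, 2] + 1)
  # the episode still qualifies: >= 30 valid below-80 samples
  b <- pe$truth$below80_start:(pe$truth$below80_end - 1)
  expect_gte(sum(ps$valid[b] & pe$spo2[b] < 80), 30)

  # an oversized request is truncated to what the episode can host
  ps2 <- plant_sl(rep(TRUE, n), pe$truth, c(200, 100), "nadir")
  total <- sum(ps2$periods[, 2] - ps2$periods[, 1])
  expect_lte(total, 150 - 30)
  b_ok <- sum(ps2$valid[b] & pe$spo2[b] < 80)
  expect_gte(b_ok, 30)

  # uniform placement obeys the same constraints
  ps3 <- plant_sl(rep(TRUE, n), pe$truth, c(15, 10), "uniform")
  expect_true(all(ps3$periods[, 1] > pe$truth$start &
                    ps3$periods[, 2] < pe$truth$end))
  expect_gte(sum(ps3$valid[b] & pe$spo2[b] < 80), 30)

  # an episode with no room for SL errors out
  tiny <- list(start = 1L, end = 35L, below80_start = 2L, below80_end = 33L)
  expect_error(plant_sl(rep(TRUE, 40), tiny, 10), "infeasible")
})

test_that("infant generation is deterministic and honors a zero event rate", {
  spec <- cohort_spec(n_infants = 1, hours_per_infant = 1, rng_seed = 9)
  a <- generate_infant(spec, 1)
  b <- generate_infant(spec, 1)
  expect_identical(a, b)

  spec0 <- cohort_spec(n_infants = 1, hours_per_infant = 1,
                       phe_rate_per_h = 0, rng_seed = 9)
  g <- generate_infant(spec0, 1)
  expect_equal(nrow(g$truth$episodes), 0L)
  expect_equal(nrow(detect_events(g$recording)$episodes), 0L)
})

test_that("zero-noise cohorts are recovered exactly by the detectors", {
  spec <- cohort_spec(n_infants = 3, hours_per_infant = 6,
                      baseline_spo2_sd = 0, rng_seed = 21)
  for (i in 1:3) {
    g <- generate_infant(spec, i)
    det <- detect_events(g$recording)
    tr <- g$truth$episodes
    expect_equal(nrow(det$episodes), nrow(tr))
    expect_equal(det$episodes$start_s, tr$start_s)
    expect_equal(det$episodes$end_s, tr$end_s)
    expect_equal(det$episodes$sl_count, tr$sl_count)
    expect_equal(det$episodes$sl_time_s, tr$sl_time_s)
    expect_equal(det$episodes$overshoot, tr$overshoot)
    expect_equal(det$episodes$overshoot_delay_s[det$episodes$overshoot],
                 tr$overshoot_delay_s[tr$overshoot])
    # SL periods (in and out of episodes) match the planted intervals
    sl_d <- det$sl_periods[order(det$sl_periods$start_s), ]
    sl_t <- g$truth$sl_periods
    expect_equal(sl_d$start_s, sl_t$start_s)
    expect_equal(sl_d$end_s, sl_t$end_s)
  }
})

test_that("cohort generation writes a consistent, reproducible manifest", {
  spec <- cohort_spec(n_infants = 2, hours_per_infant = 1, rng_seed = 4)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  expect_setequal(man$avg_mode, c("AVG_2S", "AVG_8S"))
  for (i in 1:2) {
    f1 <- file.path(d1, man$csv_path[i])
    expect_true(file.exists(f1))
    expect_identical(readLines(f1), readLines(file.path(d2, man$csv_path[i])))
    rec <- read_recording_csv(f1, man$avg_mode[i], man$patient_id[i])
    expect_s3_class(rec, "satloss_recording")
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("background SL fraction differs by averaging mode as configured", {
  spec <- cohort_spec(n_infants = 2, hours_per_infant = 4, rng_seed = 31)
  g2 <- generate_infant(spec, 1)   # AVG_2S
  g8 <- generate_infant(spec, 2)   # AVG_8S
  f2 <- mean(!g2$recording$signal_valid)
  f8 <- mean(!g8$recording$signal_valid)
  expect_gt(f2, 0.035)
  expect_lt(f2, 0.075)
  expect_gt(f8, 0.005)
  expect_lt(f8, 0.035)
  expect_gt(f2, f8)
})
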