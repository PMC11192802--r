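test_that("find_runs returns maximal qualifying runs", {
  r <- find_runs(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE), 3)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start_s, r$end_s), c(2, 5))

  expect_equal(nrow(find_runs(rep(FALSE, 10), 1)), 0L)
  r <- find_runs(rep(TRUE, 5), 5)
  expect_equal(c(r$start_s, r$end_s), c(0, 5))
  expect_equal(nrow(find_runs(rep(TRUE, 5), 6)), 0L)
  expect_equal(nrow(find_runs(logical(0), 1)), 0L)
  # NA counts as FALSE
  r <- find_runs(c(TRUE, NA, TRUE, TRUE), 2)
  expect_equal(c(r$start_s, r$end_s), c(2, 4))
})

test_that("candidate episodes follow the entry/recovery definition", {
  cand <- detect_candidate_episodes(fix_basic())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start_s, 10)
  expect_equal(cand$end_s, 70)
  expect_equal(cand$duration_s, 60)
  expect_false(cand$censored)

  # never below 90: nothing
  rec <- recording(0:59, rep(93, 60), rep(TRUE, 60))
  expect_equal(nrow(detect_candidate_episodes(rec)), 0L)

  # a 5-s recovery attempt does not close the episode
  spo2 <- c(rep(93, 10), rep(88, 5), rep(92, 5), rep(88, 10), rep(92, 10))
  rec <- recording(seq_along(spo2) - 1, spo2, rep(TRUE, length(spo2)))
  cand <- detect_candidate_episodes(rec)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start_s, cand$end_s), c(10, 30))

  # invalid samples reset a recovery run
  spo2 <- c(rep(93, 10), rep(88, 5), rep(92, 6), rep(92, 4), rep(92, 15))
  valid <- rep(TRUE, length(spo2))
  valid[22] <- FALSE                      # breaks the run at 6 s
  rec <- recording(seq_along(spo2) - 1, spo2, valid)
  cand <- detect_candidate_episodes(rec)
  expect_equal(cand$end_s, 22)            # run restarts after the gap

  # unrecovered episode is censored
  spo2 <- c(rep(93, 10), rep(85, 30))
  rec <- recording(seq_along(spo2) - 1, spo2, rep(TRUE, length(spo2)))
  cand <- detect_candidate_episodes(rec)
  expect_true(cand$censored)
  expect_null(classify_prolonged(cand[1, ], rec))
})

test_that("prolonged classification applies the 30-s hypoxemia criterion", {
  rec <- fix_basic()
  cand <- detect_candidate_episodes(rec)
  phe <- classify_prolonged(cand[1, ], rec)
  expect_equal(phe$time_below80_s, 40)
  expect_equal(phe$duration_s, 60)

  # only 20 s below 80 -> not prolonged
  spo2 <- c(rep(93, 10), rep(85, 20), rep(78, 20), rep(85, 10), rep(92, 10))
  rec2 <- recording(seq_along(spo2) - 1, spo2, rep(TRUE, length(spo2)))
  cand2 <- detect_candidate_episodes(rec2)
  expect_null(classify_prolonged(cand2[1, ], rec2))

  # 30 s cumulative split by SL qualifies cumulatively, not contiguously
  rec3 <- fix_split_hypox()
  cand3 <- detect_candidate_episodes(rec3)
  cum <- classify_prolonged(cand3[1, ], rec3)
  expect_equal(cum$time_below80_s, 30)
  expect_null(classify_prolonged(
    cand3[1, ], rec3, detection_config(hypox_time_mode = "CONTIGUOUS")))
})

test_that("signal-loss periods carry boundary SpO2 and classification", {
  spo2 <- c(90, 78, 78, 70, 72, 78, 90, 92)
  valid <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  rec <- recording(0:7, spo2, valid)
  sl <- detect_signal_loss(rec)
  expect_equal(nrow(sl), 1L)
  expect_equal(c(sl$start_s, sl$end_s), c(2, 5))
  expect_equal(sl$spo2_before, 78)
  expect_equal(sl$spo2_after, 78)
  expect_equal(sl$post_sl_class, "BELOW")

  expect_equal(nrow(detect_signal_loss(fix_basic())), 0L)

  # SL at recording start has undefined before-SpO2
  rec <- recording(0:5, c(NA, NA, 92, 92, 92, 92),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  sl <- detect_signal_loss(rec)
  expect_true(is.na(sl$spo2_before))
  expect_equal(sl$spo2_after, 92)
  # and at recording end, undefined after-SpO2 and classification
  rec <- recording(0:5, c(92, 92, 92, 92, NA, NA),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  sl <- detect_signal_loss(rec)
  expect_true(is.na(sl$spo2_after))
  expect_equal(sl$post_sl_class, "UNDEFINED")
})

test_that("post-SL classification uses inclusive target bounds", {
  expect_equal(classify_post_sl(82), "BELOW")
  expect_equal(classify_post_sl(89.9), "BELOW")
  expect_equal(classify_post_sl(90), "WITHIN")
  expect_equal(classify_post_sl(92), "WITHIN")
  expect_equal(classify_post_sl(95), "WITHIN")
  expect_equal(classify_post_sl(96), "ABOVE")
})

test_that("SL periods are clipped to episode boundaries on assignment", {
  phe <- data.frame(start_s = 10, end_s = 70, duration_s = 60,
                    time_below80_s = 40, sl_count = 0L, sl_time_s = 0,
                    sl_relative_pct = 0)
  sl <- data.frame(start_s = 35, end_s = 45, duration_s = 10)
  out <- assign_sl_to_episode(sl, phe)
  expect_equal(out$sl_count, 1L)
  expect_equal(out$sl_time_s, 10)
  expect_equal(out$sl_relative_pct, 100 * 10 / 60)

  # outside the episode: excluded
  out <- assign_sl_to_episode(data.frame(start_s = 80, end_s = 90,
                                         duration_s = 10), phe)
  expect_equal(out$sl_count, 0L)

  # straddling the episode end: clipped
  out <- assign_sl_to_episode(data.frame(start_s = 65, end_s = 75,
                                         duration_s = 10), phe)
  expect_equal(out$sl_time_s, 5)
  expect_equal(attr(out, "sl_periods")$end_s, 70)
})

test_that("overshoot detection clips runs to the 120-s window", {
  rec <- fix_overshoot()
  det <- detect_events(rec)
  expect_equal(nrow(det$episodes), 1L)
  phe <- det$episodes[1, ]
  os <- detect_overshoot(rec, phe)
  expect_equal(os$onset_s, 80)
  expect_equal(os$duration_s, 16)
  expect_equal(os$delay_after_recovery_s, 10)
  expect_equal(os$relative_duration_pct, 100 * 16 / 120)

  # no hyperoxemic sample in the window
  expect_null(detect_overshoot(fix_basic(tail_n = 60),
                               data.frame(start_s = 10, end_s = 70)))

  # run starting late is clipped below the 8-s minimum
  spo2 <- c(rep(93, 10), rep(85, 10), rep(78, 40), rep(86, 10), rep(92, 115),
            rep(98, 15), rep(93, 10))
  rec <- recording(seq_along(spo2) - 1, spo2, rep(TRUE, length(spo2)))
  # recovery at 70; run starts at 185, window ends at 190 -> 5 s clipped
  expect_null(detect_overshoot(rec, data.frame(start_s = 10, end_s = 70)))
})

test_that("detectors agree with the brute-force reference on random traces", {
  for (seed in 1:12) {
    tr <- random_trace(sample(c(900, 1800, 3600), 1), seed)
    expect_matches_oracle(trace_recording(tr), label = paste("seed", seed))
  }
})

test_that("episode and SL partitions are disjoint, ordered and conserved", {
  for (seed in 101:106) {
    tr <- random_trace(1200, seed)
    rec <- trace_recording(tr)
    det <- detect_events(rec)
    cand <- det$candidates
    if (nrow(cand) > 1) {
      expect_true(all(diff(cand$start_s) > 0))
      expect_true(all(cand$start_s[-1] >= cand$end_s[-nrow(cand)]))
    }
    sl <- det$sl_periods
    if (nrow(sl) > 1) {
      expect_true(all(sl$start_s[-1] >= sl$end_s[-nrow(sl)]))
    }
    eps <- det$episodes
    if (nrow(eps)) {
      expect_true(all(eps$sl_relative_pct >= 0 & eps$sl_relative_pct <= 100))
      expect_true(all(eps$time_below80_s <= eps$duration_s))
      expect_true(all(eps$time_below80_s >= 30))
    }
  }
})

test_that("tightening thresholds is monotone in the expected direction", {
  for (seed in 201:204) {
    tr <- random_trace(1800, seed)
    rec <- trace_recording(tr)
    n_phe <- function(min_s) {
      cfg <- detection_config(hypox_min_s = min_s)
      nrow(detect_events(rec, cfg)$episodes)
    }
    expect_true(n_phe(45) <= n_phe(30))
    expect_true(n_phe(30) <= n_phe(15))

    n_os <- function(win) {
      cfg <- detection_config(overshoot_window_s = win)
      sum(detect_events(rec, cfg)$episodes$overshoot)
    }
    expect_true(n_os(60) <= n_os(120))
    expect_true(n_os(120) <= n_os(240))
  }
})
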