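# Hand-built 1-Hz traces used across test files.

# desaturation to 78% for 40 s inside a 60-s episode [10, 70), recovery at 92%
fix_basic <- function(tail_val = 92, tail_n = 20) {
  spo2 <- c(rep(93, 10), rep(85, 10), rep(78, 40), rep(86, 10),
            rep(tail_val, tail_n))
  recording(time_s = seq_along(spo2) - 1, spo2 = spo2,
            signal_valid = rep(TRUE, length(spo2)), patient_id = "fix")
}

# same episode followed by an overshoot run of 98% on t in [80, 96)
fix_overshoot <- function() {
  spo2 <- c(rep(93, 10), rep(85, 10), rep(78, 40), rep(86, 10),
            rep(92, 10), rep(98, 16), rep(93, 14))
  recording(time_s = seq_along(spo2) - 1, spo2 = spo2,
            signal_valid = rep(TRUE, length(spo2)), patient_id = "fix")
}

# 40 s of hypoxemia split by 10 s of signal loss into two 15-s valid runs
fix_split_hypox <- function() {
  spo2 <- c(rep(93, 10), rep(85, 5), rep(78, 15), rep(NA, 10), rep(78, 15),
            rep(85, 5), rep(92, 10))
  valid <- !is.na(spo2)
  recording(time_s = seq_along(spo2) - 1, spo2 = spo2, signal_valid = valid,
            patient_id = "fix")
}

# run the full detector/oracle comparison on one recording; errors on mismatch
expect_matches_oracle <- function(rec, label = "trace") {
  spo2 <- rec$spo2
  valid <- rec$signal_valid
  cfg <- detection_config()

  cand <- detect_candidate_episodes(rec, cfg)
  oc <- oracle_candidates(spo2, valid)
  expect_equal(nrow(cand), if (is.null(oc)) 0L else nrow(oc), label = label)
  if (!is.null(oc) && nrow(cand) == nrow(oc)) {
    expect_equal(cand$start_s, oc[, 1L] - 1, label = label)
    expect_equal(cand$end_s, oc[, 2L] - 1, label = label)
    expect_equal(cand$censored, oc[, 3L] == 1L, label = label)
  }

  for (i in seq_len(nrow(cand))) {
    if (cand$censored[i]) next
    ob <- oracle_below(spo2, valid, cand$start_s[i] + 1L, cand$end_s[i] + 1L)
    phe <- classify_prolonged(cand[i, ], rec, cfg)
    expect_equal(!is.null(phe), ob$cumulative >= 30, label = label)
    if (!is.null(phe)) {
      expect_equal(phe$time_below80_s, ob$cumulative, label = label)
      os <- detect_overshoot(rec, phe, cfg)
      oo <- oracle_overshoot(spo2, valid, phe$end_s + 1L)
      expect_equal(!is.null(os), !is.null(oo), label = label)
      if (!is.null(os) && !is.null(oo)) {
        expect_equal(os$onset_s, oo[1L] - 1, label = label)
        expect_equal(os$duration_s, oo[2L], label = label)
      }
    }
    phe_c <- classify_prolonged(cand[i, ], rec,
                                detection_config(hypox_time_mode = "CONTIGUOUS"))
    expect_equal(!is.null(phe_c), ob$contiguous >= 30, label = label)
  }

  sl <- detect_signal_loss(rec, cfg = cfg)
  osl <- oracle_sl(spo2, valid)
  expect_equal(nrow(sl), if (is.null(osl)) 0L else nrow(osl), label = label)
  if (!is.null(osl) && nrow(sl) == nrow(osl)) {
    expect_equal(sl$start_s, osl[, 1L] - 1, label = label)
    expect_equal(sl$end_s, osl[, 2L] - 1, label = label)
    expect_equal(sl$spo2_before, osl[, 3L], label = label)
    expect_equal(sl$spo2_after, osl[, 4L], label = label)
  }
  invisible(TRUE)
}
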