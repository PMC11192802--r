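make_fixture_episodes <- function() {
  data.frame(
    patient_id = c("A", "A", "B"),
    avg_mode = c("AVG_2S", "AVG_8S", "AVG_2S"),
    start_s = c(100, 500, 300), end_s = c(200, 560, 500),
    duration_s = c(100, 60, 200),
    time_below80_s = c(40, 30, 90),
    sl_count = c(2L, 0L, 1L),
    sl_time_s = c(50, 0, 30),
    sl_relative_pct = c(50, 0, 15),
    overshoot = c(TRUE, FALSE, FALSE),
    overshoot_delay_s = c(10, NA, NA),
    overshoot_duration_s = c(24, NA, NA))
}

test_that("the cohort summary reproduces hand-computed row values", {
  eps <- make_fixture_episodes()
  tab <- build_table1(eps)
  get <- function(v) {
    i <- match(v, tab$variable)
    tab[i, ]
  }
  r <- get("Number of pHE")
  expect_equal(r$sl, "2 (67%)")
  expect_equal(r$no_sl, "1 (33%)")
  r <- get("Number of pHE per patient")
  expect_equal(r$sl, "1 (1 to 1)")
  r <- get("Number of pHE under 2 s averaging")
  expect_equal(r$sl, "2 (100%)")
  expect_equal(r$no_sl, "0 (0%)")
  r <- get("Total pHE duration (s)")
  expect_equal(r$sl, "150 (125 to 175)")
  expect_equal(r$no_sl, "60 (60 to 60)")
  # U for x = (100, 200) vs y = (60): both above -> exact p = 2/3
  expect_equal(r$p, 2 / 3, tolerance = 1e-9)
  r <- get("Number of SL periods")
  expect_equal(r$sl, "3 (100%)")
  expect_equal(r$no_sl, "N.A.")
  r <- get("Absolute time per pHE (s)")
  expect_equal(r$sl, "40 (35 to 45)")
  r <- get("Number of periods")
  expect_equal(r$sl, "1 (50%)")
  expect_equal(r$no_sl, "0 (0%)")
  r <- get("Participants with >= 1 SL-pHE")
  expect_equal(r$sl, "2 (100%)")
  expect_output(print(tab), "Total pHE duration")
})

test_that("SL-period details and post-SL tallies enter the summary", {
  eps <- make_fixture_episodes()
  slp <- data.frame(
    in_phe = c(TRUE, TRUE, TRUE, FALSE),
    spo2_before = c(82, 76, 88, 93),
    spo2_after = c(82, NA, 87, 93),
    post_sl_class = c("BELOW", "UNDEFINED", "BELOW", "WITHIN"))
  tab <- build_table1(eps, slp)
  i <- match("SpO2 at SL start (%)", tab$variable)
  expect_equal(tab$sl[i], "82 (79 to 85)")
  i <- match("SpO2 at SL end (%)", tab$variable)
  expect_equal(tab$sl[i], "84 (83 to 86)")  # NA dropped; integer display
  i <- match("Below target", tab$variable)
  expect_equal(tab$sl[i], "2 (100%)")   # of the 2 periods with defined end
})

test_that("group comparisons run the right tests and suppress when empty", {
  eps <- make_fixture_episodes()
  cmp <- compare_sl_groups(eps)
  expect_setequal(
    intersect(cmp$variable, c("duration_s", "time_below80_s",
                              "overshoot_occurrence",
                              "sl_occurrence_by_avg_mode")),
    c("duration_s", "time_below80_s", "overshoot_occurrence",
      "sl_occurrence_by_avg_mode"))
  expect_true(all(cmp$test[cmp$variable == "overshoot_occurrence"] ==
                    "fisher"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))

  only_sl <- eps[eps$sl_count > 0, ]
  expect_warning(tab <- build_table1(only_sl), "suppressed")
  expect_true(all(is.na(tab$p)))

  # identical group distributions give p = 1 on the exact branch
  x <- data.frame(patient_id = rep(c("A", "B"), each = 2),
                  avg_mode = "AVG_2S",
                  duration_s = c(100, 200, 100, 200),
                  time_below80_s = c(40, 80, 40, 80),
                  sl_count = c(1L, 1L, 0L, 0L),
                  sl_time_s = c(10, 10, 0, 0),
                  sl_relative_pct = c(10, 5, 0, 0),
                  overshoot = FALSE,
                  overshoot_delay_s = NA_real_,
                  overshoot_duration_s = NA_real_)
  cmp <- compare_sl_groups(x)
  expect_equal(cmp$p[cmp$variable == "duration_s"], 1)
})

test_that("SpO2 before/after SL comparison supports both conventions", {
  slp <- data.frame(spo2_before = c(82, 76, 88, 85, 80),
                    spo2_after = c(82, 77, 86, 84, 81))
  r <- compare_sl_spo2(slp)
  expect_equal(r$method, "mann-whitney")
  expect_true(r$p > 0.5)        # nearly identical distributions
  rp <- compare_sl_spo2(slp, paired = TRUE)
  expect_equal(rp$method, "wilcoxon signed-rank")
  expect_error(compare_sl_spo2(data.frame(spo2_before = NA_real_,
                                          spo2_after = NA_real_)),
               "no SL periods")
})
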