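#' Configuration of the automated oxygen controller simulator
#'
#' Models the signal-loss behaviors of the closed-loop controller: during
#' signal loss the set FiO2 falls back to a back-up value that tracks
#' "baseline FiO2"; baseline FiO2 is updated every `baseline_update_interval_s`
#' seconds to asymptotically approach the mean of the set FiO2 over the
#' trailing `trailing_window_s` seconds (fraction `approach_fraction` of the
#' remaining gap per update); set FiO2 is capped at `fio2_max_delta` above the
#' current baseline and floored at `fio2_floor`.
#'
#' The titration law applied while the signal is valid is an explicitly
#' surrogate proportional controller (`gain_per_pct` FiO2 per percent SpO2
#' error from `target_mid_pct` per step); the vendor's true increment/decrement
#' scheduling is proprietary and is not reproduced. The behaviors exercised by
#' this package — fallback, baseline tracking, and the cap — are modeled
#' exactly as described.
#'
#' @param baseline_update_interval_s baseline update period, seconds.
#' @param trailing_window_s trailing-mean window, seconds.
#' @param approach_fraction fraction of the gap to the trailing mean closed
#'   per update, in (0, 1].
#' @param fio2_max_delta cap above baseline FiO2 (fraction).
#' @param fio2_floor minimum FiO2 (room air, 0.21).
#' @param gain_per_pct surrogate proportional gain: FiO2 change per percent
#'   SpO2 error per step.
#' @param target_mid_pct SpO2 setpoint of the surrogate law, percent.
#' @param backup_mode `"baseline"` (back-up FiO2 tracks baseline, the study
#'   configuration) or `"fixed"` (manually preset value).
#' @param backup_fixed fixed back-up FiO2 when `backup_mode = "fixed"`.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(baseline_update_interval_s = 300,
                              trailing_window_s = 900,
                              approach_fraction = 0.5,
                              fio2_max_delta = 0.15, fio2_floor = 0.21,
                              gain_per_pct = 0.002, target_mid_pct = 92.5,
                              backup_mode = c("baseline", "fixed"),
                              backup_fixed = NA_real_) {
  backup_mode <- match.arg(backup_mode)
  stopifnot(approach_fraction > 0, approach_fraction <= 1,
            fio2_max_delta >= 0, fio2_floor >= 0.21 - 1e-12,
            baseline_update_interval_s > 0, trailing_window_s > 0)
  if (backup_mode == "fixed" && !is.finite(backup_fixed))
    stop("backup_fixed must be given when backup_mode = 'fixed'")
  structure(list(baseline_update_interval_s = baseline_update_interval_s,
                 trailing_window_s = trailing_window_s,
                 approach_fraction = approach_fraction,
                 fio2_max_delta = fio2_max_delta, fio2_floor = fio2_floor,
                 gain_per_pct = gain_per_pct,
                 target_mid_pct = target_mid_pct,
                 backup_mode = backup_mode, backup_fixed = backup_fixed),
            class = "controller_config")
}

#' Controller state
#'
#' @param baseline_fio2 current baseline FiO2 (fraction).
#' @param set_fio2 currently set FiO2 (defaults to baseline).
#' @param backup_fio2 back-up FiO2 (defaults to baseline).
#' @param history numeric vector of recent set-FiO2 values (newest last),
#'   enough for the trailing mean.
#' @return an object of class `controller_state`.
#' @export
controller_state <- function(baseline_fio2, set_fio2 = baseline_fio2,
                             backup_fio2 = baseline_fio2,
                             history = numeric(0)) {
  structure(list(baseline_fio2 = baseline_fio2, backup_fio2 = backup_fio2,
                 set_fio2 = set_fio2, in_backup = FALSE, history = history),
            class = "controller_state")
}

#' Periodic baseline-FiO2 update
#'
#' Moves baseline FiO2 a fraction `approach_fraction` of the way toward the
#' mean of the trailing set-FiO2 history (the mean of whatever history exists
#' when shorter than the full window); with an empty history the baseline is
#' unchanged. When back-up FiO2 tracks the baseline it is updated too.
#'
#' @param state a [controller_state()].
#' @param cfg a [controller_config()].
#' @return the updated state.
#' @export
update_baseline <- function(state, cfg = controller_config()) {
  if (length(state$history)) {
    m <- mean(state$history)
    state$baseline_fio2 <- state$baseline_fio2 +
      cfg$approach_fraction * (m - state$baseline_fio2)
    if (cfg$backup_mode == "baseline") state$backup_fio2 <- state$baseline_fio2
  }
  state
}

#' One controller step
#'
#' At an invalid sample the set FiO2 is forced to the back-up value
#' (`in_backup = TRUE`); at a valid sample the surrogate proportional law
#' titrates from the current set FiO2 and clamps to
#' `[fio2_floor, min(1, baseline + fio2_max_delta)]`. The resulting set FiO2
#' is appended to the trailing history.
#'
#' @param state a [controller_state()].
#' @param spo2 SpO2 percent (ignored when `signal_valid` is `FALSE`).
#' @param signal_valid logical.
#' @param cfg a [controller_config()].
#' @param sample_interval_s step length in seconds (sizes the stored history).
#' @return the updated state.
#' @export
controller_step <- function(state, spo2, signal_valid,
                            cfg = controller_config(), sample_interval_s = 1) {
  hi <- min(1, state$baseline_fio2 + cfg$fio2_max_delta)
  if (!signal_valid) {
    state$set_fio2 <- state$backup_fio2
    state$in_backup <- TRUE
  } else {
    f <- state$set_fio2 + cfg$gain_per_pct * (cfg$target_mid_pct - spo2)
    state$set_fio2 <- min(max(f, cfg$fio2_floor), hi)
    state$in_backup <- FALSE
  }
  keep <- as.integer(ceiling(cfg$trailing_window_s / sample_interval_s))
  state$history <- c(state$history, state$set_fio2)
  if (length(state$history) > keep)
    state$history <- state$history[(length(state$history) - keep + 1L):
                                     length(state$history)]
  state
}

#' Simulate the controller over a recording
#'
#' Steps the controller at every sample of `rec` (using its SpO2 and validity
#' channels) and applies the baseline update on its schedule (every
#' `baseline_update_interval_s` seconds of elapsed recording time, before the
#' step at that sample). The recording is returned with its `fio2_set` channel
#' replaced by the simulated set FiO2. Deterministic given its inputs.
#'
#' @param rec a [recording()] object.
#' @param cfg a [controller_config()].
#' @param initial_fio2 starting baseline/backup/set FiO2 (fraction).
#' @return the recording with simulated `fio2_set`.
#' @export
simulate_controller <- function(rec, cfg = controller_config(),
                                initial_fio2 = 0.25) {
  stopifnot(inherits(rec, "satloss_recording"))
  dt <- rec$sample_interval_s
  n <- length(rec$time_s)
  v <- rec$signal_valid
  s <- rec$spo2
  gain <- cfg$gain_per_pct
  tmid <- cfg$target_mid_pct
  floor_ <- cfg$fio2_floor
  delta <- cfg$fio2_max_delta
  alpha <- cfg$approach_fraction
  upd_n <- max(1L, as.integer(round(cfg$baseline_update_interval_s / dt)))
  win_n <- max(1L, as.integer(round(cfg$trailing_window_s / dt)))
  track <- cfg$backup_mode == "baseline"

  baseline <- initial_fio2
  backup <- if (track) initial_fio2 else cfg$backup_fixed
  setf <- initial_fio2
  out <- numeric(n)
  buf <- numeric(win_n)   # ring buffer of recent set values
  bsum <- 0; bcount <- 0L; bpos <- 0L

  for (i in seq_len(n)) {
    if (i > 1L && (i - 1L) %% upd_n == 0L && bcount > 0L) {
      baseline <- baseline + alpha * (bsum / bcount - baseline)
      if (track) backup <- baseline
    }
    if (!v[i]) {
      setf <- backup
    } else {
      f <- setf + gain * (tmid - s[i])
      hi <- baseline + delta
      if (hi > 1) hi <- 1
      if (f < floor_) f <- floor_ else if (f > hi) f <- hi
      setf <- f
    }
    out[i] <- setf
    bpos <- bpos %% win_n + 1L
    if (bcount < win_n) bcount <- bcount + 1L else bsum <- bsum - buf[bpos]
    buf[bpos] <- setf
    bsum <- bsum + setf
  }
  rec$fio2_set <- out
  rec
}
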