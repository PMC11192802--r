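#' Lognormal parameters from a printed median and interquartile range
#'
#' Matches a lognormal distribution to a median and quartiles as reported in
#' clinical summaries: `mu = log(median)` (the median is matched exactly) and
#' `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`, so the quartiles are
#' matched asymptotically.
#'
#' @param median,q1,q3 the reported median and quartiles (same units,
#'   `0 < q1 < median < q3`).
#' @return a list with `mu` and `sigma` (log scale).
#' @examples
#' lognormal_from_median_iqr(119, 86, 180)
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!(0 < q1 && q1 < median && median < q3))
    stop("need 0 < q1 < median < q3")
  z <- stats::qnorm(0.75)
  list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * z))
}

# draw from a median/IQR-matched lognormal
.rlnorm_miq <- function(n, miq) {
  p <- lognormal_from_median_iqr(miq[1L], miq[2L], miq[3L])
  stats::rlnorm(n, p$mu, p$sigma)
}

# draw from a median/IQR-matched logit-normal (values in (0,1))
.rlogitnorm_miq <- function(n, miq) {
  lg <- function(p) log(p / (1 - p))
  z <- stats::qnorm(0.75)
  mu <- lg(miq[1L])
  sigma <- (lg(miq[3L]) - lg(miq[2L])) / (2 * z)
  stats::plogis(stats::rnorm(n, mu, sigma))
}

#' Synthetic-cohort specification
#'
#' Parameters of the synthetic preterm-infant cohort generator. Defaults
#' reproduce the reported study conditions: 24 infants recorded for 12.7 h at
#' 1 Hz, prolonged hypoxemic episodes (pHEs) arriving as a Poisson process at
#' a rate giving about 3 episodes per recording, signal loss (SL) in two
#' thirds of episodes with 1-2 periods per episode (median 2), and background
#' SL totalling 5% of recording time under 2-s averaging and 1% under 8-s
#' averaging.
#'
#' Episode durations are drawn per SL group from lognormals matched to the
#' reported medians/IQRs — 135 (112-228) s with SL, 81 (58-116) s without —
#' whose 1:2 mixture has an overall median near the reported 119 s. SL time
#' within an episode is drawn as a logit-normal *relative fraction* of episode
#' duration matched to the reported 40 (18-61) % of episode time, so the
#' reported absolute SL time (median 51 s) emerges jointly with duration; a
#' pooled duration model and an absolute SL-time model (lognormal
#' 51 (33-85) s) are selectable for sensitivity checks.
#'
#' @param n_infants number of infants.
#' @param hours_per_infant recording length, hours.
#' @param sample_interval_s sampling interval, seconds.
#' @param phe_rate_per_h episode arrival rate per hour.
#' @param duration_model `"grouped"` (default) or `"pooled"`.
#' @param phe_duration pooled duration median/q1/q3, seconds.
#' @param phe_duration_sl,phe_duration_nosl group-specific duration
#'   median/q1/q3, seconds.
#' @param min_phe_duration_s shortest plantable episode, seconds.
#' @param sl_prob_per_phe probability an episode contains SL.
#' @param sl_count_prob2 probability of 2 (rather than 1) SL periods.
#' @param sl_time_model `"relative"` (default) or `"absolute"`.
#' @param sl_relative relative SL time median/q1/q3 (fractions of episode
#'   duration).
#' @param sl_duration_coupling correlation (shared Gaussian factor) between
#'   an episode's duration and its relative SL time. Signal loss suspends
#'   titration and prolongs episodes, so the two are positively dependent;
#'   0.35 calibrates the *planted* SL-time median (after the
#'   episode-qualification constraint caps what short episodes can host) to
#'   the reported 51 s while preserving the relative-time median of 40%.
#' @param sl_duration absolute SL time median/q1/q3, seconds.
#' @param sl_placement `"nadir"` (SL biased toward the episode nadir, the
#'   reported pattern) or `"uniform"`.
#' @param background_sl_fraction named fractions of recording time under
#'   background SL, per averaging mode.
#' @param background_sl_run background SL run-length median/q1/q3, seconds.
#' @param overshoot_prob probability of a post-recovery overshoot.
#' @param overshoot_delay overshoot onset delay median/q1/q3, seconds.
#' @param overshoot_duration overshoot duration median/q1/q3, seconds.
#' @param baseline_spo2_mean,baseline_spo2_sd normoxemic SpO2 mean and noise
#'   SD, percent.
#' @param nadir_range episode nadir range (percent, below 80).
#' @param initial_fio2 controller starting FiO2.
#' @param controller a [controller_config()].
#' @param rng_seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_infants = 24, hours_per_infant = 12.7,
                        sample_interval_s = 1, phe_rate_per_h = 3 / 12.7,
                        duration_model = c("grouped", "pooled"),
                        phe_duration = c(119, 86, 180),
                        phe_duration_sl = c(135, 112, 228),
                        phe_duration_nosl = c(81, 58, 116),
                        min_phe_duration_s = 40,
                        sl_prob_per_phe = 2 / 3, sl_count_prob2 = 0.6,
                        sl_time_model = c("relative", "absolute"),
                        sl_relative = c(0.40, 0.18, 0.61),
                        sl_duration_coupling = 0.35,
                        sl_duration = c(51, 33, 85),
                        sl_placement = c("nadir", "uniform"),
                        background_sl_fraction = c(AVG_2S = 0.05,
                                                   AVG_8S = 0.01),
                        background_sl_run = c(30, 15, 60),
                        overshoot_prob = 0.2,
                        overshoot_delay = c(14, 9, 21),
                        overshoot_duration = c(45, 24, 75),
                        baseline_spo2_mean = 93, baseline_spo2_sd = 1.5,
                        nadir_range = c(72, 78), initial_fio2 = 0.25,
                        controller = controller_config(), rng_seed = 1L) {
  duration_model <- match.arg(duration_model)
  sl_time_model <- match.arg(sl_time_model)
  sl_placement <- match.arg(sl_placement)
  stopifnot(n_infants >= 1, hours_per_infant > 0, sample_interval_s > 0,
            phe_rate_per_h >= 0,
            sl_prob_per_phe >= 0, sl_prob_per_phe <= 1,
            sl_count_prob2 >= 0, sl_count_prob2 <= 1,
            overshoot_prob >= 0, overshoot_prob <= 1,
            baseline_spo2_sd >= 0,
            all(nadir_range < 80), nadir_range[1] <= nadir_range[2])
  for (q in list(phe_duration, phe_duration_sl, phe_duration_nosl,
                 sl_duration, background_sl_run, overshoot_delay,
                 overshoot_duration, sl_relative))
    if (!(q[2] < q[1] && q[1] < q[3])) stop("need q1 < median < q3")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d infants x %.1f h @ %g s, seed %d\n",
              x$n_infants, x$hours_per_infant, x$sample_interval_s,
              x$rng_seed))
  cat(sprintf("  pHE rate %.3f/h, SL prob %.2f, overshoot prob %.2f\n",
              x$phe_rate_per_h, x$sl_prob_per_phe, x$overshoot_prob))
  invisible(x)
}

# number of protected valid below-80 samples an episode must keep so that it
# still qualifies as a pHE after SL planting (>= hypox_min_s at 1 Hz)
.protect_n <- 30L

#' Plant one hypoxemic episode into an SpO2 trace
#'
#' Writes a piecewise-linear desaturation (descent from just below the episode
#' entry threshold to the nadir, nadir plateau, recovery ramp) over
#' `[t0, t0 + dur_n)` (sample indices). The plateau is sized to guarantee at
#' least 30 s below 80% by construction. Fails if the span overlaps an
#' occupied region.
#'
#' @param spo2 numeric SpO2 vector (mutated copy returned).
#' @param occupied logical vector marking already-planted samples.
#' @param t0 first sample index of the episode (1-based).
#' @param dur_n episode duration in samples.
#' @param nadir_pct nadir SpO2, percent (< 80).
#' @param entry_spo2 value at the episode edges (just below the entry
#'   threshold).
#' @return a list with the updated `spo2` and `occupied` vectors and a `truth`
#'   fragment (`start`, `end` half-open indices, `below80_start`,
#'   `below80_end`, `nadir`).
#' @export
plant_event <- function(spo2, occupied, t0, dur_n, nadir_pct,
                        entry_spo2 = 89) {
  stopifnot(nadir_pct < 80, dur_n >= 40)
  idx <- t0:(t0 + dur_n - 1L)
  if (t0 < 2L || max(idx) > length(spo2)) stop("event outside recording")
  if (any(occupied[idx])) stop("event overlaps a previously planted event")
  plateau_n <- max(.protect_n + 1L, as.integer(round(0.45 * dur_n)))
  if (plateau_n > dur_n - 4L) plateau_n <- dur_n - 4L
  ramp <- dur_n - plateau_n
  d_dn <- as.integer(ceiling(ramp / 2))
  d_up <- ramp - d_dn
  vals <- c(seq(entry_spo2, nadir_pct, length.out = d_dn + 1L)[seq_len(d_dn)],
            rep(nadir_pct, plateau_n),
            seq(nadir_pct, entry_spo2, length.out = d_up + 1L)[-1L])
  vals <- round(vals, 1)
  spo2[idx] <- vals
  occupied[idx] <- TRUE
  b <- which(vals < 80)
  list(spo2 = spo2, occupied = occupied,
       truth = list(start = t0, end = t0 + dur_n,
                    below80_start = t0 + b[1L] - 1L,
                    below80_end = t0 + b[length(b)],
                    nadir = nadir_pct))
}

# place SL periods for one episode; returns matrix of [start, end) index
# pairs or NULL when infeasible under the given durations.
# Zone A precedes the protected nadir block (descent / early plateau), zone C
# follows it (late plateau / recovery ramp); requested durations are
# rebalanced against the zone capacities, truncating the total only when the
# episode cannot host it.
.place_sl <- function(truth, durations, placement, jitter_max = 10L) {
  s <- truth$start; e <- truth$end
  b1 <- truth$below80_end
  prot0 <- b1 - .protect_n          # first protected index
  capA <- prot0 - (s + 1L)          # zone A: (s+1) .. (prot0-1)
  capC <- (e - 1L) - b1             # zone C: b1 .. (e-2)
  durations <- sort(as.integer(durations), decreasing = TRUE)
  k <- length(durations)
  in_A <- function(d) {
    slack <- min(capA - d, jitter_max)
    st <- prot0 - d - sample.int(slack + 1L, 1L) + 1L
    c(st, st + d)
  }
  in_C <- function(d) {
    slack <- min(capC - d, jitter_max)
    st <- b1 + sample.int(slack + 1L, 1L) - 1L
    c(st, st + d)
  }
  if (placement == "nadir") {
    total <- min(sum(durations), capA + capC)
    if (max(capA, capC) < 2L) return(NULL)
    if (k == 2L && total >= 4L) {
      tA <- min(durations[1L], capA)
      tC <- min(durations[2L], capC)
      deficit <- total - tA - tC
      if (deficit > 0L) { add <- min(deficit, capA - tA); tA <- tA + add }
      deficit <- total - tA - tC
      if (deficit > 0L) tC <- min(capC, tC + deficit)
      if (tA >= 2L && tC >= 2L)
        return(rbind(in_A(tA), in_C(tC)))
      if (tC < 2L && capA >= total + 1L) {   # both periods before the nadir
        dmain <- max(2L, total - 2L - 1L)
        dsec <- total - 1L - dmain
        if (dsec >= 2L) {
          st1 <- prot0 - dmain
          st2 <- st1 - 1L - dsec
          if (st2 >= s + 1L)
            return(rbind(c(st2, st2 + dsec), c(st1, st1 + dmain)))
        }
      }
      # fall through to a single period of the feasible total
    }
    d <- min(if (k == 2L) sum(durations) else durations[1L],
             max(capA, capC))
    if (d < 2L) return(NULL)
    return(matrix(if (d <= capA) in_A(d) else in_C(d), 1L))
  }
  # uniform placement: random disjoint positions avoiding the protected block
  d1 <- durations[1L]
  lo <- s + 1L; hi <- e - 2L
  if (k == 1L) {
    if (hi - lo + 1L < d1) return(NULL)
    for (a in seq_len(50L)) {
      st <- lo + sample.int(hi - d1 + 1L - lo + 1L, 1L) - 1L
      if (min(st + d1, b1) - max(st, prot0) <= 0L)
        return(matrix(c(st, st + d1), 1L))
    }
    return(NULL)
  }
  d2 <- durations[2L]
  if (hi - lo + 1L < d1 || hi - lo + 1L < d2) return(NULL)
  for (a in seq_len(50L)) {
    st1 <- lo + sample.int(hi - d1 + 1L - lo + 1L, 1L) - 1L
    st2 <- lo + sample.int(hi - d2 + 1L - lo + 1L, 1L) - 1L
    iv <- rbind(c(st1, st1 + d1), c(st2, st2 + d2))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    ok_gap <- iv[2L, 1L] > iv[1L, 2L]
    ok_prot <- all(pmin(iv[, 2L], b1) - pmax(iv[, 1L], prot0) <= 0L)
    if (ok_gap && ok_prot) return(iv)
  }
  NULL
}

#' Plant signal-loss periods inside a planted episode
#'
#' Clears validity flags on `count` disjoint intervals inside the episode,
#' keeping (i) the first and last episode samples valid, (ii) at least one
#' valid sample between consecutive periods, and (iii) at least 30 s of valid
#' SpO2 < 80% so the episode still qualifies as prolonged. Requested durations
#' are rebalanced against what the episode can host around the protected
#' nadir block, truncating the total only when it exceeds the episode's
#' capacity (under uniform placement, infeasible draws are retried with
#' shrunken durations); an episode that cannot host any SL raises an error.
#'
#' @param valid logical validity vector (mutated copy returned).
#' @param truth event fragment from [plant_event()].
#' @param durations integer vector (length 1 or 2) of period durations in
#'   samples.
#' @param placement `"nadir"` or `"uniform"`.
#' @return list with the updated `valid` vector and `periods`, a matrix of
#'   half-open `[start, end)` index pairs ordered by start.
#' @export
plant_sl <- function(valid, truth, durations, placement = "nadir") {
  durations <- pmax(as.integer(round(durations)), 2L)
  for (attempt in seq_len(8L)) {
    iv <- .place_sl(truth, durations, placement)
    if (!is.null(iv)) {
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(iv)))
        valid[iv[r, 1L]:(iv[r, 2L] - 1L)] <- FALSE
      return(list(valid = valid, periods = iv))
    }
    # uniform placement only: shrink, then drop to a single period
    durations <- pmax(as.integer(floor(durations * 0.7)), 2L)
    if (attempt == 6L && length(durations) == 2L)
      durations <- durations[1L]
  }
  stop("infeasible signal-loss placement for this episode")
}

# free-interval bookkeeping for background SL --------------------------------

.carve <- function(free, st, en, margin = 2L) {
  out <- list()
  for (iv in free) {
    if (en + margin <= iv[1L] || st - margin >= iv[2L]) {
      out[[length(out) + 1L]] <- iv
    } else {
      if (st - margin > iv[1L])
        out[[length(out) + 1L]] <- c(iv[1L], st - margin)
      if (en + margin < iv[2L])
        out[[length(out) + 1L]] <- c(en + margin, iv[2L])
    }
  }
  out
}

#' Generate one synthetic infant recording with ground truth
#'
#' Builds a 1-Hz (by default) SpO2/validity trace: clipped Gaussian baseline
#' noise inside the target range, Poisson-arriving planted hypoxemic episodes,
#' SL periods inside a fraction of episodes, background SL outside episodes,
#' optional post-recovery overshoots, and a set-FiO2 channel filled by
#' [simulate_controller()]. Deterministic for a given `(rng_seed,
#' infant_index)`.
#'
#' Noise is clipped so that planted event geometry survives it: normoxemic
#' samples stay at or above the target floor, samples planted below the
#' hypoxemia threshold stay below it, and within-episode samples stay below
#' the entry threshold. Detection boundaries therefore equal the planted
#' ground truth exactly, with or without noise.
#'
#' @param spec a [cohort_spec()].
#' @param infant_index 1-based infant number (odd indices get 2-s averaging
#'   mode, even indices 8-s).
#' @return a list with `recording` (a [recording()]) and `truth`, a list of
#'   data frames `episodes`, `sl_periods`, all in seconds.
#' @export
generate_infant <- function(spec, infant_index) {
  seed <- as.integer((as.numeric(spec$rng_seed) * 1000003 +
                        infant_index * 7919) %% 2147483646) + 1L
  set.seed(seed)
  dt <- spec$sample_interval_s
  n <- as.integer(round(spec$hours_per_infant * 3600 / dt))
  mode <- if (infant_index %% 2L == 1L) "AVG_2S" else "AVG_8S"
  sd <- spec$baseline_spo2_sd

  spo2 <- spec$baseline_spo2_mean + stats::rnorm(n, 0, sd)
  spo2 <- round(pmin(pmax(spo2, 90.2), 96.4), 1)
  valid <- rep(TRUE, n)
  occupied <- rep(FALSE, n)

  # --- episode schedule ------------------------------------------------------
  n_ev <- stats::rpois(1L, spec$phe_rate_per_h * spec$hours_per_infant)
  guard <- as.integer(150 / dt)
  ev <- list()
  if (n_ev > 0) for (j in seq_len(n_ev)) {
    with_sl <- stats::runif(1) < spec$sl_prob_per_phe
    miq <- if (spec$duration_model == "pooled") spec$phe_duration
           else if (with_sl) spec$phe_duration_sl else spec$phe_duration_nosl
    z_dur <- stats::rnorm(1)
    p <- lognormal_from_median_iqr(miq[1L], miq[2L], miq[3L])
    dur <- as.integer(round(max(spec$min_phe_duration_s / dt,
                                min(900 / dt,
                                    exp(p$mu + p$sigma * z_dur) / dt))))
    placed <- FALSE
    for (a in seq_len(100L)) {
      t0 <- sample.int(n - dur - guard - 60L, 1L) + 60L
      ok <- TRUE
      for (x in ev)
        if (t0 < x$end + guard && x$start < t0 + dur + guard) { ok <- FALSE; break }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) next
    ev[[length(ev) + 1L]] <- list(start = t0, end = t0 + dur, dur = dur,
                                  with_sl = with_sl, z_dur = z_dur)
  }
  if (length(ev)) ev <- ev[order(vapply(ev, `[[`, 1L, "start"))]

  # --- plant events, SL, overshoots -----------------------------------------
  ep_rows <- list()
  sl_rows <- list()
  for (j in seq_along(ev)) {
    x <- ev[[j]]
    nadir <- stats::runif(1, spec$nadir_range[1L], spec$nadir_range[2L])
    pe <- plant_event(spo2, occupied, x$start, x$dur, round(nadir, 1))
    tr <- pe$truth
    idx <- x$start:(x$end - 1L)
    if (sd > 0) {
      planted <- pe$spo2[idx]
      noisy <- planted + stats::rnorm(length(idx), 0, sd)
      hi <- ifelse(planted < 80, 79.4, 89.3)
      lo <- pmax(planted - 3, 60)
      pe$spo2[idx] <- round(pmin(pmax(noisy, lo), hi), 1)
    }
    spo2 <- pe$spo2; occupied <- pe$occupied

    sl_time <- 0; sl_cnt <- 0L
    if (x$with_sl) {
      total <- if (spec$sl_time_model == "relative") {
        # relative SL time shares a Gaussian factor with episode duration
        lg <- function(p) log(p / (1 - p))
        z75 <- stats::qnorm(0.75)
        muR <- lg(spec$sl_relative[1L])
        sR <- (lg(spec$sl_relative[3L]) - lg(spec$sl_relative[2L])) / (2 * z75)
        rho <- spec$sl_duration_coupling
        zr <- rho * x$z_dur + sqrt(1 - rho^2) * stats::rnorm(1)
        stats::plogis(muR + sR * zr) * x$dur
      } else .rlnorm_miq(1L, spec$sl_duration) / dt
      total <- max(3L, as.integer(round(total)))
      cnt <- 1L + (stats::runif(1) < spec$sl_count_prob2)
      durs <- if (cnt == 2L && total >= 5L) {
        w <- stats::runif(1, 0.35, 0.65)
        c(max(2L, as.integer(round(total * w))), 0L)
      } else total
      if (length(durs) == 2L || durs[1L] == 0L) {
        durs <- c(durs[1L], max(2L, total - durs[1L]))
      }
      ps <- plant_sl(valid, tr, durs, spec$sl_placement)
      valid <- ps$valid
      for (r in seq_len(nrow(ps$periods))) {
        sl_rows[[length(sl_rows) + 1L]] <-
          data.frame(phe_id = j,
                     start_s = (ps$periods[r, 1L] - 1L) * dt,
                     end_s = (ps$periods[r, 2L] - 1L) * dt)
      }
      sl_cnt <- nrow(ps$periods)
      sl_time <- sum(ps$periods[, 2L] - ps$periods[, 1L]) * dt
    }

    os_onset <- NA_real_; os_dur <- NA_real_; os_delay <- NA_real_
    if (stats::runif(1) < spec$overshoot_prob) {
      delay <- as.integer(round(min(60, max(2, .rlnorm_miq(1L, spec$overshoot_delay)))))
      odur <- as.integer(round(min(115, max(8, .rlnorm_miq(1L, spec$overshoot_duration)))))
      odur <- min(odur, 145L - delay)
      onset <- x$end + as.integer(delay / dt)
      oidx <- onset:(onset + as.integer(odur / dt) - 1L)
      if (max(oidx) <= n - 5L && !any(occupied[oidx])) {
        vals <- 97.8 + stats::rnorm(length(oidx), 0, sd)
        spo2[oidx] <- round(pmin(pmax(vals, 97.3), 99.6), 1)
        occupied[oidx] <- TRUE
        os_onset <- (onset - 1L) * dt
        os_delay <- delay
        os_dur <- min(odur, 120 - delay)   # clipped to the detection window
      }
    }

    ep_rows[[j]] <- data.frame(
      start_s = (tr$start - 1L) * dt, end_s = (tr$end - 1L) * dt,
      duration_s = x$dur * dt, nadir_pct = tr$nadir,
      below80_start_s = (tr$below80_start - 1L) * dt,
      below80_end_s = (tr$below80_end - 1L) * dt,
      sl = x$with_sl && sl_cnt > 0L, sl_count = sl_cnt, sl_time_s = sl_time,
      overshoot = is.finite(os_onset), overshoot_onset_s = os_onset,
      overshoot_delay_s = os_delay, overshoot_duration_s = os_dur)
  }

  # --- background SL ---------------------------------------------------------
  frac <- spec$background_sl_fraction[[mode]]
  if (frac > 0) {
    free <- list(c(6L, n - 5L))
    for (x in ev)
      free <- .carve(free, x$start - 15L, x$end + 145L, margin = 2L)
    target <- as.integer(round(frac * n))
    placed <- 0L
    attempts <- 0L
    while (placed < target && attempts < 4L * target) {
      attempts <- attempts + 1L
      lens <- vapply(free, function(iv) iv[2L] - iv[1L], numeric(1))
      if (!length(lens) || max(lens) < 5) break
      d <- as.integer(round(min(120, max(3, .rlnorm_miq(1L, spec$background_sl_run)))))
      d <- min(d, target - placed + 2L)
      fit <- which(lens >= d + 1L)
      if (!length(fit)) next
      pick <- if (length(fit) == 1L) fit else
        sample(fit, 1L, prob = lens[fit] - d)
      iv <- free[[pick]]
      st <- iv[1L] + sample.int(iv[2L] - iv[1L] - d + 1L, 1L) - 1L
      valid[st:(st + d - 1L)] <- FALSE
      sl_rows[[length(sl_rows) + 1L]] <-
        data.frame(phe_id = NA_integer_, start_s = (st - 1L) * dt,
                   end_s = (st + d - 1L) * dt)
      free <- .carve(free, st, st + d, margin = 2L)
      placed <- placed + d
    }
  }

  rec <- recording(time_s = (seq_len(n) - 1L) * dt, spo2 = spo2,
                   signal_valid = valid,
                   patient_id = sprintf("P%03d", infant_index),
                   averaging_mode = mode, sample_interval_s = dt)
  rec <- simulate_controller(rec, spec$controller, spec$initial_fio2)

  empty_ep <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         duration_s = numeric(0), nadir_pct = numeric(0),
                         below80_start_s = numeric(0),
                         below80_end_s = numeric(0), sl = logical(0),
                         sl_count = integer(0), sl_time_s = numeric(0),
                         overshoot = logical(0),
                         overshoot_onset_s = numeric(0),
                         overshoot_delay_s = numeric(0),
                         overshoot_duration_s = numeric(0))
  episodes <- if (length(ep_rows)) do.call(rbind, ep_rows) else empty_ep
  sl_periods <- if (length(sl_rows)) do.call(rbind, sl_rows) else
    data.frame(phe_id = integer(0), start_s = numeric(0), end_s = numeric(0))
  sl_periods <- sl_periods[order(sl_periods$start_s), , drop = FALSE]
  list(recording = rec,
       truth = list(episodes = episodes, sl_periods = sl_periods,
                    seed = seed))
}

#' Generate a synthetic cohort
#'
#' Maps [generate_infant()] over `spec$n_infants` infants with per-infant
#' derived seeds. When `dir` is given, each recording is written as CSV, each
#' ground truth as JSON, and an index manifest
#' (`patient_id,avg_mode,csv_path,truth_path,seed`) as `manifest.csv`.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory (created if missing).
#' @return invisibly, a list of `generate_infant()` results; with `dir`, the
#'   manifest path is attached as `attr(, "manifest")`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  out <- vector("list", spec$n_infants)
  man <- NULL
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_len(spec$n_infants)) {
    out[[i]] <- generate_infant(spec, i)
    if (!is.null(dir)) {
      rec <- out[[i]]$recording
      csv <- file.path(dir, sprintf("%s.csv", rec$patient_id))
      truth <- file.path(dir, sprintf("%s_truth.json", rec$patient_id))
      write_recording_csv(rec, csv)
      jsonlite::write_json(out[[i]]$truth, truth, dataframe = "columns",
                           digits = NA, auto_unbox = TRUE)
      man <- rbind(man, data.frame(patient_id = rec$patient_id,
                                   avg_mode = rec$averaging_mode,
                                   csv_path = basename(csv),
                                   truth_path = basename(truth),
                                   seed = out[[i]]$truth$seed))
    }
  }
  if (!is.null(dir)) {
    mp <- file.path(dir, "manifest.csv")
    utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
    attr(out, "manifest") <- mp
  }
  invisible(out)
}
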