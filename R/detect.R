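#' Detection thresholds for hypoxemic episodes, signal loss and overshoots
#'
#' All thresholds and persistence times defining a prolonged hypoxemic episode
#' (pHE), a signal-loss (SL) period and a post-recovery hyperoxemic overshoot.
#' Defaults encode the clinical definitions used throughout the package: an
#' episode opens when valid SpO2 drops below 90%, closes at the start of the
#' first run of at least 8 s of confirmed (valid) SpO2 >= 90%, and qualifies
#' as *prolonged* when it contains at least 30 s of valid SpO2 < 80%. An
#' overshoot is SpO2 >= 97% sustained for at least 8 s within 120 s after
#' recovery.
#'
#' @param target_lower_pct,target_upper_pct SpO2 target range bounds
#'   (inclusive), percent.
#' @param episode_entry_pct episode entry threshold, percent.
#' @param hypox_pct hypoxemia threshold, percent.
#' @param hypox_min_s minimum hypoxemic time for a pHE, seconds.
#' @param recovery_min_s sustained recovery time closing an episode, seconds.
#' @param hyperox_pct overshoot threshold, percent.
#' @param overshoot_window_s post-recovery search window, seconds.
#' @param overshoot_min_s minimum overshoot duration, seconds.
#' @param hypox_time_mode how hypoxemic time is accumulated: `"CUMULATIVE"`
#'   (default) sums all valid sample time below `hypox_pct` within the episode;
#'   `"CONTIGUOUS"` uses the longest unbroken valid run. The cumulative reading
#'   is the default because signal loss frequently overlaps the episode nadir,
#'   and a strictly contiguous rule would disqualify episodes whose hypoxemia
#'   is merely interrupted by dropout.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(target_lower_pct = 90, target_upper_pct = 95,
                             episode_entry_pct = 90, hypox_pct = 80,
                             hypox_min_s = 30, recovery_min_s = 8,
                             hyperox_pct = 97, overshoot_window_s = 120,
                             overshoot_min_s = 8,
                             hypox_time_mode = c("CUMULATIVE", "CONTIGUOUS")) {
  hypox_time_mode <- match.arg(hypox_time_mode)
  if (!(hypox_pct < target_lower_pct && target_lower_pct <= target_upper_pct &&
        target_upper_pct < hyperox_pct))
    stop("thresholds must satisfy hypox < target_lower <= target_upper < hyperox")
  durs <- c(hypox_min_s, recovery_min_s, overshoot_window_s, overshoot_min_s)
  if (any(durs <= 0)) stop("all durations must be positive")
  structure(list(target_lower_pct = target_lower_pct,
                 target_upper_pct = target_upper_pct,
                 episode_entry_pct = episode_entry_pct,
                 hypox_pct = hypox_pct, hypox_min_s = hypox_min_s,
                 recovery_min_s = recovery_min_s, hyperox_pct = hyperox_pct,
                 overshoot_window_s = overshoot_window_s,
                 overshoot_min_s = overshoot_min_s,
                 hypox_time_mode = hypox_time_mode),
            class = "detection_config")
}

#' Maximal runs of TRUE in a sample-aligned mask
#'
#' @param mask logical vector aligned to a recording's time grid (`NA` counts
#'   as `FALSE`).
#' @param min_duration_s minimum run duration in seconds.
#' @param sample_interval_s grid spacing in seconds.
#' @param t0 time of the first sample, seconds.
#' @return data frame with `start_s`, `end_s` (half-open) and `duration_s`,
#'   ordered and non-overlapping.
#' @export
find_runs <- function(mask, min_duration_s = sample_interval_s,
                      sample_interval_s = 1, t0 = 0) {
  mask <- !is.na(mask) & mask
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0))
  if (!length(mask) || !any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * sample_interval_s >= min_duration_s - 1e-9
  if (!any(keep)) return(empty)
  s <- t0 + (starts[keep] - 1L) * sample_interval_s
  e <- t0 + ends[keep] * sample_interval_s
  data.frame(start_s = s, end_s = e, duration_s = e - s)
}

# indices of episode-grid helpers -------------------------------------------

.idx_of <- function(rec, t) as.integer(round((t - rec$time_s[1L]) /
                                               rec$sample_interval_s)) + 1L

#' Detect candidate desaturation episodes
#'
#' An episode starts at the first valid sample with SpO2 below
#' `episode_entry_pct` whose predecessor is a valid sample at or above the
#' threshold (or at the recording start), and ends at the start of the first
#' subsequent run of at least `recovery_min_s` of consecutive valid samples
#' with SpO2 >= `target_lower_pct`. Invalid samples never start an episode,
#' never count toward recovery, and reset an in-progress recovery run. An
#' episode that never recovers before the end of the recording is flagged
#' censored and is excluded from downstream statistics.
#'
#' @param rec a [recording()] object.
#' @param cfg a [detection_config()].
#' @return data frame with `start_s`, `end_s` (half-open), `duration_s`,
#'   `censored`.
#' @export
detect_candidate_episodes <- function(rec, cfg = detection_config()) {
  v <- rec$signal_valid
  s <- rec$spo2
  dt <- rec$sample_interval_s
  n <- length(v)
  below <- v & !is.na(s) & s < cfg$episode_entry_pct
  prev_ok <- c(TRUE, v[-n] & !is.na(s[-n]) & s[-n] >= cfg$episode_entry_pct)
  starts <- which(below & prev_ok)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), censored = logical(0))
  if (!length(starts)) return(empty)
  rec_runs <- find_runs(v & !is.na(s) & s >= cfg$target_lower_pct,
                        min_duration_s = cfg$recovery_min_s,
                        sample_interval_s = dt, t0 = rec$time_s[1L])
  rstart_idx <- if (nrow(rec_runs)) .idx_of(rec, rec_runs$start_s) else integer(0)
  out_start <- numeric(0); out_end <- numeric(0); out_cens <- logical(0)
  pos <- 1L
  for (st in starts) {
    if (st < pos) next
    nxt <- rstart_idx[rstart_idx > st]
    if (length(nxt)) {
      en <- nxt[1L]
      out_start <- c(out_start, rec$time_s[st])
      out_end <- c(out_end, rec$time_s[en])
      out_cens <- c(out_cens, FALSE)
      pos <- en
    } else {
      out_start <- c(out_start, rec$time_s[st])
      out_end <- c(out_end, rec$time_s[n] + dt)
      out_cens <- c(out_cens, TRUE)
      break
    }
  }
  data.frame(start_s = out_start, end_s = out_end,
             duration_s = out_end - out_start, censored = out_cens)
}

#' Hypoxemic time within an episode
#'
#' @keywords internal
.hypox_time <- function(rec, start_s, end_s, cfg) {
  dt <- rec$sample_interval_s
  i0 <- .idx_of(rec, start_s)
  i1 <- .idx_of(rec, end_s) - 1L
  idx <- i0:i1
  hyp <- rec$signal_valid[idx] & !is.na(rec$spo2[idx]) &
    rec$spo2[idx] < cfg$hypox_pct
  cum <- sum(hyp) * dt
  contig <- if (any(hyp)) {
    r <- rle(hyp); max(r$lengths[r$values]) * dt
  } else 0
  list(cumulative = cum, contiguous = contig)
}

#' Classify a candidate episode as a prolonged hypoxemic episode
#'
#' A candidate qualifies as a pHE when its hypoxemic time (valid SpO2 below
#' `hypox_pct`) reaches `hypox_min_s`, counted cumulatively or as the longest
#' contiguous valid run depending on `cfg$hypox_time_mode`. `time_below80_s`
#' is always reported as the cumulative value.
#'
#' @param episode one row of [detect_candidate_episodes()] output (or any list
#'   with `start_s`, `end_s`, `censored`).
#' @param rec the source [recording()].
#' @param cfg a [detection_config()].
#' @return a one-row data frame with episode metrics, or `NULL` when the
#'   episode does not qualify (or is censored).
#' @export
classify_prolonged <- function(episode, rec, cfg = detection_config()) {
  if (isTRUE(episode$censored)) return(NULL)
  ht <- .hypox_time(rec, episode$start_s, episode$end_s, cfg)
  crit <- if (cfg$hypox_time_mode == "CUMULATIVE") ht$cumulative else ht$contiguous
  if (crit < cfg$hypox_min_s - 1e-9) return(NULL)
  data.frame(start_s = episode$start_s, end_s = episode$end_s,
             duration_s = episode$end_s - episode$start_s,
             time_below80_s = ht$cumulative,
             sl_count = 0L, sl_time_s = 0, sl_relative_pct = 0,
             overshoot = FALSE, overshoot_delay_s = NA_real_,
             overshoot_duration_s = NA_real_,
             overshoot_relative_pct = NA_real_)
}

#' Classify the SpO2 value at signal return relative to the target range
#'
#' @param spo2 SpO2 percent at the first valid sample after a signal-loss
#'   period.
#' @param cfg a [detection_config()].
#' @return `"BELOW"`, `"WITHIN"` or `"ABOVE"` (target-range bounds inclusive).
#' @export
classify_post_sl <- function(spo2, cfg = detection_config()) {
  ifelse(spo2 < cfg$target_lower_pct, "BELOW",
         ifelse(spo2 <= cfg$target_upper_pct, "WITHIN", "ABOVE"))
}

#' Detect signal-loss periods
#'
#' Maximal runs of invalid samples of at least `min_sl_s`, annotated with the
#' SpO2 of the last valid sample strictly before the run (`spo2_before`) and
#' of the first valid sample at or after its end (`spo2_after`); either is
#' `NA` at a recording edge. `post_sl_class` classifies `spo2_after` against
#' the target range.
#'
#' @param rec a [recording()] object.
#' @param min_sl_s minimum duration, seconds (default: one sample interval).
#' @param cfg a [detection_config()] (for the target range).
#' @return data frame with `start_s`, `end_s`, `duration_s`, `spo2_before`,
#'   `spo2_after`, `post_sl_class`.
#' @export
detect_signal_loss <- function(rec, min_sl_s = rec$sample_interval_s,
                               cfg = detection_config()) {
  runs <- find_runs(!rec$signal_valid, min_duration_s = min_sl_s,
                    sample_interval_s = rec$sample_interval_s,
                    t0 = rec$time_s[1L])
  if (!nrow(runs)) {
    runs$spo2_before <- numeric(0)
    runs$spo2_after <- numeric(0)
    runs$post_sl_class <- character(0)
    return(runs)
  }
  vidx <- which(rec$signal_valid)
  vt <- rec$time_s[vidx]
  before <- vapply(runs$start_s, function(t) {
    k <- vidx[vt < t - 1e-9]
    if (length(k)) rec$spo2[k[length(k)]] else NA_real_
  }, numeric(1))
  after <- vapply(runs$end_s, function(t) {
    k <- vidx[vt >= t - 1e-9]
    if (length(k)) rec$spo2[k[1L]] else NA_real_
  }, numeric(1))
  runs$spo2_before <- before
  runs$spo2_after <- after
  runs$post_sl_class <- ifelse(is.na(after), "UNDEFINED",
                               classify_post_sl(after, cfg))
  runs
}

#' Attach signal-loss periods to a prolonged hypoxemic episode
#'
#' Signal-loss periods with positive overlap with the episode are clipped to
#' its half-open interval; the episode's SL count, absolute SL time and
#' relative SL time (percent of episode duration) are filled in.
#'
#' @param sl data frame from [detect_signal_loss()].
#' @param phe one-row data frame from [classify_prolonged()].
#' @return the updated episode row, with the clipped SL periods in
#'   `attr(, "sl_periods")`.
#' @export
assign_sl_to_episode <- function(sl, phe) {
  if (nrow(sl)) {
    a <- pmax(sl$start_s, phe$start_s)
    b <- pmin(sl$end_s, phe$end_s)
    keep <- b - a > 1e-9
    clipped <- sl[keep, , drop = FALSE]
    if (any(keep)) {
      clipped$start_s <- a[keep]
      clipped$end_s <- b[keep]
      clipped$duration_s <- clipped$end_s - clipped$start_s
    }
  } else clipped <- sl
  phe$sl_count <- nrow(clipped)
  phe$sl_time_s <- sum(clipped$duration_s)
  phe$sl_relative_pct <- 100 * phe$sl_time_s / phe$duration_s
  attr(phe, "sl_periods") <- clipped
  phe
}

#' Detect a hyperoxemic overshoot after episode recovery
#'
#' Searches the half-open window of `overshoot_window_s` seconds starting at
#' the episode end for the first run of consecutive valid samples at or above
#' `hyperox_pct` whose onset lies inside the window and whose duration, after
#' clipping the run to the window, reaches `overshoot_min_s`.
#'
#' @param rec a [recording()] object.
#' @param phe a recovered episode row (from [classify_prolonged()]).
#' @param cfg a [detection_config()].
#' @return a one-row data frame (`onset_s`, `duration_s`,
#'   `delay_after_recovery_s`, `relative_duration_pct`) or `NULL`.
#' @export
detect_overshoot <- function(rec, phe, cfg = detection_config()) {
  t_r <- phe$end_s
  w_end <- t_r + cfg$overshoot_window_s
  runs <- find_runs(rec$signal_valid & !is.na(rec$spo2) &
                      rec$spo2 >= cfg$hyperox_pct,
                    min_duration_s = rec$sample_interval_s,
                    sample_interval_s = rec$sample_interval_s,
                    t0 = rec$time_s[1L])
  if (!nrow(runs)) return(NULL)
  runs <- runs[runs$start_s >= t_r - 1e-9 & runs$start_s < w_end - 1e-9, ,
               drop = FALSE]
  if (!nrow(runs)) return(NULL)
  runs$end_s <- pmin(runs$end_s, w_end)
  runs$duration_s <- runs$end_s - runs$start_s
  ok <- which(runs$duration_s >= cfg$overshoot_min_s - 1e-9)
  if (!length(ok)) return(NULL)
  r <- runs[ok[1L], ]
  data.frame(onset_s = r$start_s, duration_s = r$duration_s,
             delay_after_recovery_s = r$start_s - t_r,
             relative_duration_pct = 100 * r$duration_s /
               cfg$overshoot_window_s)
}

#' Full event detection on one recording
#'
#' Runs the whole detection chain: candidate episodes, prolonged-episode
#' classification, signal-loss periods (with episode assignment and clipping)
#' and post-recovery overshoots.
#'
#' @param rec a [recording()] object.
#' @param cfg a [detection_config()].
#' @param min_sl_s minimum signal-loss duration, seconds.
#' @return an object of class `phe_detection`: a list with
#'   \describe{
#'     \item{episodes}{per-pHE metric table (one row per prolonged episode)}
#'     \item{sl_periods}{all signal-loss periods, with `phe_id` linking each
#'       period to the episode it overlaps (`NA` outside episodes)}
#'     \item{candidates}{all candidate desaturation episodes}
#'     \item{n_censored}{episodes unrecovered at the end of the recording}
#'   }
#' @examples
#' spo2 <- c(rep(93, 10), rep(85, 10), rep(78, 40), rep(86, 10), rep(92, 20))
#' rec <- recording(time_s = seq_along(spo2) - 1, spo2 = spo2,
#'                  signal_valid = rep(TRUE, length(spo2)))
#' det <- detect_events(rec)
#' det$episodes[, c("start_s", "end_s", "time_below80_s")]
#' @export
detect_events <- function(rec, cfg = detection_config(),
                          min_sl_s = rec$sample_interval_s) {
  cand <- detect_candidate_episodes(rec, cfg)
  sl <- detect_signal_loss(rec, min_sl_s, cfg)
  sl$phe_id <- rep(NA_integer_, nrow(sl))
  sl$in_phe <- rep(FALSE, nrow(sl))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    phe <- classify_prolonged(cand[i, ], rec, cfg)
    if (is.null(phe)) next
    k <- k + 1L
    phe <- assign_sl_to_episode(sl, phe)
    clipped <- attr(phe, "sl_periods")
    if (nrow(clipped)) {
      ov <- pmin(sl$end_s, phe$end_s) - pmax(sl$start_s, phe$start_s) > 1e-9
      sl$phe_id[ov] <- k
      sl$in_phe[ov] <- TRUE
    }
    os <- detect_overshoot(rec, phe, cfg)
    if (!is.null(os)) {
      phe$overshoot <- TRUE
      phe$overshoot_delay_s <- os$delay_after_recovery_s
      phe$overshoot_duration_s <- os$duration_s
      phe$overshoot_relative_pct <- os$relative_duration_pct
    }
    phe$phe_id <- k
    rows[[k]] <- phe
  }
  episodes <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(episodes))
    episodes <- data.frame(start_s = numeric(0), end_s = numeric(0),
                           duration_s = numeric(0),
                           time_below80_s = numeric(0), sl_count = integer(0),
                           sl_time_s = numeric(0),
                           sl_relative_pct = numeric(0),
                           overshoot = logical(0),
                           overshoot_delay_s = numeric(0),
                           overshoot_duration_s = numeric(0),
                           overshoot_relative_pct = numeric(0),
                           phe_id = integer(0))
  episodes$patient_id <- rep(rec$patient_id, nrow(episodes))
  episodes$avg_mode <- rep(rec$averaging_mode, nrow(episodes))
  structure(list(episodes = episodes, sl_periods = sl, candidates = cand,
                 n_censored = sum(cand$censored),
                 patient_id = rec$patient_id,
                 averaging_mode = rec$averaging_mode, config = cfg),
            class = "phe_detection")
}

#' @export
print.phe_detection <- function(x, ...) {
  cat(sprintf("<phe_detection> patient %s (%s)\n", x$patient_id,
              x$averaging_mode))
  cat(sprintf("  %d candidate episodes, %d prolonged hypoxemic episodes (%d censored)\n",
              nrow(x$candidates), nrow(x$episodes), x$n_censored))
  cat(sprintf("  %d signal-loss periods (%d inside pHEs), %d overshoots\n",
              nrow(x$sl_periods), sum(x$sl_periods$in_phe),
              sum(x$episodes$overshoot)))
  invisible(x)
}

#' Episode table CSV export
#'
#' Writes the per-episode metric table with the canonical column set
#' `patient_id,avg_mode,phe_start_s,phe_end_s,duration_s,time_below80_s,`
#' `sl_count,sl_time_s,sl_relative_pct,overshoot,overshoot_delay_s,`
#' `overshoot_duration_s`.
#'
#' @param episodes episode data frame (rows of `phe_detection$episodes`,
#'   possibly concatenated over recordings).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_episode_csv <- function(episodes, path) {
  out <- data.frame(patient_id = episodes$patient_id,
                    avg_mode = episodes$avg_mode,
                    phe_start_s = episodes$start_s,
                    phe_end_s = episodes$end_s,
                    duration_s = episodes$duration_s,
                    time_below80_s = episodes$time_below80_s,
                    sl_count = episodes$sl_count,
                    sl_time_s = episodes$sl_time_s,
                    sl_relative_pct = episodes$sl_relative_pct,
                    overshoot = as.integer(episodes$overshoot),
                    overshoot_delay_s = episodes$overshoot_delay_s,
                    overshoot_duration_s = episodes$overshoot_duration_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an episode table written by [write_episode_csv()]
#'
#' @param path CSV path.
#' @return data frame in the internal episode-table layout.
#' @export
read_episode_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(patient_id = as.character(df$patient_id),
             avg_mode = df$avg_mode,
             start_s = df$phe_start_s, end_s = df$phe_end_s,
             duration_s = df$duration_s,
             time_below80_s = df$time_below80_s,
             sl_count = df$sl_count, sl_time_s = df$sl_time_s,
             sl_relative_pct = df$sl_relative_pct,
             overshoot = df$overshoot == 1L,
             overshoot_delay_s = df$overshoot_delay_s,
             overshoot_duration_s = df$overshoot_duration_s)
}
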