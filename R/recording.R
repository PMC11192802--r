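#' Single-infant SpO2/FiO2 recording
#'
#' Container for one pulse-oximetry recording under one oximeter averaging
#' mode: a uniformly sampled series of SpO2 (percent), a signal-validity flag,
#' and the set FiO2 fraction. Signal loss (SL) — low signal quality or missing
#' SpO2 values — is encoded by `signal_valid = FALSE`; a missing SpO2 value
#' (`NA`) always implies an invalid sample, while an invalid sample may still
#' carry the last displayed SpO2 value.
#'
#' @param time_s numeric vector of sample times in seconds, strictly
#'   increasing, uniformly spaced.
#' @param spo2 numeric vector of SpO2 in percent (0-100), `NA` for absent.
#' @param signal_valid logical vector, `FALSE` during signal loss.
#' @param fio2_set numeric vector of set FiO2 fractions (0.21-1.0), `NA`
#'   allowed.
#' @param patient_id opaque identifier string.
#' @param averaging_mode `"AVG_2S"` or `"AVG_8S"` (the oximeter's internal
#'   SpO2 averaging time).
#' @param sample_interval_s sampling interval in seconds (default 1).
#'
#' @return an object of class `satloss_recording`: a list with the fields
#'   above, time grid validated.
#' @examples
#' rec <- recording(time_s = 0:9, spo2 = rep(93, 10),
#'                  signal_valid = rep(TRUE, 10), fio2_set = rep(0.25, 10))
#' print(rec)
#' @export
recording <- function(time_s, spo2, signal_valid,
                      fio2_set = rep(NA_real_, length(time_s)),
                      patient_id = "anon",
                      averaging_mode = c("AVG_2S", "AVG_8S"),
                      sample_interval_s = NULL) {
  averaging_mode <- match.arg(averaging_mode)
  n <- length(time_s)
  if (n == 0L) stop("empty recording")
  if (length(spo2) != n || length(signal_valid) != n || length(fio2_set) != n)
    stop("channel lengths differ from time_s")
  dt <- if (is.null(sample_interval_s)) {
    if (n >= 2L) time_s[2L] - time_s[1L] else 1
  } else sample_interval_s
  if (!is.finite(dt) || dt <= 0) stop("sample_interval_s must be positive")
  if (n >= 2L) {
    d <- diff(time_s)
    bad <- which(d <= 0)
    if (length(bad)) stop(sprintf("non-monotonic time at row %d", bad[1L] + 1L))
    if (any(abs(d - dt) > 1e-9))
      stop("time grid is not uniformly spaced at sample_interval_s")
  }
  bad <- which(!is.na(spo2) & (spo2 < 0 | spo2 > 100))
  if (length(bad)) stop(sprintf("spo2 out of [0,100] at row %d", bad[1L]))
  bad <- which(!is.na(fio2_set) & (fio2_set < 0.21 - 1e-9 | fio2_set > 1 + 1e-9))
  if (length(bad)) stop(sprintf("fio2_set out of [0.21,1] at row %d", bad[1L]))
  signal_valid <- as.logical(signal_valid)
  if (anyNA(signal_valid)) stop("signal_valid must be TRUE/FALSE")
  # absent SpO2 forces invalidity
  signal_valid[is.na(spo2)] <- FALSE
  structure(list(patient_id = as.character(patient_id),
                 averaging_mode = averaging_mode,
                 sample_interval_s = dt,
                 time_s = as.numeric(time_s),
                 spo2 = as.numeric(spo2),
                 signal_valid = signal_valid,
                 fio2_set = as.numeric(fio2_set)),
            class = "satloss_recording")
}

#' @export
print.satloss_recording <- function(x, ...) {
  dur <- length(x$time_s) * x$sample_interval_s
  cat(sprintf("<satloss_recording> patient %s, mode %s\n",
              x$patient_id, x$averaging_mode))
  cat(sprintf("  %d samples @ %g s (%.2f h), signal loss %.1f%% of time\n",
              length(x$time_s), x$sample_interval_s, dur / 3600,
              100 * mean(!x$signal_valid)))
  invisible(x)
}

#' @export
summary.satloss_recording <- function(object, ...) {
  v <- object$signal_valid
  s <- object$spo2[v]
  out <- list(patient_id = object$patient_id,
              averaging_mode = object$averaging_mode,
              n = length(object$time_s),
              duration_s = length(object$time_s) * object$sample_interval_s,
              sl_fraction = mean(!v),
              spo2_median = stats::median(s),
              spo2_range = range(s))
  class(out) <- "summary.satloss_recording"
  out
}

#' @export
print.summary.satloss_recording <- function(x, ...) {
  cat(sprintf("Recording %s (%s): %.2f h, SL %.1f%%, SpO2 median %.1f%% (range %.0f-%.0f)\n",
              x$patient_id, x$averaging_mode, x$duration_s / 3600,
              100 * x$sl_fraction, x$spo2_median,
              x$spo2_range[1], x$spo2_range[2]))
  invisible(x)
}

# canonical CSV header, bit-exact
.rec_header <- c("time_s", "spo2", "signal_ok", "fio2_set")

#' Read a recording from CSV
#'
#' Expects the schema `time_s,spo2,signal_ok,fio2_set` (UTF-8, LF). An empty
#' `spo2` field becomes an absent value with `signal_valid` forced `FALSE`;
#' a row with `signal_ok = 0` keeps its SpO2 value but is marked invalid.
#'
#' @param path CSV file path.
#' @param averaging_mode averaging-mode tag to attach (`"AVG_2S"`/`"AVG_8S"`).
#' @param patient_id identifier to attach (default: file name sans extension).
#' @return a [recording()] object.
#' @export
read_recording_csv <- function(path, averaging_mode = c("AVG_2S", "AVG_8S"),
                               patient_id = NULL) {
  averaging_mode <- match.arg(averaging_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, .rec_header))
    stop("malformed header: expected ", paste(.rec_header, collapse = ","))
  df <- utils::read.csv(path, colClasses = c("numeric", "character",
                                             "integer", "character"))
  if (nrow(df) == 0L) stop("empty recording")
  spo2 <- suppressWarnings(as.numeric(df$spo2))
  absent <- df$spo2 == "" | is.na(df$spo2)
  spo2[absent] <- NA_real_
  valid <- df$signal_ok == 1L & !absent
  fio2 <- suppressWarnings(as.numeric(df$fio2_set))
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  recording(time_s = df$time_s, spo2 = spo2, signal_valid = valid,
            fio2_set = fio2, patient_id = patient_id,
            averaging_mode = averaging_mode)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording_csv()]: writing then reading reproduces the
#' recording field-for-field. Absent SpO2 is written as an empty field with
#' `signal_ok = 0`.
#'
#' @param rec a [recording()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "satloss_recording"))
  if (length(rec$time_s) == 0L) stop("empty recording")
  num <- function(x) vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 12, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  lines <- c(paste(.rec_header, collapse = ","),
             paste(num(rec$time_s), num(rec$spo2),
                   as.integer(rec$signal_valid), num(rec$fio2_set),
                   sep = ","))
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Emulate oximeter SpO2 averaging with a trailing moving average
#'
#' Each output SpO2 is the mean of the *valid* SpO2 values in the trailing
#' (causal) window of length `window_s` ending at the sample; a sample with no
#' valid value anywhere in its window becomes absent/invalid. Input validity
#' flags are otherwise preserved, so signal-loss periods stay signal loss.
#'
#' @param rec a [recording()] object.
#' @param window_s averaging window in seconds, at least one sample interval.
#' @return a new [recording()] object.
#' @export
apply_moving_average <- function(rec, window_s) {
  stopifnot(inherits(rec, "satloss_recording"))
  dt <- rec$sample_interval_s
  if (window_s < dt - 1e-9) stop("window_s must be >= sample_interval_s")
  k <- max(1L, as.integer(round(window_s / dt)))
  v <- ifelse(rec$signal_valid & !is.na(rec$spo2), rec$spo2, NA_real_)
  ok <- !is.na(v)
  cs <- cumsum(ifelse(ok, v, 0))
  cn <- cumsum(ok)
  n <- length(v)
  if (k >= n) {
    lag <- rep(0, n); lagn <- rep(0L, n)
  } else {
    lag <- c(rep(0, k), cs[seq_len(n - k)])
    lagn <- c(rep(0L, k), cn[seq_len(n - k)])
  }
  cnt <- cn - lagn
  m <- ifelse(cnt > 0L, (cs - lag) / cnt, NA_real_)
  recording(time_s = rec$time_s, spo2 = m,
            signal_valid = rec$signal_valid & cnt > 0L,
            fio2_set = rec$fio2_set, patient_id = rec$patient_id,
            averaging_mode = rec$averaging_mode,
            sample_interval_s = dt)
}
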