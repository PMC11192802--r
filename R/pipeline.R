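#' Read and validate a pipeline configuration file
#'
#' One YAML file with up to four blocks: `seed` (integer), `cohort`
#' (arguments of [cohort_spec()]), `detection` (arguments of
#' [detection_config()]) and `controller` (arguments of
#' [controller_config()]). Unknown keys are rejected by name. Missing blocks
#' fall back to the package defaults.
#'
#' @param path YAML file path (`NULL` for all defaults).
#' @return a list with `spec`, `detection`, `controller`, `seed`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cf <- if (is.null(path)) list() else yaml::read_yaml(path)
  check <- function(block, fn, name) {
    if (is.null(block)) return(list())
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad))
      stop(sprintf("invalid config key(s) in '%s': %s", name,
                   paste(bad, collapse = ", ")))
    block
  }
  det <- do.call(detection_config, check(cf$detection, detection_config,
                                         "detection"))
  ctl <- do.call(controller_config, check(cf$controller, controller_config,
                                          "controller"))
  coh <- check(cf$cohort, cohort_spec, "cohort")
  coh$controller <- ctl
  if (!is.null(cf$seed)) {
    if (!is.numeric(cf$seed) || cf$seed != round(cf$seed))
      stop("invalid config key(s) in 'seed': must be an integer")
    coh$rng_seed <- as.integer(cf$seed)
  }
  spec <- do.call(cohort_spec, coh)
  list(spec = spec, detection = det, controller = ctl, seed = spec$rng_seed)
}

#' Simulate a synthetic cohort to disk
#'
#' @param config a config list from [read_pipeline_config()] (or `NULL` for
#'   defaults).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  if (is.null(config)) config <- read_pipeline_config(NULL)
  res <- generate_cohort(config$spec, dir = out_dir)
  n_ep <- sum(vapply(res, function(x) nrow(x$truth$episodes), numeric(1)))
  message(sprintf("simulated %d recordings, %d planted episodes -> %s",
                  length(res), n_ep, out_dir))
  invisible(attr(res, "manifest"))
}

#' Detect events across a simulated or recorded cohort
#'
#' Reads every recording named in the manifest, runs [detect_events()], and
#' writes one combined episode table (and SL-period table). Unreadable
#' recordings are skipped with an error log line.
#'
#' @param manifest_path manifest CSV (`patient_id,avg_mode,csv_path,...`).
#' @param config config list from [read_pipeline_config()] (or `NULL`).
#' @param out_episodes output episode-table CSV path.
#' @param out_sl optional output SL-period CSV path.
#' @return invisibly, a list with `episodes`, `sl_periods` and `n_failed`.
#' @export
run_detect <- function(manifest_path, config = NULL, out_episodes,
                       out_sl = NULL) {
  if (is.null(config)) config <- read_pipeline_config(NULL)
  man <- utils::read.csv(manifest_path)
  base <- dirname(manifest_path)
  eps <- list(); sls <- list(); failed <- 0L
  for (i in seq_len(nrow(man))) {
    path <- file.path(base, man$csv_path[i])
    rec <- tryCatch(read_recording_csv(path, man$avg_mode[i],
                                       man$patient_id[i]),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      message(sprintf("ERROR %s: %s", path, conditionMessage(rec)))
      failed <- failed + 1L
      next
    }
    det <- detect_events(rec, config$detection)
    message(sprintf("%s: %d pHEs, %d SL periods, %d overshoots",
                    man$patient_id[i], nrow(det$episodes),
                    nrow(det$sl_periods), sum(det$episodes$overshoot)))
    eps[[i]] <- det$episodes
    if (nrow(det$sl_periods)) {
      sl <- det$sl_periods
      sl$patient_id <- man$patient_id[i]
      sls[[i]] <- sl
    }
  }
  episodes <- do.call(rbind, Filter(Negate(is.null), eps))
  if (is.null(episodes)) {
    warning("no episodes detected in cohort")
    episodes <- detect_events(recording(0, 93, TRUE))$episodes
  }
  sl_periods <- do.call(rbind, Filter(Negate(is.null), sls))
  write_episode_csv(episodes, out_episodes)
  if (!is.null(out_sl) && !is.null(sl_periods))
    utils::write.csv(sl_periods, out_sl, row.names = FALSE, na = "")
  invisible(list(episodes = episodes, sl_periods = sl_periods,
                 n_failed = failed))
}

#' Summarize and compare a detected cohort, with episode figures
#'
#' Writes the cohort summary (formatted text and CSV), the group-comparison
#' CSV (`variable,test,p_value`), and, when the recordings are available,
#' per-episode figures showing the SpO2 trace (dotted), the set FiO2 trace
#' (solid black, right axis), hatched signal-loss boxes, and threshold lines
#' at 80/90/95/97%.
#'
#' @param episodes episode table (data frame or path to a CSV written by
#'   [write_episode_csv()]).
#' @param out_dir output directory.
#' @param sl_periods optional SL-period table (or CSV path).
#' @param recordings_dir optional directory with the recording CSVs and
#'   manifest, enabling figure export.
#' @param max_figures cap on the number of episode figures.
#' @param cfg a [detection_config()].
#' @return invisibly, the `phe_summary`.
#' @export
run_report <- function(episodes, out_dir, sl_periods = NULL,
                       recordings_dir = NULL, max_figures = 4,
                       cfg = detection_config()) {
  if (is.character(episodes)) episodes <- read_episode_csv(episodes)
  if (is.character(sl_periods)) sl_periods <- utils::read.csv(sl_periods)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  smry <- build_table1(episodes, sl_periods, cfg = cfg)
  write_summary_csv(smry, file.path(out_dir, "summary.csv"))
  txt <- utils::capture.output(print(smry))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  cmp <- attr(smry, "comparisons")
  if (!is.null(cmp))
    utils::write.csv(data.frame(variable = cmp$variable, test = cmp$test,
                                p_value = cmp$p),
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(recordings_dir) && nrow(episodes)) {
    man <- utils::read.csv(file.path(recordings_dir, "manifest.csv"))
    k <- 0L
    for (i in seq_len(nrow(episodes))) {
      if (k >= max_figures) break
      pid <- episodes$patient_id[i]
      j <- match(pid, man$patient_id)
      if (is.na(j)) next
      rec <- read_recording_csv(file.path(recordings_dir, man$csv_path[j]),
                                man$avg_mode[j], pid)
      k <- k + 1L
      fn <- file.path(out_dir, sprintf("episode_%03d_%s.png", k, pid))
      grDevices::png(fn, width = 900, height = 500)
      plot_episode(rec, episodes[i, ], cfg = cfg)
      grDevices::dev.off()
    }
  }
  message(sprintf("report written to %s (%d episodes)", out_dir,
                  nrow(episodes)))
  invisible(smry)
}

#' Plot one prolonged hypoxemic episode
#'
#' SpO2 as a dotted line (left axis), set FiO2 as a solid black line (right
#' axis), signal-loss periods as hatched boxes, and horizontal threshold
#' lines at the hypoxemia (80%), target (90-95%) and hyperoxemia (97%)
#' levels.
#'
#' @param rec the source [recording()].
#' @param episode one episode row (needs `start_s`, `end_s`).
#' @param pad_s context to show on either side of the episode, seconds.
#' @param cfg a [detection_config()].
#' @return invisibly, `NULL`.
#' @export
plot_episode <- function(rec, episode, pad_s = 120,
                         cfg = detection_config()) {
  t0 <- max(rec$time_s[1L], episode$start_s - pad_s)
  t1 <- min(rec$time_s[length(rec$time_s)], episode$end_s + pad_s)
  sel <- rec$time_s >= t0 & rec$time_s <= t1
  tt <- rec$time_s[sel]
  ss <- rec$spo2[sel]
  ss[!rec$signal_valid[sel]] <- NA
  op <- graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(graphics::par(op))
  graphics::plot(tt, ss, type = "l", lty = 3, ylim = c(60, 100),
                 xlab = "time (s)", ylab = "SpO2 (%)",
                 main = sprintf("pHE %s [%g, %g) s", rec$patient_id,
                                episode$start_s, episode$end_s))
  sl <- detect_signal_loss(rec, cfg = cfg)
  sl <- sl[sl$end_s > t0 & sl$start_s < t1, , drop = FALSE]
  if (nrow(sl))
    graphics::rect(pmax(sl$start_s, t0), 60, pmin(sl$end_s, t1), 100,
                   density = 12, col = "grey40", border = "grey40")
  graphics::abline(h = c(cfg$hypox_pct, cfg$target_lower_pct,
                         cfg$target_upper_pct, cfg$hyperox_pct),
                   lty = c(2, 1, 1, 2),
                   col = c("red3", "grey60", "grey60", "orange3"))
  graphics::par(new = TRUE)
  graphics::plot(tt, rec$fio2_set[sel], type = "l", lwd = 2, axes = FALSE,
                 xlab = "", ylab = "", ylim = c(0.2, 1))
  graphics::axis(4)
  graphics::mtext("set FiO2", side = 4, line = 3)
  invisible(NULL)
}
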