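# format helpers for the cohort summary ------------------------------------

.fmt_miq <- function(values, digits = 0) {
  if (!length(values) || all(is.na(values))) return("-")
  m <- median_iqr(values)
  sprintf("%s (%s to %s)", round(m[1L], digits), round(m[2L], digits),
          round(m[3L], digits))
}

.fmt_npct <- function(count, total) {
  if (total <= 0) return("-")
  sprintf("%d (%d%%)", count, percent(count, total))
}

#' Build the cohort summary of prolonged hypoxemic episodes
#'
#' Aggregates a per-episode table into the standard clinical summary layout:
#' episode counts and percentages by signal-loss (SL) group and averaging
#' mode, episode durations and hypoxemic times as median (q1 to q3) with a
#' Mann-Whitney U comparison between SL groups, SL-period characteristics,
#' and post-recovery overshoot characteristics. Patient-level tallies
#' (participants with at least one pHE / one SL-containing pHE) and the
#' classification of SpO2 at SL end against the target range are included
#' when the data allow.
#'
#' @param episodes episode table: rows of `phe_detection$episodes` (possibly
#'   concatenated across recordings), or the result of [read_episode_csv()].
#' @param sl_periods optional SL-period table (rows of
#'   `phe_detection$sl_periods`) providing SpO2 at SL start/end and the
#'   post-SL classification; only periods inside pHEs (`in_phe`) are used.
#' @param n_participants optional number of recorded participants (defaults
#'   to the number of distinct `patient_id`s in `episodes`).
#' @param cfg a [detection_config()] (target range for post-SL
#'   classification).
#' @return an object of class `phe_summary`: a data frame of labeled rows
#'   (`section`, `variable`, `sl`, `no_sl`, `p`, `test`) with the group
#'   comparison results of [compare_sl_groups()] as `attr(, "comparisons")`.
#' @export
build_table1 <- function(episodes, sl_periods = NULL, n_participants = NULL,
                         cfg = detection_config()) {
  req <- c("patient_id", "avg_mode", "duration_s", "time_below80_s",
           "sl_count", "sl_time_s", "sl_relative_pct", "overshoot",
           "overshoot_delay_s", "overshoot_duration_s")
  miss <- setdiff(req, names(episodes))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  grp <- ifelse(episodes$sl_count >= 1L, "SL", "NO_SL")
  A <- episodes[grp == "SL", , drop = FALSE]
  B <- episodes[grp == "NO_SL", , drop = FALSE]
  n_all <- nrow(episodes)
  if (is.null(n_participants))
    n_participants <- length(unique(episodes$patient_id))

  both <- nrow(A) > 0 && nrow(B) > 0
  cmp <- if (both) compare_sl_groups(episodes) else NULL
  if (!both && n_all > 0)
    warning("one SL group is empty; group comparisons suppressed")
  pval <- function(var) {
    if (is.null(cmp)) return(NA_real_)
    i <- match(var, cmp$variable)
    if (is.na(i)) NA_real_ else cmp$p[i]
  }
  tst <- function(var) {
    if (is.null(cmp)) return(NA_character_)
    i <- match(var, cmp$variable)
    if (is.na(i)) NA_character_ else cmp$test[i]
  }

  per_patient <- function(df) {
    if (!nrow(df)) return(numeric(0))
    as.numeric(table(df$patient_id))
  }
  row <- function(section, variable, sl, no_sl = "-", p = NA_real_,
                  test = NA_character_)
    data.frame(section = section, variable = variable, sl = sl,
               no_sl = no_sl, p = p, test = test)

  rows <- list(
    row("Frequency", "Number of pHE",
        .fmt_npct(nrow(A), max(n_all, 1L)), .fmt_npct(nrow(B), max(n_all, 1L))),
    row("Frequency", "Number of pHE per patient",
        .fmt_miq(per_patient(A)), .fmt_miq(per_patient(B))),
    row("Frequency", "Number of pHE under 2 s averaging",
        if (nrow(A)) .fmt_npct(sum(A$avg_mode == "AVG_2S"), nrow(A)) else "-",
        if (nrow(B)) .fmt_npct(sum(B$avg_mode == "AVG_2S"), nrow(B)) else "-",
        pval("sl_occurrence_by_avg_mode"), tst("sl_occurrence_by_avg_mode")),
    row("Frequency", "Number of pHE under 8 s averaging",
        if (nrow(A)) .fmt_npct(sum(A$avg_mode == "AVG_8S"), nrow(A)) else "-",
        if (nrow(B)) .fmt_npct(sum(B$avg_mode == "AVG_8S"), nrow(B)) else "-"),
    row("Duration (s)", "Total pHE duration (s)",
        .fmt_miq(A$duration_s), .fmt_miq(B$duration_s),
        pval("duration_s"), tst("duration_s")),
    row("Duration (s)", "Time with SpO2 < 80% (s)",
        .fmt_miq(A$time_below80_s), .fmt_miq(B$time_below80_s),
        pval("time_below80_s"), tst("time_below80_s")),
    row("Signal loss", "Number of SL periods",
        sprintf("%d (100%%)", sum(A$sl_count)), "N.A."),
    row("Signal loss", "Number of SL periods per pHE", .fmt_miq(A$sl_count)),
    row("Signal loss", "Absolute time per pHE (s)", .fmt_miq(A$sl_time_s)),
    row("Signal loss", "Relative time per pHE (%time)",
        .fmt_miq(A$sl_relative_pct)),
    row("Overshoots", "Number of periods",
        if (nrow(A)) .fmt_npct(sum(A$overshoot), nrow(A)) else "-",
        if (nrow(B)) .fmt_npct(sum(B$overshoot), nrow(B)) else "-",
        pval("overshoot_occurrence"), tst("overshoot_occurrence")),
    row("Overshoots", "Absolute duration (s)",
        .fmt_miq(A$overshoot_duration_s[A$overshoot]),
        .fmt_miq(B$overshoot_duration_s[B$overshoot]),
        pval("overshoot_duration_s"), tst("overshoot_duration_s")),
    row("Overshoots", "Relative duration (% of 120 s)",
        .fmt_miq(100 * A$overshoot_duration_s[A$overshoot] /
                   cfg$overshoot_window_s),
        .fmt_miq(100 * B$overshoot_duration_s[B$overshoot] /
                   cfg$overshoot_window_s)),
    row("Overshoots", "Delay after recovery (s)",
        .fmt_miq(A$overshoot_delay_s[A$overshoot]),
        .fmt_miq(B$overshoot_delay_s[B$overshoot]))
  )

  if (!is.null(sl_periods) && nrow(sl_periods)) {
    slp <- sl_periods[isTRUE_vec(sl_periods$in_phe), , drop = FALSE]
    rows <- append(rows, list(
      row("Signal loss", "SpO2 at SL start (%)", .fmt_miq(slp$spo2_before)),
      row("Signal loss", "SpO2 at SL end (%)", .fmt_miq(slp$spo2_after))),
      after = 10L)
    cls <- slp$post_sl_class[!is.na(slp$spo2_after)]
    nc <- length(cls)
    if (nc > 0) rows <- append(rows, list(
      row("Post-SL SpO2 vs target", "Below target",
          .fmt_npct(sum(cls == "BELOW"), nc)),
      row("Post-SL SpO2 vs target", "Within target",
          .fmt_npct(sum(cls == "WITHIN"), nc)),
      row("Post-SL SpO2 vs target", "Above target",
          .fmt_npct(sum(cls == "ABOVE"), nc))))
  }

  pat_sl <- unique(A$patient_id)
  rows <- append(rows, list(
    row("Participants", "Participants with >= 1 pHE",
        .fmt_npct(length(unique(episodes$patient_id)),
                  max(n_participants, 1L))),
    row("Participants", "Participants with >= 1 SL-pHE",
        .fmt_npct(length(pat_sl), max(n_participants, 1L)))))

  out <- do.call(rbind, rows)
  attr(out, "comparisons") <- cmp
  attr(out, "n_episodes") <- n_all
  attr(out, "n_participants") <- n_participants
  class(out) <- c("phe_summary", "data.frame")
  out
}

# vectorized isTRUE over logicals with NA
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.phe_summary <- function(x, ...) {
  cat(sprintf("Prolonged hypoxemic episodes with and without signal loss (n = %d episodes, %d participants)\n",
              attr(x, "n_episodes"), attr(x, "n_participants")))
  cat(sprintf("%-34s %-22s %-22s %s\n", "Variable", "SL", "No SL", "p"))
  sec <- ""
  for (i in seq_len(nrow(x))) {
    if (!identical(sec, x$section[i])) {
      sec <- x$section[i]
      cat(sec, "\n")
    }
    p <- if (is.na(x$p[i])) "" else formatC(x$p[i], digits = 3, format = "g")
    cat(sprintf("  %-32s %-22s %-22s %s\n", x$variable[i], x$sl[i],
                x$no_sl[i], p))
  }
  invisible(x)
}

#' Write a cohort summary as CSV
#'
#' @param x a `phe_summary` from [build_table1()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Nonparametric comparisons between SL and no-SL episodes
#'
#' Applies the Mann-Whitney U test to the duration variables (episode
#' duration, hypoxemic time, overshoot duration and delay) and the
#' chi-squared / Fisher rule to the 2x2 count tables (overshoot occurrence by
#' SL group; SL occurrence by averaging mode).
#'
#' @param episodes episode table (as in [build_table1()]).
#' @return data frame with `variable`, `test`, `statistic`, `p`.
#' @export
compare_sl_groups <- function(episodes) {
  grp <- ifelse(episodes$sl_count >= 1L, "SL", "NO_SL")
  A <- episodes[grp == "SL", , drop = FALSE]
  B <- episodes[grp == "NO_SL", , drop = FALSE]
  if (!nrow(A) || !nrow(B)) {
    warning("a group is empty; comparisons suppressed")
    return(data.frame(variable = character(0), test = character(0),
                      statistic = numeric(0), p = numeric(0)))
  }
  out <- list()
  mw <- function(variable, xa, xb) {
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (!length(xa) || !length(xb)) return(NULL)
    r <- mann_whitney_u(xa, xb)
    data.frame(variable = variable, test = "mann-whitney", statistic = r$U,
               p = r$p)
  }
  out$dur <- mw("duration_s", A$duration_s, B$duration_s)
  out$t80 <- mw("time_below80_s", A$time_below80_s, B$time_below80_s)
  out$osd <- mw("overshoot_duration_s",
                A$overshoot_duration_s[A$overshoot],
                B$overshoot_duration_s[B$overshoot])
  out$osl <- mw("overshoot_delay_s",
                A$overshoot_delay_s[A$overshoot],
                B$overshoot_delay_s[B$overshoot])
  ct <- function(variable, tab) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    r <- chi_square_or_fisher(tab)
    data.frame(variable = variable, test = r$test,
               statistic = if (is.na(r$statistic)) NA_real_ else r$statistic,
               p = r$p)
  }
  out$os <- ct("overshoot_occurrence",
               matrix(c(sum(A$overshoot), sum(B$overshoot),
                        sum(!A$overshoot), sum(!B$overshoot)), 2L))
  out$avg <- ct("sl_occurrence_by_avg_mode",
                matrix(c(sum(A$avg_mode == "AVG_2S"),
                         sum(B$avg_mode == "AVG_2S"),
                         sum(A$avg_mode == "AVG_8S"),
                         sum(B$avg_mode == "AVG_8S")), 2L))
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Compare SpO2 before vs after signal loss
#'
#' The unpaired Mann-Whitney U test on the SpO2 values at SL start and SL end
#' across SL periods (the reporting convention of the summary table); a paired
#' Wilcoxon signed-rank alternative is selectable.
#'
#' @param sl_periods SL-period table with `spo2_before`, `spo2_after`
#'   (periods with either undefined are dropped).
#' @param paired use the Wilcoxon signed-rank test instead.
#' @return a list with `p`, `method` and the two medians.
#' @export
compare_sl_spo2 <- function(sl_periods, paired = FALSE) {
  ok <- !is.na(sl_periods$spo2_before) & !is.na(sl_periods$spo2_after)
  a <- sl_periods$spo2_before[ok]
  b <- sl_periods$spo2_after[ok]
  if (!length(a)) stop("no SL periods with defined before/after SpO2")
  if (paired) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    list(p = unname(wt$p.value), method = "wilcoxon signed-rank",
         median_before = stats::median(a), median_after = stats::median(b))
  } else {
    r <- mann_whitney_u(a, b)
    list(p = r$p, method = "mann-whitney",
         median_before = stats::median(a), median_after = stats::median(b))
  }
}
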