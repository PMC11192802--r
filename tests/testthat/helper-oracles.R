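# Independent brute-force reference scanners. These re-derive every detector
# output with plain per-sample loops and explicit window re-checks, sharing no
# code with the package implementation. All work at 1 Hz on index grids
# (sample i covers time [i-1, i)).

oracle_runs <- function(mask, min_len) {
  mask <- !is.na(mask) & mask
  out <- NULL
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

.o_ge <- function(spo2, valid, j, thr) valid[j] && !is.na(spo2[j]) && spo2[j] >= thr
.o_lt <- function(spo2, valid, j, thr) valid[j] && !is.na(spo2[j]) && spo2[j] < thr

# candidate episodes: returns matrix [start_idx, end_idx(excl), censored]
oracle_candidates <- function(spo2, valid, entry = 90, rec_lo = 90,
                              rec_len = 8L) {
  n <- length(spo2)
  out <- NULL
  i <- 1L
  while (i <= n) {
    starts <- .o_lt(spo2, valid, i, entry) &&
      (i == 1L || .o_ge(spo2, valid, i - 1L, entry))
    if (!starts) { i <- i + 1L; next }
    end <- NA_integer_
    j <- i + 1L
    while (j + rec_len - 1L <= n) {
      ok <- TRUE
      for (m in j:(j + rec_len - 1L))
        if (!.o_ge(spo2, valid, m, rec_lo)) { ok <- FALSE; break }
      if (ok) { end <- j; break }
      j <- j + 1L
    }
    if (is.na(end)) {
      out <- rbind(out, c(i, n + 1L, 1L))
      break
    }
    out <- rbind(out, c(i, end, 0L))
    i <- end
  }
  out
}

# cumulative and longest-contiguous valid time below thr inside [i0, i1)
oracle_below <- function(spo2, valid, i0, i1, thr = 80) {
  cum <- 0L; best <- 0L; cur <- 0L
  for (j in i0:(i1 - 1L)) {
    if (.o_lt(spo2, valid, j, thr)) {
      cum <- cum + 1L
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else cur <- 0L
  }
  list(cumulative = cum, contiguous = best)
}

# SL periods: matrix [start, end(excl), spo2_before, spo2_after] (NA at edges)
oracle_sl <- function(spo2, valid, min_len = 1L) {
  n <- length(valid)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (!valid[i]) {
      j <- i
      while (j < n && !valid[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        before <- NA_real_
        for (m in seq_len(i - 1L)) if (valid[m]) before <- spo2[m]
        after <- NA_real_
        if (j < n) for (m in n:(j + 1L)) if (valid[m]) after <- spo2[m]
        out <- rbind(out, c(i, j + 1L, before, after))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# first qualifying overshoot in [t_r, t_r + win): c(onset, clipped_dur) or NULL
oracle_overshoot <- function(spo2, valid, t_r, win = 120L, thr = 97,
                             min_len = 8L) {
  n <- length(spo2)
  hyper <- function(j) j >= 1L && j <= n && .o_ge(spo2, valid, j, thr)
  for (j in t_r:min(n, t_r + win - 1L)) {
    if (hyper(j) && !hyper(j - 1L)) {
      m <- j
      while (hyper(m + 1L)) m <- m + 1L
      dur <- min(m + 1L, t_r + win) - j
      if (dur >= min_len) return(c(j, dur))
    }
  }
  NULL
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2L, function(k) sum(r[k]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(1, p)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
# (point-probability rule)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(v)
    exp(lchoose(m, v) + lchoose(n2, k - v) - lchoose(m + n2, k)), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random 1-Hz test trace with desaturations and dropout runs
random_trace <- function(n, seed) {
  set.seed(seed)
  drift <- stats::rnorm(n, 0, 1.4)
  base <- 93 + cumsum(drift) - cumsum(rep(mean(drift), n))
  spo2 <- pmin(100, pmax(55, base))
  # occasional forced deep desaturations so pHEs actually occur
  k <- max(1L, rpois(1L, n / 900))
  for (i in seq_len(k)) {
    at <- sample.int(n - 120L, 1L)
    d <- sample(40:110, 1L)
    depth <- runif(1, 65, 79)
    spo2[at:(at + d)] <- depth + rnorm(d + 1L, 0, 1.5)
  }
  spo2 <- round(pmin(100, pmax(55, spo2)), 1)
  # markov dropout: ~3% of time in multi-sample invalid runs
  valid <- logical(n)
  state <- TRUE
  for (i in seq_len(n)) {
    state <- if (state) runif(1) > 0.004 else runif(1) < 0.12
    valid[i] <- state
  }
  spo2[!valid & runif(n) < 0.5] <- NA   # half of invalid samples are absent
  list(spo2 = spo2, valid = valid)
}

trace_recording <- function(tr, id = "T") {
  recording(time_s = seq_along(tr$spo2) - 1, spo2 = tr$spo2,
            signal_valid = tr$valid, patient_id = id)
}
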