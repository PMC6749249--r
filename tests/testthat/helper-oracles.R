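# Independent brute-force oracles and small fixture builders.
# The oracles re-derive the detector and the Gi* statistic directly from
# their defining conditions, by explicit scanning/looping, sharing no code
# with the package implementation.

# Brute-force MOS detector over a 1 Hz conductance/temperature pair.
# Returns data.frame(t, ts) of accepted events (t in seconds from start).
oracle_detect <- function(g, st, w = c(30, 25, 15, 15, 15), cs = 75) {
  n <- length(g)
  acc_t <- numeric(0)
  acc_ts <- numeric(0)
  i <- 1
  while (i < n) {
    if (g[i + 1] > g[i]) {
      j <- i
      while (j < n && g[j + 1] > g[j]) j <- j + 1
      run <- j - i
      s1 <- if (run >= 2 && run <= 5) 1 else if (run > 5 && run <= 8) 0.5 else 0
      s3 <- if (run >= 1 && run <= 5) 1 else if (run > 5 && run <= 15) 0.5 else 0
      ang <- atan((g[j] - g[i]) / run) * 180 / pi
      s4 <- if (ang >= 10) 1 else if (ang >= 8) 0.5 else 0
      negrun <- function(o) {
        ix <- i + o
        if (ix + 3 > n) return(NA)
        all(st[ix + 1:3] - st[ix + 0:2] < 0)
      }
      f <- negrun(3)
      s2 <- 0
      if (isTRUE(f)) s2 <- 1
      else if (!is.na(f)) {
        for (o in 2:6) if (isTRUE(negrun(o))) { s2 <- 0.5; break }
      }
      s5 <- if (length(acc_t) == 0 || (i - 1) - max(acc_t) > 10) 1 else 0
      ts <- sum(c(s1, s2, s3, s4, s5) * w)
      if (ts >= cs && s5 == 1) {
        acc_t <- c(acc_t, i - 1)
        acc_ts <- c(acc_ts, ts)
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  data.frame(t = acc_t, ts = acc_ts)
}

# Brute-force Gi* z-scores: direct double loop over the defining formula,
# binary distance band including self, population SD.
oracle_gi_star <- function(x, coords, band) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum((x - xbar)^2) / n)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wij <- numeric(n)
    for (j in seq_len(n)) {
      dij <- sqrt((coords[i, 1] - coords[j, 1])^2 +
                  (coords[i, 2] - coords[j, 2])^2)
      if (dij <= band) wij[j] <- 1
    }
    wi <- sum(wij)
    s1 <- sum(wij^2)
    z[i] <- (sum(wij * x) - wi * xbar) /
      (s * sqrt((n * s1 - wi^2) / (n - 1)))
  }
  z
}

# Wrap bare 1 Hz series into a biogeo_table for direct detector calls.
make_table <- function(g, st, lat = NA_real_, lon = NA_real_) {
  n <- length(g)
  structure(
    data.frame(t = 0:(n - 1), g = g, st = st, phasic = g,
               tonic = rep(0, n), st_band = st, st_smooth = st,
               lat = rep(lat, n)[seq_len(n)], lon = rep(lon, n)[seq_len(n)]),
    class = c("biogeo_table", "data.frame"))
}

# A 1 Hz pair holding one clean canonical response: conductance rising
# delta_g over rise_s seconds from second `onset`, temperature falling for
# drop_s seconds starting at onset + 3.
make_event_pair <- function(n = 60, onset = 20, rise_s = 4, delta_g = 1,
                            drop_s = 4, st_offset = 3) {
  g <- rep(1, n)
  ramp <- seq(0, delta_g, length.out = rise_s + 1)
  g[(onset + 1):(onset + rise_s + 1)] <- 1 + ramp
  g[(onset + rise_s + 2):n] <- 1 + delta_g  # hold peak; no further rise
  st <- rep(33, n)
  d0 <- onset + st_offset
  drop <- seq(0, 0.3, length.out = drop_s + 1)
  st[(d0 + 1):(d0 + drop_s + 1)] <- 33 - drop
  st[(d0 + drop_s + 2):n] <- 33 - 0.3
  list(g = g, st = st)
}

# Low-noise canonical lab-protocol session for recovery checks.
recovery_session <- function(seed, noise = 0) {
  generate_session(session_spec(duration = 900, n_events = 10, seed = seed,
                                noise_sd_gsr = noise, noise_sd_st = noise))
}

quiet_preprocess <- function(gsr, st, geo = NULL, ...) {
  suppressWarnings(suppressMessages(preprocess_session(gsr, st, geo = geo, ...)))
}

quiet_detect <- function(tab, ...) suppressWarnings(detect_mos(tab, ...))
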