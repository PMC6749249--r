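#' Parameters of one synthetic skin-conductance response (SCR)
#'
#' Describes a single phasic event superimposed on the tonic skin-conductance
#' level, using the standard response anatomy: a latency from stimulus to
#' response onset, a rise from onset to peak, and an asymptotic recovery
#' characterised by its half-recovery time. The companion skin-temperature
#' reaction is a drop that begins a few seconds after the conductance rise
#' onset.
#'
#' Typical values reported for SCRs are a latency of 1--5 s (average near
#' 3 s), a rise time of 1--5 s and a half-recovery time of 1--10 s; the
#' constructor enforces those ranges.
#'
#' @param stimulus_time stimulus onset, seconds from session start.
#' @param latency stimulus-to-onset delay in seconds, within \[1, 5\].
#' @param rise_time onset-to-peak duration in seconds, within \[1, 5\].
#' @param half_recovery time from peak to 50% recovery, seconds, \[1, 10\].
#' @param amplitude peak conductance increase over the pre-stimulus level,
#'   microsiemens, > 0.
#' @param st_onset_delay delay from the conductance rise onset to the start
#'   of the skin-temperature decrease, seconds (default 3).
#' @param st_drop magnitude of the temperature decrease, degrees C, > 0.
#' @param st_drop_duration duration of the decrease, seconds, >= 3.
#' @return an object of class `scr_event`.
#' @export
scr_event <- function(stimulus_time = 0, latency = 3, rise_time = 4,
                      half_recovery = 5, amplitude = 1,
                      st_onset_delay = 3, st_drop = 0.3,
                      st_drop_duration = 5) {
  if (latency < 1 || latency > 5)
    stop("'latency' must lie in [1, 5] s", call. = FALSE)
  if (rise_time < 1 || rise_time > 5)
    stop("'rise_time' must lie in [1, 5] s", call. = FALSE)
  if (half_recovery < 1 || half_recovery > 10)
    stop("'half_recovery' must lie in [1, 10] s", call. = FALSE)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("'amplitude' must be > 0 uS", call. = FALSE)
  if (st_drop <= 0) stop("'st_drop' must be > 0 degC", call. = FALSE)
  if (st_drop_duration < 3)
    stop("'st_drop_duration' must be >= 3 s", call. = FALSE)
  structure(
    list(stimulus_time = stimulus_time, latency = latency,
         rise_time = rise_time, half_recovery = half_recovery,
         amplitude = amplitude, st_onset_delay = st_onset_delay,
         st_drop = st_drop, st_drop_duration = st_drop_duration),
    class = "scr_event"
  )
}

#' Evaluate an SCR waveform at arbitrary times
#'
#' The phasic waveform is 0 before `stimulus_time + latency`, rises linearly
#' to `amplitude` over `rise_time`, then decays exponentially with rate
#' `log(2) / half_recovery`, so the value at `peak + half_recovery` is
#' exactly `amplitude / 2` and the tail tends asymptotically to 0. The
#' linear rise makes the response slope analytically checkable; the
#' exponential decay matches the 50%-recovery definition of the recovery
#' feature exactly.
#'
#' @param params an [scr_event()].
#' @param t numeric vector of times (seconds from session start).
#' @return conductance increments in microsiemens, same length as `t`.
#' @examples
#' ev <- scr_event(stimulus_time = 0, latency = 3, rise_time = 4,
#'                 half_recovery = 5, amplitude = 1)
#' scr_value(ev, c(7, 12))  # peak, then half-recovery point
#' @export
scr_value <- function(params, t) {
  stopifnot(inherits(params, "scr_event"))
  onset <- params$stimulus_time + params$latency
  peak <- onset + params$rise_time
  a <- params$amplitude
  y <- numeric(length(t))
  rising <- t >= onset & t < peak
  y[rising] <- a * (t[rising] - onset) / params$rise_time
  dec <- t >= peak
  y[dec] <- a * 2^(-(t[dec] - peak) / params$half_recovery)
  y
}

#' Render an SCR waveform as a sampled trace
#'
#' @param params an [scr_event()].
#' @param rate sample rate in Hz.
#' @param duration trace duration in seconds; defaults to the stimulus time
#'   plus latency, rise and six half-recovery times (tail below 2% of the
#'   amplitude).
#' @return a GSR [signal_trace()] containing only the phasic waveform.
#' @export
render_scr_waveform <- function(params, rate = 4, duration = NULL) {
  stopifnot(inherits(params, "scr_event"))
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be > 0", call. = FALSE)
  if (is.null(duration))
    duration <- params$stimulus_time + params$latency + params$rise_time +
      6 * params$half_recovery
  n <- max(1L, floor(duration * rate))
  t <- (seq_len(n) - 1) / rate
  signal_trace(scr_value(params, t), rate = rate, kind = "GSR")
}

#' Skin-temperature reaction to one event
#'
#' Linear drop of `st_drop` degrees over `st_drop_duration` seconds, starting
#' `st_onset_delay` seconds after the conductance rise onset, followed by a
#' slow linear return to baseline over three drop durations. Returned as the
#' (non-negative) temperature deficit to subtract from the baseline.
#'
#' @keywords internal
#' @noRd
st_drop_value <- function(params, t) {
  onset <- params$stimulus_time + params$latency + params$st_onset_delay
  end_drop <- onset + params$st_drop_duration
  end_rec <- end_drop + 3 * params$st_drop_duration
  d <- numeric(length(t))
  falling <- t >= onset & t < end_drop
  d[falling] <- params$st_drop * (t[falling] - onset) / params$st_drop_duration
  rec <- t >= end_drop & t < end_rec
  d[rec] <- params$st_drop * (1 - (t[rec] - end_drop) / (3 * params$st_drop_duration))
  d
}

#' Specification of a synthetic recording session
#'
#' The defaults emulate the laboratory protocol used to calibrate the
#' detector: a session of 900 s in which ten auditory stimuli are delivered
#' at times that are random but at least 60 s apart (to avoid overlapping
#' responses), over a tonic baseline with slow drift and sensor-level
#' Gaussian noise. Skin temperature sits inside the physiologically
#' plausible 32--35 degC wrist range.
#'
#' @param duration session length in seconds.
#' @param n_events number of induced stress events.
#' @param min_spacing minimum spacing between stimuli, seconds (default 60).
#' @param stimulus_times optional explicit stimulus schedule (overrides the
#'   random schedule; stimuli at pre-determined times).
#' @param baseline_scl tonic skin-conductance level, microsiemens.
#' @param baseline_drift baseline drift, microsiemens per minute.
#' @param noise_sd_gsr Gaussian noise SD on GSR samples, microsiemens.
#' @param baseline_st skin-temperature baseline, degC, within \[32, 35\].
#' @param noise_sd_st Gaussian noise SD on ST samples, degC.
#' @param habituation multiplicative amplitude decay per successive event,
#'   in (0, 1]; 1 disables habituation.
#' @param event an [scr_event()] providing the canonical event parameters
#'   (its `stimulus_time` is ignored).
#' @param seed integer seed making the session reproducible.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(duration = 900, n_events = 10, min_spacing = 60,
                         stimulus_times = NULL,
                         baseline_scl = 2, baseline_drift = 0.01,
                         noise_sd_gsr = 0.02, baseline_st = 33,
                         noise_sd_st = 0.02, habituation = 1,
                         event = scr_event(), seed = NULL) {
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (n_events < 0) stop("'n_events' must be >= 0", call. = FALSE)
  if (baseline_st < 32 || baseline_st > 35)
    stop("'baseline_st' must lie in the plausible wrist range [32, 35] degC",
         call. = FALSE)
  if (habituation <= 0 || habituation > 1)
    stop("'habituation' must lie in (0, 1]", call. = FALSE)
  if (n_events * min_spacing >= duration)
    stop("infeasible schedule: n_events * min_spacing must be < duration",
         call. = FALSE)
  if (!is.null(stimulus_times)) {
    stimulus_times <- sort(as.numeric(stimulus_times))
    if (length(stimulus_times) != n_events)
      stop("'stimulus_times' must have length 'n_events'", call. = FALSE)
    if (n_events > 1 && any(diff(stimulus_times) < min_spacing))
      stop("explicit stimulus times violate 'min_spacing'", call. = FALSE)
  }
  structure(
    list(duration = duration, n_events = n_events, min_spacing = min_spacing,
         stimulus_times = stimulus_times, baseline_scl = baseline_scl,
         baseline_drift = baseline_drift, noise_sd_gsr = noise_sd_gsr,
         baseline_st = baseline_st, noise_sd_st = noise_sd_st,
         habituation = habituation, event = event, seed = seed),
    class = "session_spec"
  )
}

with_session_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Uniform draw over the feasible schedule simplex: shift sorted uniforms by
# the cumulative minimum spacing so consecutive gaps are >= min_spacing.
schedule_stimuli <- function(n, duration, min_spacing, margin = 30) {
  if (n == 0) return(numeric(0))
  lo <- margin
  hi <- duration - margin
  slack <- (hi - lo) - (n - 1) * min_spacing
  if (slack <= 0)
    stop("infeasible schedule: cannot place ", n, " stimuli ", min_spacing,
         " s apart in [", lo, ", ", hi, "]", call. = FALSE)
  u <- sort(stats::runif(n, 0, slack))
  lo + u + min_spacing * (seq_len(n) - 1)
}

#' Generate a ground-truthed synthetic session
#'
#' Builds 4 Hz GSR and ST traces: GSR is the tonic baseline plus drift plus
#' the sum of the injected event waveforms plus i.i.d. Gaussian noise; ST is
#' the baseline minus each event's delayed temperature drop plus noise.
#' Successive event amplitudes decay by the habituation factor. The returned
#' ground truth lists every injected event together with the time at which a
#' detector should place the corresponding moment of stress (the conductance
#' rise onset).
#'
#' @param spec a [session_spec()].
#' @param rate sample rate in Hz (nominal 4).
#' @return a list with elements `gsr` and `st` ([signal_trace()]s at `rate`),
#'   and `truth`, a data frame with one row per injected event
#'   (`stimulus_time`, `onset` = expected MOS time, `amplitude`,
#'   `rise_time`, `latency`, `half_recovery`).
#' @examples
#' ses <- generate_session(session_spec(duration = 300, n_events = 3, seed = 1))
#' ses$truth$onset
#' @export
generate_session <- function(spec, rate = 4) {
  stopifnot(inherits(spec, "session_spec"))
  with_session_seed(spec$seed, {
    stim <- if (!is.null(spec$stimulus_times)) spec$stimulus_times
            else schedule_stimuli(spec$n_events, spec$duration, spec$min_spacing)
    n <- floor(spec$duration * rate)
    t <- (seq_len(n) - 1) / rate
    base <- spec$event
    events <- lapply(seq_along(stim), function(k) {
      ev <- base
      ev$stimulus_time <- stim[k]
      ev$amplitude <- base$amplitude * spec$habituation^(k - 1)
      ev
    })
    g <- spec$baseline_scl + spec$baseline_drift * t / 60
    st <- rep(spec$baseline_st, n)
    for (ev in events) {
      g <- g + scr_value(ev, t)
      st <- st - st_drop_value(ev, t)
    }
    if (spec$noise_sd_gsr > 0) g <- g + stats::rnorm(n, 0, spec$noise_sd_gsr)
    if (spec$noise_sd_st > 0) st <- st + stats::rnorm(n, 0, spec$noise_sd_st)
    truth <- data.frame(
      stimulus_time = stim,
      onset = stim + base$latency,
      amplitude = vapply(events, function(e) e$amplitude, numeric(1)),
      rise_time = rep(base$rise_time, length(stim)),
      latency = rep(base$latency, length(stim)),
      half_recovery = rep(base$half_recovery, length(stim))
    )
    list(gsr = signal_trace(g, rate = rate, kind = "GSR"),
         st = signal_trace(st, rate = rate, kind = "ST"),
         truth = truth)
  })
}

#' Generate a synthetic GPS track with designated stress zones
#'
#' Produces one fix per second along an eastbound constant-speed walk. During
#' each zone's time window the walker slows to `zone_speed` (dwelling in the
#' zone, as a pedestrian does at a stressful crossing), so all seconds
#' falling in the window lie inside a compact area; the zone polygon
#' returned is the bounding box of those positions plus a buffer.
#' Scheduling session stimuli inside a zone's time window therefore places
#' the resulting moments of stress inside the zone.
#'
#' @param duration track duration in seconds (one fix per second).
#' @param zones list of two-element numeric vectors `c(t0, t1)`: time windows
#'   the walker spends inside a designated stress zone.
#' @param origin `c(lat, lon)` of the starting point (degrees).
#' @param speed walking speed in m/s outside zones.
#' @param zone_speed walking speed in m/s inside zones (default `speed/5`).
#' @param jitter SD of the per-second GPS jitter inside zones, metres.
#' @param start_time epoch seconds of the first fix.
#' @param seed integer seed.
#' @return a list with `track` (a [geo_track()]) and `zones` (a list of
#'   `c(lat_min, lat_max, lon_min, lon_max)` bounding boxes).
#' @export
generate_track <- function(duration, zones = list(),
                           origin = c(47.8095, 13.0550), speed = 1.4,
                           zone_speed = speed / 5, jitter = 2,
                           start_time = 0, seed = NULL) {
  if (!is.numeric(duration) || duration < 1)
    stop("'duration' must be >= 1 s (empty path)", call. = FALSE)
  for (z in zones) {
    if (length(z) != 2 || z[1] >= z[2])
      stop("each zone must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  if (length(zones) > 1) {
    o <- order(vapply(zones, `[`, numeric(1), 1))
    zs <- zones[o]
    for (i in seq_len(length(zs) - 1))
      if (zs[[i]][2] > zs[[i + 1]][1])
        stop("zones must not overlap in time", call. = FALSE)
  }
  with_session_seed(seed, {
    n <- floor(duration)
    tt <- 0:(n - 1)
    in_zone <- rep(FALSE, n)
    for (z in zones) in_zone <- in_zone | (tt >= z[1] & tt <= z[2])
    # metres east of origin: slow down inside zones, with GPS jitter there
    dx <- ifelse(in_zone, zone_speed, speed)
    x <- cumsum(c(0, dx[-n]))
    y <- numeric(n)
    if (any(in_zone)) {
      x[in_zone] <- x[in_zone] + stats::rnorm(sum(in_zone), 0, jitter)
      y[in_zone] <- y[in_zone] + stats::rnorm(sum(in_zone), 0, jitter)
    }
    ll <- local_unproject(x, y, origin_lat = origin[1], origin_lon = origin[2])
    boxes <- lapply(zones, function(z) {
      sel <- tt >= z[1] & tt <= z[2]
      pad_m <- 3 * jitter + 1
      pad_lat <- pad_m / 111320
      pad_lon <- pad_m / (111320 * cos(origin[1] * pi / 180))
      c(lat_min = min(ll$lat[sel]) - pad_lat, lat_max = max(ll$lat[sel]) + pad_lat,
        lon_min = min(ll$lon[sel]) - pad_lon, lon_max = max(ll$lon[sel]) + pad_lon)
    })
    list(track = geo_track(start_time + tt, ll$lat, ll$lon), zones = boxes)
  })
}

#' Is a point inside a zone bounding box?
#' @param lat,lon coordinates in degrees.
#' @param zone a `c(lat_min, lat_max, lon_min, lon_max)` box as returned by
#'   [generate_track()].
#' @return logical vector.
#' @export
in_zone <- function(lat, lon, zone) {
  lat >= zone["lat_min"] & lat <= zone["lat_max"] &
    lon >= zone["lon_min"] & lon <= zone["lon_max"]
}
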