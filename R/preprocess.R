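#' Butterworth filter specification
#'
#' The detector's defaults follow the published chain for this class of
#' wearable data: GSR is low-passed with a first-order filter at 5 Hz
#' (noise removal) and high-passed at 0.05 Hz (phasic/tonic separation);
#' ST is band-limited with second-order filters at 1 Hz and 0.1 Hz.
#'
#' @param order filter order, integer >= 1 (1 or 2 for the defaults).
#' @param cutoff cut-off frequency in Hz, > 0.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param zero_phase apply forward-backward (zero-phase) filtering. Zero
#'   phase leaves event onsets in place, which the skin-temperature delay
#'   rule depends on; set `FALSE` for a causal, streaming-style filter.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 1, cutoff, kind = c("lowpass", "highpass"),
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || order < 1) stop("'order' must be >= 1", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0 Hz", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff, kind = kind,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a Butterworth filter to a trace
#'
#' A cut-off at or above the Nyquist frequency of the trace is clamped to
#' 0.99 x Nyquist with a logged message: the nominal 5 Hz low-pass is then a
#' near-pass-through anti-noise stage on 4 Hz recordings, while recordings
#' sampled at 10 Hz or more use the stated cut-off unchanged.
#'
#' @param trace a [signal_trace()] without missing values (impute first).
#' @param spec a [filter_spec()].
#' @return a [signal_trace()] of the same length and rate.
#' @export
butterworth <- function(trace, spec) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "filter_spec"))
  n <- length(trace$values)
  if (n < 3 * spec$order)
    stop("signal error: trace too short to filter (need >= ",
         3 * spec$order, " samples)", call. = FALSE)
  if (any(trace$missing))
    stop("trace has missing values; impute_missing() before filtering",
         call. = FALSE)
  nyq <- trace$rate / 2
  fc <- spec$cutoff
  if (fc >= nyq) {
    fc <- 0.99 * nyq
    message(sprintf("cut-off %.3g Hz >= Nyquist %.3g Hz; clamped to %.3g Hz",
                    spec$cutoff, nyq, fc))
  }
  bf <- signal::butter(spec$order, fc / nyq,
                       type = if (spec$kind == "lowpass") "low" else "high")
  x <- trace$values
  y <- if (spec$zero_phase) zero_phase_filter(bf, x, spec$order, fc / nyq)
       else as.numeric(signal::filter(bf, x))
  signal_trace(y, rate = trace$rate, start_time = trace$start_time,
               kind = trace$kind, unit = trace$unit)
}

# One causal pass started from its steady state for a constant input equal
# to the first sample, so a constant series maps to its steady-state output
# with no start-up transient at all.
steady_pass <- function(bf, x) {
  g <- sum(bf$b) / sum(bf$a)   # DC gain
  as.numeric(signal::filter(bf$b, bf$a, x,
                            init.x = rep(x[1], length(bf$b) - 1),
                            init.y = rep(x[1] * g, length(bf$a) - 1)))
}

# Forward-backward filtering with steady-state initial conditions and an
# odd (point-reflected) extension at both ends, so constants pass a
# low-pass exactly, a high-pass maps them to exactly zero, and event
# onsets are not shifted in time.
zero_phase_filter <- function(bf, x, order, fc_norm) {
  n <- length(x)
  pad <- min(n - 1, max(12 * order, ceiling(2 / fc_norm)))
  ext <- c(2 * x[1] - x[seq(pad + 1, 2)], x,
           2 * x[n] - x[seq(n - 1, n - pad)])
  y <- steady_pass(bf, ext)
  y <- rev(steady_pass(bf, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Filter GSR and split it into phasic and tonic components
#'
#' Low-passes the raw conductance (first order, 5 Hz nominal cut-off,
#' clamped below Nyquist as needed), then separates the phasic
#' skin-conductance response (SCR) from the tonic level (SCL) with a
#' first-order 0.05 Hz high-pass: `phasic` is the high-passed filtered
#' signal and `tonic = filtered - phasic`, so the decomposition identity
#' `phasic + tonic == filtered` holds exactly.
#'
#' @param trace a GSR [signal_trace()].
#' @param lowpass_cutoff,highpass_cutoff cut-offs in Hz.
#' @param zero_phase passed to [butterworth()].
#' @return list with `filtered`, `phasic` and `tonic` traces.
#' @export
preprocess_gsr <- function(trace, lowpass_cutoff = 5, highpass_cutoff = 0.05,
                           zero_phase = TRUE) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$kind != "GSR") stop("expected a GSR trace", call. = FALSE)
  filtered <- butterworth(trace, filter_spec(1, lowpass_cutoff, "lowpass", zero_phase))
  phasic <- butterworth(filtered, filter_spec(1, highpass_cutoff, "highpass", zero_phase))
  tonic <- filtered
  tonic$values <- filtered$values - phasic$values
  list(filtered = filtered, phasic = phasic, tonic = tonic)
}

#' Band-limit skin temperature for derivative-sign tests
#'
#' Second-order low-pass at 1 Hz followed by a second-order high-pass at
#' 0.1 Hz. The band-passed signal is used only for the sign of the
#' temperature derivative in the ST-decrease rule; the raw (imputed) trace
#' is kept alongside for reporting.
#'
#' @param trace an ST [signal_trace()].
#' @param lowpass_cutoff,highpass_cutoff cut-offs in Hz.
#' @param zero_phase passed to [butterworth()].
#' @return the band-passed [signal_trace()] (same rate as the input).
#' @export
preprocess_st <- function(trace, lowpass_cutoff = 1, highpass_cutoff = 0.1,
                          zero_phase = TRUE) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$kind != "ST") stop("expected an ST trace", call. = FALSE)
  low <- butterworth(trace, filter_spec(2, lowpass_cutoff, "lowpass", zero_phase))
  butterworth(low, filter_spec(2, highpass_cutoff, "highpass", zero_phase))
}

#' Downsample a trace to 1 Hz by windowed means
#'
#' Each integer-second window `[k, k+1)` becomes one output sample equal to
#' the plain mean of the samples it contains. Edge windows with fewer than
#' the full complement of samples are instead filled by natural cubic-spline
#' interpolation through the complete-window means.
#'
#' @param trace a [signal_trace()] with rate >= 1 Hz and no missing values.
#' @return a [signal_trace()] at 1 Hz.
#' @export
downsample_1hz <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  r <- trace$rate
  n <- length(trace$values)
  if (r < 1) stop("signal error: rate must be >= 1 Hz", call. = FALSE)
  if (n < r) stop("signal error: trace shorter than 1 s", call. = FALSE)
  if (any(trace$missing))
    stop("trace has missing values; impute_missing() before downsampling",
         call. = FALSE)
  win <- floor((seq_len(n) - 1) / r)
  counts <- tabulate(win + 1L, nbins = max(win) + 1L)
  means <- as.numeric(tapply(trace$values, win, mean))
  full <- counts == max(counts)
  if (any(!full)) {
    centers <- seq_along(means) - 0.5
    if (sum(full) >= 2) {
      means[!full] <- stats::spline(centers[full], means[full],
                                    xout = centers[!full],
                                    method = "natural")$y
    }
  }
  signal_trace(means, rate = 1, start_time = trace$start_time,
               kind = trace$kind, unit = trace$unit)
}

#' Impute missing samples from their nearest valid neighbours
#'
#' A single missing sample is replaced by the average of the previous and
#' next valid values (at a series edge, by the one available neighbour).
#' Runs of more than `max_gap` consecutive missing samples violate the data
#' quality this step assumes and raise an error; larger gaps can be filled
#' by linear interpolation by raising `max_gap` explicitly.
#'
#' @param trace a [signal_trace()].
#' @param max_gap maximum tolerated run of consecutive missing samples
#'   (default 1).
#' @return a [signal_trace()] with no missing values and a cleared mask.
#' @export
impute_missing <- function(trace, max_gap = 1) {
  stopifnot(inherits(trace, "signal_trace"))
  miss <- trace$missing
  if (!any(miss)) return(trace)
  if (all(miss))
    stop("data-quality error: all samples missing", call. = FALSE)
  runs <- rle(miss)
  if (max(runs$lengths[runs$values]) > max_gap)
    stop("data-quality error: ", max(runs$lengths[runs$values]),
         " consecutive missing samples exceed max_gap = ", max_gap,
         call. = FALSE)
  x <- trace$values
  x[miss] <- NA_real_
  idx <- seq_along(x)
  good <- !miss
  x[miss] <- stats::approx(idx[good], x[good], xout = idx[miss],
                           rule = 2)$y
  signal_trace(x, rate = trace$rate, start_time = trace$start_time,
               kind = trace$kind, unit = trace$unit,
               missing = rep(FALSE, length(x)))
}

#' Assemble the per-second bio-geodatabase
#'
#' Joins the 1 Hz signals into one row per second and attaches the nearest
#' GPS fix in time, provided it lies within `tolerance` seconds; rows
#' without a close fix get `NA` coordinates (lab sessions carry no GPS and
#' spatial operations are then disabled).
#'
#' @param g,st,phasic,tonic,st_band 1 Hz [signal_trace()]s sharing start
#'   time and length: filtered conductance, raw temperature, phasic and
#'   tonic conductance components, band-passed temperature.
#' @param st_smooth optional 1 Hz noise-filtered (low-passed only)
#'   temperature trace; defaults to the raw `st` values. This is the
#'   channel the temperature-decrease rule reads by default.
#' @param geo optional [geo_track()].
#' @param tolerance maximum fix-to-second distance in seconds (default 5).
#' @return a `biogeo_table` data frame with columns `t`, `g`, `st`,
#'   `phasic`, `tonic`, `st_band`, `st_smooth`, `lat`, `lon`.
#' @export
build_biogeo <- function(g, st, phasic, tonic, st_band, st_smooth = NULL,
                         geo = NULL, tolerance = 5) {
  if (is.null(st_smooth)) st_smooth <- st
  traces <- list(g, st, phasic, tonic, st_band, st_smooth)
  lens <- vapply(traces, function(x) length(x$values), integer(1))
  starts <- vapply(traces, function(x) x$start_time, numeric(1))
  rates <- vapply(traces, function(x) x$rate, numeric(1))
  if (length(unique(lens)) != 1 || length(unique(starts)) != 1 ||
      any(rates != 1))
    stop("alignment error: all traces must be 1 Hz with equal start and length",
         call. = FALSE)
  t <- g$start_time + (seq_len(lens[1]) - 1)
  lat <- rep(NA_real_, lens[1]); lon <- rep(NA_real_, lens[1])
  if (!is.null(geo) && nrow(geo) > 0) {
    for (i in seq_along(t)) {
      j <- which.min(abs(geo$t - t[i]))
      if (abs(geo$t[j] - t[i]) <= tolerance) {
        lat[i] <- geo$lat[j]; lon[i] <- geo$lon[j]
      }
    }
  }
  structure(
    data.frame(t = t, g = g$values, st = st$values, phasic = phasic$values,
               tonic = tonic$values, st_band = st_band$values,
               st_smooth = st_smooth$values, lat = lat, lon = lon),
    class = c("biogeo_table", "data.frame")
  )
}

#' Run the full preprocessing chain on a 4 Hz session
#'
#' Imputation at the native rate, GSR filtering and phasic/tonic
#' decomposition, ST noise filtering (low-pass; also band-limited for
#' completeness), downsampling of every channel to 1 Hz by windowed means,
#' and assembly of the per-second bio-geodatabase. The temperature-decrease
#' rule reads the `st_smooth` (low-passed) channel by default: the 0.1 Hz
#' high-pass strips the multi-second monotone decrease the rule tests for.
#'
#' @param gsr a GSR [signal_trace()] (nominally 4 Hz).
#' @param st an ST [signal_trace()] of the same duration.
#' @param geo optional [geo_track()].
#' @param max_gap passed to [impute_missing()].
#' @param zero_phase passed to the filters.
#' @param geo_tolerance passed to [build_biogeo()].
#' @return a `biogeo_table` (see [build_biogeo()]).
#' @examples
#' ses <- generate_session(session_spec(duration = 120, n_events = 1, seed = 2))
#' tab <- preprocess_session(ses$gsr, ses$st)
#' nrow(tab)  # one row per second
#' @export
preprocess_session <- function(gsr, st, geo = NULL, max_gap = 1,
                               zero_phase = TRUE, geo_tolerance = 5) {
  stopifnot(inherits(gsr, "signal_trace"), inherits(st, "signal_trace"))
  gsr <- impute_missing(gsr, max_gap)
  st <- impute_missing(st, max_gap)
  gg <- preprocess_gsr(gsr, zero_phase = zero_phase)
  st_low <- butterworth(st, filter_spec(2, 1, "lowpass", zero_phase))
  stb <- butterworth(st_low, filter_spec(2, 0.1, "highpass", zero_phase))
  build_biogeo(
    g = downsample_1hz(gg$filtered),
    st = downsample_1hz(st),
    phasic = downsample_1hz(gg$phasic),
    tonic = downsample_1hz(gg$tonic),
    st_band = downsample_1hz(stb),
    st_smooth = downsample_1hz(st_low),
    geo = geo, tolerance = geo_tolerance
  )
}
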