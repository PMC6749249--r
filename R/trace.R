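#' Uniformly sampled physiological signal trace
#'
#' A `signal_trace` holds one uniformly sampled physiological series together
#' with its start time (UTC epoch seconds), sample rate and unit. The two
#' kinds used by the detector are galvanic skin response (`"GSR"`,
#' microsiemens) and skin temperature (`"ST"`, degrees Celsius). A logical
#' missing mask travels with the values so that malformed or out-of-range
#' samples survive I/O and can be imputed explicitly.
#'
#' @param values numeric vector of samples. `NA` entries are marked missing.
#' @param rate sample rate in Hz (> 0). Wrist-worn devices in this domain
#'   record both channels at a nominal 4 Hz.
#' @param start_time start of the recording, UTC epoch seconds.
#' @param kind `"GSR"` or `"ST"`.
#' @param unit measurement unit; defaults to `"uS"` for GSR and `"degC"`
#'   for ST.
#' @param missing optional logical mask, same length as `values`.
#' @return an object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(rep(2, 8), rate = 4, kind = "GSR")
#' trace_duration(tr)
#' @export
signal_trace <- function(values, rate, start_time = 0,
                         kind = c("GSR", "ST"), unit = NULL,
                         missing = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one sample", call. = FALSE)
  if (is.null(unit)) unit <- if (kind == "GSR") "uS" else "degC"
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing) | is.na(values)
  if (length(missing) != length(values))
    stop("'missing' mask must match 'values' in length", call. = FALSE)
  structure(
    list(values = values, rate = rate, start_time = as.numeric(start_time),
         kind = kind, unit = unit, missing = missing),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s [%s], %d samples @ %g Hz (%.1f s), %d missing\n",
              x$kind, x$unit, length(x$values), x$rate,
              trace_duration(x), sum(x$missing)))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace a [signal_trace()].
#' @return duration in seconds (`n / rate`).
#' @export
trace_duration <- function(trace) length(trace$values) / trace$rate

#' Sample timestamps of a trace
#' @param trace a [signal_trace()].
#' @return numeric vector of epoch timestamps, one per sample.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) / trace$rate
}

#' Geolocation track
#'
#' A sequence of GPS fixes `(t, lat, lon)` as produced by a phone's GNSS
#' receiver while the wearable records. Timestamps are UTC epoch seconds and
#' must be non-decreasing; coordinates are WGS84 degrees.
#'
#' @param t epoch timestamps (non-decreasing).
#' @param lat latitudes in degrees, within \[-90, 90\].
#' @param lon longitudes in degrees, within \[-180, 180\].
#' @return a `geo_track` data frame with columns `t`, `lat`, `lon`.
#' @export
geo_track <- function(t, lat, lon) {
  t <- as.numeric(t); lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(t) != length(lat) || length(t) != length(lon))
    stop("'t', 'lat' and 'lon' must have equal length", call. = FALSE)
  if (is.unsorted(t))
    stop("track timestamps must be non-decreasing", call. = FALSE)
  ok <- is.na(lat) | (lat >= -90 & lat <= 90)
  ok2 <- is.na(lon) | (lon >= -180 & lon <= 180)
  if (!all(ok) || !all(ok2))
    stop("coordinates out of range: lat in [-90,90], lon in [-180,180]",
         call. = FALSE)
  structure(data.frame(t = t, lat = lat, lon = lon),
            class = c("geo_track", "data.frame"))
}
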