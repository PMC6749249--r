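# GSR plausibility range in microsiemens; values outside are sensor
# artefacts and are masked as missing rather than rejected.
GSR_RANGE <- c(0.01, 100)

parse_time_column <- function(t_raw) {
  suppressWarnings(tnum <- as.numeric(t_raw))
  if (!all(is.na(tnum))) return(tnum)
  as.numeric(as.POSIXct(t_raw, tz = "UTC"))
}

#' Read an eDiary-style session CSV
#'
#' One canonical dialect: comma separator, dot decimal, header
#' `t,gsr,st,lat,lon` (`lat`/`lon` optional), with `t` either UTC epoch
#' seconds or ISO-8601 (auto-detected, always interpreted as UTC). One row
#' per sensor sample; the rate is inferred from the median timestamp step.
#' Malformed numeric cells become missing-mask entries, and GSR values
#' outside the plausible 0.01--100 uS range are masked with a logged
#' message rather than rejected.
#'
#' @param path path to the CSV file.
#' @return list with `gsr`, `st` ([signal_trace()]s sharing a start time)
#'   and `geo` (a [geo_track()] of per-second fixes, or `NULL` when no
#'   coordinates are present).
#' @export
read_ediary_csv <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("format error: empty file: ", path, call. = FALSE)
  need <- c("t", "gsr", "st")
  if (!all(need %in% names(df)))
    stop("format error: missing required columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  t <- parse_time_column(df$t)
  if (any(is.na(t))) stop("format error: unparseable timestamps", call. = FALSE)
  suppressWarnings({
    gsr <- as.numeric(df$gsr)
    st <- as.numeric(df$st)
  })
  rate <- if (length(t) > 1) 1 / stats::median(diff(t)) else 1
  oob <- !is.na(gsr) & (gsr < GSR_RANGE[1] | gsr > GSR_RANGE[2])
  if (any(oob)) {
    message(sum(oob), " GSR sample(s) outside [",
            GSR_RANGE[1], ", ", GSR_RANGE[2], "] uS masked as missing")
    gsr[oob] <- NA_real_
  }
  geo <- NULL
  if (all(c("lat", "lon") %in% names(df))) {
    suppressWarnings({
      lat <- as.numeric(df$lat)
      lon <- as.numeric(df$lon)
    })
    ok <- !is.na(lat) & !is.na(lon)
    if (any(ok)) {
      # one fix per second: keep the first located sample of each second
      sec <- floor(t[ok])
      first <- !duplicated(sec)
      geo <- geo_track(sec[first], lat[ok][first], lon[ok][first])
    }
  }
  list(gsr = signal_trace(gsr, rate = rate, start_time = t[1], kind = "GSR"),
       st = signal_trace(st, rate = rate, start_time = t[1], kind = "ST"),
       geo = geo)
}

#' Write a session in the eDiary-style CSV dialect
#'
#' @param gsr,st [signal_trace()]s sharing start time, rate and length.
#' @param geo optional [geo_track()]; each sample row receives the fix of
#'   its second, if any.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ediary_csv <- function(gsr, st, path, geo = NULL) {
  stopifnot(inherits(gsr, "signal_trace"), inherits(st, "signal_trace"))
  if (length(gsr$values) != length(st$values) || gsr$rate != st$rate)
    stop("gsr and st traces must share rate and length", call. = FALSE)
  t <- trace_times(gsr)
  lat <- rep(NA_real_, length(t)); lon <- rep(NA_real_, length(t))
  if (!is.null(geo) && nrow(geo) > 0) {
    m <- match(floor(t), floor(geo$t))
    hit <- !is.na(m)
    lat[hit] <- geo$lat[m[hit]]
    lon[hit] <- geo$lon[m[hit]]
  }
  df <- data.frame(t = sprintf("%.3f", t),
                   gsr = sprintf("%.6f", gsr$values),
                   st = sprintf("%.6f", st$values),
                   lat = ifelse(is.na(lat), "", sprintf("%.7f", lat)),
                   lon = ifelse(is.na(lon), "", sprintf("%.7f", lon)))
  df$gsr[gsr$missing] <- "NaN"
  df$st[st$missing] <- "NaN"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_e4_file <- function(path, kind) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("format error: ", path, " must contain start, rate and data lines",
         call. = FALSE)
  start <- suppressWarnings(as.numeric(lines[1]))
  rate <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(start) || is.na(rate) || rate <= 0)
    stop("format error: inconsistent header in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines[-(1:2)]))
  signal_trace(vals, rate = rate, start_time = start, kind = kind)
}

#' Read an Empatica-E4-style export directory
#'
#' Reads `EDA.csv` and `TEMP.csv`, each a single-column value file whose
#' first line is the UTC epoch start time and second line the sample rate
#' (nominally 4 Hz), followed by one value per line.
#'
#' @param dir directory containing the export.
#' @return list with `gsr` and `st` [signal_trace()]s.
#' @export
read_e4_export <- function(dir) {
  eda <- file.path(dir, "EDA.csv")
  temp <- file.path(dir, "TEMP.csv")
  if (!file.exists(eda))
    stop("format error: missing EDA.csv in ", dir, call. = FALSE)
  if (!file.exists(temp))
    stop("format error: missing TEMP.csv in ", dir, call. = FALSE)
  list(gsr = read_e4_file(eda, "GSR"), st = read_e4_file(temp, "ST"))
}

#' Write / read the bio-geodatabase CSV
#'
#' One row per second with columns
#' `t,g,st,phasic,tonic,st_band,st_smooth,lat,lon`.
#'
#' @param table a `biogeo_table`.
#' @param path file path.
#' @return `path` (writer, invisibly) or the `biogeo_table` (reader).
#' @export
write_biogeo_csv <- function(table, path) {
  stopifnot(inherits(table, "biogeo_table"))
  out <- table
  for (col in c("g", "st", "phasic", "tonic", "st_band", "st_smooth"))
    out[[col]] <- sprintf("%.9g", table[[col]])
  out$lat <- ifelse(is.na(table$lat), "", sprintf("%.7f", table$lat))
  out$lon <- ifelse(is.na(table$lon), "", sprintf("%.7f", table$lon))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_biogeo_csv
#' @export
read_biogeo_csv <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "g", "st", "phasic", "tonic", "st_band", "st_smooth",
            "lat", "lon")
  if (!all(need %in% names(df)))
    stop("format error: missing bio-geodatabase columns", call. = FALSE)
  for (col in need) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  structure(df[need], class = c("biogeo_table", "data.frame"))
}

geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null")
  invisible(path)
}

#' Write detected MOS as a GeoJSON FeatureCollection of points
#'
#' RFC 7946 output, coordinates in lon-lat order. Events without a location
#' get a `null` geometry. Properties: `t`, `total_score` and the five rule
#' scores.
#'
#' @param events a `mos_events` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mos_geojson <- function(events, path) {
  features <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    geom <- if (is.na(e$lat) || is.na(e$lon)) NULL
            else list(type = "Point", coordinates = c(e$lon, e$lat))
    list(type = "Feature", geometry = geom,
         properties = list(t = e$t, total_score = e$ts,
                           sc1 = e$sc1, sc2 = e$sc2, sc3 = e$sc3,
                           sc4 = e$sc4, sc5 = e$sc5))
  })
  geojson_write(features, path)
}

#' Write hotspot cells as GeoJSON polygons
#'
#' Each cell becomes a square polygon (cell corners unprojected back to
#' WGS84) with properties `mos_ratio`, `gi_z` and `class`.
#'
#' @param cells a `hotspot_cells` data frame with `gi_z` and `class`
#'   columns (see [hotspot_analysis()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_geojson <- function(cells, path) {
  cs <- attr(cells, "cell_size")
  o_lat <- attr(cells, "origin_lat"); o_lon <- attr(cells, "origin_lon")
  features <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    x0 <- cl$cell_x * cs; x1 <- x0 + cs
    y0 <- cl$cell_y * cs; y1 <- y0 + cs
    corners <- local_unproject(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0),
                               o_lat, o_lon)
    ring <- lapply(seq_along(corners$lat),
                   function(j) c(corners$lon[j], corners$lat[j]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(mos_ratio = cl$ratio,
                           n_seconds = cl$n_seconds, n_mos = cl$n_mos,
                           gi_z = if (is.null(cl$gi_z)) NA else cl$gi_z,
                           class = if (is.null(cl$class)) NA else cl$class))
  })
  geojson_write(features, path)
}

#' Write the ground truth of a synthetic session as a sidecar CSV
#'
#' @param truth the `truth` data frame from [generate_session()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
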