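# Local tangent-plane (equirectangular) projection about an origin.
# Metric cell sizes only need local accuracy: over the few kilometres a
# walking or cycling session covers, the error versus a conformal
# projection is far below one cell.
EARTH_RADIUS_M <- 6378137

local_project <- function(lat, lon, origin_lat, origin_lon) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(x = (lon - origin_lon) * k * cos(origin_lat * pi / 180),
       y = (lat - origin_lat) * k)
}

local_unproject <- function(x, y, origin_lat, origin_lon) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(lat = origin_lat + y / k,
       lon = origin_lon + x / (k * cos(origin_lat * pi / 180)))
}

#' Aggregate measurement seconds and MOS into grid cells
#'
#' Lays a square grid (half-open cells, metric size) over the located rows
#' of the bio-geodatabase in a local metric projection about the data
#' centroid. Each cell counts the measurement seconds spent in it and the
#' moments of stress located in it; the MOS ratio `x_j = n_mos / n_seconds`
#' standardises the counts by exposure time. Cells without measurement
#' seconds are omitted.
#'
#' @param table a `biogeo_table` with located rows.
#' @param events a `mos_events` data frame (may be empty).
#' @param cell_size cell edge length in metres, > 0.
#' @return a `hotspot_cells` data frame with columns `cell_x`, `cell_y`
#'   (integer grid indices), `px`, `py` (projected cell-centre metres),
#'   `lat`, `lon` (cell-centre degrees), `n_seconds`, `n_mos`, `ratio`.
#'   Attributes `cell_size`, `origin_lat`, `origin_lon` record the grid.
#' @export
grid_aggregate <- function(table, events, cell_size) {
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("'cell_size' must be > 0 m", call. = FALSE)
  loc <- !is.na(table$lat) & !is.na(table$lon)
  if (!any(loc))
    stop("spatial error: no located rows in the bio-geodatabase", call. = FALSE)
  o_lat <- mean(table$lat[loc]); o_lon <- mean(table$lon[loc])
  p <- local_project(table$lat[loc], table$lon[loc], o_lat, o_lon)
  cx <- floor(p$x / cell_size); cy <- floor(p$y / cell_size)
  key <- paste(cx, cy)
  secs <- table(key)
  mos <- integer(length(secs))
  names(mos) <- names(secs)
  if (!is.null(events) && nrow(events) > 0) {
    eloc <- !is.na(events$lat) & !is.na(events$lon)
    if (any(eloc)) {
      pe <- local_project(events$lat[eloc], events$lon[eloc], o_lat, o_lon)
      ekey <- paste(floor(pe$x / cell_size), floor(pe$y / cell_size))
      for (k in ekey) if (k %in% names(mos)) mos[k] <- mos[k] + 1L
    }
  }
  ids <- names(secs)
  parts <- do.call(rbind, strsplit(ids, " ", fixed = TRUE))
  cell_x <- as.integer(parts[, 1]); cell_y <- as.integer(parts[, 2])
  px <- (cell_x + 0.5) * cell_size
  py <- (cell_y + 0.5) * cell_size
  ll <- local_unproject(px, py, o_lat, o_lon)
  out <- data.frame(cell_x = cell_x, cell_y = cell_y, px = px, py = py,
                    lat = ll$lat, lon = ll$lon,
                    n_seconds = as.integer(secs), n_mos = as.integer(mos),
                    ratio = as.integer(mos) / as.integer(secs))
  structure(out[order(out$cell_x, out$cell_y), , drop = FALSE],
            class = c("hotspot_cells", "data.frame"),
            cell_size = cell_size, origin_lat = o_lat, origin_lon = o_lon)
}

#' Getis-Ord Gi* z-scores for the cell field
#'
#' Local statistic of high/low-value clustering over a binary fixed
#' distance band that includes the focal cell itself (the self-inclusive
#' Gi* convention). For cell i with weights `w_ij`:
#' `z_i = (sum_j w_ij x_j - W_i xbar) / (SD(x) sqrt((n S1_i - W_i^2)/(n-1)))`
#' with `W_i = sum_j w_ij`, `S1_i = sum_j w_ij^2`, and the mean and
#' (population) standard deviation taken over all n cells. The statistic is
#' already a z-score; no further conversion is applied.
#'
#' @param cells a `hotspot_cells` data frame (or any data frame with
#'   columns `px`, `py`, `ratio`).
#' @param band distance band in metres; centroids within `band` (inclusive)
#'   are neighbours. Defaults to twice the grid cell size.
#' @return numeric vector of z-scores, one per cell.
#' @export
gi_star <- function(cells, band = NULL) {
  n <- nrow(cells)
  if (n < 2) stop("spatial error: at least two cells are required", call. = FALSE)
  x <- cells$ratio
  xbar <- mean(x)
  s <- sqrt(mean(x^2) - xbar^2)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate-field error: cell values are constant (SD = 0)",
         call. = FALSE)
  if (is.null(band)) {
    cs <- attr(cells, "cell_size")
    if (is.null(cs))
      stop("'band' must be given when cells carry no cell_size attribute",
           call. = FALSE)
    band <- 2 * cs
  }
  d <- as.matrix(stats::dist(cbind(cells$px, cells$py)))
  w <- (d <= band) * 1
  wi <- rowSums(w)
  s1 <- rowSums(w^2)
  denom <- s * sqrt((n * s1 - wi^2) / (n - 1))
  num <- as.numeric(w %*% x) - wi * xbar
  z <- unname(num / denom)
  if (any(!is.finite(z)))
    stop("spatial error: a cell's distance band covers every cell; reduce 'band'",
         call. = FALSE)
  z
}

#' Classify Gi* z-scores into hot spots and cold spots
#'
#' Two-sided normal approximation at level `alpha`: z at or above the
#' critical value marks a hot spot (clustered stress), at or below its
#' negative a cold spot (clustered relaxation), otherwise not significant.
#'
#' @param z numeric vector of Gi* z-scores.
#' @param alpha significance level (default 0.05; critical value 1.96).
#' @return character vector in `{"hot", "cold", "not-significant"}`.
#' @export
classify_hotspots <- function(z, alpha = 0.05) {
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / 2)
  ifelse(z >= zc, "hot", ifelse(z <= -zc, "cold", "not-significant"))
}

#' Full hotspot analysis of detected events
#'
#' Convenience wrapper: grid aggregation, Gi* and classification.
#'
#' @inheritParams grid_aggregate
#' @inheritParams gi_star
#' @inheritParams classify_hotspots
#' @return the `hotspot_cells` data frame with added columns `gi_z` and
#'   `class`.
#' @export
hotspot_analysis <- function(table, events, cell_size, band = NULL,
                             alpha = 0.05) {
  cells <- grid_aggregate(table, events, cell_size)
  z <- gi_star(cells, band)
  cells$gi_z <- z
  cells$class <- classify_hotspots(z, alpha)
  cells
}
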