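#' Great-circle distance between points
#'
#' Haversine distance on a sphere. All arguments are vectorised and recycled.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84 axes,
#'   longitude in \[-180, 180\], latitude in \[-90, 90\]).
#' @param radius_km Sphere radius in km (default mean Earth radius, 6371 km).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0) # one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = EARTH_RADIUS_KM) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    abort("coordinates out of bounds: lon must lie in [-180, 180], lat in [-90, 90]")
  }
  invisible(NULL)
}

# initial great-circle bearing, degrees clockwise from north, vectorised
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Per-step movement metrics for a track
#'
#' Computes, for each consecutive pair of fixes of each animal, the
#' great-circle step distance, elapsed time, observed (ground) speed, initial
#' bearing and the ground-velocity vector decomposed into east and north
#' components.
#'
#' @param track A track tibble (columns `animal_id`, `t`, `lon`, `lat`, ...).
#' @return A tibble with one row per step: `animal_id`, `t` (step start),
#'   `lon`, `lat` (start fix), `distance_km`, `dt_s`, `observed_speed`
#'   (m/s), `bearing` (degrees clockwise from north), `gv_east`, `gv_north`
#'   (m/s).
#' @export
step_metrics <- function(track) {
  check_track(track)
  track |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        abort(paste0("track ", key$animal_id, " has fewer than 2 fixes"))
      }
      n <- nrow(df)
      dt <- as.numeric(difftime(df$t[-1], df$t[-n], units = "secs"))
      if (any(dt <= 0)) abort("non-increasing timestamps in track")
      d <- haversine_km(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1])
      b <- bearing_deg(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1])
      s <- 1000 * d / dt
      tibble::tibble(
        t = df$t[-n], lon = df$lon[-n], lat = df$lat[-n],
        distance_km = d, dt_s = dt, observed_speed = s, bearing = b,
        gv_east = s * sin(b * pi / 180), gv_north = s * cos(b * pi / 180)
      )
    }) |>
    dplyr::ungroup()
}

#' Distance from points to the nearest coastline segment
#'
#' Minimum point-to-segment distance over all coastline polyline segments,
#' evaluated in a local equirectangular projection centred on each query point
#' (x scaled by cos latitude), so it is accurate at the tens-of-km scales of
#' shelf migration corridors.
#'
#' @param lon,lat Query coordinates (degrees), vectorised.
#' @param coast Coastline tibble with columns `polyline_id`, `vertex_index`,
#'   `lon`, `lat`.
#' @return Numeric vector of distances in km (>= 0).
#' @export
distance_to_coast_km <- function(lon, lat, coast) {
  if (is.null(coast) || nrow(coast) == 0) abort("empty coastline")
  check_lonlat(lon, lat)
  # segment endpoints, dropping joins between different polylines
  same <- coast$polyline_id[-nrow(coast)] == coast$polyline_id[-1]
  ax <- coast$lon[-nrow(coast)][same]; ay <- coast$lat[-nrow(coast)][same]
  bx <- coast$lon[-1][same];          by <- coast$lat[-1][same]
  if (length(ax) == 0) { # degenerate: isolated vertices only
    ax <- coast$lon; ay <- coast$lat; bx <- coast$lon; by <- coast$lat
  }
  kmdeg <- pi * EARTH_RADIUS_KM / 180
  vapply(seq_along(lon), function(i) {
    cx <- cos(lat[i] * pi / 180)
    x1 <- (ax - lon[i]) * kmdeg * cx; y1 <- (ay - lat[i]) * kmdeg
    x2 <- (bx - lon[i]) * kmdeg * cx; y2 <- (by - lat[i]) * kmdeg
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    tt <- ifelse(len2 > 0, pmin(pmax(-(x1 * dx + y1 * dy) / len2, 0), 1), 0)
    px <- x1 + tt * dx; py <- y1 + tt * dy
    sqrt(min(px^2 + py^2))
  }, numeric(1))
}

#' Sample a gridded field at point locations
#'
#' Returns the value of the grid cell containing each point. Cells are
#' half-open `[edge_i, edge_{i+1})`: a point exactly on an interior edge
#' belongs to the cell with the larger index. Time-indexed fields are matched
#' to the slice whose calendar month contains `t` (monthly fields) or to the
#' nearest slice in time (daily fields).
#'
#' @param field A [grid_field()].
#' @param lon,lat Point coordinates (degrees), vectorised.
#' @param t Optional POSIXct vector of times (required for multi-slice fields).
#' @return Numeric vector of sampled values; `NA` where the cell is missing.
#' @export
sample_field <- function(field, lon, lat, t = NULL) {
  stopifnot(inherits(field, "grid_field"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  ix <- findInterval(lon, field$lon_edges)
  iy <- findInterval(lat, field$lat_edges)
  nlon <- length(field$lon_edges) - 1L
  nlat <- length(field$lat_edges) - 1L
  bad <- ix < 1L | ix > nlon | iy < 1L | iy > nlat
  if (any(bad)) {
    abort(sprintf("%d point(s) outside the %s grid domain", sum(bad), field$name))
  }
  nt <- dim(field$values)[1]
  if (nt == 1L) {
    it <- rep(1L, n)
  } else {
    if (is.null(t)) abort("field has multiple time slices; supply t")
    t <- rep_len(t, n)
    it <- match_time_slice(field, t)
  }
  field$values[cbind(it, iy, ix)]
}

match_time_slice <- function(field, t) {
  if (identical(field$time_step, "monthly")) {
    key <- format(field$times, "%Y-%m", tz = "UTC")
    it <- match(format(t, "%Y-%m", tz = "UTC"), key)
    if (anyNA(it)) abort("no monthly slice covers one or more timestamps")
    it
  } else {
    ft <- as.numeric(field$times)
    vapply(as.numeric(t), function(x) which.min(abs(ft - x)), integer(1))
  }
}

#' Current-corrected swimming velocity
#'
#' Vector-subtracts the ocean current from the ground velocity of each step
#' (swimming = ground - current), giving the through-water swimming vector
#' and speed, a proxy of swimming effort.
#'
#' @param steps A step-metrics tibble (see [step_metrics()]) with columns
#'   `gv_east`, `gv_north`, or any tibble carrying those columns.
#' @param current_u,current_v Eastward and northward current components at the
#'   step's start fix, m/s (vectors recycled to `nrow(steps)`).
#' @return `steps` with added columns `current_u`, `current_v`,
#'   `current_speed`, `swim_east`, `swim_north`, `swim_speed` (all m/s).
#' @export
swimming_velocity <- function(steps, current_u, current_v) {
  stopifnot(is.data.frame(steps), all(c("gv_east", "gv_north") %in% names(steps)))
  u <- rep_len(current_u, nrow(steps))
  v <- rep_len(current_v, nrow(steps))
  steps |>
    dplyr::mutate(
      current_u = u, current_v = v,
      current_speed = sqrt(u^2 + v^2),
      swim_east = .data$gv_east - u,
      swim_north = .data$gv_north - v,
      swim_speed = sqrt(.data$swim_east^2 + .data$swim_north^2)
    )
}
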