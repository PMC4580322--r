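#' Read tracking data from CSV
#'
#' Reads a fix table (one row per satellite fix), validates it, and returns a
#' tidy track tibble sorted by animal and time. Exact duplicate rows are
#' dropped; duplicate timestamps within an animal are resolved by keeping the
#' fix with the best Argos location class (order G > 3 > 2 > 1 > 0 > A > B > Z),
#' then the first occurrence — deterministic ingestion.
#'
#' @param path CSV file path.
#' @param dialect Named character vector mapping the canonical column names
#'   `id`, `timestamp`, `lon`, `lat`, and optionally `loc_class`, `source`, to
#'   the column names used in the file, e.g.
#'   `c(id = "ptt", timestamp = "date")`. Columns already canonically named
#'   need no entry.
#' @return A tibble with columns `animal_id` (character), `t` (POSIXct, UTC),
#'   `lon`, `lat` (double), `loc_class` (character, one of G,3,2,1,0,A,B,Z),
#'   `source` (`"argos"` or `"gps"`), plus any label columns
#'   (`migration`, `mode`, `phase`) present in the file. An empty file yields
#'   an empty tibble.
#' @export
read_track_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) return(empty_track())
  canon <- c(id = "animal_id", timestamp = "timestamp", lon = "lon", lat = "lat",
             loc_class = "loc_class", source = "source")
  for (key in names(canon)) {
    from <- if (!is.null(dialect) && key %in% names(dialect)) dialect[[key]] else canon[[key]]
    if (from %in% names(raw) && from != canon[[key]]) {
      names(raw)[names(raw) == from] <- canon[[key]]
    }
  }
  req <- c("animal_id", "timestamp", "lon", "lat")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  t <- parse_timestamp(raw$timestamp)
  if (anyNA(t)) {
    abort(paste0("unparseable timestamp at line(s): ",
                 paste(which(is.na(t)) + 1L, collapse = ", ")))
  }
  tr <- tibble::tibble(
    animal_id = raw$animal_id,
    t = t,
    lon = as.numeric(raw$lon),
    lat = as.numeric(raw$lat),
    loc_class = if ("loc_class" %in% names(raw)) raw$loc_class else "G",
    source = if ("source" %in% names(raw)) raw$source else NA_character_
  )
  tr$source[is.na(tr$source)] <- ifelse(tr$loc_class[is.na(tr$source)] == "G", "gps", "argos")
  for (lab in c("migration", "mode", "phase")) {
    if (lab %in% names(raw)) tr[[lab]] <- raw[[lab]]
  }
  if ("migration" %in% names(tr)) tr$migration <- as.logical(tr$migration)
  if ("phase" %in% names(tr)) tr$phase <- as.integer(tr$phase)
  tr <- dplyr::distinct(tr)
  tr$lon <- normalize_lon(tr$lon)
  # duplicate-timestamp tie-break by class quality, then first occurrence
  tr <- tr |>
    dplyr::mutate(.q = match(.data$loc_class, LOC_CLASSES), .row = dplyr::row_number()) |>
    dplyr::arrange(.data$animal_id, .data$t, .data$.q, .data$.row) |>
    dplyr::distinct(.data$animal_id, .data$t, .keep_all = TRUE) |>
    dplyr::select(-".q", -".row")
  check_track(tr)
  tr
}

parse_timestamp <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    return(as.POSIXct(num, origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[lon == 180] <- 180
  out
}

empty_track <- function() {
  tibble::tibble(animal_id = character(), t = as.POSIXct(character(), tz = "UTC"),
                 lon = double(), lat = double(), loc_class = character(),
                 source = character())
}

#' Validate a track tibble
#'
#' Checks the track column contract: required columns present, coordinates in
#' bounds, location classes from the allowed set, and timestamps strictly
#' increasing within each animal (the index of the first offending pair is
#' reported).
#'
#' @param track A track tibble.
#' @return `track`, invisibly; errors describe the violation.
#' @export
check_track <- function(track) {
  req <- c("animal_id", "t", "lon", "lat")
  miss <- setdiff(req, names(track))
  if (length(miss) > 0) abort(paste0("track is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(track) > 0) {
    check_lonlat(track$lon, track$lat)
    if ("loc_class" %in% names(track)) {
      bad <- !track$loc_class %in% LOC_CLASSES
      if (any(bad)) abort(paste0("invalid location class: ",
                                 paste(unique(track$loc_class[bad]), collapse = ", ")))
    }
    for (id in unique(track$animal_id)) {
      tt <- track$t[track$animal_id == id]
      d <- diff(as.numeric(tt))
      if (any(d <= 0)) {
        abort(sprintf("non-increasing timestamps for animal %s at fix index %d",
                      id, which(d <= 0)[1] + 1L))
      }
    }
  }
  invisible(track)
}

#' Write tracking data to CSV
#'
#' Inverse of [read_track_csv()]: ISO-8601 UTC timestamps, full float
#' precision, label columns (`migration`, `mode`, `phase`) written when
#' present.
#'
#' @param track A track tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  check_track(track)
  out <- track
  out$timestamp <- format(out$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  keep <- c("animal_id", "timestamp", "lon", "lat", "loc_class", "source",
            intersect(c("migration", "mode", "phase", "kd"), names(out)))
  keep <- intersect(keep, names(out))
  readr::write_csv(out[keep], path, progress = FALSE)
  invisible(path)
}

#' Construct a gridded environmental field
#'
#' A regular lon/lat raster of one environmental variable, optionally
#' time-indexed. Values are stored as an array `[time, lat, lon]`; missing
#' cells are `NA`.
#'
#' @param name Variable name: one of `kd490`, `sst`, `bathymetry`,
#'   `current_u`, `current_v`, `slope` (free names allowed).
#' @param lon_edges,lat_edges Strictly increasing cell-boundary coordinates
#'   (length = number of cells + 1).
#' @param values Numeric array. A matrix `[lat, lon]` is promoted to a single
#'   time slice; otherwise dimensions must be `[time, lat, lon]`.
#' @param times Optional POSIXct vector, one per time slice.
#' @param units Unit string; defaulted from `name` where conventional
#'   (Kd: 1/m; SST: degC; bathymetry: m positive down; currents: m/s).
#' @param time_step `"monthly"`, `"daily"`, or `NA` to infer from `times`
#'   spacing (>= 28 days mean spacing reads as monthly).
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(name, lon_edges, lat_edges, values, times = NULL,
                       units = NULL, time_step = NA) {
  stopifnot(is.numeric(lon_edges), is.numeric(lat_edges))
  if (any(diff(lon_edges) <= 0) || any(diff(lat_edges) <= 0)) {
    abort("grid edges must be strictly increasing")
  }
  if (is.matrix(values)) values <- array(values, dim = c(1L, dim(values)))
  if (length(dim(values)) != 3) abort("values must be [time, lat, lon] or [lat, lon]")
  nlat <- length(lat_edges) - 1L
  nlon <- length(lon_edges) - 1L
  if (dim(values)[2] != nlat || dim(values)[3] != nlon) {
    abort(sprintf("value array %s inconsistent with axes (%d lat x %d lon cells)",
                  paste(dim(values), collapse = "x"), nlat, nlon))
  }
  if (!is.null(times)) {
    if (length(times) != dim(values)[1]) abort("length(times) must match the time dimension")
    times <- as.POSIXct(times, tz = "UTC")
  } else if (dim(values)[1] > 1) {
    abort("multi-slice values need a times vector")
  }
  if (is.null(units)) {
    units <- c(kd490 = "1/m", sst = "degC", bathymetry = "m (positive down)",
               current_u = "m/s", current_v = "m/s", slope = "degrees")[name]
    if (is.na(units)) units <- ""
  }
  if (is.na(time_step) && !is.null(times) && length(times) > 1) {
    time_step <- if (mean(diff(as.numeric(times))) >= 28 * 86400) "monthly" else "daily"
  }
  structure(list(name = name, lon_edges = as.numeric(lon_edges),
                 lat_edges = as.numeric(lat_edges), times = times,
                 values = values, units = unname(units),
                 time_step = if (is.na(time_step)) NULL else time_step),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_field> %s [%s]: %d time slice(s), %d x %d cells, %d missing\n",
              x$name, x$units, d[1], d[2], d[3], sum(is.na(x$values))))
  invisible(x)
}

# cell-centre coordinate helpers
lon_centers <- function(field) (field$lon_edges[-1] + head(field$lon_edges, -1)) / 2
lat_centers <- function(field) (field$lat_edges[-1] + head(field$lat_edges, -1)) / 2

#' Read / write gridded fields
#'
#' Plain-text JSON exchange format for [grid_field()] objects: cell-edge
#' vectors, optional ISO-8601 time vector, and a flat value vector with its
#' dimensions (missing cells serialised as `null`). Round-trips at machine
#' precision.
#'
#' @param path File path.
#' @param name Optional name override on read.
#' @return `read_grid_field()` returns a `grid_field`; `write_grid_field()`
#'   returns `path` invisibly.
#' @export
read_grid_field <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- as.numeric(obj$values)
  if (length(vals) != prod(obj$dim)) {
    abort(sprintf("value block length %d does not match dim %s",
                  length(vals), paste(obj$dim, collapse = "x")))
  }
  times <- if (!is.null(obj$times)) as.POSIXct(obj$times, tz = "UTC",
                                               format = "%Y-%m-%dT%H:%M:%SZ") else NULL
  grid_field(name = name %||% obj$name,
             lon_edges = obj$lon_edges, lat_edges = obj$lat_edges,
             values = array(vals, dim = obj$dim), times = times,
             units = obj$units,
             time_step = obj$time_step %||% NA)
}

#' @rdname read_grid_field
#' @param field A `grid_field` object.
#' @export
write_grid_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  obj <- list(
    name = field$name, units = field$units,
    lon_edges = field$lon_edges, lat_edges = field$lat_edges,
    times = if (!is.null(field$times)) format(field$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    time_step = field$time_step,
    dim = dim(field$values), values = as.vector(field$values)
  )
  # I(17) significant digits: doubles round-trip bit-exactly through text
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read / write a coastline polyline table
#'
#' @param path CSV with columns `polyline_id`, `vertex_index`, `lon`, `lat`;
#'   vertices ordered within each polyline.
#' @return A coastline tibble.
#' @export
read_coastline <- function(path) {
  co <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("polyline_id", "vertex_index", "lon", "lat")
  miss <- setdiff(req, names(co))
  if (length(miss) > 0) abort(paste0("coastline file missing column(s): ",
                                     paste(miss, collapse = ", ")))
  dplyr::arrange(co, .data$polyline_id, .data$vertex_index)
}

#' @rdname read_coastline
#' @param coast A coastline tibble.
#' @export
write_coastline <- function(coast, path) {
  readr::write_csv(coast, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
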