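#' Interpolate a track at regular along-path spacing
#'
#' Linearly interpolates the path at a target spacing (default 1 km) along
#' the great circle of each raw segment, while retaining every raw fix so no
#' data are lost. A raw segment of length L km is subdivided into
#' `ceiling(L / spacing)` equal sub-arcs; inserted points carry timestamps
#' linear in along-path distance within the segment.
#'
#' @param track A single-animal track tibble (>= 2 fixes).
#' @param spacing_km Target spacing in km (> 0).
#' @return A tibble with columns `lon`, `lat`, `t`, `is_raw`.
#' @export
interpolate_path <- function(track, spacing_km = 1) {
  check_track(track)
  one_animal(track)
  if (nrow(track) < 2) abort("need at least 2 fixes to interpolate")
  stopifnot(spacing_km > 0)
  n <- nrow(track)
  segs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    L <- haversine_km(track$lon[i], track$lat[i], track$lon[i + 1], track$lat[i + 1])
    m <- max(1L, ceiling(L / spacing_km - 1e-9))
    f <- seq_len(m - 1L) / m
    if (length(f) > 0) {
      p <- gc_interp(track$lon[i], track$lat[i], track$lon[i + 1], track$lat[i + 1], f)
      tt <- track$t[i] + f * as.numeric(difftime(track$t[i + 1], track$t[i], units = "secs"))
      segs[i] <- list(tibble::tibble(lon = p$lon, lat = p$lat, t = tt, is_raw = FALSE))
    }
  }
  raw <- tibble::tibble(lon = track$lon, lat = track$lat, t = track$t, is_raw = TRUE)
  out <- dplyr::bind_rows(
    purrr::map(seq_len(n - 1L), function(i) dplyr::bind_rows(raw[i, ], segs[[i]])),
    raw[n, ]
  )
  out
}

# spherical linear interpolation between two lon/lat points at fractions f
gc_interp <- function(lon1, lat1, lon2, lat2, f) {
  to_xyz <- function(lon, lat) {
    lon <- lon * pi / 180; lat <- lat * pi / 180
    c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  }
  a <- to_xyz(lon1, lat1); b <- to_xyz(lon2, lat2)
  omega <- acos(pmin(pmax(sum(a * b), -1), 1))
  if (omega < 1e-12) {
    return(list(lon = rep(lon1, length(f)), lat = rep(lat1, length(f))))
  }
  sa <- sin((1 - f) * omega) / sin(omega)
  sb <- sin(f * omega) / sin(omega)
  x <- sa * a[1] + sb * b[1]
  y <- sa * a[2] + sb * b[2]
  z <- sa * a[3] + sb * b[3]
  list(lon = atan2(y, x) * 180 / pi, lat = asin(pmin(pmax(z, -1), 1)) * 180 / pi)
}

one_animal <- function(track) {
  if ("animal_id" %in% names(track) && length(unique(track$animal_id)) > 1) {
    abort("this operation works on one animal at a time; split the track first")
  }
  invisible(track)
}

# Core FPT computation at one path point for a sorted radius vector.
# Walks outward from point i in both time directions to the first positions
# at distance > r; crossing times are interpolated linearly in
# distance-to-centre between the bracketing path points. NA where a walk
# reaches a track end while still inside the circle.
fpt_point_core <- function(lon, lat, tsec, i, radii) {
  n <- length(lon)
  d <- haversine_km(lon[i], lat[i], lon, lat)
  out <- rep(NA_real_, length(radii))
  if (i == n || i == 1L) return(out)
  # forward walk
  dv <- d[(i + 1L):n]
  cmf <- cummax(dv)
  posf <- findInterval(radii, cmf) + 1L     # first index in dv with cummax > r
  okf <- posf <= length(dv)
  # backward walk
  dvb <- d[(i - 1L):1L]
  cmb <- cummax(dvb)
  posb <- findInterval(radii, cmb) + 1L
  okb <- posb <= length(dvb)
  ok <- okf & okb
  if (!any(ok)) return(out)
  kf <- i + posf[ok]                         # first exceedance, absolute index
  kb <- i - posb[ok]
  r <- radii[ok]
  tf <- tsec[kf - 1L] + (r - d[kf - 1L]) / (d[kf] - d[kf - 1L]) * (tsec[kf] - tsec[kf - 1L])
  tb <- tsec[kb + 1L] + (r - d[kb + 1L]) / (d[kb] - d[kb + 1L]) * (tsec[kb] - tsec[kb + 1L])
  out[ok] <- tf - tb
  out
}

#' First passage time at a single path point
#'
#' The time the animal takes to cross a circle of radius `r` centred on path
#' point `i`: the interval between the (interpolated) backward and forward
#' crossing times of the circle boundary. Undefined (`NA`) when the path ends
#' before leaving the circle in either direction.
#'
#' @param path An interpolated path (see [interpolate_path()]).
#' @param i Path point index.
#' @param r Radius in km (> 0).
#' @return FPT in seconds, or `NA` if undefined.
#' @export
fpt_at_point <- function(path, i, r) {
  stopifnot(r > 0, i >= 1, i <= nrow(path))
  fpt_point_core(path$lon, path$lat, as.numeric(path$t), i, r)
}

#' First-passage-time profile over a radius grid
#'
#' Computes FPT at every path point for every radius. Within each point's
#' row, FPT is non-decreasing in the radius wherever defined.
#'
#' @param path An interpolated path.
#' @param radii Positive, strictly increasing radii in km.
#' @return An object of class `fpt_profile`: a list with `radii`, `fpt`
#'   (matrix points x radii, seconds, `NA` = undefined), `t`, `is_raw`.
#' @export
fpt_profile <- function(path, radii) {
  if (length(radii) == 0) abort("empty radius grid")
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    abort("radii must be positive and strictly increasing")
  }
  n <- nrow(path)
  tsec <- as.numeric(path$t)
  fpt <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    fpt[i, ] <- fpt_point_core(path$lon, path$lat, tsec, i, radii)
  }
  structure(list(radii = radii, fpt = fpt, t = path$t, is_raw = path$is_raw),
            class = "fpt_profile")
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("<fpt_profile> %d points x %d radii [%g, %g] km; %.1f%% defined\n",
              nrow(x$fpt), length(x$radii), min(x$radii), max(x$radii),
              100 * mean(!is.na(x$fpt))))
  invisible(x)
}

#' Variance-of-log-FPT spectrum
#'
#' The variance of `log(FPT)` across path points, per radius (sample
#' variance, n - 1 denominator), computed over points with defined FPT.
#' A peak marks the spatial scale of area-restricted search. Radii with
#' fewer than 3 defined values get a missing variance.
#'
#' @param profile An [fpt_profile()].
#' @return A tibble of class `fpt_spectrum` with columns `radius_km`,
#'   `var_log_fpt`, `n_defined`.
#' @export
variance_spectrum <- function(profile) {
  stopifnot(inherits(profile, "fpt_profile"))
  nd <- colSums(!is.na(profile$fpt))
  v <- vapply(seq_along(profile$radii), function(k) {
    x <- profile$fpt[, k]
    x <- x[!is.na(x)]
    if (length(x) < 3) NA_real_ else var(log(x))
  }, numeric(1))
  if (all(is.na(v))) abort("FPT undefined at every radius; track too short for this radius grid")
  out <- tibble::tibble(radius_km = profile$radii, var_log_fpt = v,
                        n_defined = as.integer(nd))
  class(out) <- c("fpt_spectrum", class(out))
  out
}

#' Select the area-restricted-search spatial scale
#'
#' The radius at the global maximum of the variance-of-log-FPT spectrum.
#' Ties break toward the smaller radius (the analysis targets the smallest
#' foraging scale). Returns `NA` when the maximum variance is zero (no
#' heterogeneity, e.g. straight transit at constant speed).
#'
#' @param spectrum An `fpt_spectrum` tibble.
#' @return The selected radius in km, or `NA` if no scale stands out.
#' @export
select_ars_scale <- function(spectrum) {
  v <- spectrum$var_log_fpt
  if (all(is.na(v))) abort("spectrum has no defined variance at any radius")
  vmax <- max(v, na.rm = TRUE)
  if (vmax <= 1e-12) return(NA_real_) # numerically homogeneous FPT: no ARS scale
  spectrum$radius_km[which(v == vmax)[1]]  # radii ascending: first hit = smallest
}
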