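#' Fill missing raster cells by inverse distance weighting
#'
#' Estimates every missing cell of a gridded field as the inverse-distance
#' weighted mean of its `k_neighbors` nearest observed cells,
#' `sum(w_i z_i) / sum(w_i)` with `w_i = d_i^-power`, where `d_i` is the
#' great-circle distance between cell centres. Observed cells are left
#' untouched, so the interpolator is exact at the data. Time slices are
#' filled independently.
#'
#' @param field A [grid_field()] with at least one non-missing cell per slice.
#' @param power IDW exponent (default 2).
#' @param k_neighbors Number of nearest observed cells used (default 8).
#' @return The field with no missing cells.
#' @export
idw_interpolate <- function(field, power = 2, k_neighbors = 8) {
  stopifnot(inherits(field, "grid_field"))
  lc <- lon_centers(field); la <- lat_centers(field)
  grid <- expand.grid(lat = la, lon = lc) # row-major over [lat, lon] slices
  nt <- dim(field$values)[1]
  for (s in seq_len(nt)) {
    z <- as.vector(field$values[s, , ])
    obs <- which(!is.na(z))
    mis <- which(is.na(z))
    if (length(obs) == 0) abort("all cells missing: nothing to interpolate from")
    if (length(mis) == 0) next
    for (m in mis) {
      d <- haversine_km(grid$lon[m], grid$lat[m], grid$lon[obs], grid$lat[obs])
      k <- min(k_neighbors, length(obs))
      nn <- order(d)[seq_len(k)]
      w <- d[nn]^(-power)
      z[m] <- if (any(!is.finite(w))) mean(z[obs][nn][!is.finite(w)]) else
        sum(w * z[obs][nn]) / sum(w)
    }
    field$values[s, , ] <- z
  }
  field
}

#' Seafloor slope from bathymetry
#'
#' Per-cell slope in degrees, `atan(sqrt(gx^2 + gy^2))`, with gradients from
#' Horn's 3x3 weighted finite differences. Cell sizes are converted to
#' metres, the east-west size scaled by cos(latitude) of the cell row. Border
#' cells use one-sided first differences.
#'
#' @param bathy A single-slice bathymetry [grid_field()] (m, positive down).
#' @return A `slope` [grid_field()] on the same grid (degrees).
#' @export
slope_from_bathymetry <- function(bathy) {
  stopifnot(inherits(bathy, "grid_field"))
  if (dim(bathy$values)[1] != 1) abort("slope needs a single-time bathymetry grid")
  z <- bathy$values[1, , ]
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) abort("grid must be at least 3 x 3")
  la <- lat_centers(bathy); lc <- lon_centers(bathy)
  m_per_deg <- pi * EARTH_RADIUS_KM * 1000 / 180
  dy <- diff(la)[1] * m_per_deg                    # meridional cell size, m
  dx_row <- diff(lc)[1] * m_per_deg * cos(la * pi / 180) # zonal size per row
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # Horn weights: (z[ne] + 2 z[e] + z[se] - z[nw] - 2 z[w] - z[sw]) / (8 dx)
  gx[i, j] <- (z[i + 1, j + 1] + 2 * z[i, j + 1] + z[i - 1, j + 1] -
               z[i + 1, j - 1] - 2 * z[i, j - 1] - z[i - 1, j - 1]) / (8 * dx_row[i])
  gy[i, j] <- (z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1] -
               z[i - 1, j - 1] - 2 * z[i - 1, j] - z[i - 1, j + 1]) / (8 * dy)
  # one-sided borders
  gx[, 1] <- (z[, 2] - z[, 1]) / dx_row
  gx[, nc] <- (z[, nc] - z[, nc - 1]) / dx_row
  gy[1, ] <- (z[2, ] - z[1, ]) / dy
  gy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / dy
  gy[2:(nr - 1), 1] <- (z[3:nr, 1] - z[1:(nr - 2), 1]) / (2 * dy)
  gy[2:(nr - 1), nc] <- (z[3:nr, nc] - z[1:(nr - 2), nc]) / (2 * dy)
  gx[1, 2:(nc - 1)] <- (z[1, 3:nc] - z[1, 1:(nc - 2)]) / (2 * dx_row[1])
  gx[nr, 2:(nc - 1)] <- (z[nr, 3:nc] - z[nr, 1:(nc - 2)]) / (2 * dx_row[nr])
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  grid_field("slope", bathy$lon_edges, bathy$lat_edges, slope, units = "degrees")
}

#' Extract habitat covariates at fix locations
#'
#' Samples each supplied environmental field at every fix, carrying any mode
#' and phase labels through, producing the per-fix covariate table used in
#' foraging-vs-transiting habitat comparisons.
#'
#' @param track A track tibble (optionally with `mode` / `phase` columns).
#' @param fields Named list of gap-filled [grid_field()]s, e.g.
#'   `list(kd = ..., sst = ..., bathy = ..., slope = ...)`.
#' @return `track` with one numeric column per field.
#' @export
extract_covariates <- function(track, fields) {
  check_track(track)
  stopifnot(is.list(fields), !is.null(names(fields)))
  out <- track
  for (nm in names(fields)) {
    f <- fields[[nm]]
    out[[nm]] <- sample_field(f, track$lon, track$lat,
                              t = if (dim(f$values)[1] > 1) track$t else NULL)
  }
  out
}

#' Compare a covariate between transiting and foraging fixes
#'
#' Two-sample comparison of one environmental variable between the `NoARS`
#' (transiting) and `ARS` (foraging) modes. Each group is first gated through
#' a Shapiro-Wilk normality test at alpha = 0.05: if either group departs
#' from normality the Wilcoxon-Mann-Whitney rank-sum test is used, otherwise
#' a two-sample t-test. The report records which branch ran.
#'
#' @param covariates A covariate table (see [extract_covariates()]) with a
#'   `mode` column.
#' @param variable Name of the covariate column to compare.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A one-row tibble: group sizes, means, SDs, `test`
#'   (`"wilcoxon"` or `"t"`), `statistic`, `p_value`, and the two
#'   Shapiro-Wilk p-values.
#' @export
compare_modes <- function(covariates, variable, alpha = 0.05) {
  stopifnot(all(c("mode", variable) %in% names(covariates)))
  a <- covariates[[variable]][covariates$mode == "NoARS"]
  b <- covariates[[variable]][covariates$mode == "ARS"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("both modes must be present with n >= 3 each")
  }
  sw <- function(x) { # constant samples are trivially non-normal
    if (sd(x) == 0) return(0)
    shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)$p.value
  }
  sw_a <- sw(a)
  sw_b <- sw(b)
  if (sw_a < alpha || sw_b < alpha) {
    rs <- rank_sum_test(a, b)
    test <- "wilcoxon"; statistic <- rs$statistic; p <- rs$p_value
  } else {
    tt <- t.test(a, b)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(
    variable = variable,
    n_transiting = length(a), n_foraging = length(b),
    mean_transiting = mean(a), sd_transiting = sd(a),
    mean_foraging = mean(b), sd_foraging = sd(b),
    test = test, statistic = statistic, p_value = p,
    shapiro_p_transiting = sw_a, shapiro_p_foraging = sw_b
  )
}
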