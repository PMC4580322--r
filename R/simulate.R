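#' Configuration for the synthetic study system
#'
#' Parameters of the synthetic migration system used to validate the
#' pipeline: a two-regime movement process (fast, directed transit along a
#' meridional coast; slow, tortuous area-restricted search inside a terminal
#' foraging patch), an alongshore counter-current jet with a Gaussian
#' cross-shore profile, a turbid river-plume patch in the Kd490 field, a
#' linear shelf bathymetry ramp, and tag-like observation: fixes at
#' exponential intervals with Argos-class-dependent Gaussian position noise.
#'
#' Default magnitudes echo a shelf migration of a few thousand km at ~0.5-1
#' m/s against a ~0.5 m/s boundary current peaking ~100 km offshore, with a
#' foraging patch of 15 km radius.
#'
#' @param seed Integer RNG seed; a fixed seed makes every simulate_* output
#'   reproducible.
#' @param n_fixes Number of observed fixes (default 600, spanning ~7 weeks at
#'   the default 2-h mean interval: a multi-week foraging residence is needed
#'   for first passage times at patch-scale radii to be observable).
#' @param mean_dt Mean fix interval, hours (default 2).
#' @param dt_exponential Exponential fix intervals (default TRUE); FALSE
#'   gives regular intervals of exactly `mean_dt`.
#' @param transit_speed,ars_speed Through-water speeds, m/s (0.8, 0.2).
#' @param turn_sd_transit,turn_sd_ars Turning-angle SD per step, rad
#'   (0.2, 1.2).
#' @param coast_lon Longitude of the straight meridional coast (ocean to the
#'   east).
#' @param start_lat,start_offshore_km Release point.
#' @param patch_center `c(lon, lat)` of the foraging patch, or `NULL` for a
#'   patchless (pure transit) system.
#' @param patch_radius Foraging patch radius, km (default 15).
#' @param noise_sd_by_class Per-class isotropic position noise SD, m.
#' @param class_probs Sampling weights of the Argos/GPS location classes.
#' @param current_peak_speed Jet peak speed, m/s (default 0.5, flowing north,
#'   i.e. opposing the southward transit).
#' @param offshore_peak_km Cross-shore position of the jet core, km (100).
#' @param jet_width_km Gaussian cross-shore SD of the jet, km (50).
#' @param plume_center `c(lon, lat)` of the turbidity plume blob.
#' @param plume_sigma_km Gaussian SD of the plume, km (80).
#' @param kd_peak,kd_background Plume peak amplitude above background and
#'   background Kd490, 1/m (0.6, 0.05).
#' @param shelf_slope Bathymetry ramp, m of depth per km offshore (1).
#' @param step_dt_s Behavioural process time step, s (default 14400 = 4 h):
#'   the interval at which headings are redrawn, which together with the
#'   turning-angle SDs sets the persistence of transit and the mixing rate of
#'   the area-restricted search inside the patch.
#' @param dive_depth_median,dive_depth_sdlog Lognormal max-depth parameters
#'   per regime, m (transit 30, foraging 18; foraging dives are shallower).
#' @param dive_duration_median,dive_duration_sdlog Lognormal max-duration
#'   parameters per regime, min (transit 20, foraging 35; foraging dives are
#'   longer).
#' @param dives_per_period Mean dives per 4-h period (Poisson, 25).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_fixes = 600L,
                       mean_dt = 2,
                       dt_exponential = TRUE,
                       transit_speed = 0.8,
                       ars_speed = 0.2,
                       turn_sd_transit = 0.2,
                       turn_sd_ars = 1.2,
                       coast_lon = -50,
                       start_lat = 5,
                       start_offshore_km = 20,
                       patch_center = c(-49.75, -1.3),
                       patch_radius = 15,
                       noise_sd_by_class = c(G = 50, `3` = 250, `2` = 500, `1` = 1500,
                                             `0` = 5000, A = 8000, B = 15000, Z = 15000),
                       class_probs = c(G = 0.60, `3` = 0.10, `2` = 0.10, `1` = 0.10,
                                       `0` = 0.04, A = 0.03, B = 0.02, Z = 0.01),
                       current_peak_speed = 0.5,
                       offshore_peak_km = 100,
                       jet_width_km = 50,
                       plume_center = c(-49.7, 2),
                       plume_sigma_km = 80,
                       kd_peak = 0.6,
                       kd_background = 0.05,
                       shelf_slope = 1,
                       step_dt_s = 14400,
                       dive_depth_median = c(transit = 30, foraging = 18),
                       dive_depth_sdlog = c(transit = 0.4, foraging = 0.35),
                       dive_duration_median = c(transit = 20, foraging = 35),
                       dive_duration_sdlog = c(transit = 0.4, foraging = 0.35),
                       dives_per_period = 25) {
  stopifnot(transit_speed > 0, ars_speed > 0, patch_radius > 0, mean_dt > 0,
            n_fixes >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

# local planar coordinates (km east/north of coast_lon, start_lat)
sim_to_lonlat <- function(cfg, x_km, y_km) {
  lat <- cfg$start_lat + y_km / KM_PER_DEG
  lon <- cfg$coast_lon + x_km / (KM_PER_DEG * cos(lat * pi / 180))
  list(lon = lon, lat = lat)
}
sim_from_lonlat <- function(cfg, lon, lat) {
  y <- (lat - cfg$start_lat) * KM_PER_DEG
  x <- (lon - cfg$coast_lon) * KM_PER_DEG * cos(lat * pi / 180)
  list(x = x, y = y)
}

# analytic environmental fields in planar km coordinates
sim_current <- function(cfg, x_km) { # northward jet, Gaussian cross-shore
  v <- cfg$current_peak_speed *
    exp(-(x_km - cfg$offshore_peak_km)^2 / (2 * cfg$jet_width_km^2))
  list(u = rep(0, length(v)), v = v)
}
sim_kd <- function(cfg, x_km, y_km) {
  pc <- sim_from_lonlat(cfg, cfg$plume_center[1], cfg$plume_center[2])
  d2 <- (x_km - pc$x)^2 + (y_km - pc$y)^2
  cfg$kd_background + cfg$kd_peak * exp(-d2 / (2 * cfg$plume_sigma_km^2))
}
sim_depth <- function(cfg, x_km) { # m, positive down; negative = land
  ifelse(x_km >= 0, cfg$shelf_slope * x_km, -10)
}

#' Simulate a two-regime migration track with ground truth
#'
#' Simulates a biased correlated random walk alongshore (transit regime) that
#' switches permanently to area-restricted search on first entry into the
#' foraging patch (slow, tortuous, reflectively confined within the patch
#' radius). Each internal step is advected by the alongshore current jet.
#' The process is observed at exponential (or regular) fix intervals with
#' class-dependent Gaussian position noise.
#'
#' @param cfg A [sim_config()].
#' @param t0 Start time (POSIXct, default 2014-03-01 00:00 UTC).
#' @param animal_id Animal identifier (default `"sim1"`).
#' @return A list with `track` (observed track tibble) and `truth` (tibble:
#'   per-fix true position `lon_true`, `lat_true`, `regime`
#'   (`"transit"`/`"ars"`), `phase` (1/2/3, `NA` in the ars regime), plus
#'   attributes-free columns), and scalars `patch_entry_time` (POSIXct or
#'   `NA`) carried as an attribute of `truth`.
#' @export
simulate_track <- function(cfg, t0 = as.POSIXct("2014-03-01", tz = "UTC"),
                           animal_id = "sim1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # observation times
  gaps <- if (cfg$dt_exponential) {
    pmax(60, rexp(cfg$n_fixes - 1, rate = 1 / (cfg$mean_dt * 3600)))
  } else rep(cfg$mean_dt * 3600, cfg$n_fixes - 1)
  obs_t <- c(0, cumsum(gaps))
  horizon <- obs_t[length(obs_t)]

  has_patch <- !is.null(cfg$patch_center)
  if (has_patch) {
    pc <- sim_from_lonlat(cfg, cfg$patch_center[1], cfg$patch_center[2])
    goal <- c(pc$x, pc$y)
  } else {
    goal <- c(cfg$start_offshore_km, -1e6) # due south, far away
  }

  dt <- cfg$step_dt_s
  n_steps <- ceiling(horizon / dt) + 1L
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- cfg$start_offshore_km; y[1] <- 0
  regime <- character(n_steps + 1); regime[1] <- "transit"
  dev <- 0 # heading deviation from the goal bearing (AR(1))
  entry_t <- NA_real_
  for (s in seq_len(n_steps)) {
    in_ars <- regime[s] == "ars"
    if (!in_ars && has_patch &&
        sqrt((x[s] - goal[1])^2 + (y[s] - goal[2])^2) <= cfg$patch_radius) {
      in_ars <- TRUE
      entry_t <- (s - 1) * dt
    }
    if (in_ars) {
      dev <- dev + rnorm(1, 0, cfg$turn_sd_ars)
      hd <- atan2(goal[1] - x[s], goal[2] - y[s]) + dev
      sp <- cfg$ars_speed
    } else {
      dev <- 0.8 * dev + rnorm(1, 0, cfg$turn_sd_transit)
      hd <- atan2(goal[1] - x[s], goal[2] - y[s]) + dev
      sp <- cfg$transit_speed
    }
    cur <- sim_current(cfg, x[s])
    step_km <- (c(sp * sin(hd) + cur$u, sp * cos(hd) + cur$v)) * dt / 1000
    nx <- x[s] + step_km[1]; ny <- y[s] + step_km[2]
    if (in_ars) { # reflective confinement within the patch
      dpatch <- sqrt((nx - goal[1])^2 + (ny - goal[2])^2)
      if (dpatch > cfg$patch_radius) {
        scl <- (2 * cfg$patch_radius - dpatch) / dpatch
        scl <- max(scl, 0.1)
        nx <- goal[1] + (nx - goal[1]) * scl
        ny <- goal[2] + (ny - goal[2]) * scl
      }
    }
    if (nx < 1) nx <- 1 # stay off the beach
    x[s + 1] <- nx; y[s + 1] <- ny
    regime[s + 1] <- if (in_ars) "ars" else "transit"
  }
  proc_t <- (0:n_steps) * dt

  # observe: interpolate the process at fix times, add class noise
  xi <- stats::approx(proc_t, x, xout = obs_t)$y
  yi <- stats::approx(proc_t, y, xout = obs_t)$y
  reg_i <- regime[pmin(findInterval(obs_t, proc_t), n_steps + 1L)]
  cls <- sample(names(cfg$class_probs), cfg$n_fixes, replace = TRUE,
                prob = cfg$class_probs)
  nsd <- cfg$noise_sd_by_class[cls] / 1000 # km
  xo <- xi + rnorm(cfg$n_fixes, 0, nsd)
  yo <- yi + rnorm(cfg$n_fixes, 0, nsd)
  ll_true <- sim_to_lonlat(cfg, xi, yi)
  ll_obs <- sim_to_lonlat(cfg, xo, yo)
  tt <- t0 + obs_t
  track <- tibble::tibble(
    animal_id = animal_id, t = tt, lon = ll_obs$lon, lat = ll_obs$lat,
    loc_class = cls, source = ifelse(cls == "G", "gps", "argos")
  )
  # true phases on transit fixes from the analytic plume
  phase <- rep(NA_integer_, cfg$n_fixes)
  trans <- which(reg_i == "transit")
  kd_true <- sim_kd(cfg, xi[trans], yi[trans])
  inplume <- kd_true >= 0.15
  if (any(inplume)) {
    rng <- range(which(inplume))
    phase[trans] <- ifelse(seq_along(trans) < rng[1], 1L,
                           ifelse(seq_along(trans) > rng[2], 3L, 2L))
  } else {
    phase[trans] <- 1L
  }
  truth <- tibble::tibble(
    animal_id = animal_id, t = tt,
    lon_true = ll_true$lon, lat_true = ll_true$lat,
    regime = ifelse(reg_i == "ars", "ars", "transit"),
    phase = phase
  )
  attr(truth, "patch_entry_time") <- if (is.na(entry_t)) as.POSIXct(NA, tz = "UTC") else
    t0 + entry_t
  list(track = track, truth = truth)
}

#' Simulate the gridded environmental fields and coastline
#'
#' Builds the synthetic study seascape on regular lon/lat grids: an
#' alongshore counter-current jet (`current_u`, `current_v`) with a Gaussian
#' cross-shore profile peaking `offshore_peak_km` off the coast, a Kd490
#' field of a clear background plus a Gaussian turbid plume blob, a linear
#' shelf bathymetry ramp (land west of the coast), and the straight
#' meridional coastline polyline.
#'
#' @param cfg A [sim_config()].
#' @param cell_deg Grid resolution in degrees (default 0.05; currents at
#'   0.25).
#' @param lat_range,lon_range Domain bounds (defaults sized to the transit
#'   corridor).
#' @return A list: `kd`, `bathymetry`, `current_u`, `current_v`
#'   ([grid_field()]s) and `coast` (coastline tibble).
#' @export
simulate_fields <- function(cfg, cell_deg = 0.05,
                            lat_range = c(cfg$start_lat - 8, cfg$start_lat + 1),
                            lon_range = c(cfg$coast_lon - 0.5, cfg$coast_lon + 3.5)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$patch_center)) {
    if (cfg$patch_center[1] < lon_range[1] || cfg$patch_center[1] > lon_range[2] ||
        cfg$patch_center[2] < lat_range[1] || cfg$patch_center[2] > lat_range[2]) {
      abort("foraging patch lies outside the field domain")
    }
  }
  mk_axes <- function(step) {
    list(lon = seq(lon_range[1], lon_range[2], by = step),
         lat = seq(lat_range[1], lat_range[2], by = step))
  }
  fill_field <- function(name, axes, fun) {
    lc <- (axes$lon[-1] + head(axes$lon, -1)) / 2
    la <- (axes$lat[-1] + head(axes$lat, -1)) / 2
    g <- expand.grid(lat = la, lon = lc)
    p <- sim_from_lonlat(cfg, g$lon, g$lat)
    vals <- matrix(fun(p$x, p$y), nrow = length(la), ncol = length(lc))
    grid_field(name, axes$lon, axes$lat, vals)
  }
  ax_f <- mk_axes(cell_deg)
  ax_c <- mk_axes(0.25)
  kd <- fill_field("kd490", ax_f, function(x, y) sim_kd(cfg, x, y))
  bathy <- fill_field("bathymetry", ax_f, function(x, y) sim_depth(cfg, x))
  cu <- fill_field("current_u", ax_c, function(x, y) sim_current(cfg, x)$u)
  cv <- fill_field("current_v", ax_c, function(x, y) sim_current(cfg, x)$v)
  coast_lat <- seq(lat_range[1], lat_range[2], by = 0.5)
  coast <- tibble::tibble(polyline_id = 1L, vertex_index = seq_along(coast_lat),
                          lon = cfg$coast_lon, lat = coast_lat)
  list(kd = kd, bathymetry = bathy, current_u = cu, current_v = cv, coast = coast)
}

#' Simulate 4-hour dive-histogram records
#'
#' Draws, for each 4-hour period spanned by the simulated track, a Poisson
#' number of dives with regime-dependent lognormal maximum depth and maximum
#' duration (foraging dives shallower and longer than transit dives by
#' default), bins them per [dive_bin_scheme()], and builds duration-weighted
#' TAD and TAT percent vectors normalised to 100.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` tibble from [simulate_track()].
#' @return A list with `records` (histogram tibble) and `truth` (tibble:
#'   `period_start`, `regime`).
#' @export
simulate_dive_histograms <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000003L)
  scheme <- dive_bin_scheme()
  t0 <- min(truth$t)
  starts <- seq(from = t0, to = max(truth$t), by = 4 * 3600)
  tt <- as.numeric(truth$t)
  recs <- vector("list", length(starts))
  reg_out <- character(length(starts))
  for (i in seq_along(starts)) {
    mid <- as.numeric(starts[i]) + 2 * 3600
    reg <- truth$regime[which.min(abs(tt - mid))]
    regk <- if (reg == "ars") "foraging" else "transit"
    reg_out[i] <- regk
    nd <- rpois(1, cfg$dives_per_period)
    if (nd == 0) nd <- 1L
    depth <- rlnorm(nd, log(cfg$dive_depth_median[[regk]]), cfg$dive_depth_sdlog[[regk]])
    dur <- rlnorm(nd, log(cfg$dive_duration_median[[regk]]), cfg$dive_duration_sdlog[[regk]])
    dur <- pmin(dur, 59.9)
    temp <- rnorm(nd, 28, 1.5)
    dbin <- pmin(findInterval(depth, c(0, scheme$depth_edges), left.open = TRUE),
                 length(scheme$depth_edges))
    ubin <- pmin(findInterval(dur, c(0, scheme$duration_edges), left.open = TRUE),
                 length(scheme$duration_edges))
    tbin <- pmin(pmax(findInterval(temp, c(-Inf, scheme$temp_edges), left.open = TRUE), 1),
                 length(scheme$temp_edges))
    dcounts <- tabulate(dbin, length(scheme$depth_edges))
    ucounts <- tabulate(ubin, length(scheme$duration_edges))
    tad <- vapply(seq_along(scheme$depth_edges),
                  function(b) sum(dur[dbin == b]), numeric(1))
    tad <- tad / sum(tad) * 100
    tat <- vapply(seq_along(scheme$temp_edges),
                  function(b) sum(dur[tbin == b]), numeric(1))
    tat <- tat / sum(tat) * 100
    row <- c(list(animal_id = truth$animal_id[1], period_start = starts[i]),
             setNames(as.list(dcounts), scheme$depth_cols),
             setNames(as.list(ucounts), scheme$duration_cols),
             setNames(as.list(tad), scheme$tad_cols),
             setNames(as.list(tat), scheme$tat_cols))
    recs[[i]] <- tibble::as_tibble(row)
  }
  list(records = dplyr::bind_rows(recs),
       truth = tibble::tibble(period_start = starts, regime = reg_out))
}
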