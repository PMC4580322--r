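# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (plain loops, closed forms, exhaustive enumeration) and share no code
# with the package internals they check.

T0 <- as.POSIXct("2014-03-01", tz = "UTC")
KM_DEG <- pi * 6371 / 180 # km per degree of great-circle arc

# straight equatorial track moving east at `speed` m/s, fixes every dt_s
straight_track <- function(n = 60, speed = 1, dt_s = 3600, id = "st1") {
  tibble::tibble(
    animal_id = id,
    t = T0 + (0:(n - 1)) * dt_s,
    lon = (0:(n - 1)) * (speed * dt_s / 1000) / KM_DEG,
    lat = 0,
    loc_class = "G", source = "gps"
  )
}

# independent great-circle distance: spherical law of cosines
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(pmax(d, -1), 1))
}

# plain-loop brute-force FPT on an explicit path (independent of the
# package's vectorised implementation)
brute_fpt <- function(lon, lat, tsec, i, r) {
  n <- length(lon)
  cross <- function(dir) {
    j <- i
    repeat {
      j2 <- j + dir
      if (j2 < 1 || j2 > n) return(NA_real_)
      d2 <- slc_km(lon[i], lat[i], lon[j2], lat[j2])
      if (d2 > r) {
        d1 <- slc_km(lon[i], lat[i], lon[j], lat[j])
        return(tsec[j] + (r - d1) / (d2 - d1) * (tsec[j2] - tsec[j]))
      }
      j <- j2
    }
  }
  fw <- cross(1L); bw <- cross(-1L)
  if (is.na(fw) || is.na(bw)) NA_real_ else fw - bw
}

# exhaustive minimum-contrast segmentation for K <= 3 (oracle for the DP)
exhaustive_lavielle <- function(y, K, Lmin) {
  n <- length(y)
  sse <- function(a, b) { v <- y[a:b]; sum((v - mean(v))^2) }
  if (K == 1) return(list(J = sse(1, n), ends = n))
  best <- Inf; ends <- NULL
  if (K == 2) {
    for (c1 in Lmin:(n - Lmin)) {
      J <- sse(1, c1) + sse(c1 + 1, n)
      if (J < best) { best <- J; ends <- c(c1, n) }
    }
  } else if (K == 3) {
    for (c1 in Lmin:(n - 2 * Lmin)) {
      for (c2 in (c1 + Lmin):(n - Lmin)) {
        J <- sse(1, c1) + sse(c1 + 1, c2) + sse(c2 + 1, n)
        if (J < best) { best <- J; ends <- c(c1, c2, n) }
      }
    }
  }
  list(J = best, ends = ends)
}

# exact two-sided rank-sum p by full enumeration of group assignments
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  U_all <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - n * (n + 1) / 2
  })
  mu <- n * length(b) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu))
}

# outward spiral traversed at constant speed, plus a 10-m densified copy for
# brute-force FPT oracles; returns list(path, dense)
spiral_fixture <- function(speed = 0.5, n = 400) {
  th <- seq(0, 6 * pi, length.out = n)
  r_km <- 0.5 + 0.4 * th
  lon <- r_km * cos(th) / KM_DEG
  lat <- r_km * sin(th) / KM_DEG
  seg <- slc_km(lon[-1], lat[-1], lon[-n], lat[-n])
  tsec <- c(0, cumsum(seg * 1000 / speed))
  dl <- list(lon = numeric(0), lat = numeric(0), t = numeric(0))
  for (s in seq_along(seg)) {
    m <- max(2, ceiling(seg[s] / 0.01))
    f <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    dl$lon <- c(dl$lon, lon[s] + f * (lon[s + 1] - lon[s]))
    dl$lat <- c(dl$lat, lat[s] + f * (lat[s + 1] - lat[s]))
    dl$t <- c(dl$t, tsec[s] + f * (tsec[s + 1] - tsec[s]))
  }
  list(path = tibble::tibble(lon = lon, lat = lat, t = T0 + tsec, is_raw = TRUE),
       dense = dl)
}

# small single-slice grid field with a linear gradient a + bx*lon + by*lat
gradient_field <- function(name = "sst", lon_edges = seq(0, 1, by = 0.1),
                           lat_edges = seq(0, 1, by = 0.1),
                           a = 10, bx = 2, by = 3) {
  lc <- (lon_edges[-1] + head(lon_edges, -1)) / 2
  la <- (lat_edges[-1] + head(lat_edges, -1)) / 2
  vals <- outer(la, lc, function(y, x) a + bx * x + by * y)
  grid_field(name, lon_edges, lat_edges, vals)
}
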