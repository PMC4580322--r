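test_that("haversine agrees with closed forms and an independent formula", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  expect_equal(haversine_km(0, 0, 1, 0), pi * 6371 / 180, tolerance = 1e-12)
  expect_error(haversine_km(0, 95, 0, 0), "out of bounds")

  withr::local_seed(11)
  lon1 <- runif(100, -180, 180); lat1 <- runif(100, -85, 85)
  lon2 <- runif(100, -180, 180); lat2 <- runif(100, -85, 85)
  d1 <- haversine_km(lon1, lat1, lon2, lat2)
  d2 <- slc_km(lon1, lat1, lon2, lat2)
  expect_lt(max(abs(d1 - d2) / pmax(d2, 1e-6)), 1e-6)
})

test_that("haversine satisfies the triangle inequality on random triples", {
  withr::local_seed(12)
  for (i in 1:50) {
    p <- matrix(c(runif(3, -170, 170), runif(3, -80, 80)), ncol = 2)
    ab <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    ac <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("step metrics recover speed, bearing and velocity components", {
  tr <- tibble::tibble(animal_id = "a", t = T0 + c(0, 3600),
                       lon = c(0, 3.6 / KM_DEG), lat = 0,
                       loc_class = "G", source = "gps")
  sm <- step_metrics(tr)
  expect_equal(sm$observed_speed, 1.0, tolerance = 1e-9)
  expect_equal(sm$bearing, 90, tolerance = 1e-6)
  expect_equal(sm$gv_east, 1.0, tolerance = 1e-6)
  expect_equal(sm$gv_north, 0.0, tolerance = 1e-6)

  # due north step
  tr$lon <- c(0, 0); tr$lat <- c(0, 3.6 / KM_DEG)
  sm <- step_metrics(tr)
  expect_equal(sm$bearing, 0, tolerance = 1e-6)
  expect_equal(sm$gv_north, 1.0, tolerance = 1e-6)
})

test_that("step distances sum to the polyline length", {
  withr::local_seed(13)
  n <- 20
  tr <- tibble::tibble(animal_id = "a", t = T0 + (0:(n - 1)) * 3600,
                       lon = cumsum(runif(n, -0.1, 0.1)),
                       lat = cumsum(runif(n, -0.1, 0.1)),
                       loc_class = "G", source = "gps")
  sm <- step_metrics(tr)
  oracle <- sum(slc_km(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1]))
  expect_equal(sum(sm$distance_km), oracle, tolerance = 1e-6)
})

test_that("distance to a straight meridional coast is the perpendicular offset", {
  coast <- tibble::tibble(polyline_id = 1L, vertex_index = 1:5,
                          lon = 0, lat = seq(-2, 2))
  p_lon <- 10 / (KM_DEG * cos(0.5 * pi / 180))
  d <- distance_to_coast_km(p_lon, 0.5, coast)
  expect_equal(d, 10, tolerance = 0.01)
  expect_equal(distance_to_coast_km(0, 1, coast), 0, tolerance = 1e-9)
  expect_error(distance_to_coast_km(0, 0, coast[0, ]), "empty")
})

test_that("distance to a curved coast matches a densified brute-force minimum", {
  th <- seq(0, pi / 2, length.out = 25)
  coast <- tibble::tibble(polyline_id = 1L, vertex_index = seq_along(th),
                          lon = cos(th), lat = sin(th))
  # densify each segment at ~10 m spacing and take the vertex minimum
  withr::local_seed(14)
  for (i in 1:10) {
    p <- c(runif(1, 0.1, 1.4), runif(1, 0.1, 1.4))
    dd <- numeric(0)
    for (s in seq_len(nrow(coast) - 1)) {
      L <- slc_km(coast$lon[s], coast$lat[s], coast$lon[s + 1], coast$lat[s + 1])
      f <- seq(0, 1, length.out = max(2, ceiling(L / 0.01)))
      lons <- coast$lon[s] + f * (coast$lon[s + 1] - coast$lon[s])
      lats <- coast$lat[s] + f * (coast$lat[s + 1] - coast$lat[s])
      dd <- c(dd, min(slc_km(p[1], p[2], lons, lats)))
    }
    expect_equal(distance_to_coast_km(p[1], p[2], coast), min(dd),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})

test_that("field sampling uses half-open cells and honours the time axis", {
  g <- grid_field("sst", c(0, 1, 2), c(0, 1, 2), matrix(5, 2, 2))
  expect_equal(sample_field(g, 0.5, 0.5), 5)
  # cell-edge point belongs to the larger-index cell
  g2 <- grid_field("sst", c(0, 1, 2), c(0, 1, 2),
                   matrix(c(1, 3, 2, 4), 2, 2)) # [lat, lon]
  expect_equal(sample_field(g2, 1, 0.5), 2)  # lon edge -> second lon cell
  expect_equal(sample_field(g2, 0.5, 1), 3)  # lat edge -> second lat cell
  expect_error(sample_field(g2, 2.5, 0.5), "outside")

  # monthly matching picks the slice whose month contains t
  vals <- array(c(1, 2), dim = c(2, 1, 1))
  gm <- grid_field("kd490", c(0, 1), c(0, 1), vals,
                   times = as.POSIXct(c("2014-03-01", "2014-04-01"), tz = "UTC"))
  expect_equal(gm$time_step, "monthly")
  expect_equal(sample_field(gm, 0.5, 0.5, as.POSIXct("2014-04-20", tz = "UTC")), 2)
})

test_that("gradient-field sampling matches direct index arithmetic", {
  g <- gradient_field()
  withr::local_seed(15)
  lon <- runif(50, 0, 0.999); lat <- runif(50, 0, 0.999)
  got <- sample_field(g, lon, lat)
  ix <- floor(lon / 0.1) + 1; iy <- floor(lat / 0.1) + 1
  expected <- 10 + 2 * (ix - 0.5) * 0.1 + 3 * (iy - 0.5) * 0.1
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("current correction subtracts the drift vector", {
  st <- tibble::tibble(gv_east = 0.5, gv_north = 0)
  out <- swimming_velocity(st, -0.4, 0)
  expect_equal(out$swim_east, 0.9)
  expect_equal(out$swim_speed, 0.9)
  # pure drift
  out <- swimming_velocity(tibble::tibble(gv_east = 0.3, gv_north = -0.2), 0.3, -0.2)
  expect_equal(out$swim_speed, 0)
})

test_that("swimming speed equals the component-norm oracle and obeys its bounds", {
  withr::local_seed(16)
  n <- 100
  st <- tibble::tibble(gv_east = rnorm(n), gv_north = rnorm(n))
  u <- rnorm(n); v <- rnorm(n)
  out <- swimming_velocity(st, u, v)
  oracle <- sqrt((st$gv_east - u)^2 + (st$gv_north - v)^2)
  expect_equal(out$swim_speed, oracle, tolerance = 1e-12)
  gs <- sqrt(st$gv_east^2 + st$gv_north^2)
  cs <- sqrt(u^2 + v^2)
  expect_true(all(out$swim_speed >= abs(gs - cs) - 1e-12))
  expect_true(all(out$swim_speed <= gs + cs + 1e-12))
})
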