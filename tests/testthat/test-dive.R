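make_records <- function(n = 4, id = "a") {
  scheme <- dive_bin_scheme()
  base <- tibble::tibble(animal_id = id,
                         period_start = T0 + (0:(n - 1)) * 4 * 3600)
  for (col in c(scheme$depth_cols, scheme$duration_cols)) base[[col]] <- 0
  for (col in scheme$tad_cols) base[[col]] <- 0
  for (col in scheme$tat_cols) base[[col]] <- 0
  base$d20 <- 10; base$u20 <- 10
  base$tad20 <- 100; base$tat28 <- 100
  base
}

test_that("the bin scheme is contiguous and strictly increasing", {
  s <- dive_bin_scheme()
  expect_true(all(diff(s$depth_edges) > 0))
  expect_true(all(diff(s$duration_edges) > 0))
  expect_true(all(diff(s$temp_edges) > 0))
  expect_equal(length(s$depth_cols), length(s$depth_edges))
  expect_equal(length(s$duration_cols), length(s$duration_edges))
  # the 5-10 min bin bridges the minute-resolution and 10-minute blocks
  expect_true(all(c(5, 10) %in% s$duration_edges))
})

test_that("histogram parsing validates the scheme and percent normalisation", {
  recs <- make_records()
  f <- withr::local_tempfile(fileext = ".csv")
  write_histograms(recs, f)
  back <- parse_histograms(f)
  expect_equal(back$tad20, rep(100, 4))
  expect_equal(as.numeric(back$period_start), as.numeric(recs$period_start))
  expect_equal(back$d20, recs$d20)

  bad <- recs; bad$tad20[2] <- 93
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_histograms(bad, f2)
  expect_error(parse_histograms(f2), "sum to 100")

  expect_error(validate_histograms <- parse_histograms(
    { f3 <- withr::local_tempfile(fileext = ".csv")
      readr::write_csv(recs[, 1:10], f3); f3 }), "bin scheme")
})

test_that("records are split at the foraging onset (closed lower bound)", {
  recs <- make_records(n = 6)
  tr <- tibble::tibble(animal_id = "a", t = T0 + (0:23) * 3600,
                       lon = 0, lat = 0, loc_class = "G", source = "gps",
                       mode = "NoARS",
                       phase = rep(c(1L, 2L, 3L), each = 8))
  onset <- recs$period_start[3]
  out <- assign_mode_phase(recs, tr, onset)
  expect_equal(out$mode, c("transiting", "transiting", rep("foraging", 4)))
  expect_true(all(is.na(out$phase[out$mode == "foraging"])))
  expect_equal(out$phase[1:2], c(1L, 1L))

  # no onset: everything transits
  out2 <- assign_mode_phase(recs, tr, as.POSIXct(NA, tz = "UTC"))
  expect_true(all(out2$mode == "transiting"))

  # records outside the track span are flagged NA with a warning
  recs_out <- make_records(n = 2)
  recs_out$period_start <- recs_out$period_start + 365 * 86400
  expect_warning(out3 <- assign_mode_phase(recs_out, tr, onset), "outside")
  expect_true(all(is.na(out3$mode)))
  expect_equal(attr(out3, "n_outside"), 2L)
})

test_that("mode labels match a direct timestamp comparison on simulated records", {
  cfg <- sim_config(seed = 71, n_fixes = 300)
  sim <- simulate_track(cfg)
  dh <- simulate_dive_histograms(cfg, sim$truth)
  tr <- sim$track
  tr$mode <- ifelse(sim$truth$regime == "ars", "ARS", "NoARS")
  tr$phase <- sim$truth$phase
  onset <- attr(sim$truth, "patch_entry_time")
  out <- suppressWarnings(assign_mode_phase(dh$records, tr, onset))
  inside <- out$period_start >= min(tr$t) & out$period_start <= max(tr$t)
  want <- ifelse(out$period_start[inside] >= onset, "foraging", "transiting")
  expect_equal(out$mode[inside], want)
})

test_that("delaying the onset never converts transiting records to foraging", {
  recs <- make_records(n = 10)
  tr <- tibble::tibble(animal_id = "a", t = T0 + (0:39) * 3600,
                       lon = 0, lat = 0, loc_class = "G", source = "gps",
                       mode = "NoARS", phase = 1L)
  o1 <- assign_mode_phase(recs, tr, recs$period_start[4])$mode
  o2 <- assign_mode_phase(recs, tr, recs$period_start[7])$mode
  expect_true(all(!(o1 == "transiting" & o2 == "foraging")))
})

test_that("dive summaries use bin-share and midpoint conventions", {
  recs <- make_records(n = 3)
  recs$mode <- "transiting"
  s <- summarize_dives(recs, "mode")
  depth <- s$shares[s$shares$variable == "max_depth_m", ]
  expect_equal(depth$share[depth$bin == "d20"], 1)
  expect_equal(sum(depth$share), 1)
  summ <- s$summary[s$summary$variable == "max_depth_m", ]
  expect_equal(summ$mean, 15) # midpoint of the 10-20 m bin
  expect_equal(summ$sd, 0)

  # two equal bins -> shares 0.5/0.5
  recs$d30 <- 10
  s2 <- summarize_dives(recs, "mode")
  d2 <- s2$shares[s2$shares$variable == "max_depth_m", ]
  expect_equal(sort(d2$share[d2$share > 0]), c(0.5, 0.5))
})

test_that("group shares match a hand tally and conserve the grand total", {
  cfg <- sim_config(seed = 72, n_fixes = 400)
  sim <- simulate_track(cfg)
  dh <- simulate_dive_histograms(cfg, sim$truth)
  recs <- dh$records
  recs$mode <- ifelse(dh$truth$regime == "foraging", "foraging", "transiting")
  s <- summarize_dives(recs, "mode")
  scheme <- dive_bin_scheme()
  for (grp in unique(recs$mode)) {
    tal <- colSums(recs[recs$mode == grp, scheme$depth_cols])
    want <- unname(tal / sum(tal))
    got <- s$shares[s$shares$group == grp & s$shares$variable == "max_depth_m", ]
    expect_equal(got$share[match(scheme$depth_cols, got$bin)], want)
    expect_equal(sum(got$share), 1, tolerance = 1e-12)
  }
  # grand tally conservation across groups
  expect_equal(sum(s$summary$n_dives[s$summary$variable == "max_depth_m"]),
               sum(as.matrix(recs[scheme$depth_cols])))
})
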