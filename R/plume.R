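#' Sample water turbidity (Kd490) along a track
#'
#' Extracts the diffuse attenuation coefficient at 490 nm at every fix from a
#' (typically monthly) gridded field. Cells missing in the field (cloud
#' cover, failed atmospheric correction) are filled first with
#' [idw_interpolate()], so every fix receives a value.
#'
#' @param track A track tibble.
#' @param kd A `kd490` [grid_field()].
#' @param ... Passed to [idw_interpolate()] when the field has missing cells.
#' @return `track` with a numeric `kd` column (1/m).
#' @export
extract_kd_along_track <- function(track, kd, ...) {
  check_track(track)
  if (any(is.na(kd$values))) kd <- idw_interpolate(kd, ...)
  track$kd <- sample_field(kd, track$lon, track$lat,
                           t = if (dim(kd$values)[1] > 1) track$t else NULL)
  track
}

#' Delineate the plume-crossing phases of a transiting track
#'
#' Splits the transiting portion of a migration into three phases from the
#' turbidity record along the track: before (1), within (2) and after (3) the
#' river plume. Candidate plume fixes have `kd >= kd_threshold`; candidate
#' runs separated by fewer than `min_run` clear fixes are merged, and phase 2
#' is the longest merged run of at least `min_run` fixes (ties to the
#' earliest). Fixes in foraging mode (`mode == "ARS"`) keep phase `NA`: the
#' phases describe the transit only. With no qualifying run, every transiting
#' fix is phase 1 and the time within the plume is zero.
#'
#' @param track A track tibble with a `kd` column (see
#'   [extract_kd_along_track()]) and optionally a `mode` column.
#' @param kd_threshold Turbidity threshold in 1/m separating plume from clear
#'   water (default 0.15, between typical clear-water foraging and in-plume
#'   transit values).
#' @param min_run Minimum run length in fixes for a plume crossing
#'   (default 3); also the merging gap.
#' @return An object of class `phase_assignment`: list with `track` (input
#'   plus integer `phase` column), `entry`, `exit` (POSIXct bounds of phase
#'   2, `NA` if none) and `time_phase2_days`.
#' @export
segment_phases <- function(track, kd_threshold = 0.15, min_run = 3) {
  check_track(track)
  one_animal(track)
  stopifnot("kd" %in% names(track))
  transiting <- if ("mode" %in% names(track)) track$mode != "ARS" else rep(TRUE, nrow(track))
  if (!any(transiting)) abort("no transiting fixes: phases are defined for the transit only")
  idx <- which(transiting)
  cand <- track$kd[idx] >= kd_threshold
  run <- plume_run(cand, min_run)
  phase <- rep(NA_integer_, nrow(track))
  if (is.null(run)) {
    phase[idx] <- 1L
    entry <- exit <- as.POSIXct(NA, tz = "UTC")
    tp2 <- 0
  } else {
    phase[idx] <- ifelse(seq_along(idx) < run[1], 1L,
                         ifelse(seq_along(idx) > run[2], 3L, 2L))
    entry <- track$t[idx[run[1]]]
    exit <- track$t[idx[run[2]]]
    tp2 <- as.numeric(difftime(exit, entry, units = "days"))
  }
  out <- track
  out$phase <- phase
  structure(list(track = out, entry = entry, exit = exit, time_phase2_days = tp2,
                 kd_threshold = kd_threshold, min_run = min_run),
            class = "phase_assignment")
}

# longest merged candidate run of length >= min_run; returns c(start, end)
# positions in the candidate vector, or NULL
plume_run <- function(cand, min_run) {
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) return(NULL)
  # merge candidate runs separated by gaps < min_run
  merged <- list()
  cur <- c(starts[runs[1]], ends[runs[1]])
  for (j in runs[-1]) {
    gap <- starts[j] - cur[2] - 1L
    if (gap < min_run) cur[2] <- ends[j]
    else { merged[[length(merged) + 1L]] <- cur; cur <- c(starts[j], ends[j]) }
  }
  merged[[length(merged) + 1L]] <- cur
  lens <- vapply(merged, function(m) m[2] - m[1] + 1L, integer(1))
  ok <- lens >= min_run
  if (!any(ok)) return(NULL)
  merged[ok][[which.max(lens[ok])]]
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("<phase_assignment> phases 1/2/3: %d/%d/%d fixes; time in plume %.2f days\n",
              sum(x$track$phase == 1, na.rm = TRUE), sum(x$track$phase == 2, na.rm = TRUE),
              sum(x$track$phase == 3, na.rm = TRUE), x$time_phase2_days))
  invisible(x)
}

#' @export
tidy.phase_assignment <- function(x, ...) x$track

#' @export
glance.phase_assignment <- function(x, ...) {
  tibble::tibble(entry = x$entry, exit = x$exit,
                 time_phase2_days = x$time_phase2_days,
                 kd_threshold = x$kd_threshold)
}

#' Per-phase movement summary table
#'
#' Mean and SD of distance to shore, observed speed, current-corrected
#' swimming speed and current velocity, per migration phase and over the
#' whole migration — the standard summary layout for a plume-crossing
#' migration. Speeds are per-step quantities attributed to the step's start
#' fix; distance to shore is a per-fix quantity.
#'
#' @param track A track tibble with a `phase` column (see
#'   [segment_phases()]).
#' @param coast Coastline tibble.
#' @param current_u,current_v Current-component [grid_field()]s (m/s).
#' @return A tibble with columns `variable`, `phase` (`"1"`, `"2"`, `"3"`,
#'   `"all"`), `mean`, `sd`, `n`. Phases with no data are absent rather than
#'   zero-filled.
#' @export
phase_summaries <- function(track, coast, current_u, current_v) {
  check_track(track)
  stopifnot("phase" %in% names(track))
  steps <- step_metrics(track)
  # attribute step rows to the start fix; currents sampled at the start fix
  start_idx <- match(paste(steps$animal_id, as.numeric(steps$t)),
                     paste(track$animal_id, as.numeric(track$t)))
  u <- sample_field(current_u, steps$lon, steps$lat,
                    t = if (dim(current_u$values)[1] > 1) steps$t else NULL)
  v <- sample_field(current_v, steps$lon, steps$lat,
                    t = if (dim(current_v$values)[1] > 1) steps$t else NULL)
  steps <- swimming_velocity(steps, u, v)
  steps$phase <- track$phase[start_idx]
  fix_tbl <- tibble::tibble(
    variable = "distance_to_shore_km", phase = as.character(track$phase),
    value = distance_to_coast_km(track$lon, track$lat, coast)
  )
  step_tbl <- dplyr::bind_rows(
    tibble::tibble(variable = "observed_speed_ms", phase = as.character(steps$phase),
                   value = steps$observed_speed),
    tibble::tibble(variable = "swimming_speed_ms", phase = as.character(steps$phase),
                   value = steps$swim_speed),
    tibble::tibble(variable = "current_speed_ms", phase = as.character(steps$phase),
                   value = steps$current_speed)
  )
  all_tbl <- dplyr::bind_rows(fix_tbl, step_tbl)
  per_phase <- all_tbl |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::group_by(.data$variable, .data$phase) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  overall <- all_tbl |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(phase = "all")
  dplyr::bind_rows(per_phase, overall) |>
    dplyr::arrange(.data$variable, .data$phase)
}
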