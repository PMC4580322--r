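#' Label the migration phase with a daily-speed filter
#'
#' Marks each fix as migratory when the daily travel rate exceeds the
#' threshold (default 30 km/day, strict). The daily speed of fix i is the
#' great-circle distance from the previous fix divided by the elapsed time,
#' scaled to km/day; the first fix of each animal inherits the label of the
#' second.
#'
#' @param track A track tibble.
#' @param daily_speed_threshold Threshold in km/day (> 0).
#' @return `track` with a logical `migration` column.
#' @export
label_migration <- function(track, daily_speed_threshold = 30) {
  check_track(track)
  stopifnot(daily_speed_threshold > 0)
  track |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) abort(paste0("track ", key$animal_id, " has fewer than 2 fixes"))
      n <- nrow(df)
      d <- haversine_km(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1])
      dt_days <- as.numeric(difftime(df$t[-1], df$t[-n], units = "days"))
      v <- d / dt_days
      df$migration <- c(v[1] > daily_speed_threshold, v > daily_speed_threshold)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("animal_id")
}

new_filter_report <- function(n_input, removed) {
  rep <- tibble::tibble(rule = names(removed), n_removed = unname(as.integer(removed)))
  structure(list(n_input = as.integer(n_input),
                 n_output = as.integer(n_input - sum(rep$n_removed)),
                 removed = rep),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in -> %d out\n", x$n_input, x$n_output))
  print(x$removed)
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$removed

#' Remove implausible positions
#'
#' Applies the position plausibility filters in a fixed order, each fix being
#' charged to the first rule that rejects it: (1) on land — bathymetry
#' (positive down) at the fix is negative, i.e. above sea level; (2) Argos
#' location class Z; (3) instantaneous speed from the previously retained fix
#' exceeds the cap (greedy forward pass, re-evaluated after each removal).
#'
#' @param track A track tibble.
#' @param bathy Bathymetry [grid_field()] (m, positive down) used for the
#'   land test, or `NULL` to skip it.
#' @param speed_cap Maximum plausible speed, km/h (default 10).
#' @param drop_class_z Drop class-Z fixes (default `TRUE`).
#' @return A list with `track` (the retained fixes) and `report`
#'   (a `filter_report` whose counts reconcile: n_input = n_output + removals).
#' @export
apply_plausibility_filters <- function(track, bathy = NULL, speed_cap = 10,
                                       drop_class_z = TRUE) {
  check_track(track)
  stopifnot(speed_cap > 0)
  n_input <- nrow(track)
  removed <- c(on_land = 0L, class_Z = 0L, speed_cap = 0L)

  if (!is.null(bathy)) {
    depth <- sample_field(bathy, track$lon, track$lat)
    on_land <- !is.na(depth) & depth < 0
    removed["on_land"] <- sum(on_land)
    track <- track[!on_land, , drop = FALSE]
  }
  if (drop_class_z && "loc_class" %in% names(track)) {
    z <- track$loc_class == "Z"
    removed["class_Z"] <- sum(z)
    track <- track[!z, , drop = FALSE]
  }
  track <- track |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- speed_cap_pass(df, speed_cap)
      removed["speed_cap"] <<- removed[["speed_cap"]] + sum(!keep)
      df[keep, , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("animal_id")
  if (nrow(track) == 0) abort("all fixes removed: empty track after filtering")
  list(track = track, report = new_filter_report(n_input, removed))
}

# greedy forward pass: drop the later fix of an offending pair, re-evaluate
speed_cap_pass <- function(df, speed_cap) {
  n <- nrow(df)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  last <- 1L
  for (i in 2:n) {
    d <- haversine_km(df$lon[last], df$lat[last], df$lon[i], df$lat[i])
    dt_h <- as.numeric(difftime(df$t[i], df$t[last], units = "hours"))
    if (d / dt_h > speed_cap) keep[i] <- FALSE else last <- i
  }
  keep
}

#' Drop dive records deeper than the plausibility cap
#'
#' Removes 4-hour histogram records whose deepest occupied maximum-depth bin
#' lies beyond the cap (default 100 m), where pressure-sensor depths and
#' shelf bathymetry diverge substantially. Optionally also drops records
#' whose deepest occupied bin's lower edge exceeds the local water depth at
#' the matched fix by more than a tolerance.
#'
#' @param records Dive-histogram tibble (see [parse_histograms()]).
#' @param max_depth_cap Depth cap in m: a record is dropped when any count
#'   sits in a bin whose upper edge exceeds the cap.
#' @param bathy,track Optional bathymetry field and track for the
#'   bathymetry-plausibility check (record matched to nearest-in-time fix).
#' @param bathy_tol_m Tolerance for that check, m (default 10).
#' @return A list with `records` and `report` (a `filter_report`).
#' @export
filter_depth_records <- function(records, max_depth_cap = 100,
                                 bathy = NULL, track = NULL, bathy_tol_m = 10) {
  scheme <- dive_bin_scheme()
  dcols <- scheme$depth_cols
  stopifnot(all(dcols %in% names(records)))
  n_input <- nrow(records)
  removed <- c(depth_cap = 0L, bathy_implausible = 0L)
  if (n_input > 0) {
    deepest <- deepest_occupied_edge(records, scheme)
    over <- !is.na(deepest) & deepest > max_depth_cap
    removed["depth_cap"] <- sum(over)
    records <- records[!over, , drop = FALSE]
    if (!is.null(bathy) && !is.null(track) && nrow(records) > 0) {
      idx <- vapply(as.numeric(records$period_start), function(x) {
        which.min(abs(as.numeric(track$t) - x))
      }, integer(1))
      depth_here <- sample_field(bathy, track$lon[idx], track$lat[idx])
      lower_edge <- deepest_lower_edge(records, scheme)
      bad <- !is.na(lower_edge) & !is.na(depth_here) &
        lower_edge > depth_here + bathy_tol_m
      removed["bathy_implausible"] <- sum(bad)
      records <- records[!bad, , drop = FALSE]
    }
  }
  list(records = records, report = new_filter_report(n_input, removed))
}

deepest_occupied_edge <- function(records, scheme) {
  m <- as.matrix(records[scheme$depth_cols])
  apply(m, 1, function(r) {
    occ <- which(r > 0)
    if (length(occ) == 0) NA_real_ else scheme$depth_edges[max(occ)]
  })
}

deepest_lower_edge <- function(records, scheme) {
  lower <- c(0, head(scheme$depth_edges, -1))
  m <- as.matrix(records[scheme$depth_cols])
  apply(m, 1, function(r) {
    occ <- which(r > 0)
    if (length(occ) == 0) NA_real_ else lower[max(occ)]
  })
}
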