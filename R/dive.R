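#' The tag's 4-hour histogram bin scheme
#'
#' Bin layout transmitted by the tags: per-dive maximum depth every 10 m from
#' 10 to 100 m then every 50 m to 250 m; maximum duration at 30 s, 1 min,
#' every minute to 5 min, a single 5-10 min bin, then every 10 min to 60 min;
#' water temperature every degree from 20 to 32 C. Edges are bin upper
#' bounds; the first bin starts at 0 (depth, duration) or below 20 C (temp).
#'
#' @return A list with `depth_edges` (m), `duration_edges` (min),
#'   `temp_edges` (degC), `period_hours`, the column-name vectors
#'   (`depth_cols`, `duration_cols`, `tad_cols`, `tat_cols`) and midpoint
#'   vectors (`depth_mid`, `duration_mid`).
#' @export
dive_bin_scheme <- function() {
  depth_edges <- c(seq(10, 100, by = 10), 150, 200, 250)
  duration_edges <- c(0.5, 1, 2, 3, 4, 5, 10, 20, 30, 40, 50, 60)
  temp_edges <- 20:32
  mid <- function(edges, lower0 = 0) (c(lower0, head(edges, -1)) + edges) / 2
  list(
    depth_edges = depth_edges,
    duration_edges = duration_edges,
    temp_edges = temp_edges,
    period_hours = 4,
    depth_cols = paste0("d", depth_edges),
    duration_cols = paste0("u", sub("\\.", "_", duration_edges)),
    tad_cols = paste0("tad", depth_edges),
    tat_cols = paste0("tat", temp_edges),
    depth_mid = mid(depth_edges),
    duration_mid = mid(duration_edges)
  )
}

#' Read 4-hour dive-histogram records from CSV
#'
#' One row per 4-hour period: `animal_id`, `period_start`, per-bin dive
#' counts for maximum depth (`d10`..`d250`) and maximum duration
#' (`u0_5`..`u60`), and the time-at-depth (`tad10`..`tad250`) and
#' time-at-temperature (`tat20`..`tat32`) percent vectors. TAD and TAT rows
#' must each sum to 100 +- 0.5 %.
#'
#' @param path CSV file path.
#' @return A validated tibble of records, `period_start` as POSIXct UTC.
#' @export
parse_histograms <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_histograms(df)
}

validate_histograms <- function(df) {
  scheme <- dive_bin_scheme()
  need <- c("animal_id", "period_start", scheme$depth_cols, scheme$duration_cols,
            scheme$tad_cols, scheme$tat_cols)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("histogram table does not match the tag bin scheme; missing: ",
                 paste(head(miss, 8), collapse = ", "),
                 if (length(miss) > 8) " ..." else ""))
  }
  if (!inherits(df$period_start, "POSIXct")) {
    df$period_start <- parse_timestamp(as.character(df$period_start))
  }
  cnt <- as.matrix(df[c(scheme$depth_cols, scheme$duration_cols)])
  if (any(cnt < 0)) abort("negative bin counts")
  for (set in list(scheme$tad_cols, scheme$tat_cols)) {
    s <- rowSums(as.matrix(df[set]))
    bad <- which(abs(s - 100) > 0.5)
    if (length(bad) > 0) {
      abort(sprintf("percent-time bins must sum to 100 +- 0.5; record %d sums to %.2f",
                    bad[1], s[bad[1]]))
    }
  }
  tibble::as_tibble(df)
}

#' @rdname parse_histograms
#' @param records A record tibble.
#' @export
write_histograms <- function(records, path) {
  out <- records
  out$period_start <- format(out$period_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Label dive records with behavioural mode and migration phase
#'
#' Dive histograms carry no per-dive position, so the behavioural mode is
#' inherited from the FPT analysis of the track: a record is `foraging` iff
#' its period starts at or after the foraging onset (all `transiting` when
#' the track shows no foraging). Transiting records additionally receive the
#' plume phase of the nearest-in-time transiting fix; foraging records keep
#' phase `NA`. Records outside the track's time span get `NA` labels and are
#' counted in the `n_outside` attribute (with a warning).
#'
#' @param records Dive-histogram tibble.
#' @param track A track tibble with `mode` and `phase` columns.
#' @param foraging_onset POSIXct onset from [detect_foraging()], or `NA`.
#' @return `records` with `mode` and `phase` columns.
#' @export
assign_mode_phase <- function(records, track, foraging_onset) {
  stopifnot("phase" %in% names(track))
  ts <- records$period_start
  inside <- ts >= min(track$t) & ts <= max(track$t)
  if (any(!inside)) {
    warn(sprintf("%d record(s) outside the track's time span; labels set to NA",
                 sum(!inside)))
  }
  mode <- rep(NA_character_, nrow(records))
  phase <- rep(NA_integer_, nrow(records))
  onset_known <- !is.na(foraging_onset)
  mode[inside] <- if (onset_known) {
    ifelse(ts[inside] >= foraging_onset, "foraging", "transiting")
  } else "transiting"
  trans_idx <- which(!is.na(track$phase))
  if (length(trans_idx) > 0) {
    need <- which(inside & mode == "transiting")
    if (length(need) > 0) {
      tt <- as.numeric(track$t[trans_idx])
      near <- vapply(as.numeric(ts[need]),
                     function(x) trans_idx[which.min(abs(tt - x))], integer(1))
      phase[need] <- track$phase[near]
    }
  }
  out <- records
  out$mode <- mode
  out$phase <- phase
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Summarise dive distributions per group
#'
#' Per-group distributions of maximum dive depth and maximum dive duration:
#' each group's per-bin share of dives (summing to 1), and a mean +- SD
#' computed on bin midpoints weighted by counts (the tags transmit bins, not
#' exact values, so midpoints are an explicit approximation).
#'
#' @param records Labelled dive-histogram tibble (see [assign_mode_phase()]).
#' @param group_by Grouping column: `"mode"` or `"phase"`.
#' @return A list of class `dive_summary`: `shares` (tibble: group, variable,
#'   bin, upper edge, midpoint, n_dives, share) and `summary` (tibble: group,
#'   variable, mean, sd, n_dives, n_records). Empty groups are omitted.
#' @export
summarize_dives <- function(records, group_by = c("mode", "phase")) {
  group_by <- match.arg(group_by)
  stopifnot(group_by %in% names(records))
  scheme <- dive_bin_scheme()
  recs <- records[!is.na(records[[group_by]]), , drop = FALSE]
  per_var <- function(cols, edges, mids, varname) {
    long <- recs |>
      dplyr::select(dplyr::all_of(c(group_by, cols))) |>
      tidyr::pivot_longer(dplyr::all_of(cols), names_to = "bin", values_to = "n") |>
      dplyr::group_by(.data[[group_by]], .data$bin) |>
      dplyr::summarise(n_dives = sum(.data$n), .groups = "drop_last") |>
      dplyr::mutate(share = .data$n_dives / sum(.data$n_dives)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = varname,
                    upper_edge = edges[match(.data$bin, cols)],
                    midpoint = mids[match(.data$bin, cols)]) |>
      dplyr::arrange(.data[[group_by]], .data$upper_edge)
    names(long)[1] <- "group"
    long
  }
  shares <- dplyr::bind_rows(
    per_var(scheme$depth_cols, scheme$depth_edges, scheme$depth_mid, "max_depth_m"),
    per_var(scheme$duration_cols, scheme$duration_edges, scheme$duration_mid,
            "max_duration_min")
  )
  n_rec <- recs |>
    dplyr::count(.data[[group_by]], name = "n_records")
  names(n_rec)[1] <- "group"
  summ <- shares |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(
      mean = sum(.data$share * .data$midpoint),
      sd = sqrt(pmax(0, sum(.data$share * .data$midpoint^2) -
                        sum(.data$share * .data$midpoint)^2)),
      n_dives = sum(.data$n_dives), .groups = "drop"
    ) |>
    dplyr::left_join(n_rec, by = "group")
  summ$group <- as.character(summ$group)
  shares$group <- as.character(shares$group)
  structure(list(shares = shares, summary = summ, group_by = group_by),
            class = "dive_summary")
}

#' @export
print.dive_summary <- function(x, ...) {
  cat(sprintf("<dive_summary> grouped by %s\n", x$group_by))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.dive_summary <- function(x, ...) x$shares

#' @export
glance.dive_summary <- function(x, ...) x$summary

#' @rdname autoplot.fpt_spectrum
#' @export
autoplot.dive_summary <- function(object, ...) {
  ggplot2::ggplot(object$shares,
                  ggplot2::aes(x = factor(.data$upper_edge), y = .data$share,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~.data$variable, scales = "free_x") +
    ggplot2::labs(x = "bin upper edge", y = "share of dives",
                  fill = object$group_by) +
    ggplot2::theme_minimal()
}
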