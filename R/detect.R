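#' Detect foraging (ARS) behaviour along a track
#'
#' End-to-end first-passage-time inference for one animal: interpolate the
#' track at `spacing_km`, compute the FPT profile over the radius grid, select
#' the spatial scale at the variance-of-log-FPT maximum, segment the FPT
#' series at that scale with [lavielle_segment()], classify segments into
#' `NoARS` (transiting) vs `ARS` (foraging), and transfer the per-point modes
#' back to the raw fixes. Path points whose FPT is undefined (near the track
#' ends) inherit the mode of the nearest-in-time defined point.
#'
#' @param track A single-animal, preprocessed (migration-phase) track tibble.
#' @param radii Radius grid in km (default 1-km steps, 1 to 400 km).
#' @param spacing_km Interpolation spacing, km (default 1).
#' @param Lmin,Kmax,alpha Segmentation parameters, see [lavielle_segment()].
#' @return An object of class `ars_fit`: list with `track` (input plus a
#'   `mode` column), `spectrum`, `ars_scale_km` (`NA` if none), `segmentation`
#'   (`NULL` if no scale selected), `foraging_onset` (POSIXct of the first ARS
#'   fix, `NA` if the track shows no foraging), and `profile`.
#' @export
detect_foraging <- function(track, radii = seq(1, 400, by = 1), spacing_km = 1,
                            Lmin = 5, Kmax = 20, alpha = 0.75) {
  check_track(track)
  one_animal(track)
  path <- interpolate_path(track, spacing_km = spacing_km)
  profile <- fpt_profile(path, radii)
  spectrum <- variance_spectrum(profile)
  scale <- select_ars_scale(spectrum)
  n <- nrow(path)
  path_mode <- rep("NoARS", n)
  seg <- NULL
  if (!is.na(scale)) {
    k <- match(scale, profile$radii)
    series <- profile$fpt[, k]
    defined <- which(!is.na(series))
    if (length(defined) >= 2 * Lmin) {
      seg <- classify_modes(
        lavielle_segment(series[defined], Lmin = Lmin, Kmax = Kmax, alpha = alpha)
      )
      path_mode[defined] <- seg$modes
      undef <- which(is.na(series))
      if (length(undef) > 0) { # inherit from nearest-in-time defined point
        tsec <- as.numeric(path$t)
        near <- vapply(undef, function(i) defined[which.min(abs(tsec[defined] - tsec[i]))],
                       integer(1))
        path_mode[undef] <- path_mode[near]
      }
    }
  }
  out <- track
  out$mode <- path_mode[path$is_raw]
  onset <- if (any(out$mode == "ARS")) min(out$t[out$mode == "ARS"]) else
    as.POSIXct(NA, tz = "UTC")
  structure(list(track = out, spectrum = spectrum, ars_scale_km = scale,
                 segmentation = seg, foraging_onset = onset, profile = profile),
            class = "ars_fit")
}

#' @export
print.ars_fit <- function(x, ...) {
  cat(sprintf("<ars_fit> %s: %d fixes, ARS scale %s km, %d ARS fix(es), onset %s\n",
              x$track$animal_id[1], nrow(x$track),
              ifelse(is.na(x$ars_scale_km), "none", format(x$ars_scale_km)),
              sum(x$track$mode == "ARS"),
              ifelse(is.na(x$foraging_onset), "none", format(x$foraging_onset, "%Y-%m-%d %H:%M"))))
  invisible(x)
}

#' @export
tidy.ars_fit <- function(x, ...) x$track

#' @export
glance.ars_fit <- function(x, ...) {
  tibble::tibble(
    animal_id = x$track$animal_id[1],
    n_fixes = nrow(x$track),
    ars_scale_km = x$ars_scale_km,
    n_segments = if (is.null(x$segmentation)) 1L else x$segmentation$K,
    prop_ars = mean(x$track$mode == "ARS"),
    foraging_onset = x$foraging_onset
  )
}

#' Plot methods for FPT results
#'
#' `autoplot.fpt_spectrum` draws the variance-of-log-FPT curve against
#' radius, marking the selected ARS scale; `autoplot.ars_fit` shows the FPT
#' series at the selected scale over time, coloured by mode, with segment
#' means overlaid.
#'
#' @param object An `fpt_spectrum` or `ars_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fpt_spectrum <- function(object, ...) {
  sel <- select_ars_scale(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$radius_km, y = .data$var_log_fpt)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius r (km)", y = "var(log FPT)",
                  title = "FPT variance spectrum") +
    ggplot2::theme_minimal()
  if (!is.na(sel)) {
    p <- p + ggplot2::geom_vline(xintercept = sel, linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname autoplot.fpt_spectrum
#' @export
autoplot.ars_fit <- function(object, ...) {
  if (is.na(object$ars_scale_km)) {
    return(autoplot.fpt_spectrum(object$spectrum))
  }
  k <- match(object$ars_scale_km, object$profile$radii)
  df <- tibble::tibble(t = object$profile$t,
                       fpt_days = object$profile$fpt[, k] / 86400)
  df <- df[!is.na(df$fpt_days), ]
  seg <- object$segmentation
  df$mode <- seg$modes
  segdf <- seg$segments
  segdf$t_start <- df$t[segdf$start]; segdf$t_end <- df$t[segdf$end]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$fpt_days, colour = .data$mode)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_segment(data = segdf,
                          ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                                       y = .data$mean / 86400, yend = .data$mean / 86400),
                          inherit.aes = FALSE, colour = "red") +
    ggplot2::labs(x = NULL, y = sprintf("FPT at r = %g km (days)", object$ars_scale_km),
                  colour = "mode") +
    ggplot2::theme_minimal()
}

#' Map a track coloured by a label column
#'
#' @param track A track tibble.
#' @param colour Name of the column to colour by (default `"mode"` when
#'   present).
#' @param coast Optional coastline tibble drawn as lines.
#' @return A ggplot object.
#' @export
plot_track <- function(track, colour = NULL, coast = NULL) {
  colour <- colour %||% intersect(c("mode", "phase", "migration"), names(track))[1]
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$lon, y = .data$lat))
  if (!is.null(coast)) {
    p <- p + ggplot2::geom_path(data = coast,
                                ggplot2::aes(group = .data$polyline_id),
                                colour = "grey30")
  }
  if (!is.na(colour) && !is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p + ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
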