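## The previously published two-point workflow: transit time of the dye
## front between two hand-picked points and a cylinder volume from the mean
## of five manually measured diameters. Kept as a faithful comparator for
## the continuous 3D workflow.

#' Tubule volume from manually measured diameters
#'
#' The classic stereotyped 2D volume estimate: the tubule is treated as a
#' cylinder whose diameter is the mean of (typically five) manual diameter
#' measurements, `V = pi * (mean(d)/2)^2 * length`.
#'
#' @param diameters_um one or more measured diameters, micrometres.
#' @param length_um distance between the two measurement points along the
#'   tubule, micrometres.
#' @return volume in cubic micrometres.
#' @export
cylinder_volume <- function(diameters_um, length_um) {
  if (length(diameters_um) < 1L || any(diameters_um <= 0) || length_um <= 0)
    stop("diameters and length must be positive", call. = FALSE)
  pi * (mean(diameters_um) / 2)^2 * length_um
}

#' Dye transit time between two measurement points
#'
#' Arrival at each point is the frame of maximum forward difference of the
#' (optionally smoothed) intensity-vs-frame curve — the same maximum-slope
#' arrival estimator the turning-point threshold uses, so the comparison
#' between workflows isolates their structural difference (two points +
#' cylinder versus continuous measurement + 3D volume) rather than a
#' difference in arrival detection.
#'
#' @param curve_a,curve_b intensity over frames at the upstream and
#'   downstream point (equal length, >= 3 frames).
#' @param frame_rate_fps frames per second.
#' @param smooth_window odd moving-average window applied to both curves
#'   before the difference (1 = none).
#' @return transit time in seconds (strictly positive).
#' @export
transit_time <- function(curve_a, curve_b, frame_rate_fps,
                         smooth_window = 1L) {
  if (length(curve_a) != length(curve_b) || length(curve_a) < 3L)
    stop("curves must share a length of at least 3 frames", call. = FALSE)
  arrival <- function(curve) {
    if (smooth_window > 1L) {
      h <- (smooth_window - 1) %/% 2
      curve <- vapply(seq_along(curve), function(t)
        mean(curve[max(1, t - h):min(length(curve), t + h)]), numeric(1))
    }
    d <- diff(curve)
    if (max(d) <= 0) stop("curve shows no rise", call. = FALSE)
    which.max(d) # index of the rising step
  }
  dt <- (arrival(curve_b) - arrival(curve_a)) / frame_rate_fps
  if (dt <= 0)
    stop("downstream point rises before (or with) the upstream point",
         call. = FALSE)
  dt
}

#' Two-point snGFR estimate
#'
#' `snGFR = cylinder_volume / transit_time`, converted to nl/min.
#'
#' @param curve_a,curve_b intensity-vs-frame curves at the two points.
#' @param diameters_um manually measured tubule diameters (typically five).
#' @param distance_um arclength between the two points, micrometres.
#' @param frame_rate_fps frames per second.
#' @param smooth_window odd smoothing window for arrival detection.
#' @return An object of class `sngfr_twopoint`: list with `sngfr_nl_min`,
#'   `volume_um3`, `transit_s`, and the inputs' summary.
#' @export
twopoint_sngfr <- function(curve_a, curve_b, diameters_um, distance_um,
                           frame_rate_fps, smooth_window = 1L) {
  vol <- cylinder_volume(diameters_um, distance_um)
  dt <- transit_time(curve_a, curve_b, frame_rate_fps, smooth_window)
  structure(list(sngfr_nl_min = vol / dt * 60 / 1e6,
                 volume_um3 = vol, transit_s = dt,
                 mean_diameter_um = mean(diameters_um),
                 distance_um = distance_um),
            class = "sngfr_twopoint")
}

#' @export
print.sngfr_twopoint <- function(x, digits = 4, ...) {
  cat("Single-nephron GFR (two-point transit method)\n")
  cat(sprintf(
    "  snGFR: %s nl/min  (V = %s um^3 over %s s)\n",
    format(x$sngfr_nl_min, digits = digits),
    format(x$volume_um3, digits = digits),
    format(x$transit_s, digits = digits)))
  invisible(x)
}

#' Extract the two-point measurement from a time series and ROI
#'
#' The ROI's first and last vertices serve as the upstream and downstream
#' measurement points (the same line the extended workflow uses end to end).
#'
#' @param series a [frame_series()].
#' @param roi a [polyline_roi()].
#' @param line_width_px averaging width for the point intensity curves.
#' @return list with `curve_a`, `curve_b`, and `distance_um` (ROI
#'   arclength).
#' @export
twopoint_from_series <- function(series, roi, line_width_px = 1L) {
  stopifnot(inherits(series, "frame_series"), inherits(roi, "polyline_roi"))
  check_roi_in_frame(roi, dim(series$frames)[1:2])
  g <- arclength_grid(roi, series$meta$pixel_size_um)
  ends <- rbind(g$points[1, ], g$points[nrow(g$points), ])
  tang <- rbind(g$tangents[1, ], g$tangents[nrow(g$tangents), ])
  nt <- dim(series$frames)[3]
  curves <- vapply(seq_len(nt), function(t)
    sample_profile(series$frames[, , t], ends, tang, line_width_px),
    numeric(2))
  list(curve_a = curves[1, ], curve_b = curves[2, ],
       distance_um = g$length_um)
}
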