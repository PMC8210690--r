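## From pixels to physics: arclength axis along the ROI, per-frame intensity
## profiles (kymograph), and the position -> cumulative-tubule-volume map
## that turns front positions into front volumes.

#' Regular arclength grid along the tubule ROI
#'
#' Computes the cumulative Euclidean length along the polyline (in
#' micrometres, via `pixel_size_um`) and places sample points every
#' `spacing_um` by linear interpolation along the segments. The final grid
#' point sits at the total arclength, which is the reported tubule length.
#'
#' @param roi a [polyline_roi()].
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param spacing_um sample spacing along the tubule; defaults to one pixel.
#' @return list with `positions_um` (regular grid incl. 0 and the total
#'   length), `points` (n x 2 matrix of pixel coordinates of the samples),
#'   `tangents` (unit tangent per sample), and `length_um`.
#' @export
arclength_grid <- function(roi, pixel_size_um, spacing_um = pixel_size_um) {
  stopifnot(inherits(roi, "polyline_roi"))
  if (spacing_um <= 0) stop("spacing_um must be > 0", call. = FALSE)
  v <- unclass(roi)
  seg <- diff(v)
  seg_len_um <- sqrt(rowSums(seg^2)) * pixel_size_um
  s_vert <- c(0, cumsum(seg_len_um))
  total <- s_vert[length(s_vert)]
  if (total <= 0) stop("degenerate ROI of zero length", call. = FALSE)
  pos <- unique(c(seq(0, total, by = spacing_um), total))
  k <- pmin(findInterval(pos, s_vert, rightmost.closed = TRUE),
            nrow(seg))
  frac <- (pos - s_vert[k]) / seg_len_um[k]
  pts <- v[k, , drop = FALSE] + seg[k, , drop = FALSE] * frac
  tang <- seg[k, , drop = FALSE] / sqrt(rowSums(seg[k, , drop = FALSE]^2))
  list(positions_um = pos, points = pts, tangents = tang, length_um = total)
}

#' Sample an intensity profile along the ROI in one frame
#'
#' Bilinear interpolation at each sample point; with `line_width_px > 1` the
#' mean over `line_width_px` single-pixel profiles offset perpendicular to
#' the local tangent (centred: offsets `-(w-1)/2 ... (w-1)/2`), mirroring a
#' wide-line intensity measurement.
#'
#' @param frame `[y, x]` numeric matrix.
#' @param points n x 2 matrix of `(x, y)` pixel coordinates.
#' @param tangents n x 2 matrix of unit tangents (needed when
#'   `line_width_px > 1`).
#' @param line_width_px odd line width in pixels.
#' @return numeric vector of intensities, one per point.
#' @export
sample_profile <- function(frame, points, tangents = NULL,
                           line_width_px = 1L) {
  w <- as.integer(line_width_px)
  if (w < 1L) stop("line_width_px must be >= 1", call. = FALSE)
  if (w == 1L) return(bilinear(frame, points[, 1], points[, 2]))
  if (is.null(tangents))
    stop("tangents required for line_width_px > 1", call. = FALSE)
  normals <- cbind(-tangents[, 2], tangents[, 1])
  offsets <- seq_len(w) - (w + 1) / 2
  prof <- 0
  for (o in offsets)
    prof <- prof + bilinear(frame,
                            points[, 1] + o * normals[, 1],
                            points[, 2] + o * normals[, 2])
  prof / w
}

# bilinear interpolation with 0-based pixel-centred coordinates; points must
# lie inside [0, ncol-1] x [0, nrow-1]
bilinear <- function(frame, x, y) {
  nyx <- dim(frame)
  if (any(x < 0 | x > nyx[2] - 1 | y < 0 | y > nyx[1] - 1))
    stop("sample point outside frame bounds", call. = FALSE)
  x0 <- pmin(floor(x), nyx[2] - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nyx[1] - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i10 <- cbind(y1 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x1 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  frame[i00] * (1 - fx) * (1 - fy) + frame[i10] * (1 - fx) * fy +
    frame[i01] * fx * (1 - fy) + frame[i11] * fx * fy
}

#' Build the position x time kymograph of dye intensity along the ROI
#'
#' One intensity profile per frame on a shared arclength grid: the
#' continuous-measurement core of the extended workflow, replacing two
#' hand-picked measurement points with the whole tubule.
#'
#' @param series a [frame_series()].
#' @param roi a [polyline_roi()].
#' @param spacing_um profile sample spacing (default: one pixel).
#' @param line_width_px odd averaging width perpendicular to the ROI.
#' @return A `kymograph`: list with `positions_um`, `times_frames` (0-based
#'   frame indices), `values` (positions x frames matrix), `length_um`,
#'   `grid` (the [arclength_grid()]), and `meta`.
#' @export
build_kymograph <- function(series, roi, spacing_um = NULL,
                            line_width_px = 1L) {
  stopifnot(inherits(series, "frame_series"), inherits(roi, "polyline_roi"))
  check_roi_in_frame(roi, dim(series$frames)[1:2])
  px <- series$meta$pixel_size_um
  if (is.null(spacing_um)) spacing_um <- px
  g <- arclength_grid(roi, px, spacing_um)
  nt <- dim(series$frames)[3]
  vals <- vapply(seq_len(nt), function(t)
    sample_profile(series$frames[, , t], g$points, g$tangents,
                   line_width_px),
    numeric(length(g$positions_um)))
  structure(list(positions_um = g$positions_um,
                 times_frames = seq_len(nt) - 1L,
                 values = vals, length_um = g$length_um, grid = g,
                 meta = series$meta),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d positions (0..%.1f um) x %d frames\n",
              length(x$positions_um), x$length_um,
              length(x$times_frames)))
  invisible(x)
}

#' Write a kymograph as CSV (position_um, then one column per frame)
#' @param kymo a `kymograph`.
#' @param path output path.
#' @export
write_kymograph_csv <- function(kymo, path) {
  df <- data.frame(position_um = kymo$positions_um, kymo$values)
  names(df)[-1] <- paste0("frame_", kymo$times_frames)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Map arclength to cumulative segmented tubule volume
#'
#' Every mask voxel is assigned the arclength of the orthogonal projection
#' of its `(x, y)` centre onto the ROI polyline (z is ignored: the ROI is
#' drawn on a single plane while the tubule model is 3D, so the x-y
#' projection is the only correspondence the drawn ROI defines). Voxels
#' whose unclamped projection falls beyond either end of the polyline are
#' excluded and counted in `n_excluded`. The cumulative volume at grid
#' position `s` is then `voxel_volume * #\{voxels with arclength <= s\}`.
#'
#' @param mask a `tubule_mask` from [select_tubule_label()].
#' @param roi a [polyline_roi()].
#' @param positions_um arclength grid (from [arclength_grid()] /
#'   [build_kymograph()]).
#' @param pixel_size_um lateral pixel size, micrometres.
#' @return A `volume_profile`: list with `positions_um`, `cumvol_um3`
#'   (non-decreasing), `total_um3`, and `n_excluded`.
#' @export
map_cumulative_volume <- function(mask, roi, positions_um, pixel_size_um) {
  stopifnot(inherits(mask, "tubule_mask"), inherits(roi, "polyline_roi"))
  idx <- which(mask$mask)
  if (!length(idx)) stop("empty tubule mask", call. = FALSE)
  co <- arrayInd(idx, dim(mask$mask)) # (y, x, z), 1-based
  pr <- .project_polyline_cpp(co[, 2] - 1, co[, 1] - 1,
                              roi[, "x"], roi[, "y"])
  inside <- pr$beyond == 0L
  if (!any(inside))
    stop("tubule mask does not overlap the ROI span", call. = FALSE)
  s_um <- pr$arclength[inside] * pixel_size_um
  cumvol <- vapply(positions_um, function(s) sum(s_um <= s), numeric(1)) *
    mask$voxel_volume_um3
  structure(list(positions_um = positions_um, cumvol_um3 = cumvol,
                 total_um3 = sum(inside) * mask$voxel_volume_um3,
                 n_excluded = sum(!inside)),
            class = "volume_profile")
}

#' @export
print.volume_profile <- function(x, ...) {
  cat(sprintf(
    "Volume profile: %.1f um^3 over %.1f um (%d end-overhang voxels excluded)\n",
    x$total_um3, max(x$positions_um), x$n_excluded))
  invisible(x)
}

#' Write a volume profile as CSV (position_um, cumvol_um3)
#' @param profile a `volume_profile`.
#' @param path output path.
#' @export
write_volume_profile_csv <- function(profile, path) {
  write.csv(data.frame(position_um = profile$positions_um,
                       cumvol_um3 = profile$cumvol_um3),
            path, row.names = FALSE)
  invisible(path)
}
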