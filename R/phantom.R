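## Synthetic phantom: a dye-filling tubule rendered as a time series plus a
## co-registered three-channel z-stack, with closed-form ground truth for
## every downstream stage. The generative model is deliberately minimal —
## a front advancing along the tubule's arclength at a known volumetric
## flow, with a ~1 px soft edge, Gaussian noise and channel bleed-through —
## because that is exactly the signal model the workflow assumes.

#' Specify a tubule phantom
#'
#' Defaults describe a downsampled intravital field of view (~192 x 192 x
#' 47.5 um at 3 um lateral pixels and 2.5 um sections) holding a straight
#' proximal tubule of 15 um luminal radius, filled at a physiological
#' 1.7 nl/min and imaged at 6 fps for 30 frames — chosen so the lumen spans
#' at least 5 voxels per axis (keeping voxelization error small) and the
#' front transit covers most of the series.
#'
#' @param shape stack dimensions `(ny, nx, nz)` in voxels.
#' @param n_frames number of time-series frames.
#' @param meta an [acquisition_meta()]; pixel size, voxel depth, frame rate.
#' @param centerline `"straight"`, `"sine"` or `"arc"` tubule axis (drawn in
#'   the x-y plane at the stack's mid-depth).
#' @param radius_um luminal radius; length 1 (constant) or 2
#'   (`c(r_start, r_end)`, linear taper along arclength).
#' @param flow_nl_min ground-truth volumetric flow Q.
#' @param intensity_max plateau dye intensity (arbitrary camera units).
#' @param noise_sigma Gaussian noise SD as a fraction of `intensity_max`.
#' @param bleed_fractions named fractions of the vessel and nuclei
#'   structures bleeding into the dye channel.
#' @param amplitude_um lateral amplitude of the `"sine"`/`"arc"` axis.
#' @param decoy add a bright decoy blob away from the tubule (tests ROI
#'   label selection).
#' @param seed integer; fixes all randomness of the render.
#' @return A `phantom_spec` (validated named list).
#' @export
phantom_spec <- function(shape = c(64L, 64L, 20L), n_frames = 30L,
                         meta = acquisition_meta(3, 2.5, 6),
                         centerline = c("straight", "sine", "arc"),
                         radius_um = 15, flow_nl_min = 1.7,
                         intensity_max = 200, noise_sigma = 0.05,
                         bleed_fractions = c(vessel = 0.2, nuclei = 0.1),
                         amplitude_um = 12, decoy = FALSE, seed = 1L) {
  centerline <- match.arg(centerline)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_frames >= 2L,
            inherits(meta, "acquisition_meta"),
            length(radius_um) %in% 1:2, all(radius_um > 0),
            flow_nl_min > 0, intensity_max > 0, noise_sigma >= 0,
            all(bleed_fractions >= 0), amplitude_um >= 0)
  # the tube (radius + 2 voxel margin) must fit the stack depth and width
  rmax <- max(radius_um)
  if (2 * rmax + 4 * meta$voxel_depth_um > shape[3] * meta$voxel_depth_um)
    stop("tube exceeds the stack depth (need >= 2 voxel z-margin)",
         call. = FALSE)
  lat <- rmax + (if (centerline == "straight") 0 else amplitude_um)
  if (2 * lat + 4 * meta$pixel_size_um > shape[1] * meta$pixel_size_um)
    stop("tube exceeds the lateral field (need >= 2 voxel margin)",
         call. = FALSE)
  structure(list(shape = as.integer(shape), n_frames = as.integer(n_frames),
                 meta = meta, centerline = centerline,
                 radius_um = as.numeric(radius_um),
                 flow_nl_min = flow_nl_min, intensity_max = intensity_max,
                 noise_sigma = noise_sigma,
                 bleed_fractions = bleed_fractions,
                 amplitude_um = amplitude_um, decoy = isTRUE(decoy),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# dense centerline polyline in pixel coordinates + its arclength (um)
phantom_centerline <- function(spec, n_dense = 600L) {
  ny <- spec$shape[1]; nx <- spec$shape[2]
  px <- spec$meta$pixel_size_um
  margin_px <- 3
  x <- seq(margin_px, nx - 1 - margin_px, length.out = n_dense)
  yc <- (ny - 1) / 2
  amp_px <- spec$amplitude_um / px
  y <- switch(spec$centerline,
    straight = rep(yc, n_dense),
    sine = yc + amp_px * sin(2 * pi * (x - x[1]) / (max(x) - x[1])),
    arc = yc - amp_px + amp_px * sqrt(pmax(0,
      1 - ((x - mean(x)) / (diff(range(x)) / 2))^2)))
  v <- cbind(x = x, y = y)
  seg <- sqrt(rowSums(diff(v)^2)) * px
  list(vertices = v, s_um = c(0, cumsum(seg)),
       length_um = sum(seg))
}

# radius at arclength s (um)
phantom_radius <- function(spec, s_um, length_um) {
  if (length(spec$radius_um) == 1L) rep(spec$radius_um, length(s_um))
  else spec$radius_um[1] +
    (spec$radius_um[2] - spec$radius_um[1]) * s_um / length_um
}

#' Closed-form cumulative tubule volume of a phantom
#'
#' `V(s) = integral of pi * r(s')^2 ds'` from the upstream end to `s`;
#' analytic for constant and linearly tapering radii.
#'
#' @param spec a [phantom_spec()].
#' @param s_um arclength(s) in `[0, length]`, micrometres.
#' @param length_um tubule length; defaults to the rendered centreline
#'   length.
#' @return volume(s) in cubic micrometres.
#' @export
closed_form_cumvol <- function(spec, s_um,
                               length_um = phantom_centerline(spec)$length_um) {
  if (any(s_um < -1e-9 | s_um > length_um + 1e-9))
    stop("arclength out of [0, length]", call. = FALSE)
  r <- spec$radius_um
  if (length(r) == 1L) return(pi * r^2 * s_um)
  dr <- (r[2] - r[1]) / length_um
  pi * (r[1]^2 * s_um + r[1] * dr * s_um^2 + dr^2 * s_um^3 / 3)
}

#' Ground-truth front position of a phantom
#'
#' Solves `V(s(t)) = Q * t` (Q converted to um^3/frame), clipped to the
#' tubule: the arclength the dye front has reached by frame `t`.
#'
#' @param spec a [phantom_spec()].
#' @param t_frames frame index/indices (0-based, may be fractional).
#' @return arclength(s) in micrometres.
#' @export
front_position <- function(spec, t_frames) {
  cl <- phantom_centerline(spec)
  L <- cl$length_um
  q_frame <- spec$flow_nl_min * 1e6 / 60 / spec$meta$frame_rate_fps
  vtot <- closed_form_cumvol(spec, L, L)
  vapply(t_frames, function(t) {
    if (t <= 0) return(0)
    v <- q_frame * t
    if (v >= vtot) return(L)
    if (length(spec$radius_um) == 1L)
      return(v / (pi * spec$radius_um^2))
    stats::uniroot(function(s) closed_form_cumvol(spec, s, L) - v,
                   c(0, L), tol = 1e-9)$root
  }, numeric(1))
}

#' Render a phantom dataset
#'
#' Produces the full synthetic acquisition: a three-channel z-stack (`dye`
#' with vessel/nuclei bleed-through, `vessel`, `nuclei`), the mid-depth dye
#' time series with the front advancing at the ground-truth flow, the
#' centreline ROI, and a `phantom_truth` object (true tube mask, closed-form
#' cumulative volume, front position function, Q). All intensities are
#' rounded to integers (bit-exact TIFF round trips); all randomness is
#' driven by `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `series` ([frame_series()]), `volumes`
#'   ([channel_volumes()]), `roi` ([polyline_roi()]), and `truth`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  ny <- spec$shape[1]; nx <- spec$shape[2]; nz <- spec$shape[3]
  px <- spec$meta$pixel_size_um; dz <- spec$meta$voxel_depth_um
  M <- spec$intensity_max
  edge_um <- px # ~1 px soft edge

  cl <- phantom_centerline(spec)
  L <- cl$length_um
  zc_um <- (nz - 1) / 2 * dz

  # project every pixel centre onto the centreline once
  grid <- expand.grid(y = seq_len(ny) - 1, x = seq_len(nx) - 1)
  pr <- .project_polyline_cpp(grid$x, grid$y,
                              cl$vertices[, "x"], cl$vertices[, "y"])
  d_xy_um <- matrix(pr$distance * px, ny, nx)
  s_um <- matrix(pr$arclength * px, ny, nx)
  beyond <- matrix(pr$beyond, ny, nx)
  r_at_s <- matrix(phantom_radius(spec, as.numeric(s_um), L), ny, nx)

  # radial soft-edge tube intensity per z-section (half-max at d3 = r)
  z_um <- (seq_len(nz) - 1) * dz
  tube <- array(0, dim = c(ny, nx, nz))
  tube_mask <- array(FALSE, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) {
    d3 <- sqrt(d_xy_um^2 + (z_um[k] - zc_um)^2)
    tube[, , k] <- M * pmin(pmax((r_at_s - d3) / edge_um + 0.5, 0), 1)
    tube_mask[, , k] <- d3 <= r_at_s & beyond == 0L
  }

  # vessel: a parallel tube offset laterally; nuclei: scattered spheres
  off_um <- max(spec$radius_um) + 8
  d_ves <- sqrt(pmax(d_xy_um - off_um, 0)^2) # distance to offset sheath
  vessel <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) {
    d3 <- sqrt((d_xy_um - off_um)^2 + (z_um[k] - zc_um)^2)
    vessel[, , k] <- 0.75 * M * pmin(pmax((4 - d3) / edge_um + 0.5, 0), 1)
  }
  nuclei <- array(0, dim = c(ny, nx, nz))
  ycoord <- (seq_len(ny) - 1) * px
  xcoord <- (seq_len(nx) - 1) * px
  n_nuc <- 30L
  placed <- 0L
  while (placed < n_nuc) {
    cy <- runif(1, 0, (ny - 1) * px); cx <- runif(1, 0, (nx - 1) * px)
    czz <- runif(1, 0, (nz - 1) * dz)
    pj <- .project_polyline_cpp(cx / px, cy / px,
                                cl$vertices[, "x"], cl$vertices[, "y"])
    rloc <- phantom_radius(spec, min(max(pj$arclength * px, 0), L), L)
    d3c <- sqrt((pj$distance * px)^2 + (czz - zc_um)^2)
    if (d3c < rloc + 4) next # nuclei sit in tissue, not in the lumen
    placed <- placed + 1L
    dy2 <- outer((ycoord - cy)^2, (xcoord - cx)^2, "+")
    for (k in seq_len(nz)) {
      d3 <- sqrt(dy2 + (z_um[k] - czz)^2)
      nuclei[, , k] <- pmax(nuclei[, , k],
        0.6 * M * pmin(pmax((3 - d3) / edge_um + 0.5, 0), 1))
    }
  }

  dye_clean <- tube
  if (spec$decoy) { # bright blob away from the tubule, in the dye channel
    cy <- 0.15 * (ny - 1) * px; cx <- 0.85 * (nx - 1) * px
    czz <- zc_um
    dy2 <- outer((ycoord - cy)^2, (xcoord - cx)^2, "+")
    for (k in seq_len(nz)) {
      d3 <- sqrt(dy2 + (z_um[k] - czz)^2)
      dye_clean[, , k] <- pmax(dye_clean[, , k],
        M * pmin(pmax((8 - d3) / edge_um + 0.5, 0), 1))
    }
  }
  bf <- spec$bleed_fractions
  dye_obs <- dye_clean + bf[["vessel"]] * vessel + bf[["nuclei"]] * nuclei

  quantize <- function(a) {
    if (spec$noise_sigma > 0)
      a <- a + rnorm(length(a), 0, spec$noise_sigma * M)
    array(pmax(round(a), 0), dim = dim(a))
  }
  channels <- list(dye = quantize(dye_obs), vessel = quantize(vessel),
                   nuclei = quantize(nuclei))

  # time series: mid-depth section with the front at s(t), trailing soft
  # edge. The front keeps advancing past the field of view (the dye flows on
  # into unseen downstream segments at the end radius), so the last ROI
  # position brightens at the physically correct time too.
  k_mid <- floor((nz - 1) / 2) + 1L
  base <- tube[, , k_mid]
  q_frame <- spec$flow_nl_min * 1e6 / 60 / spec$meta$frame_rate_fps
  vtot <- closed_form_cumvol(spec, L, L)
  r_end <- phantom_radius(spec, L, L)
  s_front <- vapply(seq_len(spec$n_frames) - 1, function(t) {
    v <- q_frame * t
    if (v <= vtot) front_position(spec, t)
    else L + (v - vtot) / (pi * r_end^2)
  }, numeric(1))
  frames <- array(0, dim = c(ny, nx, spec$n_frames))
  for (t in seq_len(spec$n_frames)) {
    fac <- pmin(pmax((s_front[t] - s_um) / edge_um, 0), 1)
    frames[, , t] <- base * fac
  }
  frames <- quantize(frames)

  # ROI: the centreline sampled every ~4 px
  keep <- unique(c(seq(1, nrow(cl$vertices), by = 40), nrow(cl$vertices)))
  roi <- polyline_roi(cl$vertices[keep, , drop = FALSE])

  truth <- structure(list(
    tube_mask = tube_mask,
    length_um = L,
    cumvol_fn = function(s) closed_form_cumvol(spec, s, L),
    front_fn = function(t) front_position(spec, t),
    total_um3 = closed_form_cumvol(spec, L, L),
    q_nl_min = spec$flow_nl_min,
    radius_um = spec$radius_um,
    spec = spec), class = "phantom_truth")

  list(series = frame_series(frames, spec$meta),
       volumes = channel_volumes(channels, spec$meta),
       roi = roi, truth = truth)
}

#' Write a rendered phantom to disk
#'
#' Persists the acquisition exactly as a microscope export would look: the
#' time series and one TIFF stack per channel, the ROI as JSON, the
#' acquisition metadata as a YAML sidecar, and the ground truth (flow,
#' length, total volume, radius) as JSON labelled synthetic.
#'
#' @param phantom result of [render_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_stack(phantom$series$frames, file.path(dir, "timeseries.tif"))
  for (ch in names(phantom$volumes$channels))
    write_image_stack(phantom$volumes$channels[[ch]],
                      file.path(dir, paste0("zstack_", ch, ".tif")))
  write_polyline_roi(phantom$roi, file.path(dir, "roi.json"))
  m <- phantom$series$meta
  yaml::write_yaml(list(pixel_size_um = m$pixel_size_um,
                        voxel_depth_um = m$voxel_depth_um,
                        frame_rate_fps = m$frame_rate_fps,
                        channels = names(phantom$volumes$channels)),
                   file.path(dir, "meta.yaml"))
  tr <- phantom$truth
  jsonlite::write_json(list(synthetic = TRUE,
                            q_nl_min = tr$q_nl_min,
                            length_um = tr$length_um,
                            total_um3 = tr$total_um3,
                            radius_um = tr$radius_um),
                       file.path(dir, "truth_synthetic.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
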