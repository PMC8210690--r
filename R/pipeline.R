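## Orchestration: run the full extended workflow (or the legacy two-point
## workflow) from a config, persisting every intermediate and a JSON run
## log so each analysis step can be verified after the fact.

#' Assemble a run configuration
#'
#' Either build the config in code (pass the loaded objects directly) or
#' from files via `read_run_config()`. Acquisition metadata is mandatory —
#' it is never defaulted, because a wrong pixel size or frame rate corrupts
#' snGFR by orders of magnitude, silently.
#'
#' @param series a [frame_series()] or path to a multi-page TIFF.
#' @param volumes a [channel_volumes()], or character vector of per-channel
#'   TIFF paths (named by channel; must include `dye`).
#' @param roi a [polyline_roi()] or path to a `.json`/`.roi` file.
#' @param meta an [acquisition_meta()] or path to a metadata sidecar.
#' @param out_dir directory for intermediates and results (`NULL`: nothing
#'   is written).
#' @param dataset_id identifier used in the result table.
#' @param params analysis parameters; see [default_params()].
#' @param emit_plots write diagnostic PNGs (intensity-vs-time with the
#'   threshold line; volume-vs-frame with the regression line)?
#' @return A `run_config` list.
#' @export
run_config <- function(series, volumes, roi, meta, out_dir = NULL,
                       dataset_id = "dataset", params = default_params(),
                       emit_plots = FALSE) {
  if (is.character(meta)) meta <- read_acquisition_meta(meta)
  if (!inherits(meta, "acquisition_meta"))
    stop("acquisition metadata is required (pixel size, voxel depth, ",
         "frame rate) and is never defaulted", call. = FALSE)
  if (is.character(roi)) roi <- read_polyline_roi(roi)
  if (is.character(series)) series <- read_frame_series(series, meta)
  if (is.character(volumes)) {
    if (is.null(names(volumes)) || !"dye" %in% names(volumes))
      stop("channel paths must be named and include 'dye'", call. = FALSE)
    volumes <- read_channel_volumes(volumes, names(volumes), meta)
  }
  p <- default_params()
  p[names(params)] <- params
  structure(list(series = series, volumes = volumes, roi = roi,
                 meta = meta, out_dir = out_dir, dataset_id = dataset_id,
                 params = p, emit_plots = isTRUE(emit_plots)),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_params <- function() {
  list(median_radius = 1L,         # voxels; 3x3x3 denoising box
       bleedthrough_scales = 1,    # direct channel subtraction
       binarize_method = "otsu",
       fixed_threshold = NULL,
       seed_min_distance = 5,      # voxels between watershed seeds
       roi_dilation_px = 3,        # ROI-to-label matching tolerance
       spacing_um = NULL,          # profile spacing; NULL = one pixel
       line_width_px = 1L,
       smooth_window = 3L,         # frames; turning-point pre-smoothing
       trim_low_frac = 0.05,       # usable front-volume band
       trim_high_frac = 0.95)
}

#' Load a run configuration from a YAML/JSON file
#'
#' Keys: `timeseries` (TIFF path), `channels` (named map channel -> TIFF
#' path, including `dye`), `roi` (path), `meta` (inline mapping or sidecar
#' path), `out_dir`, `dataset_id`, `emit_plots`, plus any parameter from
#' [default_params()]. Relative paths resolve against the config file's
#' directory.
#'
#' @param path config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p
    else file.path(base, p)
  for (key in c("timeseries", "roi"))
    if (is.null(cfg[[key]])) stop("config lacks '", key, "'", call. = FALSE)
  if (is.null(cfg$channels) || is.null(names(cfg$channels)))
    stop("config lacks a named 'channels' map", call. = FALSE)
  meta <- if (is.character(cfg$meta)) read_acquisition_meta(rel(cfg$meta))
  else if (is.list(cfg$meta))
    acquisition_meta(cfg$meta$pixel_size_um, cfg$meta$voxel_depth_um,
                     cfg$meta$frame_rate_fps)
  else stop("config lacks 'meta'", call. = FALSE)
  params <- cfg[intersect(names(cfg), names(default_params()))]
  run_config(series = rel(cfg$timeseries),
             volumes = setNames(unlist(lapply(cfg$channels, rel)),
                                names(cfg$channels)),
             roi = rel(cfg$roi), meta = meta,
             out_dir = rel(cfg$out_dir),
             dataset_id = if (is.null(cfg$dataset_id)) "dataset"
             else cfg$dataset_id,
             params = params, emit_plots = isTRUE(cfg$emit_plots))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the extended (continuous + 3D volume) snGFR workflow
#'
#' Executes denoising, bleed-through subtraction, 3D watershed
#' segmentation, ROI-guided tubule selection, kymograph construction,
#' cumulative-volume mapping, turning-point thresholding, front tracking
#' and the volume-vs-time regression. When `out_dir` is set, persists the
#' kymograph CSV, volume-profile CSV, label and mask TIFFs, result CSV,
#' optional diagnostic plots, and a JSON run log with every parameter and
#' decision.
#'
#' @param config a `run_config` (or path to a config file).
#' @return the [sngfr_fit()], with the [result_row()] attached as
#'   `$result`.
#' @export
run_extended <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  meta <- config$meta
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rlog <- list(dataset_id = config$dataset_id, params = p,
              meta = unclass(meta),
              volume_mapping = "xy-orthogonal-projection")

  ch <- config$volumes$channels
  vd <- c(meta$pixel_size_um, meta$pixel_size_um, meta$voxel_depth_um)

  cleaned <- stage("preprocess", {
    filt <- lapply(ch, median_filter_3d, radius = p$median_radius)
    contam <- filt[setdiff(names(filt), "dye")]
    if (length(contam))
      subtract_bleedthrough(filt$dye, contam,
                            rep_len(p$bleedthrough_scales, length(contam)))
    else filt$dye
  })

  seg <- stage("segmentation", {
    fg <- binarize(cleaned, p$binarize_method, p$fixed_threshold)
    rlog$binarize_threshold <- attr(fg, "threshold")
    labels <- watershed_3d(cleaned, fg, voxel_dims = vd,
                           seed_min_distance = p$seed_min_distance)
    mask <- select_tubule_label(
      labels, config$roi, dilation_px = p$roi_dilation_px,
      save_path = if (!is.null(out)) file.path(out, "tubule_mask.tif"))
    if (!is.null(out))
      write_image_stack(
        array(as.integer(labels$labels), dim = dim(labels$labels)),
        file.path(out, "watershed_labels.tif"))
    rlog$n_labels <- labels$n_labels
    rlog$labels_kept <- mask$labels_kept
    mask
  })

  kymo <- stage("kymograph", {
    k <- build_kymograph(config$series, config$roi,
                         spacing_um = p$spacing_um,
                         line_width_px = p$line_width_px)
    if (!is.null(out)) write_kymograph_csv(k, file.path(out, "kymograph.csv"))
    k
  })

  volprof <- stage("volume-mapping", {
    v <- map_cumulative_volume(seg, config$roi, kymo$positions_um,
                               meta$pixel_size_um)
    rlog$excluded_overhang_voxels <- v$n_excluded
    if (!is.null(out))
      write_volume_profile_csv(v, file.path(out, "volume_profile.csv"))
    v
  })

  fit <- stage("front-regression", {
    sm <- smooth_time_curves(kymo, p$smooth_window)
    thr <- find_threshold(sm)
    rlog$front_threshold <- as.numeric(thr)
    trace <- track_front(sm, thr, volprof,
                         low_frac = p$trim_low_frac,
                         high_frac = p$trim_high_frac)
    rlog$frames_used <- trace$frames
    sngfr_fit(trace, meta, volprofile = volprof,
              pt_length_um = kymo$length_um)
  })

  fit$result <- assemble_result(config$dataset_id, fit)
  if (!is.null(out)) {
    write_results(fit$result, file.path(out, "result.csv"))
    rlog$sngfr_nl_min <- fit$sngfr_nl_min
    rlog$r_squared <- fit$r_squared
    jsonlite::write_json(rlog, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (config$emit_plots) emit_diagnostics(kymo, fit, out)
  }
  fit
}

emit_diagnostics <- function(kymo, fit, out) {
  png(file.path(out, "intensity_vs_time.png"), 800, 600)
  cols <- hcl.colors(length(kymo$positions_um), "Blue-Red")
  matplot(kymo$times_frames, t(kymo$values), type = "l", lty = 1,
          col = cols, xlab = "frame", ylab = "intensity",
          main = "Dye arrival per position (blue = upstream, red = end)")
  abline(h = fit$threshold, lty = 2)
  dev.off()
  png(file.path(out, "volume_vs_frame.png"), 800, 600)
  plot(fit)
  dev.off()
}

#' Run the legacy two-point snGFR workflow
#'
#' Intensity curves at the ROI's first and last vertices, transit time by
#' the maximum-slope arrival estimator, and the cylinder volume from the
#' supplied manual diameters.
#'
#' @param config a `run_config` (the z-stack is not used).
#' @param diameters_um manually measured tubule diameters, micrometres
#'   (typically five).
#' @return An `sngfr_twopoint` with the [result_row()] attached as
#'   `$result`.
#' @export
run_legacy <- function(config, diameters_um) {
  stopifnot(inherits(config, "run_config"))
  tp <- stage("two-point", {
    x <- twopoint_from_series(config$series, config$roi,
                              config$params$line_width_px)
    twopoint_sngfr(x$curve_a, x$curve_b, diameters_um, x$distance_um,
                   config$meta$frame_rate_fps,
                   smooth_window = config$params$smooth_window)
  })
  tp$result <- result_row(config$dataset_id,
                          sngfr_nl_min = tp$sngfr_nl_min,
                          pt_length_um = tp$distance_um,
                          pt_volume_um3 = tp$volume_um3)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(tp$result, file.path(config$out_dir, "result_legacy.csv"))
  }
  tp
}

#' Replicate-variability (jitter) study on one phantom
#'
#' The computational analogue of repeated manual analysis: for each seed,
#' the ROI vertices are perturbed by Gaussian jitter (re-tracing error) and
#' the manual diameters by multiplicative noise (re-measuring error), and
#' both estimators are run on the same rendered phantom. The spread of the
#' replicate estimates measures each workflow's susceptibility to user
#' interaction.
#'
#' @param phantom a rendered phantom ([render_phantom()]).
#' @param n_replicates number of simulated re-annotations.
#' @param roi_jitter_px SD of the vertex jitter, pixels.
#' @param diameter_cv SD of the manual diameter error, as a fraction of the
#'   true diameter.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param params analysis parameters (see [default_params()]).
#' @return `data.frame` with one row per replicate and columns `replicate`,
#'   `extended`, `twopoint` (snGFR in nl/min; `NA` where a replicate's
#'   analysis failed).
#' @export
jitter_study <- function(phantom, n_replicates = 20L, roi_jitter_px = 1,
                         diameter_cv = 0.1, seed = 100L,
                         params = default_params()) {
  true_d <- 2 * mean(phantom$truth$radius_um)
  rows <- lapply(seq_len(n_replicates), function(i) {
    set.seed(seed + i)
    v <- unclass(phantom$roi)
    v <- v + matrix(rnorm(length(v), 0, roi_jitter_px), nrow(v), 2)
    dims <- dim(phantom$series$frames)[1:2]
    v[, 1] <- pmin(pmax(v[, 1], 0), dims[2] - 1)
    v[, 2] <- pmin(pmax(v[, 2], 0), dims[1] - 1)
    roi <- polyline_roi(v)
    diam <- true_d * (1 + rnorm(5, 0, diameter_cv))
    cfg <- run_config(phantom$series, phantom$volumes, roi,
                      phantom$series$meta, dataset_id = sprintf("rep%02d", i),
                      params = params)
    ext <- tryCatch(run_extended(cfg)$sngfr_nl_min,
                    error = function(e) NA_real_)
    leg <- tryCatch(run_legacy(cfg, diam)$sngfr_nl_min,
                    error = function(e) NA_real_)
    data.frame(replicate = i, extended = ext, twopoint = leg)
  })
  do.call(rbind, rows)
}
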