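## The core computation: a data-adaptive intensity threshold at the temporal
## turning point of the dye-arrival curves, per-frame localisation of the
## dye-front volume, and ordinary least squares of volume against time.
## The slope, converted from um^3/frame to nl/min, is the snGFR.

#' Moving-average smoothing of a kymograph along time
#'
#' Centred moving average per position over `window_frames` frames (odd;
#' truncated at the series edges). Window 1 is the identity. Used to tame
#' frame-to-frame noise before the discrete-derivative turning-point search.
#'
#' @param kymo a `kymograph`.
#' @param window_frames odd window length, `<=` number of frames.
#' @return a smoothed `kymograph`.
#' @export
smooth_time_curves <- function(kymo, window_frames = 3L) {
  w <- as.integer(window_frames)
  nt <- ncol(kymo$values)
  if (w < 1L || w %% 2L == 0L)
    stop("window_frames must be a positive odd integer", call. = FALSE)
  if (w > nt)
    stop("window_frames exceeds the number of frames", call. = FALSE)
  if (w == 1L) return(kymo)
  h <- (w - 1L) %/% 2L
  sm <- t(apply(kymo$values, 1, function(row) {
    vapply(seq_len(nt), function(t) {
      lo <- max(1L, t - h); hi <- min(nt, t + h)
      mean(row[lo:hi])
    }, numeric(1))
  }))
  out <- kymo
  out$values <- sm
  out
}

#' Turning-point intensity threshold
#'
#' At each retained position the dye-arrival curve rises sigmoidally as the
#' front passes; its turning point (maximum slope over time) sits at
#' half-maximum for a logistic rise. The per-position turning intensity is
#' the mean of the two intensities flanking the frame step with maximal
#' forward difference; the global front threshold is the median of these
#' over positions, drawn as the single dashed threshold line of the
#' workflow's diagnostic plot.
#'
#' @param kymo a (possibly smoothed) `kymograph`.
#' @param positions index vector (or logical) of positions to use; default:
#'   positions whose intensity rise exceeds `min_rise_frac` of the largest
#'   rise anywhere, i.e. positions the dye actually transits.
#' @param min_rise_frac fraction of the global maximum rise below which a
#'   position is considered untouched by the dye.
#' @return the threshold intensity, with per-position turning intensities as
#'   attribute `"per_position"`.
#' @export
find_threshold <- function(kymo, positions = NULL, min_rise_frac = 0.25) {
  vals <- kymo$values
  if (ncol(vals) < 3L)
    stop("need at least 3 frames", call. = FALSE)
  rises <- apply(vals, 1, function(r) max(r) - min(r))
  if (max(rises) <= 0)
    stop("no dye transit detected (flat intensity curves)", call. = FALSE)
  if (is.null(positions)) positions <- rises >= min_rise_frac * max(rises)
  sel <- vals[positions, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty position subset", call. = FALSE)
  turning <- apply(sel, 1, function(r) {
    d <- diff(r)
    k <- which.max(d)
    if (d[k] <= 0) return(NA_real_)
    (r[k] + r[k + 1]) / 2
  })
  turning <- turning[!is.na(turning)]
  if (!length(turning))
    stop("no dye transit detected (no rising curve)", call. = FALSE)
  structure(median(turning), per_position = turning)
}

#' Locate the dye-front volume in one frame
#'
#' Scans the profile from the glomerular end: the front is the end of the
#' initial contiguous run of samples at or above the threshold, refined to
#' sub-sample precision by linear interpolation between the bracketing
#' samples, then converted to a volume through the cumulative volume
#' profile. Returns `NA` when the front has not yet entered the tubule
#' (first sample below threshold) or has already left it (profile never
#' drops below threshold).
#'
#' @param profile intensity per position (one kymograph column).
#' @param threshold front intensity threshold.
#' @param volprofile a `volume_profile` on the same grid.
#' @return front volume in cubic micrometres, or `NA`.
#' @export
locate_front <- function(profile, threshold, volprofile) {
  if (length(profile) != length(volprofile$positions_um))
    stop("profile and volume profile grids differ", call. = FALSE)
  above <- profile >= threshold
  if (!above[1]) return(NA_real_)
  k <- which(!above)[1] # first sample below threshold
  if (is.na(k)) return(NA_real_)
  # crossing between samples k-1 (>= thr) and k (< thr)
  s0 <- volprofile$positions_um[k - 1]; s1 <- volprofile$positions_um[k]
  i0 <- profile[k - 1]; i1 <- profile[k]
  s_star <- s0 + (i0 - threshold) / (i0 - i1) * (s1 - s0)
  approx(volprofile$positions_um, volprofile$cumvol_um3, xout = s_star,
         rule = 2)$y
}

#' Track the dye front across all frames
#'
#' Applies [locate_front()] per frame, drops frames where the front is
#' outside the tubule, and trims frames whose front volume lies outside
#' `(low_frac, high_frac)` of the total tubule volume — the pre-arrival and
#' saturation plateaus that would bias the regression.
#'
#' @param kymo a (possibly smoothed) `kymograph`.
#' @param threshold intensity threshold from [find_threshold()].
#' @param volprofile a `volume_profile`.
#' @param low_frac,high_frac usable band of front volumes as fractions of
#'   the total tubule volume.
#' @return A `front_trace`: list with `frames` (0-based indices used),
#'   `front_volume_um3`, `threshold`, and `n_dropped`.
#' @export
track_front <- function(kymo, threshold, volprofile,
                        low_frac = 0.05, high_frac = 0.95) {
  vols <- vapply(seq_along(kymo$times_frames), function(t)
    locate_front(kymo$values[, t], threshold, volprofile), numeric(1))
  ok <- !is.na(vols) &
    vols > low_frac * volprofile$total_um3 &
    vols < high_frac * volprofile$total_um3
  if (sum(ok) < 3L)
    stop("insufficient front transit for regression (",
         sum(ok), " usable frame(s))", call. = FALSE)
  structure(list(frames = kymo$times_frames[ok],
                 front_volume_um3 = vols[ok],
                 threshold = as.numeric(threshold),
                 n_dropped = sum(!ok)),
            class = "front_trace")
}

#' Convert a regression slope to snGFR
#'
#' `snGFR [nl/min] = slope [um^3/frame] * frame_rate [1/s] * 60 [s/min] *
#' 1e-6 [nl/um^3]`. Exactly linear and invertible.
#'
#' @param slope_um3_per_frame fitted slope of front volume against frame.
#' @param frame_rate_fps frames per second.
#' @return snGFR in nl/min.
#' @export
convert_slope <- function(slope_um3_per_frame, frame_rate_fps) {
  if (frame_rate_fps <= 0)
    stop("frame_rate_fps must be > 0", call. = FALSE)
  slope_um3_per_frame * frame_rate_fps * 60 / 1e6
}

#' Fit the snGFR front-volume regression
#'
#' The central estimator: ordinary least squares of front volume (um^3)
#' against frame index. The slope, converted by [convert_slope()], is the
#' single-nephron glomerular filtration rate; R-squared (squared Pearson
#' correlation) quantifies how well a constant-flow front explains the
#' trace.
#'
#' @param trace a `front_trace` from [track_front()], or any data with
#'   columns/fields `frames` and `front_volume_um3`.
#' @param meta an [acquisition_meta()] supplying the frame rate.
#' @param volprofile optionally, the `volume_profile`, so the fit can report
#'   tubule volume; `pt_length_um` likewise.
#' @param pt_length_um tubule (ROI) length in micrometres.
#' @return An object of class `sngfr_fit`: the `lm` fit plus `sngfr_nl_min`,
#'   `r_squared`, `threshold`, `n_frames_used`, `pt_length_um`,
#'   `pt_volume_um3`, with the usual [coef()], [fitted()], [residuals()],
#'   [predict()], [print()], [summary()] and [plot()] methods.
#' @export
sngfr_fit <- function(trace, meta, volprofile = NULL, pt_length_um = NA_real_) {
  stopifnot(inherits(meta, "acquisition_meta"))
  frames <- trace$frames
  vols <- trace$front_volume_um3
  if (length(frames) < 3L)
    stop("need at least 3 (frame, volume) points", call. = FALSE)
  if (var(frames) == 0)
    stop("zero variance in frame indices", call. = FALSE)
  df <- data.frame(frame = as.numeric(frames), volume = as.numeric(vols))
  fit <- lm(volume ~ frame, data = df)
  # squared Pearson correlation; a front that never moves has no
  # explainable variance and gets NA rather than a spurious score
  r2 <- if (sd(df$volume) == 0) NA_real_
  else cor(df$frame, df$volume)^2
  slope <- unname(coef(fit)[2])
  structure(list(lm = fit, data = df,
                 slope_um3_per_frame = slope,
                 intercept_um3 = unname(coef(fit)[1]),
                 r_squared = r2,
                 sngfr_nl_min = convert_slope(slope, meta$frame_rate_fps),
                 threshold = if (!is.null(trace$threshold))
                   trace$threshold else NA_real_,
                 n_frames_used = length(frames),
                 pt_length_um = pt_length_um,
                 pt_volume_um3 = if (!is.null(volprofile))
                   volprofile$total_um3 else NA_real_,
                 volprofile = volprofile,
                 meta = meta),
            class = "sngfr_fit")
}

#' @export
print.sngfr_fit <- function(x, digits = 4, ...) {
  cat("Single-nephron GFR (dye-front regression)\n")
  cat(sprintf("  snGFR: %s nl/min  (R^2 = %s, %d frames)\n",
              format(x$sngfr_nl_min, digits = digits),
              format(x$r_squared, digits = digits), x$n_frames_used))
  invisible(x)
}

#' @export
summary.sngfr_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.sngfr_fit")
}

#' @export
print.summary.sngfr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Single-nephron GFR, extended (continuous + 3D volume) workflow\n\n")
  cat(sprintf("  snGFR:            %s nl/min\n",
              format(f$sngfr_nl_min, digits = digits)))
  cat(sprintf("  slope:            %s um^3/frame at %g fps\n",
              format(f$slope_um3_per_frame, digits = digits),
              f$meta$frame_rate_fps))
  cat(sprintf("  R-squared:        %s\n",
              format(f$r_squared, digits = digits)))
  cat(sprintf("  front threshold:  %s (intensity units)\n",
              format(f$threshold, digits = digits)))
  cat(sprintf("  frames used:      %d\n", f$n_frames_used))
  if (is.finite(f$pt_length_um))
    cat(sprintf("  PT length:        %s um\n",
                format(f$pt_length_um, digits = digits)))
  if (is.finite(f$pt_volume_um3))
    cat(sprintf("  PT volume:        %s um^3\n",
                format(f$pt_volume_um3, digits = digits)))
  invisible(x)
}

#' @export
coef.sngfr_fit <- function(object, ...) coef(object$lm)

#' @export
fitted.sngfr_fit <- function(object, ...) fitted(object$lm)

#' @export
residuals.sngfr_fit <- function(object, ...) residuals(object$lm)

#' @export
predict.sngfr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$lm))
  if (!is.data.frame(newdata)) newdata <- data.frame(frame = newdata)
  predict(object$lm, newdata = newdata, ...)
}

#' @export
plot.sngfr_fit <- function(x, ...) {
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  par(mar = c(4.5, 4.5, 2, 1))
  plot(x$data$frame, x$data$volume, pch = 19, col = "steelblue",
       xlab = "frame", ylab = expression("front volume (" * mu * m^3 * ")"),
       main = sprintf("snGFR = %.3f nl/min (R² = %.3f)",
                      x$sngfr_nl_min, x$r_squared), ...)
  abline(x$lm, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Assemble the shared result row from a fitted front regression
#'
#' @param dataset_id identifier for the analysed dataset.
#' @param fit an `sngfr_fit`.
#' @return a one-row `data.frame` in the [result_row()] schema.
#' @export
assemble_result <- function(dataset_id, fit) {
  stopifnot(inherits(fit, "sngfr_fit"))
  result_row(dataset_id,
             sngfr_nl_min = fit$sngfr_nl_min,
             r_squared = fit$r_squared,
             pt_length_um = fit$pt_length_um,
             pt_volume_um3 = fit$pt_volume_um3,
             threshold = fit$threshold,
             n_frames_used = fit$n_frames_used)
}
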