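## Readers/writers for the external formats: multi-page TIFF stacks, the
## polyline ROI (native JSON dialect + ImageJ .roi import), result CSVs.

#' Construct a dye-channel time series
#'
#' @param frames a `[y, x, t]` numeric array, or a list of equally sized
#'   `[y, x]` matrices (stacked in time order).
#' @param meta an [acquisition_meta()].
#' @return A `frame_series` object: list with `frames` (`[y, x, t]` array)
#'   and `meta`.
#' @export
frame_series <- function(frames, meta) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L)
      stop("all frames must share the same height/width", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must form a [y, x, t] array", call. = FALSE)
  if (dim(frames)[3] < 2L)
    stop("at least 2 frames required", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite", call. = FALSE)
  if (min(frames) < 0)
    stop("frame intensities must be non-negative", call. = FALSE)
  stopifnot(inherits(meta, "acquisition_meta"))
  structure(list(frames = frames, meta = meta), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dye time series: %d frames of %d x %d px at %g fps\n",
              d[3], d[1], d[2], x$meta$frame_rate_fps))
  invisible(x)
}

#' Construct a multi-channel z-stack
#'
#' @param channels named list of `[y, x, z]` numeric arrays with identical
#'   dimensions.
#' @param meta an [acquisition_meta()].
#' @return A `channel_volumes` object.
#' @export
channel_volumes <- function(channels, meta) {
  if (!is.list(channels) || length(channels) < 1L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a non-empty named list", call. = FALSE)
  shapes <- unique(lapply(channels, dim))
  if (length(shapes) != 1L || length(shapes[[1]]) != 3L)
    stop("all channels must be [y, x, z] arrays of identical shape",
         call. = FALSE)
  stopifnot(inherits(meta, "acquisition_meta"))
  structure(list(channels = channels, meta = meta),
            class = "channel_volumes")
}

#' @export
print.channel_volumes <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("z-stack: %s | %d x %d x %d voxels\n",
              paste(names(x$channels), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

#' Construct a proximal-tubule polyline ROI
#'
#' Vertices are ordered from the glomerular (upstream) end to the distal end,
#' in 0-based pixel coordinates `(x, y)`. A straight line ROI is simply a
#' 2-vertex polyline.
#'
#' @param vertices an n x 2 matrix (or data.frame) of `(x, y)` vertices.
#' @return A `polyline_roi` object (matrix with columns `x`, `y`).
#' @export
polyline_roi <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 2L)
    stop("ROI needs at least 2 (x, y) vertices", call. = FALSE)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop("ROI vertices must be finite numbers", call. = FALSE)
  dup <- rowSums(abs(diff(v))) == 0
  if (any(dup))
    stop("repeated consecutive ROI vertex at index ",
         which(dup)[1] + 1L, call. = FALSE)
  colnames(v) <- c("x", "y")
  rownames(v) <- NULL
  structure(v, class = c("polyline_roi", class(v)))
}

#' @export
print.polyline_roi <- function(x, ...) {
  cat(sprintf("Polyline ROI: %d vertices, %.2f px arclength\n", nrow(x),
              sum(sqrt(rowSums(diff(unclass(x))^2)))))
  invisible(x)
}

check_roi_in_frame <- function(roi, frame_dim) {
  ok <- roi[, "x"] >= 0 & roi[, "x"] <= frame_dim[2] - 1 &
        roi[, "y"] >= 0 & roi[, "y"] <= frame_dim[1] - 1
  if (!all(ok))
    stop("ROI vertex ", which(!ok)[1], " lies outside the frame bounds",
         call. = FALSE)
  invisible(TRUE)
}

## -- TIFF ------------------------------------------------------------------

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  if (any(info$samples.per.pixel > 1L))
    stop("page ", which(info$samples.per.pixel > 1L)[1], " of ", path,
         " is RGB/multi-sample; expected single-channel grayscale",
         call. = FALSE)
  # 8/16-bit pages are read as stored integers; 32-bit pages are IEEE float
  as_is <- all(info$bits.per.sample %in% c(8L, 16L))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) {
    bad <- which(!vapply(pages, function(p)
      identical(dim(p), dim(pages[[1]])), logical(1)))[1]
    stop("page ", bad, " of ", path, " differs in shape from page 1",
         call. = FALSE)
  }
  pages
}

#' Read a dye-channel time series from a multi-page grayscale TIFF
#'
#' One page per time point, page order = time order. 8- and 16-bit pages are
#' read bit-exactly as stored integers; 32-bit float pages as stored floats.
#'
#' @param path multi-page grayscale TIFF.
#' @param meta an [acquisition_meta()].
#' @return A [frame_series()].
#' @export
read_frame_series <- function(path, meta) {
  frame_series(read_tiff_pages(path), meta)
}

#' Read one or more z-stacks into a multi-channel volume
#'
#' Either one single-channel multi-page TIFF per channel (`path` a character
#' vector parallel to `names`), or one interleaved multi-channel stack with
#' `pages = channel-fastest` declared via `interleaved = TRUE` (page order
#' ch1 z1, ch2 z1, ..., ch1 z2, ...). z order is preserved.
#'
#' @param path character vector of TIFF paths (one per channel), or a single
#'   path when `interleaved`.
#' @param names channel names, e.g. `c("dye", "vessel", "nuclei")`.
#' @param meta an [acquisition_meta()].
#' @param interleaved set to `TRUE` when `path` is a single multi-channel
#'   stack with channel-fastest page order.
#' @return A [channel_volumes()].
#' @export
read_channel_volumes <- function(path, names, meta, interleaved = FALSE) {
  if (interleaved) {
    if (length(path) != 1L)
      stop("interleaved reading expects a single stack", call. = FALSE)
    pages <- read_tiff_pages(path)
    nc <- length(names)
    if (length(pages) %% nc != 0L)
      stop("page count ", length(pages),
           " is not a multiple of the declared ", nc, " channels",
           call. = FALSE)
    chans <- lapply(seq_len(nc), function(c)
      simplify2array(pages[seq(c, length(pages), by = nc)]))
    names(chans) <- names
  } else {
    if (length(path) != length(names))
      stop("need one path per channel name", call. = FALSE)
    chans <- lapply(path, function(p) simplify2array(read_tiff_pages(p)))
    names(chans) <- names
    shapes <- unique(lapply(chans, dim))
    if (length(shapes) != 1L)
      stop("channel stacks differ in shape", call. = FALSE)
  }
  channel_volumes(chans, meta)
}

#' Write a `[y, x, z]` or `[y, x, t]` array as a multi-page TIFF
#'
#' Integer-valued arrays are stored as uint8/uint16 (bit-exact round trip);
#' other arrays must lie in `[0, 1]` and are stored as 32-bit float.
#'
#' @param vol numeric array (3D) or matrix (single page).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(vol, path) {
  if (is.matrix(vol)) vol <- array(vol, dim = c(dim(vol), 1L))
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
  mx <- max(vol)
  if (all(vol == round(vol)) && min(vol) >= 0 && mx <= 65535) {
    bits <- if (mx <= 255) 8L else 16L
    scale <- 2^bits - 1
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = bits)
  } else {
    if (min(vol) < 0 || mx > 1)
      stop("non-integer volumes must lie in [0, 1] for float TIFF storage",
           call. = FALSE)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

## -- ROI files -------------------------------------------------------------

#' Read a tubule ROI from file
#'
#' Native format is a JSON dialect `{"vertices": [[x, y], ...]}` in 0-based
#' pixel coordinates. Files ending in `.roi` are parsed as ImageJ ROI files
#' (polyline or straight-line subtypes), the format the workflow's manual
#' tracing step naturally produces.
#'
#' @param path `.json` or ImageJ `.roi` file.
#' @return A [polyline_roi()].
#' @export
read_polyline_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  if (grepl("\\.roi$", path, ignore.case = TRUE))
    return(read_imagej_roi(path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed ROI JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$vertices))
    stop("ROI JSON lacks a 'vertices' field", call. = FALSE)
  polyline_roi(obj$vertices)
}

#' @rdname read_polyline_roi
#' @param roi a [polyline_roi()] to serialize.
#' @export
write_polyline_roi <- function(roi, path) {
  stopifnot(inherits(roi, "polyline_roi"))
  jsonlite::write_json(
    list(vertices = unname(unclass(roi))), path,
    digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# ImageJ .roi binary layout: magic "Iout", version short, type byte at 6
# (3 = line, 5 = polyline, 6 = freeline), bounds top/left/bottom/right as
# shorts at 8..15, n coordinates short at 16, x1/y1/x2/y2 floats at 18..33
# for straight lines, and for polylines n shorts of x-left then n shorts of
# y-top starting at byte 64. Big-endian throughout.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file: ", path, call. = FALSE)
  rshort <- function(off)
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  type <- as.integer(raw[7])
  if (type == 3L) { # straight line: coordinates stored as floats at 18
    xy <- readBin(raw[19:34], "numeric", n = 4, size = 4, endian = "big")
    return(polyline_roi(matrix(c(xy[1], xy[3], xy[2], xy[4]), 2, 2)))
  }
  if (!type %in% c(5L, 6L))
    stop("unsupported ImageJ ROI type ", type,
         " (only line/polyline/freeline)", call. = FALSE)
  top <- rshort(8); left <- rshort(10)
  n <- rshort(16)
  if (n < 2L) stop("ImageJ ROI has fewer than 2 vertices", call. = FALSE)
  coords <- readBin(raw[65:(64 + 4 * n)], "integer", n = 2 * n, size = 2,
                    endian = "big")
  polyline_roi(cbind(x = coords[1:n] + left, y = coords[(n + 1):(2 * n)] + top))
}

## -- result tables ---------------------------------------------------------

result_columns <- c("dataset_id", "sngfr_nl_min", "r_squared", "pt_length_um",
                    "pt_volume_um3", "threshold", "n_frames_used")

#' Build a result row for one analysed dataset
#'
#' @param dataset_id free-text identifier of the time series / stack pair.
#' @param sngfr_nl_min estimated snGFR in nl/min.
#' @param r_squared coefficient of determination of the volume-vs-time
#'   regression, in `[0, 1]`; `NA` for the two-point method.
#' @param pt_length_um ROI arclength in micrometres.
#' @param pt_volume_um3 segmented tubule volume in cubic micrometres.
#' @param threshold dye-front intensity threshold (image intensity units).
#' @param n_frames_used number of frames entering the regression.
#' @return one-row `data.frame` with the shared result schema.
#' @export
result_row <- function(dataset_id, sngfr_nl_min, r_squared = NA_real_,
                       pt_length_um = NA_real_, pt_volume_um3 = NA_real_,
                       threshold = NA_real_, n_frames_used = NA_integer_) {
  if (!is.finite(sngfr_nl_min))
    stop("snGFR must be finite", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  for (v in c(pt_length_um, pt_volume_um3))
    if (!is.na(v) && v < 0)
      stop("lengths and volumes must be non-negative", call. = FALSE)
  data.frame(dataset_id = as.character(dataset_id),
             sngfr_nl_min = sngfr_nl_min, r_squared = r_squared,
             pt_length_um = pt_length_um, pt_volume_um3 = pt_volume_um3,
             threshold = threshold,
             n_frames_used = as.integer(n_frames_used),
             stringsAsFactors = FALSE)
}

#' Write / read the shared snGFR result table
#'
#' CSV with the fixed column set `dataset_id, sngfr_nl_min, r_squared,
#' pt_length_um, pt_volume_um3, threshold, n_frames_used`; numbers carry full
#' double precision (15 significant digits).
#'
#' @param rows a `data.frame` of [result_row()]s (rbind-ed).
#' @param path output CSV path.
#' @return `path` invisibly; `read_results()` returns the `data.frame`.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) < 1L)
    stop("need at least one result row", call. = FALSE)
  if (!identical(names(rows), result_columns))
    stop("result table columns must be: ",
         paste(result_columns, collapse = ", "), call. = FALSE)
  out <- rows
  for (cn in setdiff(result_columns, c("dataset_id", "n_frames_used")))
    out[[cn]] <- vapply(rows[[cn]], function(v)
      if (is.na(v)) "" else format(v, digits = 15), character(1))
  write.csv(out, path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(dataset_id = "character"))
  if (!identical(names(df), result_columns))
    stop("unexpected result table columns in ", path, call. = FALSE)
  df
}
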