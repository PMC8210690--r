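## Tubule segmentation: global threshold -> distance-transform-seeded 3D
## watershed -> selection of the basin(s) the hand-drawn ROI traces.

#' Global intensity threshold / binarization
#'
#' `method = "otsu"` maximizes the between-class variance over a 256-bin
#' histogram of the intensity range (ties between equally good split points
#' resolve to the middle of the tied run, which places the threshold midway
#' between well-separated modes). `method = "fixed"` uses `fixed_value`.
#' Foreground is `volume >= threshold`.
#'
#' @param volume `[y, x, z]` numeric array (or any numeric array).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold intensity when `method = "fixed"`.
#' @return logical array of the same shape, with the threshold used attached
#'   as attribute `"threshold"`.
#' @export
binarize <- function(volume, method = c("otsu", "fixed"),
                     fixed_value = NULL) {
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(fixed_value))
      stop("method 'fixed' requires fixed_value", call. = FALSE)
    fixed_value
  } else {
    otsu_threshold(volume)
  }
  structure(volume >= thr, threshold = thr)
}

#' @rdname binarize
#' @param n_bins number of histogram bins for the Otsu search.
#' @export
otsu_threshold <- function(volume, n_bins = 256L) {
  v <- as.numeric(volume)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot Otsu-threshold a constant volume", call. = FALSE)
  # histogram on n_bins equal-width bins spanning the data range
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)                  # class-0 mass up to split k
  m <- cumsum(counts * mids)           # class-0 first moment
  wtot <- w[n_bins]; mtot <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- wtot - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (mtot - m[k][valid]) / w1[valid]
  sigma_b[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  split <- best[ceiling(length(best) / 2)] # centre of a tied plateau
  edges[split + 1L]                        # upper edge of the last class-0 bin
}

#' Seeded 3D watershed of a foreground mask
#'
#' Seeds are local maxima of the (anisotropic) Euclidean distance transform
#' of the foreground, thinned so that no two seeds lie within
#' `seed_min_distance` voxels of each other; the foreground is then flooded
#' on the negated distance transform (Meyer flooding, 26-connectivity), so
#' every foreground voxel receives exactly one label and background stays 0.
#'
#' @param volume `[y, x, z]` intensity array (used only for shape checks;
#'   the geometry driving the watershed is the foreground's distance map).
#' @param foreground logical array of the same shape; must be non-empty.
#' @param voxel_dims physical voxel size `(dy, dx, dz)` in micrometres, used
#'   for the anisotropic distance transform.
#' @param seed_min_distance minimum seed separation in voxels.
#' @return A `label_volume`: list with `labels` (integer array, 0 =
#'   background), `voxel_dims`, and `n_labels`.
#' @export
watershed_3d <- function(volume, foreground, voxel_dims = c(1, 1, 1),
                         seed_min_distance = 5) {
  stopifnot(identical(dim(volume), dim(foreground)))
  fg <- as.logical(foreground)
  if (!any(fg)) stop("empty foreground", call. = FALSE)
  dims <- dim(foreground)
  dist <- array(.edt3_cpp(fg, dims, as.numeric(voxel_dims)), dim = dims)
  dist[!is.finite(dist)] <- max(dims * voxel_dims) # all-foreground guard
  seeds <- seed_maxima(dist, fg, seed_min_distance)
  labels <- .watershed_flood_cpp(seeds, as.numeric(dist), fg, dims)
  structure(list(labels = array(labels, dim = dims),
                 voxel_dims = as.numeric(voxel_dims),
                 n_labels = max(labels)),
            class = "label_volume")
}

# Local maxima of the distance map within the foreground, greedily thinned
# by min_distance (in voxels). A plateau of equal maxima collapses to its
# first voxel in array order, keeping seeding deterministic.
seed_maxima <- function(dist, fg, min_distance) {
  dims <- dim(dist)
  is_max <- fg
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    shifted <- shift_array(dist, c(dy, dx, dz), fill = -Inf)
    is_max <- is_max & (dist >= shifted)
  }
  idx <- which(is_max)
  if (!length(idx)) idx <- which.max(dist * fg)
  ord <- order(-dist[idx], idx)
  idx <- idx[ord]
  coords <- arrayInd(idx, dims)
  keep <- logical(length(idx))
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_along(idx)) {
    if (nrow(kept) == 0 ||
        min(sqrt(rowSums(sweep(kept, 2, coords[i, ])^2))) >= min_distance) {
      keep[i] <- TRUE
      kept <- rbind(kept, coords[i, ])
    }
  }
  seeds <- array(0L, dim = dims)
  seeds[idx[keep]] <- seq_len(sum(keep))
  seeds
}

shift_array <- function(a, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (by[k] >= 0) {
      src[[k]] <- seq_len(d[k] - by[k])
      dst[[k]] <- seq_len(d[k] - by[k]) + by[k]
    } else {
      src[[k]] <- seq_len(d[k] + by[k]) - by[k]
      dst[[k]] <- seq_len(d[k] + by[k])
    }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("3D watershed labels: %d object(s) in %s volume\n",
              x$n_labels, paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Select the watershed basin(s) traced by the tubule ROI
#'
#' The watershed may split a long tubule into several basins; the hand-drawn
#' ROI decides which fragments make up the proximal tubule. A label is kept
#' when its x-y projection intersects the ROI polyline dilated by
#' `dilation_px` pixels (absorbing small tracing error). The resulting mask
#' can be written out with [write_image_stack()] for visual verification.
#'
#' @param labels a `label_volume` from [watershed_3d()].
#' @param roi a [polyline_roi()].
#' @param dilation_px lateral tolerance around the polyline, pixels.
#' @param save_path optional path; when given, the mask is saved there as a
#'   uint8 TIFF stack for visual verification.
#' @return A `tubule_mask`: list with `mask` (logical array), `voxel_dims`,
#'   `voxel_volume_um3`, `volume_um3`, and `labels_kept`.
#' @export
select_tubule_label <- function(labels, roi, dilation_px = 3,
                                save_path = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(roi, "polyline_roi"))
  lab <- labels$labels
  if (max(lab) < 1L) stop("no nonzero label to select from", call. = FALSE)
  dims <- dim(lab)
  # x-y pixels within dilation_px of the polyline
  grid <- expand.grid(y = seq_len(dims[1]) - 1L, x = seq_len(dims[2]) - 1L)
  pr <- .project_polyline_cpp(grid$x, grid$y, roi[, "x"], roi[, "y"])
  near <- matrix(pr$distance <= dilation_px, dims[1], dims[2])
  hit_labels <- sort(unique(as.integer(
    lab[array(near, dim = dims) & lab > 0L])))
  if (!length(hit_labels))
    stop("ROI does not touch any segmented object", call. = FALSE)
  mask <- array(lab %in% hit_labels, dim = dims)
  vd <- labels$voxel_dims
  out <- structure(list(mask = mask, voxel_dims = vd,
                        voxel_volume_um3 = prod(vd),
                        volume_um3 = sum(mask) * prod(vd),
                        labels_kept = hit_labels),
                   class = "tubule_mask")
  if (!is.null(save_path))
    write_image_stack(array(as.integer(mask) * 255L, dim = dims), save_path)
  out
}

#' @export
print.tubule_mask <- function(x, ...) {
  cat(sprintf(
    "Tubule mask: %d voxels, %.1f um^3 (labels kept: %s)\n",
    sum(x$mask), x$volume_um3, paste(x$labels_kept, collapse = ", ")))
  invisible(x)
}

#' 26-connected components of a boolean volume
#'
#' @param mask logical `[y, x, z]` array.
#' @return integer array of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  array(.conncomp26_cpp(as.logical(mask), dim(mask)), dim = dim(mask))
}
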