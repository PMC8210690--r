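## Stack clean-up ahead of segmentation: 3D median denoising and spectral
## bleed-through removal by channel subtraction.

#' 3D median filter
#'
#' Replaces every voxel by the median of its `(2r+1)^3` box neighbourhood
#' (per-axis radii allowed); borders are handled by edge replication, so a
#' constant volume is preserved exactly and the output stays within the input
#' range. `radius = 0` is the identity.
#'
#' @param volume a `[y, x, z]` numeric array.
#' @param radius neighbourhood radius in voxels; either one number or a
#'   length-3 vector `(ry, rx, rz)`.
#' @return filtered array, same shape.
#' @export
median_filter_3d <- function(volume, radius = 1L) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  r <- as.integer(round(rep_len(radius, 3L)))
  if (any(r < 0)) stop("radius must be >= 0 per axis", call. = FALSE)
  if (any(2L * r + 1L > dim(volume)))
    stop("filter box exceeds the volume extent", call. = FALSE)
  if (all(r == 0L)) return(volume)
  out <- .medfilt3_cpp(as.numeric(volume), dim(volume), r)
  array(out, dim = dim(volume))
}

#' Subtract spectral bleed-through channels
#'
#' Removes contamination of the dye channel by other fluorophores:
#' `out = max(0, target - sum(scale_i * contaminant_i))`, voxel-wise. The
#' clamp at zero matches unsigned-integer image subtraction and keeps
#' downstream intensity thresholds meaningful. Since the operation is
#' voxel-wise it is equivalently a plane-by-plane subtraction of the
#' contaminant z-sections from the target z-sections.
#'
#' @param target `[y, x, z]` array (the dye channel).
#' @param contaminants one array, or a list of arrays, of the same shape.
#' @param scales non-negative multiplier per contaminant (default 1: direct
#'   channel subtraction).
#' @return cleaned array: `0 <= out <= target` everywhere.
#' @export
subtract_bleedthrough <- function(target, contaminants, scales = 1) {
  if (is.array(contaminants) && !is.list(contaminants))
    contaminants <- list(contaminants)
  scales <- rep_len(scales, length(contaminants))
  if (any(scales < 0)) stop("scales must be >= 0", call. = FALSE)
  out <- target
  for (i in seq_along(contaminants)) {
    ci <- contaminants[[i]]
    if (!identical(dim(ci), dim(target)))
      stop("contaminant ", i, " shape differs from target", call. = FALSE)
    out <- out - scales[i] * ci
  }
  out[out < 0] <- 0
  out
}
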