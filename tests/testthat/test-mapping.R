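test_that("arclength grid reproduces closed-form polyline lengths", {
  roi <- polyline_roi(rbind(c(0, 0), c(10, 0)))
  g <- arclength_grid(roi, pixel_size_um = 1, spacing_um = 1)
  expect_equal(g$positions_um, 0:10)
  expect_equal(g$length_um, 10)
  expect_equal(g$points[, 1], 0:10)   # samples walk along x
  expect_equal(g$points[, 2], rep(0, 11))

  roi345 <- polyline_roi(rbind(c(0, 0), c(3, 0), c(3, 4)))
  expect_equal(arclength_grid(roi345, 1)$length_um, 7) # 3-4-5 geometry

  set.seed(31)
  v <- matrix(runif(16, 0, 50), 8, 2)
  roi_r <- polyline_roi(v)
  oracle <- sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)) * 0.7
  expect_equal(arclength_grid(roi_r, 0.7)$length_um, oracle)
  expect_error(arclength_grid(roi, 1, spacing_um = 0), "> 0")
})

test_that("profile sampling is exact on constant and linear frames", {
  roi <- polyline_roi(rbind(c(1, 4), c(14, 4)))
  g <- arclength_grid(roi, 1, 0.5)
  const <- matrix(7, 16, 16)
  expect_equal(sample_profile(const, g$points, g$tangents, 1),
               rep(7, nrow(g$points)))
  expect_equal(sample_profile(const, g$points, g$tangents, 3),
               rep(7, nrow(g$points)))
  gradx <- matrix(rep(0:15, each = 16), 16, 16) # I(x, y) = x
  expect_equal(sample_profile(gradx, g$points, g$tangents, 1),
               g$points[, 1])
  expect_error(
    sample_profile(const, matrix(c(99, 2), 1, 2), line_width_px = 1),
    "outside")
})

test_that("wide-line sampling averages parallel single-pixel profiles", {
  set.seed(32)
  frame <- matrix(runif(400, 0, 100), 20, 20)
  roi <- polyline_roi(rbind(c(3, 10), c(16, 12)))
  g <- arclength_grid(roi, 1, 1)
  got <- sample_profile(frame, g$points, g$tangents, 3)
  normal <- cbind(-g$tangents[, 2], g$tangents[, 1])
  oracle <- (sample_profile(frame, g$points - normal, g$tangents, 1) +
             sample_profile(frame, g$points, g$tangents, 1) +
             sample_profile(frame, g$points + normal, g$tangents, 1)) / 3
  expect_equal(got, oracle)
})

test_that("kymograph stacks per-frame profiles on one grid", {
  meta <- acquisition_meta(1, 1, 6)
  frames <- array(5, c(16, 16, 3))
  fs <- frame_series(frames, meta)
  roi <- polyline_roi(rbind(c(2, 8), c(13, 8)))
  k <- build_kymograph(fs, roi)
  expect_equal(ncol(k$values), 3)
  expect_true(all(k$values == 5)) # constant series -> identical columns
  expect_equal(k$length_um, 11)
  # linearity: adding a constant offset to one frame shifts its column only
  frames2 <- frames; frames2[, , 2] <- frames2[, , 2] + 3
  k2 <- build_kymograph(frame_series(frames2, meta), roi)
  expect_equal(k2$values[, 2], k$values[, 2] + 3)
  expect_equal(k2$values[, c(1, 3)], k$values[, c(1, 3)])
})

test_that("phantom kymograph front advances monotonically", {
  p <- noiseless_phantom()
  k <- build_kymograph(p$series, p$roi)
  half <- p$truth$spec$intensity_max / 2
  crossing <- apply(k$values, 2, function(prof) {
    above <- prof >= half
    if (!above[1]) return(NA_real_)
    i <- which(!above)[1]
    if (is.na(i)) return(max(k$positions_um))
    k$positions_um[i - 1]
  })
  # frame 0 is before dye arrival: profile at the noise floor
  expect_lt(max(k$values[, 1]), 0.05 * p$truth$spec$intensity_max)
  expect_true(is.na(crossing[1]))
  cr <- crossing[!is.na(crossing)]
  expect_true(all(diff(cr) >= 0)) # half-max crossing never retreats
})

cylinder_fixture <- function() {
  p <- noiseless_phantom()
  cleaned <- subtract_bleedthrough(
    median_filter_3d(p$volumes$channels$dye, 1),
    list(median_filter_3d(p$volumes$channels$vessel, 1),
         median_filter_3d(p$volumes$channels$nuclei, 1)))
  lv <- watershed_3d(cleaned, binarize(cleaned, "otsu"),
                     voxel_dims = c(3, 3, 2.5))
  list(p = p, mask = select_tubule_label(lv, p$roi))
}

test_that("cumulative volume tracks the closed-form cylinder profile", {
  fx <- cylinder_fixture()
  p <- fx$p
  g <- arclength_grid(p$roi, 3)
  vp <- map_cumulative_volume(fx$mask, p$roi, g$positions_um, 3)
  expect_true(all(diff(vp$cumvol_um3) >= 0)) # non-decreasing
  expect_equal(vp$cumvol_um3[length(vp$cumvol_um3)], vp$total_um3)
  # within the voxelization budget of pi r^2 s at every position: the
  # truncated cylinder up to s is voxelized, so its surface voxel layer
  # (including the cut face) bounds the achievable accuracy
  r <- p$truth$radius_um
  xarc <- (rep(seq_len(64) - 1, each = 64) - 3) * 3 # straight tube: s = x
  xarc <- array(rep(xarc, 20), c(64, 64, 20))
  for (s in g$positions_um[seq(5, length(g$positions_um), by = 10)]) {
    budget <- surface_voxel_volume(fx$mask$mask & xarc <= s, 22.5)
    i <- which(g$positions_um == s)
    expect_lt(abs(vp$cumvol_um3[i] - pi * r^2 * s), budget)
  }
  expect_lt(abs(vp$total_um3 - p$truth$total_um3) / p$truth$total_um3, 0.05)
})

test_that("reversing the ROI complements the volume profile", {
  fx <- cylinder_fixture()
  p <- fx$p
  g <- arclength_grid(p$roi, 3)
  vp <- map_cumulative_volume(fx$mask, p$roi, g$positions_um, 3)
  rev_roi <- polyline_roi(unclass(p$roi)[nrow(p$roi):1, ])
  vp_r <- map_cumulative_volume(fx$mask, rev_roi, g$positions_um, 3)
  L <- max(g$positions_um)
  # cumvol_rev(s) ~ total - cumvol(L - s); voxels whose assigned arclength
  # coincides with a grid point fall on the closed side of the count in
  # both directions, so the two staircases disagree by at most about one
  # arclength bin of voxels
  fwd_at <- approx(g$positions_um, vp$cumvol_um3, xout = L - g$positions_um,
                   rule = 2)$y
  one_bin <- max(diff(c(0, vp$cumvol_um3)))
  expect_lte(max(abs(vp_r$cumvol_um3 - (vp$total_um3 - fwd_at))),
             1.5 * one_bin)
  expect_equal(vp_r$total_um3, vp$total_um3)
})

test_that("voxels beyond the ROI ends are excluded, not binned", {
  mask <- structure(list(
    mask = array(TRUE, c(3, 9, 2)), voxel_dims = c(1, 1, 1),
    voxel_volume_um3 = 1), class = "tubule_mask")
  # ROI spans x = 3..5 only; columns 0..2 and 6..8 overhang the ends
  roi <- polyline_roi(rbind(c(3, 1), c(5, 1)))
  vp <- map_cumulative_volume(mask, roi, 0:2, 1)
  expect_equal(vp$n_excluded, 6 * 3 * 2)
  expect_equal(vp$total_um3, 3 * 3 * 2)
  expect_equal(vp$cumvol_um3[1], 6) # the x = 3 column maps to s = 0
  # a mask entirely past the end is an error
  mask2 <- mask; mask2$mask[] <- FALSE; mask2$mask[2, 8:9, 1] <- TRUE
  expect_error(map_cumulative_volume(mask2, roi, 0:2, 1), "overlap")
})
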