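# small helpers: spheres on a voxel grid
sphere_mask <- function(dims, centre, r) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  array(sqrt((co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
               (co[, 3] - centre[3])^2) <= r, dims)
}

test_that("Otsu lands strictly between two separated modes", {
  v <- array(c(rep(10, 400), rep(200, 600)), c(10, 10, 10))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  fg <- binarize(v, "otsu")
  expect_identical(as.vector(fg), as.vector(v == 200)) # bright class only
  expect_equal(attr(fg, "threshold"), thr)
})

test_that("fixed binarization and its preconditions behave", {
  v <- array(runif(27), c(3, 3, 3))
  expect_true(all(binarize(v, "fixed", fixed_value = 0)))
  expect_error(binarize(v, "fixed"), "fixed_value")
  expect_error(binarize(array(5, c(3, 3, 3)), "otsu"), "constant")
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  set.seed(21)
  v <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  thr <- otsu_threshold(v)
  # oracle: direct two-class variance over every candidate bin edge
  x <- as.numeric(v)
  edges <- seq(min(x), max(x), length.out = 257)
  mids <- (edges[-1] + edges[-257]) / 2
  counts <- tabulate(pmin(pmax(findInterval(x, edges,
                                            rightmost.closed = TRUE), 1),
                          256), 256)
  best <- -Inf; best_k <- NA
  for (k in 1:255) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / n1
    s <- n0 * n1 * (mu0 - mu1)^2
    if (s > best) { best <- s; best_k <- k }
  }
  expect_equal(thr, edges[best_k + 1])
})

test_that("watershed of one solid sphere yields exactly one basin", {
  fg <- sphere_mask(c(20, 20, 20), c(10, 10, 10), 6)
  lv <- watershed_3d(array(1, dim(fg)), fg)
  expect_equal(lv$n_labels, 1)
  expect_identical(lv$labels > 0, fg) # labels cover exactly the foreground
})

test_that("disjoint objects get basins equal to connected components", {
  fg <- sphere_mask(c(30, 30, 12), c(8, 8, 6), 4) |
    sphere_mask(c(30, 30, 12), c(22, 22, 6), 4)
  lv <- watershed_3d(array(1, dim(fg)), fg)
  expect_equal(lv$n_labels, 2)
  cc <- connected_components(fg)
  # same partition up to label permutation
  tab <- table(lv$labels[fg], cc[fg])
  expect_equal(sum(tab > 0), 2)
  expect_error(watershed_3d(array(1, dim(fg)), fg & FALSE), "empty")
})

test_that("overlapping spheres split along the waist like a two-seed flood", {
  dims <- c(26, 40, 16)
  c1 <- c(13, 14, 8); c2 <- c(13, 26, 8); r <- 8 # centres 1.5 r apart
  fg <- sphere_mask(dims, c1, r) | sphere_mask(dims, c2, r)
  lv <- watershed_3d(array(1, dims), fg, seed_min_distance = 5)
  expect_equal(lv$n_labels, 2)
  expect_identical(lv$labels > 0, fg) # union of basins = foreground
  # oracle: flood from the two true centres -> nearer-centre assignment;
  # compare away from the waist where the basin boundary may wander
  co <- arrayInd(which(fg), dims)
  d1 <- sqrt(rowSums(sweep(co, 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(co, 2, c2)^2))
  lab <- lv$labels[fg]
  clear <- abs(d1 - d2) > 2
  nearer <- ifelse(d1 < d2, lab[which.min(d1)], lab[which.min(d2)])
  expect_true(all(lab[clear] == nearer[clear]))
  # the boundary voxels sit in the overlap waist (|d1 - d2| small)
  boundary <- lab != nearer
  expect_true(all(abs(d1 - d2)[boundary] <= 2))
})

test_that("every foreground voxel gets exactly one label, background none", {
  p <- noiseless_phantom()
  fg <- binarize(p$volumes$channels$dye, "otsu")
  lv <- watershed_3d(p$volumes$channels$dye, fg,
                     voxel_dims = c(3, 3, 2.5))
  expect_identical(lv$labels > 0, unclass(fg), ignore_attr = TRUE)
  expect_true(all(lv$labels[!fg] == 0))
})

test_that("ROI selects the traced basin and rejects empty background", {
  dims <- c(40, 40, 12)
  near <- sphere_mask(dims, c(20, 10, 6), 5)  # under the ROI
  far <- sphere_mask(dims, c(33, 33, 6), 4)   # away from it
  fg <- near | far
  lv <- watershed_3d(array(1, dims), fg)
  lv$voxel_dims <- c(1, 1, 1)
  roi <- polyline_roi(rbind(c(5, 19), c(15, 19))) # (x, y) across 'near'
  mask <- select_tubule_label(lv, roi, dilation_px = 3)
  expect_identical(mask$mask, near)
  expect_equal(mask$volume_um3, sum(near))
  roi_bg <- polyline_roi(rbind(c(0, 38), c(6, 38)))
  expect_error(select_tubule_label(lv, roi_bg, dilation_px = 1),
               "does not touch")
})

test_that("phantom tubule is recovered despite a decoy object", {
  p <- decoy_phantom()
  cleaned <- subtract_bleedthrough(
    median_filter_3d(p$volumes$channels$dye, 1),
    list(median_filter_3d(p$volumes$channels$vessel, 1),
         median_filter_3d(p$volumes$channels$nuclei, 1)))
  fg <- binarize(cleaned, "otsu")
  lv <- watershed_3d(cleaned, fg, voxel_dims = c(3, 3, 2.5))
  mask <- select_tubule_label(lv, p$roi, dilation_px = 3)
  truth <- p$truth$tube_mask
  dice <- 2 * sum(mask$mask & truth) / (sum(mask$mask) + sum(truth))
  expect_gte(dice, 0.95)
  # the decoy blob was segmented but not selected
  expect_lt(sum(mask$mask), sum(fg))
})

test_that("mask volume is voxel count times voxel volume, label-invariant", {
  p <- noiseless_phantom()
  fg <- binarize(p$volumes$channels$dye, "otsu")
  lv <- watershed_3d(p$volumes$channels$dye, fg, voxel_dims = c(3, 3, 2.5))
  mask <- select_tubule_label(lv, p$roi)
  expect_equal(mask$volume_um3, sum(mask$mask) * 3 * 3 * 2.5)
  # relabeling (permuting label ids) leaves the selected mask unchanged
  perm <- lv
  relab <- c(0, rev(seq_len(lv$n_labels)))
  perm$labels <- array(relab[lv$labels + 1L], dim(lv$labels))
  mask2 <- select_tubule_label(perm, p$roi)
  expect_identical(mask2$mask, mask$mask)
})
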