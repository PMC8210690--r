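# a synthetic kymograph with logistic dye-arrival curves: position s is
# reached by the front at time t0(s); intensity rises to M with rate k.
# The slow rise (k << 1) makes the frame grid effectively dense relative
# to the rise, and the irrational per-position phase avoids symmetric
# tie-breaking artifacts a step-aligned front would produce.
logistic_kymo <- function(n_pos = 50, n_t = 80, M = 100, k = 0.3,
                          noise = 0, seed = 41) {
  set.seed(seed)
  pos <- seq(0, n_pos - 1)
  t <- seq(0, n_t - 1)
  vals <- vapply(t, function(tt)
    M / (1 + exp(-k * (tt - 10.37 - pos * 0.731))), numeric(n_pos))
  if (noise > 0) vals <- vals + rnorm(length(vals), 0, noise * M)
  structure(list(positions_um = pos, times_frames = t, values = vals,
                 length_um = max(pos),
                 meta = acquisition_meta(1, 1, 6)),
            class = "kymograph")
}

test_that("temporal smoothing matches the truncated-window oracle", {
  k <- logistic_kymo(n_pos = 10, n_t = 12, noise = 0.1)
  expect_identical(smooth_time_curves(k, 1), k)          # window 1
  const <- k; const$values[] <- 3
  expect_equal(smooth_time_curves(const, 3)$values, const$values)
  sm <- smooth_time_curves(k, 3)
  oracle <- k$values
  for (i in seq_len(nrow(oracle))) for (t in seq_len(ncol(oracle)))
    oracle[i, t] <- mean(k$values[i, max(1, t - 1):min(ncol(oracle), t + 1)])
  expect_equal(sm$values, oracle)
  expect_error(smooth_time_curves(k, 2), "odd")
  expect_error(smooth_time_curves(k, 99), "exceeds")
})

test_that("turning-point threshold sits at half-maximum of logistic rises", {
  k <- logistic_kymo()
  thr <- find_threshold(k)
  expect_equal(as.numeric(thr), 50, tolerance = 0.05) # M/2
  # single position with a clean step between frames: flanking mean
  k1 <- structure(list(positions_um = 0, times_frames = 0:9,
                       values = matrix(c(rep(0, 5), rep(100, 5)), 1),
                       length_um = 0, meta = acquisition_meta(1, 1, 6)),
                  class = "kymograph")
  expect_equal(as.numeric(find_threshold(k1, positions = 1)), 50)
  flat <- k; flat$values[] <- 10
  expect_error(find_threshold(flat), "no dye transit")
})

test_that("threshold is robust to per-position noise", {
  # a front passing each position in a few frames (k = 1.5), 5% noise:
  # the maximum-slope frame stays on the rise, so the median turning
  # intensity stays near half-maximum
  k <- logistic_kymo(k = 1.5, noise = 0.05, seed = 42)
  thr <- find_threshold(k)
  expect_lt(abs(as.numeric(thr) - 50) / 50, 0.10)
})

test_that("front localization solves the interpolated crossing", {
  # profile 100 up to 5 um then 0; pi r^2 = 10 um^2 -> V(5 um) = 50 um^3
  pos <- 0:10
  vp <- structure(list(positions_um = pos, cumvol_um3 = 10 * pos,
                       total_um3 = 100), class = "volume_profile")
  prof <- c(rep(100, 6), rep(0, 5))
  # crossing interpolates half-way into the 5..6 interval at threshold 50
  expect_equal(locate_front(prof, 50, vp), 55)
  expect_true(is.na(locate_front(rep(0, 11), 50, vp)))   # not yet entered
  expect_true(is.na(locate_front(rep(90, 11), 50, vp)))  # past the end
  expect_error(locate_front(prof[1:5], 50, vp), "grids differ")
})

test_that("piecewise-linear crossings equal a dense-scan root oracle", {
  set.seed(43)
  pos <- seq(0, 40, by = 1)
  vp <- structure(list(positions_um = pos, cumvol_um3 = 7 * pos,
                       total_um3 = 7 * 40), class = "volume_profile")
  for (rep in 1:20) {
    prof <- 100 * exp(-(pos / runif(1, 8, 25))^runif(1, 1, 3)) +
      c(0, cumsum(rnorm(40, 0, 2)))
    prof <- pmax(prof, 0)
    thr <- runif(1, 20, 80)
    got <- locate_front(prof, thr, vp)
    above <- prof >= thr
    if (!above[1] || all(above)) {
      expect_true(is.na(got))
      next
    }
    # oracle: dense scan of the linear interpolant for its first downward
    # threshold crossing
    s_dense <- seq(0, 40, length.out = 10001)
    i_dense <- approx(pos, prof, xout = s_dense)$y
    k <- which(i_dense < thr)[1]
    s_star <- s_dense[k - 1] +
      (i_dense[k - 1] - thr) / (i_dense[k - 1] - i_dense[k]) *
        (s_dense[k] - s_dense[k - 1])
    expect_equal(got, 7 * s_star, tolerance = 1e-3)
  }
})

test_that("front tracking keeps only frames inside the usable band", {
  p <- noiseless_phantom()
  k <- build_kymograph(p$series, p$roi)
  g <- arclength_grid(p$roi, 3)
  vp <- structure(list(positions_um = g$positions_um,
                       cumvol_um3 = p$truth$cumvol_fn(g$positions_um),
                       total_um3 = p$truth$total_um3),
                  class = "volume_profile")
  sm <- smooth_time_curves(k, 3)
  thr <- find_threshold(sm)
  tr <- track_front(sm, thr, vp)
  expect_gte(length(tr$frames), 3)
  expect_true(all(tr$front_volume_um3 > 0.05 * vp$total_um3))
  expect_true(all(tr$front_volume_um3 < 0.95 * vp$total_um3))
  # constant inflow: the surviving points are collinear
  fit <- lm(tr$front_volume_um3 ~ tr$frames)
  expect_gt(summary(fit)$r.squared, 0.999)
  # blank series: no transit
  blank <- k; blank$values[] <- 0
  expect_error(track_front(blank, 10, vp), "insufficient")
  # saturated series: front past the end everywhere
  sat <- k; sat$values[] <- 100
  expect_error(track_front(sat, 10, vp), "insufficient")
})

test_that("regression slope, intercept and R^2 match closed forms", {
  meta <- acquisition_meta(1, 1, 6)
  tr <- list(frames = 0:2, front_volume_um3 = c(0, 10, 20), threshold = 1)
  fit <- sngfr_fit(tr, meta)
  expect_equal(unname(coef(fit)), c(0, 10))
  expect_equal(fit$r_squared, 1)
  tr2 <- list(frames = 0:2, front_volume_um3 = c(0, 10, 0), threshold = 1)
  expect_equal(sngfr_fit(tr2, meta)$slope_um3_per_frame, 0)
  expect_error(sngfr_fit(list(frames = 0:1, front_volume_um3 = c(0, 1)),
                         meta), "at least 3")
  expect_error(sngfr_fit(list(frames = c(2, 2, 2),
                              front_volume_um3 = c(0, 1, 2)), meta),
               "variance")
})

test_that("OLS agrees with the normal-equation oracle to 1e-10", {
  set.seed(44)
  f <- sort(sample(0:200, 100))
  v <- 3.2 * f + 40 + rnorm(100, 0, 25)
  fit <- sngfr_fit(list(frames = f, front_volume_um3 = v),
                   acquisition_meta(1, 1, 6))
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  r2 <- cor(f, v)^2
  expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
})

test_that("slope conversion is the exact unit algebra, and invertible", {
  expect_equal(convert_slope(0, 6), 0)
  expect_equal(convert_slope(1e6 / 360, 6), 1.0) # the closed-form identity
  s <- runif(1, 1, 1e4)
  expect_equal(convert_slope(s, 6) / (6 * 60 / 1e6), s)
  expect_error(convert_slope(1, 0), "> 0")
})

test_that("intensity scaling leaves the front trace and snGFR unchanged", {
  p <- noiseless_phantom()
  k <- build_kymograph(p$series, p$roi)
  g <- arclength_grid(p$roi, 3)
  vp <- structure(list(positions_um = g$positions_um,
                       cumvol_um3 = p$truth$cumvol_fn(g$positions_um),
                       total_um3 = p$truth$total_um3),
                  class = "volume_profile")
  run <- function(kymo) {
    sm <- smooth_time_curves(kymo, 3)
    tr <- track_front(sm, find_threshold(sm), vp)
    sngfr_fit(tr, p$series$meta)
  }
  base <- run(k)
  scaled <- k; scaled$values <- 4 * k$values # binary-exact scaling
  fit2 <- run(scaled)
  expect_equal(fit2$sngfr_nl_min, base$sngfr_nl_min, tolerance = 1e-12)
  expect_equal(fit2$threshold, 4 * base$threshold, tolerance = 1e-12)
})

test_that("time reversal never yields a silently positive snGFR", {
  p <- noiseless_phantom()
  k <- build_kymograph(p$series, p$roi)
  rev_k <- k
  rev_k$values <- k$values[, ncol(k$values):1]
  g <- arclength_grid(p$roi, 3)
  vp <- structure(list(positions_um = g$positions_um,
                       cumvol_um3 = p$truth$cumvol_fn(g$positions_um),
                       total_um3 = p$truth$total_um3),
                  class = "volume_profile")
  sm <- smooth_time_curves(rev_k, 3)
  res <- tryCatch({
    tr <- track_front(sm, find_threshold(sm), vp)
    sngfr_fit(tr, p$series$meta)$sngfr_nl_min
  }, error = function(e) {
    expect_match(conditionMessage(e), "transit")
    NA_real_
  })
  if (!is.na(res)) expect_lt(res, 0)
})

test_that("fit methods behave like a standard model object", {
  set.seed(45)
  f <- 0:19
  v <- 100 * f + rnorm(20, 0, 5)
  fit <- sngfr_fit(list(frames = f, front_volume_um3 = v, threshold = 50),
                   acquisition_meta(1, 1, 6), pt_length_um = 120)
  expect_s3_class(fit, "sngfr_fit")
  expect_length(fitted(fit), 20)
  expect_equal(fitted(fit) + residuals(fit), v, ignore_attr = TRUE)
  expect_equal(unname(predict(fit, newdata = data.frame(frame = 0))),
               fit$intercept_um3)
  expect_output(print(fit), "snGFR")
  expect_output(print(summary(fit)), "PT length")
  row <- assemble_result("d1", fit)
  expect_equal(row$sngfr_nl_min, fit$sngfr_nl_min)
  expect_equal(row$n_frames_used, 20L)
})
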