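test_that("ROI normalization fixes mean 0 and SD 100 and is idempotent", {
  set.seed(1)
  ch <- array(50 + 5 * rnorm(16 * 16 * 2), c(16, 16, 2))
  roi <- array(FALSE, dim(ch)); roi[4:12, 4:12, ] <- TRUE
  out <- normalize_roi(ch, roi)
  expect_equal(mean(out[roi]), 0, tolerance = 1e-6)
  expect_equal(sd(out[roi]), 100, tolerance = 1e-6)
  # applying again changes nothing (already mean 0 / sd 100)
  expect_equal(normalize_roi(out, roi), out, tolerance = 1e-12)
  # affine: the same map is applied outside the roi
  a <- 100 / sd(ch[roi]); b <- -mean(ch[roi]) * a
  expect_equal(out, ch * a + b, tolerance = 1e-9)
  expect_error(normalize_roi(array(3, dim(ch)), roi),
               class = "plq_validation_error")
})

test_that("signed distance matches brute force on small grids", {
  set.seed(2)
  sp <- c(0.5, 0.5, 1.5)
  for (rep in 1:3) {
    m <- array(runif(12 * 12 * 2) < 0.4, c(12, 12, 2))
    if (!any(m) || all(m)) next
    d <- signed_distance(m, sp)
    # brute force: per slice, nearest voxel of the opposite set
    for (k in 1:2) {
      mk <- m[, , k]
      if (!any(mk) || all(mk)) next
      fg <- which(mk, arr.ind = TRUE); bg <- which(!mk, arr.ind = TRUE)
      for (i in seq_len(nrow(fg))) {
        ref <- -min(sqrt(colSums((t(bg) - fg[i, ])^2))) * sp[1]
        expect_equal(d[fg[i, 1], fg[i, 2], k], ref, tolerance = 1e-9)
      }
      for (i in seq_len(min(nrow(bg), 30))) {
        ref <- min(sqrt(colSums((t(fg) - bg[i, ])^2))) * sp[1]
        expect_equal(d[bg[i, 1], bg[i, 2], k], ref, tolerance = 1e-9)
      }
    }
  }
})

test_that("signed distance conventions: disc center, symmetry, boundary", {
  m <- disc_mask(40, 0.5, 5)
  d <- signed_distance(m, c(0.5, 0.5, 1.5))
  center <- d[20, 20, 1]
  expect_lt(abs(center + 5), sqrt(2) * 0.5)  # about -5 mm at the center
  expect_equal(signed_distance(!m, c(0.5, 0.5, 1.5)), -d)
  # voxels adjacent to the boundary are within one voxel diagonal
  b <- which(m & abs(d) <= 0.5 + 1e-9)
  expect_gt(length(b), 0)
  expect_error(signed_distance(array(TRUE, c(4, 4, 1)), c(1, 1, 1)),
               class = "plq_validation_error")
  expect_error(signed_distance(array(FALSE, c(4, 4, 1)), c(1, 1, 1)),
               class = "plq_validation_error")
})

test_that("resampling at the native spacing reproduces the input", {
  set.seed(3)
  arr <- array(rnorm(24 * 20 * 2), c(24, 20, 2))
  out <- resample_inplane(arr, c(0.25, 0.25, 1.5))
  expect_identical(dim(out$data), dim(arr))
  expect_equal(out$data, arr, tolerance = 1e-9)
  expect_equal(out$spacing, c(0.25, 0.25, 1.5))
  expect_error(resample_inplane(arr, NULL), class = "plq_validation_error")
})

test_that("resampled disc mask preserves area within 5%", {
  m <- disc_mask(40, 0.5, 5)
  out <- resample_inplane(m * 1, c(0.5, 0.5, 1.5), labels = TRUE)
  area_in <- sum(m) * 0.25
  area_out <- sum(out$data) * 0.0625
  expect_lt(abs(area_out - area_in) / area_in, 0.05)
})

test_that("label resampling preserves the partition", {
  set.seed(4)
  lab <- array(sample(0:3, 32 * 32 * 2, replace = TRUE), c(32, 32, 2))
  out <- resample_inplane(lab, c(0.5, 0.5, 1.5), labels = TRUE)
  expect_true(all(out$data %in% 0:3))
  # checkerboard stays a two-phase partition
  cb <- array(outer(1:16, 1:16, function(i, j) (i + j) %% 2), c(16, 16, 1))
  outcb <- resample_inplane(cb, c(0.5, 0.5, 1.5), labels = TRUE)
  expect_true(all(outcb$data %in% 0:1))
})

test_that("per-slice Dice matches hand-computed values", {
  a <- array(FALSE, c(30, 30, 3)); b <- a
  a[1:20, 1:10, 1] <- TRUE            # 200 voxels
  b[1:20, 1:10, 1] <- TRUE
  # slice 2: A 200, B 200, overlap 150
  a[1:20, 1:10, 2] <- TRUE
  b[6:25, 1:10, 2] <- TRUE
  # slice 3: both empty -> NA
  d <- dice_per_slice(a, b)
  expect_equal(d[1], 1.0)
  expect_equal(d[2], 2 * 150 / 400)
  expect_true(is.na(d[3]))
  # disjoint masks
  b2 <- array(FALSE, dim(a)); b2[25:30, 25:30, 1] <- TRUE
  expect_equal(dice_per_slice(a, b2)[1], 0)
  expect_error(dice_per_slice(a, b2[1:10, , , drop = FALSE]),
               class = "plq_validation_error")
})

test_that("mean contour distance: identity, annulus, symmetry", {
  a <- disc_mask(60, 0.25, 5)
  b <- disc_mask(60, 0.25, 6)
  expect_equal(mean_contour_distance(a, a, c(0.25, 0.25, 1.5)), 0)
  mcd <- mean_contour_distance(a, b, c(0.25, 0.25, 1.5))
  expect_lt(abs(mcd - 1), 0.15)
  expect_equal(mcd, mean_contour_distance(b, a, c(0.25, 0.25, 1.5)))
  expect_error(mean_contour_distance(a, array(FALSE, dim(a)), c(0.25, 0.25, 1.5)),
               class = "plq_validation_error")
})

test_that("wall geometry enforces containment and derives the wall", {
  lum <- disc_mask(40, 0.5, 2.5)
  out <- disc_mask(40, 0.5, 5)
  g <- wall_geometry(lum, out, c(0.5, 0.5, 1.5))
  expect_identical(g$wall, out & !lum)
  expect_error(wall_geometry(out, lum, c(0.5, 0.5, 1.5)),
               class = "plq_validation_error")
})
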