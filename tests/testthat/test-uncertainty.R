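phantom_u <- generate_phantom(small_spec(seed = 21))

test_that("soft labels with sigma 0 and n 0 are exactly the hard labels", {
  d <- phantom_u$per_slice_dice$dice
  fld <- soft_labels(phantom_u$reference_labels, d, 0, 0, c(0.5, 0.5, 1.5))
  for (c in 1:3) {
    onehot <- (phantom_u$reference_labels == c) * 1
    expect_identical(fld$w[[c]][fld$included], onehot[fld$included])
  }
  expect_identical(fld$included, phantom_u$reference_labels > 0)
})

test_that("per-voxel soft-label sums equal Dice^n on every slice", {
  d <- phantom_u$per_slice_dice$dice
  for (n_exp in c(1, 24)) {
    fld <- soft_labels(phantom_u$reference_labels, d, 0.5, n_exp,
                       c(0.5, 0.5, 1.5))
    tot <- fld$w$C + fld$w$F + fld$w$LRNC
    for (k in seq_along(d)) {
      inc <- fld$included[, , k]
      expect_lt(max(abs(tot[, , k][inc] - d[k]^n_exp)), 1e-6)
    }
  }
})

test_that("the Dice exponent reweights slices by the closed-form ratio", {
  lab <- array(0L, c(10, 10, 2)); lab[3:8, 3:8, ] <- 2L
  fld <- soft_labels(lab, c(0.9, 0.6), 0, 24, c(0.5, 0.5, 1.5))
  w1 <- fld$w$F[3, 3, 1]; w2 <- fld$w$F[3, 3, 2]
  expect_equal(w1 / w2, (0.9 / 0.6)^24, tolerance = 1e-9)
  # monotonicity: larger n never favors the lower-Dice slice
  r_prev <- 1
  for (n_exp in c(0, 3, 9, 27)) {
    f <- soft_labels(lab, c(0.9, 0.6), 0, n_exp, c(0.5, 0.5, 1.5))
    r <- f$w$F[3, 3, 1] / f$w$F[3, 3, 2]
    expect_gte(r, r_prev)
    r_prev <- r
  }
})

test_that("contour weights hit the printed endpoints and midpoint", {
  expect_equal(contour_weight(0, 0, 0.3), 1)
  expect_equal(contour_weight(5, 0, 0), 0)   # governing contour 5 mm, at lumen
  expect_equal(contour_weight(0, 5, 1), 0)   # governing contour 5 mm, at outer
  expect_equal(contour_weight(2.5, 2.5, 0.5), 0.5)
  expect_equal(contour_weight(2.5, 0, 0.5), 0.75)
  expect_equal(contour_weight(10, 10, 0.5), 0)  # clamped past 5 mm
})

test_that("identical geometries give weight 1 across the wall", {
  g <- phantom_u$invivo_geometry
  cw <- contour_weights(g, g)
  expect_true(all(abs(cw$w[g$wall] - 1) < 1e-12))
})

test_that("contour differences are symmetric in the two geometries", {
  b <- generate_phantom(small_spec(seed = 22, misreg_amplitude_mm = 1.5))
  cw1 <- contour_weights(b$reference_geometry, b$invivo_geometry)
  cw2 <- contour_weights(b$invivo_geometry, b$reference_geometry)
  expect_equal(cw1$w_lumen, cw2$w_lumen)
  expect_equal(cw1$w_outer, cw2$w_outer)
})

test_that("robust Gaussian fit agrees with plain estimates on clean data", {
  set.seed(31)
  S <- matrix(c(2, 0.5, 0, 0.5, 1, 0.3, 0, 0.3, 1.5), 3)
  X <- matrix(rnorm(5000 * 3), ncol = 3) %*% chol(S)
  f <- robust_gaussian_fit(X)
  expect_true(f$converged)
  expect_lt(max(abs(f$mean - colMeans(X))), 0.08)
  expect_lt(max(abs(f$cov - cov(X))) / max(abs(cov(X))), 0.08)
})

test_that("robust mean beats the plain mean under 5% gross outliers", {
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    X <- matrix(rnorm(n * 3), ncol = 3)
    X[seq_len(round(0.05 * n)), ] <- X[seq_len(round(0.05 * n)), ] + 10
    rf <- robust_gaussian_fit(X)
    sqrt(sum(rf$mean^2)) < sqrt(sum(colMeans(X)^2))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("degenerate point clouds raise a numerical error", {
  expect_error(robust_gaussian_fit(matrix(1, 20, 3)),
               class = "plq_numerical_error")
  expect_error(robust_gaussian_fit(matrix(rnorm(12), 4, 3)),
               class = "plq_validation_error")
})

test_that("outlier rejection removes exactly ceil(fraction * n) per class", {
  set.seed(32)
  X <- rbind(matrix(rnorm(1000 * 2), ncol = 2),
             matrix(rnorm(500 * 2, 5), ncol = 2),
             matrix(rnorm(333 * 2, -5), ncol = 2))
  lab <- rep(c("C", "F", "LRNC"), c(1000, 500, 333))
  tab <- make_table(X, lab)
  out <- reject_outliers(tab, 0.10)
  expect_equal(sum(!out$keep & out$hard_label == "C"), 100)
  expect_equal(sum(!out$keep & out$hard_label == "F"), 50)
  expect_equal(sum(!out$keep & out$hard_label == "LRNC"), ceiling(33.3))
  expect_true(all(reject_outliers(tab, 0)$keep))
  small <- make_table(X[1:20, ], rep(c("C", "F", "LRNC"), c(18, 1, 1)))
  expect_error(reject_outliers(small, 0.1), class = "plq_validation_error")
})

test_that("planted mislabeled samples are concentrated in the rejected set", {
  b <- generate_phantom(phantom_spec(misreg_amplitude_mm = 0, seed = 42))
  st <- prepare_stack(b$images, b$invivo_geometry$outer)
  tab <- extract_features(st, b$invivo_geometry, labels = b$true_labels)
  fc <- attr(tab, "feature_cols")
  capture <- vapply(1:20, function(s) {
    set.seed(s)
    t2 <- tab
    crows <- which(t2$hard_label == "C")
    frows <- which(t2$hard_label == "F")
    n_plant <- round(0.08 * length(crows))
    plant <- sample(crows, n_plant)
    t2[plant, fc] <- t2[sample(frows, n_plant), fc]
    t3 <- reject_outliers(t2, 0.10)
    mean(plant %in% which(!t3$keep))
  }, numeric(1))
  expect_gte(mean(capture), 0.70)
})
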