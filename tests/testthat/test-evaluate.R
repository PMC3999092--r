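test_that("relative volumes match hand counts and sum to 100", {
  lab <- array(0L, c(20, 20, 1))
  wall <- array(FALSE, c(20, 20, 1))
  wall[1:10, 1:20, 1] <- TRUE               # 200 wall voxels
  idx <- which(wall)
  lab[idx[1:10]] <- 1L; lab[idx[11:130]] <- 2L; lab[idx[131:200]] <- 3L
  v <- relative_volumes(lab, wall)
  expect_equal(v$per_subject$percent, c(5, 60, 35))
  expect_equal(sum(v$per_subject$percent), 100, tolerance = 1e-6)
  by_slice <- tapply(v$per_slice$percent, v$per_slice$slice, sum)
  expect_true(all(abs(by_slice - 100) < 1e-6))
  # single-class wall
  lab1 <- lab; lab1[wall] <- 1L
  expect_equal(relative_volumes(lab1, wall)$per_subject$percent, c(100, 0, 0))
})

test_that("volume metrics: identity, constant offset, Spearman oracle", {
  set.seed(51)
  truth <- expand.grid(subject = paste0("S", 1:5),
                       component = c("C", "F", "LRNC"))
  truth$percent <- runif(nrow(truth), 10, 50)
  m0 <- volume_metrics(truth, truth)
  expect_equal(m0$bias, rep(0, 3))
  expect_equal(m0$abs_error, rep(0, 3))
  expect_equal(m0$spearman, rep(1, 3))
  shifted <- truth; shifted$percent <- truth$percent + 5
  m5 <- volume_metrics(shifted, truth)
  expect_equal(m5$bias, rep(5, 3))
  expect_equal(m5$abs_error, rep(5, 3))
  expect_equal(m5$spearman, rep(1, 3))
  # Spearman against a brute-force midrank implementation
  brute_spearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    a <- sample(1:5, n, replace = TRUE)  # ties likely
    b <- sample(1:5, n, replace = TRUE)
    p <- data.frame(subject = seq_len(n), component = "C", percent = a)
    t <- data.frame(subject = seq_len(n), component = "C", percent = b)
    got <- volume_metrics(p, t)$spearman[1]
    expect_equal(got, brute_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("Friedman statistic matches the hand formula on a toy table", {
  # 3 methods x 4 slices, no ties
  m <- rbind(c(1.0, 2.0, 3.0),
             c(2.1, 1.1, 3.2),
             c(1.2, 2.2, 3.1),
             c(1.3, 3.3, 2.3))
  colnames(m) <- c("a", "b", "c")
  res <- friedman_compare(m)
  R <- colSums(t(apply(m, 1, rank)))
  n <- 4; k <- 3
  chi <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, chi, tolerance = 1e-12)
  expect_equal(res$mean_ranks, R / n, tolerance = 1e-12)
  # random tie-free inputs vs the same closed form
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(5:10, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("m", 1:k)))
    res <- friedman_compare(m)
    R <- colSums(t(apply(m, 1, rank)))
    chi <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
    expect_equal(res$statistic, chi, tolerance = 1e-9)
  }
})

test_that("Friedman handles identical and dominated methods", {
  m <- matrix(rep(c(1, 2, 1.5, 3), 3), 4, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  res <- friedman_compare(m)
  expect_equal(res$statistic, 0)
  expect_true(res$degenerate)
  set.seed(53)
  base <- matrix(rnorm(30), 10, 3)
  worse <- cbind(base[, 1:2], base[, 3] + 10)
  colnames(worse) <- c("a", "b", "bad")
  res2 <- friedman_compare(worse)
  expect_equal(names(which.max(res2$mean_ranks)), "bad")
  expect_error(friedman_compare(base[, 1, drop = FALSE]),
               class = "plq_validation_error")
})

test_that("forward selection finds planted separators in column order", {
  set.seed(54)
  n <- 200
  y <- rep(c("C", "F"), each = n / 2)
  sep <- ifelse(y == "C", 5, -5) + rnorm(n, sd = 0.3)
  X <- cbind(noise1 = rnorm(n), key = sep, dup = sep, noise2 = rnorm(n))
  tab <- make_table(X, y)
  sel <- forward_select(tab, c("C", "F"), k = 3)
  expect_equal(sel[1], "key")                 # perfect separator first
  expect_false(sel[2] == "dup")               # duplicate adds nothing
  expect_warning(forward_select(tab, c("C", "F"), k = 10))
})

test_that("CTA is selected first for separating calcification from fibrous", {
  b <- generate_phantom(small_spec(misreg_amplitude_mm = 0, seed = 55))
  st <- prepare_stack(b$images, b$invivo_geometry$outer)
  tab <- extract_features(st, b$invivo_geometry, labels = b$true_labels)
  sel <- forward_select(tab, c("C", "F"), k = 1)
  expect_equal(sel, "cta")
})
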