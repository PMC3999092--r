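test_that("one-hot weighted LDC reduces to classical LDA estimates", {
  set.seed(41)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(160, 2), 80, 2),
             matrix(rnorm(120, -2), 60, 2))
  y <- rep(c("C", "F", "LRNC"), c(100, 80, 60))
  W <- 1 * outer(y, c("C", "F", "LRNC"), "==")
  colnames(W) <- c("C", "F", "LRNC")
  m <- fit_ldc(X, W)
  # brute-force formulas: class means, pooled MLE covariance, count priors
  for (k in c("C", "F", "LRNC"))
    expect_equal(m$means[k, ], colMeans(X[y == k, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  Sp <- Reduce(`+`, lapply(c("C", "F", "LRNC"), function(k) {
    Xc <- sweep(X[y == k, ], 2, colMeans(X[y == k, ]))
    crossprod(Xc)
  })) / nrow(X)
  expect_equal(m$cov, Sp, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(m$priors), c(100, 80, 60) / 240, tolerance = 1e-12)
  # class means agree with an independent reference implementation
  skip_if_not_installed("MASS")
  ml <- MASS::lda(X, grouping = factor(y))
  expect_equal(unname(m$means[ml$lev, ]), unname(ml$means), tolerance = 1e-9)
})

test_that("duplicating a sample equals doubling its weight", {
  set.seed(42)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(c("C", "F"), 30)
  W <- 1 * outer(y, c("C", "F"), "==")
  colnames(W) <- c("C", "F")
  Wd <- W; Wd[7, ] <- 2 * W[7, ]
  m_dup <- fit_ldc(rbind(X, X[7, , drop = FALSE]),
                   rbind(W, W[7, , drop = FALSE]))
  m_wt <- fit_ldc(X, Wd)
  expect_equal(m_dup$means, m_wt$means, tolerance = 1e-10)
  expect_equal(m_dup$cov, m_wt$cov, tolerance = 1e-10)
  expect_equal(m_dup$priors, m_wt$priors, tolerance = 1e-10)
})

test_that("posteriors are normalized, Bayes-consistent and tie-stable", {
  set.seed(43)
  # two unit-variance classes at -1 and +1: boundary at 0
  X1 <- matrix(c(rnorm(300, -1), rnorm(300, 1)), ncol = 1)
  y1 <- rep(c("C", "F"), each = 300)
  W1 <- 1 * outer(y1, c("C", "F"), "==")
  colnames(W1) <- c("C", "F")
  m1 <- fit_ldc(X1, W1)
  # symmetrize to the exact textbook case
  m1$means[, 1] <- c(-1, 1); m1$cov[1, 1] <- 1; m1$priors[] <- 0.5
  p0 <- predict_ldc(m1, matrix(0, 1, 1))
  expect_equal(unname(p0$posterior[1, ]), c(0.5, 0.5))
  expect_equal(as.character(p0$labels), "C")  # tie -> lowest class index
  expect_equal(as.character(predict_ldc(m1, matrix(0.2, 1, 1))$labels), "F")
  # random instances vs direct Gaussian Bayes rule
  K <- 3; d <- 4
  mu <- matrix(rnorm(K * d), K, d, dimnames = list(c("C", "F", "LRNC"), NULL))
  A <- matrix(rnorm(d * d), d); S <- crossprod(A) + diag(d)
  pri <- c(0.2, 0.5, 0.3)
  model <- structure(list(means = mu, cov = S, priors = pri,
                          classes = c("C", "F", "LRNC")),
                     class = "ldc_model")
  Xt <- matrix(rnorm(50 * d), 50, d)
  got <- predict_ldc(model, Xt)
  dens <- sapply(1:K, function(k)
    pri[k] * exp(-stats::mahalanobis(Xt, mu[k, ], S) / 2))
  ref <- dens / rowSums(dens)
  expect_equal(unname(got$posterior), unname(ref), tolerance = 1e-9)
  expect_true(all(abs(rowSums(got$posterior) - 1) < 1e-9))
  expect_error(predict_ldc(model, Xt[, 1:2]), class = "plq_validation_error")
})

test_that("LDC separates the zero-misregistration phantom wall", {
  b <- generate_phantom(small_spec(misreg_amplitude_mm = 0, seed = 44))
  st <- prepare_stack(b$images, b$invivo_geometry$outer)
  tab <- extract_features(st, b$invivo_geometry, labels = b$true_labels)
  m <- fit_ldc(tab)
  acc <- mean(predict_ldc(m, tab)$labels == tab$hard_label)
  expect_gt(acc, 0.95)
})

test_that("zero-weight classes and dimension mismatches are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  W <- cbind(C = rep(1, 20), F = rep(0, 20))
  expect_error(fit_ldc(X, W), class = "plq_validation_error")
})

test_that("weighted SVM separates, votes, and honors zero weights", {
  set.seed(45)
  X <- rbind(matrix(rnorm(60, 2), 30, 2), matrix(rnorm(60, -2), 30, 2))
  y <- factor(rep(c("C", "F"), each = 30))
  m <- fit_svm(X, C = 100, gamma = 0.5, y = y)
  expect_equal(mean(predict_svm(m, X) != y), 0)
  expect_length(m$models, 1)
  # zero weight == removal, exactly
  w <- rep(1, 60); w[c(5, 35)] <- 0
  m1 <- fit_svm(X, C = 10, gamma = 0.5, y = y, weights = w)
  m2 <- fit_svm(X[-c(5, 35), ], C = 10, gamma = 0.5, y = y[-c(5, 35)])
  expect_lt(max(abs(predict_svm(m1, X, decision_values = TRUE) -
                    predict_svm(m2, X, decision_values = TRUE))), 1e-6)
  # three classes -> exactly 3 pairwise models
  X3 <- rbind(X, matrix(rnorm(60, c(2, -2)), 30, 2, byrow = TRUE) +
                matrix(c(0, 5), 30, 2, byrow = TRUE))
  y3 <- factor(c(as.character(y), rep("LRNC", 30)),
               levels = c("C", "F", "LRNC"))
  m3 <- fit_svm(X3, C = 10, gamma = 0.5, y = y3)
  expect_length(m3$models, 3)
  # a training point deep on the positive side keeps its own label
  far <- X[which.max(X[, 1] + X[, 2]), , drop = FALSE] + 3
  expect_equal(as.character(predict_svm(m3, far)), "C")
  expect_error(fit_svm(X, C = -1, gamma = 0.5, y = y),
               class = "plq_validation_error")
  expect_error(predict_svm(m3, X3[, 1, drop = FALSE]),
               class = "plq_validation_error")
})

test_that("SVM decision values match the explicit kernel expansion", {
  set.seed(46)
  X <- rbind(matrix(rnorm(40, 1.5), 20, 2), matrix(rnorm(40, -1.5), 20, 2))
  y <- factor(rep(c("C", "F"), each = 20))
  gamma <- 0.7
  m <- fit_svm(X, C = 5, gamma = gamma, y = y)
  bm <- m$models[[1]]
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  ref <- sapply(seq_len(nrow(Xs)), function(i) {
    sum(bm$coef * exp(-gamma * colSums((t(bm$sv) - Xs[i, ])^2))) + bm$b
  })
  got <- predict_svm(m, X, decision_values = TRUE)[, 1]
  expect_equal(got, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("one-vs-one vote ties resolve to the lowest class index", {
  # build a 3-class model by hand with cyclic pairwise winners
  sv <- matrix(0, 1, 1)
  mk <- function(pair, sign) list(sv = sv, coef = matrix(sign), b = sign,
                                  pair = pair)
  model <- structure(list(
    models = list(mk(c("C", "F"), 1),      # C beats F
                  mk(c("C", "LRNC"), -1),  # LRNC beats C
                  mk(c("F", "LRNC"), 1)),  # F beats LRNC
    classes = c("C", "F", "LRNC"), C = 1, gamma = 1,
    center = 0, scale = 1), class = "svm_model")
  # every class gets exactly one vote -> tie -> C
  expect_equal(as.character(predict_svm(model, matrix(0, 1, 1))), "C")
})

test_that("models survive a JSON round trip", {
  set.seed(47)
  X <- matrix(rnorm(90), 30, 3)
  y <- rep(c("C", "F", "LRNC"), 10)
  W <- 1 * outer(y, c("C", "F", "LRNC"), "==")
  colnames(W) <- c("C", "F", "LRNC")
  m <- fit_ldc(X, W)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_ldc(m2, X)$posterior, predict_ldc(m, X)$posterior,
               tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad, auto_unbox = TRUE)
  expect_error(read_model(bad), class = "plq_format_error")
})
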