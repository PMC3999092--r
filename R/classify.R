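# Sample-weighted linear discriminant classification and instance-weighted
# one-vs-one RBF-SVM.

# Extract feature matrix and per-class weight matrix from a sample_table.
table_xw <- function(table) {
  X <- feature_matrix(table)
  wcols <- paste0("w_", COMPONENTS)
  if (!all(wcols %in% names(table))) {
    if (is.null(table$hard_label))
      stop_validation("table needs w_C/w_F/w_LRNC columns or hard labels")
    W <- 1 * outer(as.character(table$hard_label), COMPONENTS, "==")
  } else {
    W <- as.matrix(table[, wcols])
  }
  colnames(W) <- COMPONENTS
  if (!is.null(table$keep)) W <- W * table$keep
  list(X = X, W = W)
}

#' Fit a sample-weighted linear discriminant classifier
#'
#' Gaussian classes with a shared (pooled) covariance. Class means are
#' weighted means under each class's sample weights, the pooled covariance
#' is the weighted within-class covariance (normalized by the total weight),
#' and the priors are each class's share of the total weight. With one-hot
#' weights this reduces to the maximum-likelihood LDA estimates, and
#' duplicating a sample is exactly equivalent to doubling its weight.
#'
#' @param x feature matrix (samples x features), or a `sample_table` with
#'   `w_C`/`w_F`/`w_LRNC` columns (rows with `keep = FALSE` get weight 0).
#' @param weights per-class weight matrix (samples x classes, named columns);
#'   ignored when `x` is a table.
#' @return An object of class `ldc_model`: `means` (classes x features),
#'   `cov`, `priors`, `classes`.
#' @export
fit_ldc <- function(x, weights = NULL) {
  if (is.data.frame(x)) {
    xw <- table_xw(x)
    x <- xw$X; weights <- xw$W
  }
  x <- as.matrix(x)
  W <- as.matrix(weights)
  if (nrow(W) != nrow(x))
    stop_validation("weights must have one row per sample")
  if (is.null(colnames(W)))
    colnames(W) <- paste0("class", seq_len(ncol(W)))
  tot <- colSums(W)
  active <- tot > 0
  if (sum(active) < 2)
    stop_validation("need at least two classes with positive total weight")
  if (any(!active))
    stop_validation(sprintf("class(es) with zero total weight: %s",
                            paste(colnames(W)[!active], collapse = ", ")))
  K <- ncol(W); d <- ncol(x)
  means <- matrix(0, K, d, dimnames = list(colnames(W), colnames(x)))
  S <- matrix(0, d, d)
  for (k in seq_len(K)) {
    wk <- W[, k]
    means[k, ] <- colSums(x * wk) / tot[k]
    xc <- sweep(x, 2, means[k, ])
    S <- S + crossprod(xc * sqrt(wk))
  }
  S <- S / sum(tot)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    message("pooled covariance singular; applying ridge regularization")
    S <- S + diag(1e-8 * sum(diag(S)) / d + 1e-12, d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop_numerical("pooled covariance singular after regularization")
  }
  structure(list(means = means, cov = S, priors = tot / sum(tot),
                 classes = colnames(W)),
            class = "ldc_model")
}

#' Posterior probabilities and labels from a linear discriminant model
#'
#' Evaluates the Gaussian Bayes rule under the pooled covariance: posterior
#' rows sum to 1; the label is the class with the highest posterior, ties
#' going to the lowest class index.
#'
#' @param model an `ldc_model`.
#' @param x feature matrix or `sample_table` with matching feature columns.
#' @return list with `posterior` (samples x classes) and `labels` (factor).
#' @export
predict_ldc <- function(model, x) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop_validation("feature dimension does not match the model")
  Sinv <- chol2inv(chol(model$cov))
  K <- length(model$classes)
  logp <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    xc <- sweep(x, 2, model$means[k, ])
    q <- rowSums((xc %*% Sinv) * xc)
    logp[, k] <- -q / 2 + log(model$priors[k])
  }
  m <- apply(logp, 1, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  labels <- factor(model$classes[max.col(post, ties.method = "first")],
                   levels = model$classes)
  list(posterior = post, labels = labels)
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# Solve one instance-weighted soft-margin SVM dual with kernlab's QP solver:
#   max sum(alpha) - 1/2 alpha' Q alpha,  0 <= alpha_i <= C * w_i,
#   sum(alpha_i y_i) = 0,  Q_ij = y_i y_j K_ij.
svm_binary_fit <- function(X, y, w, C, gamma) {
  keep <- w > 0
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  n <- length(y)
  if (length(unique(y)) < 2)
    stop_validation("a class pair has an empty class")
  if (n > 3000)
    stop_validation("SVM pair exceeds 3000 samples; subsample the training set")
  K <- rbf_kernel(X, X, gamma)
  H <- (y %*% t(y)) * K + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0,
                       l = rep(0, n), u = C * w, r = 0, sigf = 8,
                       maxiter = 100)
  alpha <- kernlab::primal(sol)
  alpha <- pmin(pmax(alpha, 0), C * w)
  f <- as.vector(K %*% (alpha * y))
  u <- C * w
  free <- alpha > 1e-8 * C & alpha < u - 1e-8 * C
  b <- if (any(free)) {
    mean(y[free] - f[free])
  } else {
    # no free support vectors: take the midpoint of the KKT interval
    # (alpha = 0 wants y*(f+b) >= 1, alpha = u wants y*(f+b) <= 1)
    lo <- suppressWarnings(max((y - f)[(y == 1 & alpha >= u - 1e-8 * C) |
                                        (y == -1 & alpha <= 1e-8 * C)]))
    hi <- suppressWarnings(min((y - f)[(y == 1 & alpha <= 1e-8 * C) |
                                        (y == -1 & alpha >= u - 1e-8 * C)]))
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else stats::median(y - f)
  }
  sv <- alpha > 1e-10
  list(sv = X[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b)
}

#' Fit an instance-weighted one-vs-one RBF-SVM
#'
#' Features are standardized to zero mean and unit variance with the
#' training statistics, then one soft-margin RBF-SVM is trained per class
#' pair; sample i's box constraint is `C * w_i`, where `w_i` is the weight
#' of the sample's hard class (1 for hard labels, the soft/contour weight
#' otherwise, 0 for rejected samples, which are dropped).
#'
#' @param table a `sample_table` with `hard_label` (and optionally weight /
#'   `keep` columns), or a feature matrix if `y` is given.
#' @param C penalty parameter (> 0).
#' @param gamma RBF kernel coefficient (> 0), `exp(-gamma * |x - z|^2)`.
#' @param y,weights labels (factor) and per-sample weights when `table` is a
#'   matrix.
#' @return An object of class `svm_model` with one binary model per class
#'   pair, plus the standardization parameters.
#' @export
fit_svm <- function(table, C, gamma, y = NULL, weights = NULL) {
  if (C <= 0 || gamma <= 0)
    stop_validation("C and gamma must be positive")
  if (is.data.frame(table)) {
    X <- feature_matrix(table)
    y <- table$hard_label
    if (is.null(y)) stop_validation("table must carry hard labels")
    wcols <- paste0("w_", COMPONENTS)
    weights <- if (all(wcols %in% names(table))) {
      W <- as.matrix(table[, wcols])
      W[cbind(seq_len(nrow(W)), as.integer(y))]
    } else rep(1, nrow(X))
    if (!is.null(table$keep)) weights <- weights * table$keep
  } else {
    X <- as.matrix(table)
    if (is.null(y)) stop_validation("y is required for matrix input")
    if (is.null(weights)) weights <- rep(1, nrow(X))
  }
  y <- factor(y)
  # weighted standardization statistics: zero-weight samples contribute
  # nothing, so w_i = 0 is exactly equivalent to removing sample i
  sw <- sum(weights)
  if (sw <= 0) stop_validation("all sample weights are zero")
  mu <- colSums(X * weights) / sw
  sd <- sqrt(colSums(sweep(X, 2, mu)^2 * weights) / sw)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  classes <- levels(y)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    rows <- y %in% p
    yy <- ifelse(y[rows] == p[1], 1, -1)
    fit <- svm_binary_fit(Xs[rows, , drop = FALSE], yy, weights[rows], C, gamma)
    c(fit, list(pair = p))
  })
  structure(list(models = models, classes = classes, C = C, gamma = gamma,
                 center = mu, scale = sd),
            class = "svm_model")
}

#' Predict class labels with a one-vs-one SVM
#'
#' Each pairwise decision function is thresholded at 0 and the class with
#' the majority of votes wins; vote ties go to the lowest class index.
#'
#' @param model an `svm_model`.
#' @param x feature matrix or `sample_table`.
#' @param decision_values return the pairwise decision values instead of
#'   labels.
#' @return Factor of predicted labels (or a matrix of decision values).
#' @export
predict_svm <- function(model, x, decision_values = FALSE) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop_validation("feature dimension does not match the model")
  Xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  votes <- matrix(0, nrow(Xs), length(model$classes),
                  dimnames = list(NULL, model$classes))
  dec <- matrix(0, nrow(Xs), length(model$models))
  for (m in seq_along(model$models)) {
    bm <- model$models[[m]]
    f <- as.vector(rbf_kernel(Xs, bm$sv, model$gamma) %*% bm$coef) + bm$b
    dec[, m] <- f
    winner <- ifelse(f >= 0, bm$pair[1], bm$pair[2])
    votes[cbind(seq_len(nrow(Xs)), match(winner, model$classes))] <-
      votes[cbind(seq_len(nrow(Xs)), match(winner, model$classes))] + 1
  }
  if (decision_values) {
    colnames(dec) <- vapply(model$models,
                            function(b) paste(b$pair, collapse = "/"), "")
    return(dec)
  }
  factor(model$classes[max.col(votes, ties.method = "first")],
         levels = model$classes)
}

#' Serialize a fitted model to JSON
#'
#' @param model an `ldc_model` or `svm_model`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1]
  obj <- list(format = "plaqueseg-model", version = 1L, kind = kind,
              model = unclass(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Read a model serialized with [write_model()]
#'
#' @param path JSON file written by [write_model()].
#' @return The deserialized model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "plaqueseg-model"))
    stop_format("not a plaqueseg model file")
  m <- obj$model
  if (obj$kind == "ldc_model") {
    m$means <- matrix(unlist(m$means), ncol = length(m$classes))
    m$means <- t(m$means)  # stored classes x features
    m$cov <- as.matrix(m$cov)
    rownames(m$means) <- m$classes
  }
  structure(m, class = obj$kind)
}
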