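# Internal helpers: error conditions, seeded RNG, separable image operators.
#
# Conventions used throughout the package:
#   * volumes are R arrays indexed [i, j, k] where (i, j) are in-plane and k
#     is the slice; spacing is c(sx, sy, sz) in mm
#   * physical coordinates: x = (i - 1) * sx (voxel centers, 0-based origin)
#   * component codes: 0 = background, 1 = C, 2 = F, 3 = LRNC

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("plq_validation_error", "plq_error", "error")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("plq_numerical_error", "plq_error", "error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("plq_format_error", "plq_error", "error")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code does not disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

# Derive a reproducible sub-seed from a master seed (kept below 2^31).
subseed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  x != 0
}

check_same_dim <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b)))
    stop_validation(sprintf("%s must share one grid (got %s vs %s)",
                            what, paste(dim(a), collapse = "x"),
                            paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# Promote a matrix to a single-slice 3D array.
as_vol <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop_validation("expected a 2D or 3D array")
  x
}

## ---- separable in-plane operators (built as dense banded matrices) ----

# 1D sampled-Gaussian blur matrix with replicate boundary; h = grid step (mm).
gauss_blur_matrix <- function(n, h, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma / h))
  k <- stats::dnorm((-r:r) * h, sd = sigma)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    j <- pmin(pmax(idx + o, 1L), n)
    B[cbind(idx, j)] <- B[cbind(idx, j)] + k[o + r + 1L]
  }
  B
}

# 1D first-derivative matrix: central differences, one-sided at the edges.
diff1_matrix <- function(n, h) {
  D <- matrix(0, n, n)
  if (n == 1L) return(D)
  for (i in 2:(n - 1L)) {
    D[i, i - 1L] <- -1 / (2 * h)
    D[i, i + 1L] <- 1 / (2 * h)
  }
  D[1L, 1L] <- -1 / h; D[1L, 2L] <- 1 / h
  D[n, n - 1L] <- -1 / h; D[n, n] <- 1 / h
  D
}

# 1D second-derivative matrix: (1, -2, 1)/h^2 in the interior, zero at edges.
diff2_matrix <- function(n, h) {
  D <- matrix(0, n, n)
  if (n < 3L) return(D)
  for (i in 2:(n - 1L)) {
    D[i, i - 1L] <- 1 / h^2
    D[i, i] <- -2 / h^2
    D[i, i + 1L] <- 1 / h^2
  }
  D
}

# Apply row/column operator matrices to every slice of a volume.
apply_inplane <- function(vol, Mx, My) {
  vol <- as_vol(vol)
  out <- array(0, c(nrow(Mx), nrow(My), dim(vol)[3]))
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- Mx %*% vol[, , k] %*% t(My)
  out
}

## ---- cubic B-spline interpolation machinery ----

# Cubic B-spline basis function.
bspline3 <- function(t) {
  a <- abs(t)
  out <- numeric(length(t))
  i1 <- a < 1
  out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

# Interpolation system for cubic B-spline coefficients with mirror boundary:
# f(i) = (c[i-1] + 4 c[i] + c[i+1]) / 6, c[-1] = c[1], c[n] = c[n-2].
bspline_coef_solve <- function(n) {
  if (n < 3L) return(diag(n))
  T <- matrix(0, n, n)
  for (i in 2:(n - 1L)) {
    T[i, i - 1L] <- 1 / 6; T[i, i] <- 4 / 6; T[i, i + 1L] <- 1 / 6
  }
  T[1L, 1L] <- 4 / 6; T[1L, 2L] <- 2 / 6
  T[n, n] <- 4 / 6; T[n, n - 1L] <- 2 / 6
  solve(T)
}

mirror_index <- function(i, n) {
  # reflect 0-based index into [0, n-1] (whole-sample symmetry)
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- i %% p
  i[i < 0] <- i[i < 0] + p
  ifelse(i > (n - 1L), p - i, i)
}

# Evaluation matrix: rows evaluate the cubic B-spline at 0-based positions.
bspline_eval_matrix <- function(pos, n) {
  E <- matrix(0, length(pos), n)
  for (m in seq_along(pos)) {
    base <- floor(pos[m])
    for (o in -1:2) {
      i <- base + o
      w <- bspline3(pos[m] - i)
      if (w > 0) {
        j <- mirror_index(i, n) + 1L
        E[m, j] <- E[m, j] + w
      }
    }
  }
  E
}

# Linear interpolation evaluation matrix (for label indicator maps).
linear_eval_matrix <- function(pos, n) {
  E <- matrix(0, length(pos), n)
  pos <- pmin(pmax(pos, 0), n - 1L)
  for (m in seq_along(pos)) {
    i0 <- floor(pos[m])
    f <- pos[m] - i0
    i0 <- min(i0, n - 1L)
    i1 <- min(i0 + 1L, n - 1L)
    E[m, i0 + 1L] <- E[m, i0 + 1L] + (1 - f)
    E[m, i1 + 1L] <- E[m, i1 + 1L] + f
  }
  E
}
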