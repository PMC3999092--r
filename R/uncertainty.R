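# The three mechanisms for handling misregistered training labels:
#   1. soft labels: Gaussian-blurred class maps normalized to sum 1, then
#      multiplied per slice by Dice^n, so boundary voxels and badly
#      registered slices contribute less;
#   2. contour-distance weights: per-voxel weights that fall linearly from 1
#      (contours agree) to 0 (5 mm apart), blended by the voxel's relative
#      position between lumen and outer wall;
#   3. robust Gaussian outlier rejection: per class, iteratively reweighted
#      mean/covariance estimation followed by rejection of the 10% of
#      samples with the largest Mahalanobis distance.

#' Soft labels from blurred class maps with Dice^n slice weighting
#'
#' Each component's binary map is blurred in-plane with a Gaussian of scale
#' `sigma_blur_mm`, the three blurred maps are normalized to sum to 1 per
#' voxel, and every voxel on slice s is multiplied by `dice[s]^n`. With
#' `sigma_blur_mm = 0` and `n_exponent = 0` the result is exactly the one-hot
#' hard labels. Voxels where all three blurred maps vanish (outside the
#' blurred supports), and slices with undefined Dice, are flagged excluded.
#'
#' @param labels integer 3D label array (0 = background, 1..3 = C/F/LRNC).
#' @param dice_per_slice numeric vector of per-slice Dice values (NA =
#'   undefined slice, excluded).
#' @param sigma_blur_mm Gaussian blur scale in mm, >= 0.
#' @param n_exponent Dice exponent, >= 0.
#' @param spacing_mm voxel size in mm.
#' @return An object of class `soft_label_field`: list of per-class weight
#'   arrays `w` (named C, F, LRNC), logical array `included`, and the
#'   parameters.
#' @export
soft_labels <- function(labels, dice_per_slice, sigma_blur_mm, n_exponent,
                        spacing_mm) {
  if (sigma_blur_mm < 0 || n_exponent < 0)
    stop_validation("sigma_blur_mm and n_exponent must be >= 0")
  labels <- as_vol(labels)
  nz <- dim(labels)[3]
  if (length(dice_per_slice) != nz)
    stop_validation("dice_per_slice must have one value per slice")
  blur <- lapply(1:3, function(c) {
    m <- (labels == c) * 1
    if (sigma_blur_mm == 0) return(m)
    Bx <- gauss_blur_matrix(dim(labels)[1], spacing_mm[1], sigma_blur_mm)
    By <- gauss_blur_matrix(dim(labels)[2], spacing_mm[2], sigma_blur_mm)
    apply_inplane(m, Bx, By)
  })
  denom <- blur[[1]] + blur[[2]] + blur[[3]]
  if (all(denom == 0))
    stop_validation("degenerate input: all blurred class maps are zero")
  slice_w <- ifelse(is.na(dice_per_slice), NA_real_, dice_per_slice^n_exponent)
  sw <- array(rep(slice_w, each = prod(dim(labels)[1:2])), dim(labels))
  included <- denom > 0 & !is.na(sw)
  w <- lapply(blur, function(b) {
    out <- array(0, dim(labels))
    out[included] <- b[included] / denom[included] * sw[included]
    out
  })
  names(w) <- COMPONENTS
  structure(list(w = w, included = included, sigma_blur_mm = sigma_blur_mm,
                 n_exponent = n_exponent, dice_per_slice = dice_per_slice),
            class = "soft_label_field")
}

#' Contour-distance weight kernel
#'
#' The per-voxel combination rule: weights for the lumen and outer-wall
#' contours fall linearly from 1 at zero contour difference to 0 at
#' `max_dist_mm`, and are blended as `w = (1 - r) * w_lumen + r * w_outer`
#' where `r` is the relative position between lumen (`r = 0`) and outer wall
#' (`r = 1`), so agreement of the nearby contour dominates.
#'
#' @param delta_lumen_mm,delta_outer_mm absolute contour differences in mm.
#' @param r relative position in `[0, 1]`.
#' @param max_dist_mm difference at which the weight reaches 0 (default 5).
#' @return Weights in `[0, 1]` (vectorized).
#' @export
contour_weight <- function(delta_lumen_mm, delta_outer_mm, r, max_dist_mm = 5) {
  w_lum <- pmin(pmax(1 - delta_lumen_mm / max_dist_mm, 0), 1)
  w_out <- pmin(pmax(1 - delta_outer_mm / max_dist_mm, 0), 1)
  (1 - r) * w_lum + r * w_out
}

#' Contour-distance weight field
#'
#' Per voxel, the lumen (outer) contour difference is the absolute difference
#' of the unsigned distance-to-lumen (-outer) maps between the reference and
#' in vivo geometries; the relative position `r = d_lumen / (d_lumen +
#' d_outer)` uses the in vivo unsigned distances. Voxels with
#' `d_lumen + d_outer = 0` are excluded with a warning.
#'
#' @param ref_geometry,invivo_geometry [wall_geometry()] objects on one grid.
#' @param max_dist_mm contour difference mapped to weight 0 (default 5 mm).
#' @return An object of class `contour_weight_field`: arrays `w_lumen`,
#'   `w_outer`, `r`, `w`, and logical `excluded`.
#' @export
contour_weights <- function(ref_geometry, invivo_geometry, max_dist_mm = 5) {
  check_same_dim(ref_geometry$lumen, invivo_geometry$lumen, "geometries")
  d_lum <- abs(abs(ref_geometry$d_lumen) - abs(invivo_geometry$d_lumen))
  d_out <- abs(abs(ref_geometry$d_outer) - abs(invivo_geometry$d_outer))
  dl <- abs(invivo_geometry$d_lumen)
  do <- abs(invivo_geometry$d_outer)
  denom <- dl + do
  excluded <- !is.finite(denom) | denom == 0 | !is.finite(d_lum) | !is.finite(d_out)
  if (any(excluded & invivo_geometry$wall))
    warning("excluding wall voxel(s) with d_lumen + d_outer = 0 or undefined distances")
  r <- array(0, dim(dl))
  r[!excluded] <- dl[!excluded] / denom[!excluded]
  w <- array(0, dim(dl))
  w[!excluded] <- contour_weight(d_lum[!excluded], d_out[!excluded],
                                 r[!excluded], max_dist_mm)
  structure(list(w_lumen = pmin(pmax(1 - d_lum / max_dist_mm, 0), 1),
                 w_outer = pmin(pmax(1 - d_out / max_dist_mm, 0), 1),
                 r = r, w = w, excluded = excluded,
                 max_dist_mm = max_dist_mm),
            class = "contour_weight_field")
}

#' Robust Gaussian fit by iterative reweighting
#'
#' Estimates a Gaussian target distribution robustly: starting from a
#' high-breakdown initial estimate (coordinatewise median and a diagonal
#' MAD^2 scatter), samples are iteratively reweighted by
#' `exp(-d^2/2)` of their Mahalanobis distance `d` under the current
#' estimate (floored at 1e-12), and the weighted mean/covariance are
#' recomputed (with the Gaussian consistency factor 2 and a small ridge,
#' `1e-6 * trace/d`) until the relative parameter change drops below `1e-8`
#' or 50 iterations. On clean Gaussian data the estimate agrees with the
#' plain sample mean/covariance up to sampling error; clustered
#' contamination is driven to negligible weight.
#'
#' @param X numeric matrix (samples x features), at least `ncol(X) + 2` rows.
#' @param max_iter,tol,ridge iteration controls.
#' @return An object of class `robust_gaussian_fit`: `mean`, `cov`,
#'   `iterations`, `converged`, and the final `weights`.
#' @export
robust_gaussian_fit <- function(X, max_iter = 50, tol = 1e-8, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 2)
    stop_validation(sprintf("need at least %d samples for %d features", d + 2, d))
  w <- rep(1, n)
  # high-breakdown initialization (coordinatewise median, MAD^2 diagonal):
  # starting from the plain mean/covariance masks clustered contamination,
  # because a contaminated direction's inflated variance hides its outliers
  mu <- apply(X, 2, stats::median)
  s0 <- apply(X, 2, stats::mad)
  fallback <- apply(X, 2, stats::sd)
  s0[s0 == 0] <- fallback[s0 == 0]
  S <- diag(s0^2, d)
  regularize <- function(S) {
    tr <- sum(diag(S))
    S + diag(ridge * tr / d, d)
  }
  safe_inv <- function(S) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop_numerical("singular covariance in robust Gaussian fit")
    chol2inv(ch)
  }
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    S_reg <- regularize(S)
    Sinv <- safe_inv(S_reg)
    d2 <- stats::mahalanobis(X, mu, Sinv, inverted = TRUE)
    w <- pmax(exp(-d2 / 2), 1e-12)
    sw <- sum(w)
    mu_new <- colSums(X * w) / sw
    Xc <- sweep(X, 2, mu_new)
    # the factor 2 is the Gaussian consistency correction: weighting a
    # Gaussian sample by exp(-d^2/2) halves its covariance, so without it
    # the iteration would implode the estimate on clean data
    S_new <- 2 * crossprod(Xc * sqrt(w)) / sw
    rel <- max(max(abs(mu_new - mu)) / (max(abs(mu)) + 1e-12),
               max(abs(S_new - S)) / (max(abs(S)) + 1e-12))
    mu <- mu_new; S <- S_new
    if (rel < tol) { converged <- TRUE; break }
  }
  S_reg <- regularize(S)
  safe_inv(S_reg)  # final singularity check
  structure(list(mean = mu, cov = S_reg, iterations = it,
                 converged = converged, weights = w),
            class = "robust_gaussian_fit")
}

#' Gaussian outlier rejection
#'
#' For each component class independently, fits [robust_gaussian_fit()] to
#' that class's feature vectors and clears `keep` for the `ceil(fraction *
#' n_class)` samples with the largest Mahalanobis distance (ties broken by
#' row order). With `fraction = 0` nothing is rejected.
#'
#' @param table a `sample_table` with a `hard_label` column.
#' @param fraction fraction of each class to reject (default 0.10).
#' @return The table with an updated logical `keep` column.
#' @export
reject_outliers <- function(table, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1)
    stop_validation("fraction must be in [0, 1)")
  if (is.null(table$hard_label))
    stop_validation("table must carry hard labels")
  X <- feature_matrix(table)
  if (is.null(table$keep)) table$keep <- TRUE
  if (fraction == 0) return(table)
  d <- ncol(X)
  for (cls in levels(table$hard_label)) {
    rows <- which(table$hard_label == cls)
    if (length(rows) == 0) next
    if (length(rows) < max(10, d + 2))
      stop_validation(sprintf(
        "class %s has %d samples; need at least %d for outlier rejection",
        cls, length(rows), max(10, d + 2)))
    fit <- robust_gaussian_fit(X[rows, , drop = FALSE])
    Sinv <- chol2inv(chol(fit$cov))
    d2 <- stats::mahalanobis(X[rows, , drop = FALSE], fit$mean, Sinv,
                             inverted = TRUE)
    k <- ceiling(fraction * length(rows))
    rej <- rows[order(-d2)[seq_len(k)]]
    table$keep[rej] <- FALSE
  }
  table
}
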