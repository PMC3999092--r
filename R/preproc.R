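#' Multi-modal image stack
#'
#' Bundles the six co-registered channels (five MR contrasts and one CTA) on a
#' common grid. Channel names are fixed: `t1w2d`, `pdw`, `tof`, `t1w3d_pre`,
#' `t1w3d_post`, `cta`.
#'
#' @param channels named list of 3D intensity arrays sharing one grid.
#' @param spacing_mm numeric length-3 voxel size (in-plane x, in-plane y,
#'   through-plane) in mm.
#' @return An object of class `multimodal_stack`.
#' @export
multimodal_stack <- function(channels, spacing_mm) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop_validation("channels must be a named list")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_validation("spacing_mm must be three positive numbers")
  channels <- lapply(channels, as_vol)
  dims <- lapply(channels, dim)
  for (d in dims) {
    if (!identical(d, dims[[1]]))
      stop_validation("all channels must share one grid")
  }
  structure(list(channels = channels, spacing = as.numeric(spacing_mm)),
            class = "multimodal_stack")
}

#' Vessel-wall geometry with signed distance maps
#'
#' Builds the wall mask (outer minus lumen) and slice-wise signed Euclidean
#' distance maps to the lumen and outer-wall boundaries, in mm. Negative
#' inside the respective mask, positive outside.
#'
#' @param lumen_mask,outer_mask binary 3D arrays; the lumen must be contained
#'   in the outer-wall mask.
#' @param spacing_mm voxel size c(sx, sy, sz) in mm (in-plane isotropic).
#' @return An object of class `wall_geometry` with elements `lumen`, `outer`,
#'   `wall`, `d_lumen`, `d_outer`, `spacing`.
#' @export
wall_geometry <- function(lumen_mask, outer_mask, spacing_mm) {
  lumen <- as_mask(as_vol(lumen_mask))
  outer <- as_mask(as_vol(outer_mask))
  check_same_dim(lumen, outer, "lumen and outer masks")
  if (any(lumen & !outer))
    stop_validation("lumen mask must be contained in the outer-wall mask")
  structure(list(
    lumen = lumen, outer = outer, wall = outer & !lumen,
    d_lumen = signed_distance(lumen, spacing_mm),
    d_outer = signed_distance(outer, spacing_mm),
    spacing = as.numeric(spacing_mm)
  ), class = "wall_geometry")
}

#' Normalize a channel by the statistics of a region of interest
#'
#' Applies the affine map that sets the ROI mean to 0 and the ROI standard
#' deviation to 100; the same affine is applied to the whole channel.
#'
#' @param channel 3D intensity array.
#' @param roi binary mask on the same grid with at least two voxels and
#'   nonzero intensity variance.
#' @return The transformed channel.
#' @export
normalize_roi <- function(channel, roi) {
  channel <- as_vol(channel)
  roi <- as_mask(as_vol(roi))
  check_same_dim(channel, roi, "channel and roi")
  v <- channel[roi]
  if (length(v) < 2)
    stop_validation("roi must contain at least two voxels")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop_validation("degenerate roi: zero intensity variance")
  (channel - mean(v)) / s * 100
}

#' Slice-wise signed Euclidean distance map
#'
#' For every voxel, the in-plane Euclidean distance (mm) to the nearest voxel
#' on the other side of the mask boundary: negative inside the mask, positive
#' outside. Computed per slice with an exact Euclidean distance transform.
#' Slices that are entirely empty (full) get `+Inf` (`-Inf`).
#'
#' @param mask binary 3D (or 2D) array, neither empty nor full overall.
#' @param spacing_mm voxel size in mm; in-plane spacing must be isotropic.
#' @return Array of signed distances in mm.
#' @export
signed_distance <- function(mask, spacing_mm) {
  mask <- as_mask(as_vol(mask))
  if (!any(mask) || all(mask))
    stop_validation("degenerate mask: empty or full")
  h <- spacing_mm[1]
  if (abs(spacing_mm[1] - spacing_mm[2]) > 1e-9 * h)
    stop_validation("signed_distance requires isotropic in-plane spacing")
  out <- array(0, dim(mask))
  for (k in seq_len(dim(mask)[3])) {
    m <- mask[, , k]
    if (!any(m)) { out[, , k] <- Inf; next }
    if (all(m)) { out[, , k] <- -Inf; next }
    d_in <- as.matrix(EBImage::distmap(m * 1))        # inside: dist to nearest outside voxel
    d_out <- as.matrix(EBImage::distmap((1 - m) * 1)) # outside: dist to nearest inside voxel
    out[, , k] <- (d_out - d_in) * h
  }
  out
}

#' Resample a volume in-plane
#'
#' Intensity images are resampled with cubic B-spline interpolation (exact
#' interpolation of the input samples, mirror boundary). Label maps are
#' resampled by linear interpolation of the per-class indicator maps followed
#' by per-voxel argmax; ties go to the lowest class code, so the result is
#' always a partition. Through-plane spacing is unchanged.
#'
#' @param x 3D array (intensities, or integer label codes if `labels = TRUE`).
#' @param spacing_mm current voxel size c(sx, sy, sz) in mm.
#' @param target_mm target in-plane spacing, default 0.25 mm.
#' @param labels logical; treat `x` as a label map.
#' @return list with `data` (resampled array) and `spacing` (new voxel size).
#' @export
resample_inplane <- function(x, spacing_mm, target_mm = 0.25, labels = FALSE) {
  if (missing(spacing_mm) || is.null(spacing_mm) || any(is.na(spacing_mm)))
    stop_validation("spacing metadata is required for resampling")
  x <- as_vol(x)
  nx <- dim(x)[1]; ny <- dim(x)[2]
  mx <- max(1L, as.integer(round(nx * spacing_mm[1] / target_mm)))
  my <- max(1L, as.integer(round(ny * spacing_mm[2] / target_mm)))
  px <- (seq_len(mx) - 1) * target_mm / spacing_mm[1]
  py <- (seq_len(my) - 1) * target_mm / spacing_mm[2]
  newsp <- c(target_mm, target_mm, spacing_mm[3])
  if (labels) {
    lev <- sort(unique(as.vector(x)))
    Ex <- linear_eval_matrix(px, nx)
    Ey <- linear_eval_matrix(py, ny)
    score <- array(0, c(mx, my, dim(x)[3], length(lev)))
    for (l in seq_along(lev))
      score[, , , l] <- apply_inplane((x == lev[l]) * 1, Ex, Ey)
    flat <- matrix(score, ncol = length(lev))
    win <- max.col(flat, ties.method = "first")
    out <- array(lev[win], c(mx, my, dim(x)[3]))
    return(list(data = out, spacing = newsp))
  }
  Ex <- bspline_eval_matrix(px, nx) %*% bspline_coef_solve(nx)
  Ey <- bspline_eval_matrix(py, ny) %*% bspline_coef_solve(ny)
  list(data = apply_inplane(x, Ex, Ey), spacing = newsp)
}

#' Per-slice Dice overlap of two masks
#'
#' `2|A n B| / (|A| + |B|)` per slice; slices where both masks are empty are
#' undefined and returned as `NA` (they are excluded from training).
#'
#' @param wall_a,wall_b binary 3D arrays on the same grid.
#' @return Numeric vector, one value in `[0, 1]` (or `NA`) per slice.
#' @export
dice_per_slice <- function(wall_a, wall_b) {
  a <- as_mask(as_vol(wall_a)); b <- as_mask(as_vol(wall_b))
  check_same_dim(a, b, "masks")
  vapply(seq_len(dim(a)[3]), function(k) {
    sa <- sum(a[, , k]); sb <- sum(b[, , k])
    if (sa + sb == 0) return(NA_real_)
    2 * sum(a[, , k] & b[, , k]) / (sa + sb)
  }, numeric(1))
}

# In-plane boundary voxels: mask voxels with a 4-neighbour outside the mask
# (the image edge counts as outside).
boundary_mask <- function(mask) {
  mask <- as_mask(as_vol(mask))
  out <- array(FALSE, dim(mask))
  nx <- dim(mask)[1]; ny <- dim(mask)[2]
  for (k in seq_len(dim(mask)[3])) {
    m <- mask[, , k]
    pad <- matrix(FALSE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- m
    inner <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
      pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
    out[, , k] <- m & !inner
  }
  out
}

#' Mean contour distance between two masks
#'
#' Symmetric mean of in-plane nearest-boundary distances (mm): the average of
#' the two directed means over boundary voxels, pooled over slices where both
#' masks are nonempty.
#'
#' @param mask_a,mask_b binary 3D arrays on the same grid, both nonempty.
#' @param spacing_mm voxel size in mm (in-plane isotropic).
#' @return Mean contour distance in mm.
#' @export
mean_contour_distance <- function(mask_a, mask_b, spacing_mm) {
  a <- as_mask(as_vol(mask_a)); b <- as_mask(as_vol(mask_b))
  check_same_dim(a, b, "masks")
  if (!any(a) || !any(b))
    stop_validation("degenerate input: empty mask")
  h <- spacing_mm[1]
  ba <- boundary_mask(a); bb <- boundary_mask(b)
  d_ab <- c(); d_ba <- c()
  for (k in seq_len(dim(a)[3])) {
    if (!any(ba[, , k]) || !any(bb[, , k])) next
    dist_to_bb <- as.matrix(EBImage::distmap((1 - bb[, , k]) * 1)) * h
    dist_to_ba <- as.matrix(EBImage::distmap((1 - ba[, , k]) * 1)) * h
    d_ab <- c(d_ab, dist_to_bb[ba[, , k]])
    d_ba <- c(d_ba, dist_to_ba[bb[, , k]])
  }
  if (length(d_ab) == 0)
    stop_validation("no slice has boundaries in both masks")
  (mean(d_ab) + mean(d_ba)) / 2
}
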