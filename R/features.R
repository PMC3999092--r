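# Per-voxel feature extraction and training-sample assembly.
#
# The full feature set has 24 columns: the five normalized MR intensities,
# the same five blurred with a Gaussian (sigma = 1 mm), their in-plane
# gradient magnitudes and Laplacians at the same scale, the original CTA
# intensity, the unsigned distances to the lumen and outer wall, and the
# product of those distances (which lets a linear classifier keep the
# necrotic core away from both boundaries).

subset_channels <- function(subset) {
  switch(subset,
         "all" = , "mri+distances" = , "mri" = MR_CHANNELS,
         "cta" = , "cta+distances" = , "distances" = character(0))
}

subset_has_cta <- function(subset) subset %in% c("all", "cta", "cta+distances")
subset_has_dist <- function(subset)
  subset %in% c("all", "distances", "mri+distances", "cta+distances")

#' Normalize the MR channels of a stack within a region of interest
#'
#' Applies [normalize_roi()] (mean 0, SD 100 inside the ROI) to each of the
#' five MR channels; the CTA channel is left at its original intensities.
#'
#' @param stack a [multimodal_stack()].
#' @param roi binary mask (typically the outer-wall mask of the subject).
#' @return The stack with normalized MR channels.
#' @export
prepare_stack <- function(stack, roi) {
  for (ch in intersect(MR_CHANNELS, names(stack$channels)))
    stack$channels[[ch]] <- normalize_roi(stack$channels[[ch]], roi)
  stack
}

#' Extract per-voxel features
#'
#' Computes the configured feature subset at every voxel of `mask` and
#' returns one row per voxel. Distance features are taken from `geometry`:
#' pass the reference (histology) geometry for training rows and the in vivo
#' geometry for testing rows. MR channels are expected to be normalized
#' already (see [prepare_stack()]); the CTA channel is used as-is.
#'
#' @param images a [multimodal_stack()].
#' @param geometry a [wall_geometry()] supplying the distance features.
#' @param mask binary array of voxels to turn into rows (default: the
#'   geometry's wall mask).
#' @param sigma_mm Gaussian scale (mm) for the blurred/derivative features.
#' @param subset one of `"all"`, `"mri"`, `"cta"`, `"distances"`,
#'   `"mri+distances"`, `"cta+distances"` (24/20/1/3/23/4 columns).
#' @param subject subject identifier stored with each row.
#' @param labels optional integer label array; adds a `hard_label` column.
#' @return A `sample_table` data.frame with columns `subject`, `slice`,
#'   `voxel` (linear index into the grid), the feature columns (recorded in
#'   `attr(, "feature_cols")`), and optionally `hard_label`.
#' @export
extract_features <- function(images, geometry, mask = geometry$wall,
                             sigma_mm = 1, subset = "all", subject = 1L,
                             labels = NULL) {
  if (!subset %in% FEATURE_SUBSETS)
    stop_validation(sprintf("unknown feature subset '%s'", subset))
  mask <- as_mask(as_vol(mask))
  sp <- images$spacing
  need <- subset_channels(subset)
  if (subset_has_cta(subset)) need <- c(need, "cta")
  missing_ch <- setdiff(need, names(images$channels))
  if (length(missing_ch))
    stop_validation(paste("missing channel(s) for subset:",
                          paste(missing_ch, collapse = ", ")))
  idx <- which(mask)
  ai <- arrayInd(idx, dim(mask))
  feats <- list()
  mr <- subset_channels(subset)
  if (length(mr)) {
    nx <- dim(mask)[1]; ny <- dim(mask)[2]
    Bx <- gauss_blur_matrix(nx, sp[1], sigma_mm)
    By <- gauss_blur_matrix(ny, sp[2], sigma_mm)
    Dx <- diff1_matrix(nx, sp[1]); Dy <- diff1_matrix(ny, sp[2])
    Dxx <- diff2_matrix(nx, sp[1]); Dyy <- diff2_matrix(ny, sp[2])
    for (ch in mr) {
      v <- as_vol(images$channels[[ch]])
      bl <- apply_inplane(v, Bx, By)
      gx <- apply_inplane(bl, Dx, diag(ny))
      gy <- apply_inplane(bl, diag(nx), Dy)
      lap <- apply_inplane(bl, Dxx, diag(ny)) + apply_inplane(bl, diag(nx), Dyy)
      feats[[ch]] <- v[idx]
      feats[[paste0(ch, "_blur")]] <- bl[idx]
      feats[[paste0(ch, "_grad")]] <- sqrt(gx[idx]^2 + gy[idx]^2)
      feats[[paste0(ch, "_lapl")]] <- lap[idx]
    }
    # column order: 5 intensities, 5 blurred, 5 gradients, 5 Laplacians
    ord <- c(mr, paste0(mr, "_blur"), paste0(mr, "_grad"), paste0(mr, "_lapl"))
    feats <- feats[ord]
  }
  if (subset_has_cta(subset))
    feats[["cta"]] <- as_vol(images$channels[["cta"]])[idx]
  if (subset_has_dist(subset)) {
    dl <- abs(geometry$d_lumen)[idx]
    do <- abs(geometry$d_outer)[idx]
    feats[["d_lumen"]] <- dl
    feats[["d_outer"]] <- do
    feats[["d_prod"]] <- dl * do
  }
  tab <- data.frame(subject = subject, slice = ai[, 3], voxel = idx)
  for (nm in names(feats)) tab[[nm]] <- feats[[nm]]
  if (!is.null(labels)) {
    code <- as_vol(labels)[idx]
    tab$hard_label <- factor(COMPONENTS[ifelse(code >= 1 & code <= 3, code, NA)],
                             levels = COMPONENTS)
  }
  attr(tab, "feature_cols") <- names(feats)
  attr(tab, "subset") <- subset
  attr(tab, "sigma_mm") <- sigma_mm
  class(tab) <- c("sample_table", "data.frame")
  tab
}

feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc))
    stop_validation("table has no feature_cols attribute")
  fc
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_cols(table), drop = FALSE])
}

#' Subsample a training table
#'
#' Draws a fixed fraction of the rows with a seeded permutation, stratified
#' by subject and slice (floor rounding per stratum), so the identical
#' subset is reused across experiment configurations for a given seed.
#'
#' @param table a `sample_table`.
#' @param fraction fraction of rows to keep, in (0, 1].
#' @param seed integer seed.
#' @return The subsampled table (row order preserved).
#' @export
subsample_training <- function(table, fraction = 0.10, seed = 1) {
  if (nrow(table) == 0)
    stop_validation("degenerate input: empty table")
  if (fraction <= 0 || fraction > 1)
    stop_validation("fraction must be in (0, 1]")
  if (fraction == 1) return(table)
  grp <- interaction(table$subject, table$slice, drop = TRUE)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), grp), function(rows) {
      k <- floor(fraction * length(rows))
      if (k == 0) return(integer(0))
      sort(rows[sample.int(length(rows))[seq_len(k)]])
    }), use.names = FALSE)
  })
  out <- table[sort(keep), , drop = FALSE]
  attributes(out)[c("feature_cols", "subset", "sigma_mm")] <-
    attributes(table)[c("feature_cols", "subset", "sigma_mm")]
  class(out) <- class(table)
  out
}
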