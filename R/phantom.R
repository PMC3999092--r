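# Synthetic vessel phantom: annular wall with angular component sectors,
# modality-specific contrasts, additive noise, and a smooth in-plane
# misregistration applied to the reference (histology-like) labels.

default_modality_means <- function() {
  # rows: modality; cols: component means plus background and lumen.
  # CTA: calcium far brighter than soft tissue, and F == LRNC (no CT contrast
  # between fibrous and lipid tissue). Post-contrast T1w: fibrous enhances,
  # LRNC does not — the main MR discriminator between F and LRNC.
  m <- rbind(
    t1w2d      = c(C = 80,  F = 100, LRNC = 120, bg = 20, lumen = 40),
    pdw        = c(C = 80,  F = 110, LRNC = 130, bg = 20, lumen = 60),
    tof        = c(C = 90,  F = 100, LRNC = 115, bg = 20, lumen = 200),
    t1w3d_pre  = c(C = 85,  F = 100, LRNC = 125, bg = 20, lumen = 50),
    t1w3d_post = c(C = 90,  F = 140, LRNC = 100, bg = 20, lumen = 80),
    cta        = c(C = 400, F = 50,  LRNC = 50,  bg = 0,  lumen = 350)
  )
  m
}

#' Specification of a synthetic vessel phantom
#'
#' Defines the geometry, composition, contrast model, noise and
#' misregistration of one synthetic subject. Component fractions are the
#' target relative volumes (% of the vessel wall) of calcification (C),
#' fibrous tissue (F) and lipid-rich necrotic core (LRNC) and must sum to
#' 100.
#'
#' @param n_slices number of slices.
#' @param grid_shape in-plane grid size (voxels), length 2.
#' @param spacing_mm voxel size c(sx, sy, sz) in mm.
#' @param lumen_radius_mm,wall_thickness_mm vessel geometry in mm.
#' @param component_fractions named numeric c(C=, F=, LRNC=), summing to 100.
#' @param modality_means matrix of per-modality mean intensities with rows
#'   `t1w2d, pdw, tof, t1w3d_pre, t1w3d_post, cta` and columns
#'   `C, F, LRNC, bg, lumen`.
#' @param noise_sd named per-modality additive Gaussian noise scale.
#' @param misreg_amplitude_mm peak in-plane displacement (mm) of the smooth
#'   deformation applied to the reference labels; 0 disables it.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 6,
                         grid_shape = c(64, 64),
                         spacing_mm = c(0.5, 0.5, 1.5),
                         lumen_radius_mm = 3,
                         wall_thickness_mm = 4,
                         component_fractions = c(C = 5, F = 57, LRNC = 38),
                         modality_means = default_modality_means(),
                         noise_sd = c(t1w2d = 10, pdw = 10, tof = 10,
                                      t1w3d_pre = 10, t1w3d_post = 10, cta = 15),
                         misreg_amplitude_mm = 1.5,
                         seed = 1) {
  fr <- component_fractions[COMPONENTS]
  if (any(is.na(fr)))
    stop_validation("component_fractions must be named C, F, LRNC")
  if (abs(sum(fr) - 100) > 1e-9)
    stop_validation("component_fractions must sum to 100")
  if (any(fr < 0))
    stop_validation("component_fractions must be non-negative")
  if (misreg_amplitude_mm < 0)
    stop_validation("misreg_amplitude_mm must be >= 0")
  outer_r <- lumen_radius_mm + wall_thickness_mm
  fov <- grid_shape * spacing_mm[1:2]
  if (2 * (outer_r + misreg_amplitude_mm) >= min(fov))
    stop_validation("vessel (plus misregistration margin) does not fit the grid")
  if (!all(ALL_CHANNELS %in% rownames(modality_means)))
    stop_validation("modality_means must have one row per channel")
  structure(list(
    n_slices = as.integer(n_slices), grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm), lumen_radius_mm = lumen_radius_mm,
    wall_thickness_mm = wall_thickness_mm, component_fractions = fr,
    modality_means = modality_means, noise_sd = noise_sd,
    misreg_amplitude_mm = misreg_amplitude_mm, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Voxel-center coordinate grids (mm) for one slice.
slice_coords <- function(spec) {
  list(x = (seq_len(spec$grid_shape[1]) - 1) * spec$spacing_mm[1],
       y = (seq_len(spec$grid_shape[2]) - 1) * spec$spacing_mm[2])
}

#' Generate a synthetic multi-modal vessel phantom
#'
#' Builds an annular vessel wall whose components occupy angular sectors with
#' the requested relative volumes (sector boundaries rotate slowly along the
#' axis and the vessel center drifts slightly), renders the six channels as
#' per-class constant means plus white noise, and derives the reference
#' ("histology") labels by applying a smooth in-plane misregistration to the
#' truth.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_bundle`: `images`
#'   ([multimodal_stack()]), `invivo_geometry` and `reference_geometry`
#'   ([wall_geometry()]), `true_labels` and `reference_labels` (integer
#'   arrays, 0 = background, 1 = C, 2 = F, 3 = LRNC), `per_slice_dice`
#'   (data.frame slice/dice of the in vivo vs reference wall), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$n_slices
    co <- slice_coords(spec)
    cx0 <- mean(range(co$x)); cy0 <- mean(range(co$y))
    lumen <- array(FALSE, c(nx, ny, nz))
    outer <- array(FALSE, c(nx, ny, nz))
    labels <- array(0L, c(nx, ny, nz))
    fr <- spec$component_fractions / 100
    cuts <- 2 * pi * cumsum(c(0, fr))
    rot0 <- stats::runif(1, 0, 2 * pi)
    for (k in seq_len(nz)) {
      # slow axial variation: drifting center, rotating sector boundaries
      cx <- cx0 + 0.6 * sin(2 * pi * k / nz)
      cy <- cy0 + 0.6 * cos(2 * pi * k / nz)
      rot <- rot0 + 0.4 * k
      dx <- outer(co$x - cx, rep(1, ny))
      dy <- outer(rep(1, nx), co$y - cy)
      r <- sqrt(dx^2 + dy^2)
      th <- (atan2(dy, dx) - rot) %% (2 * pi)
      lum <- r < spec$lumen_radius_mm
      out <- r < spec$lumen_radius_mm + spec$wall_thickness_mm
      wall <- out & !lum
      lab <- matrix(0L, nx, ny)
      for (c in 1:3)
        lab[wall & th >= cuts[c] & th < cuts[c + 1]] <- c
      lab[wall & lab == 0L] <- 3L  # th == 2*pi edge case
      lumen[, , k] <- lum; outer[, , k] <- out; labels[, , k] <- lab
    }
    # render channels: per-class constant mean + white noise
    channels <- list()
    for (ch in ALL_CHANNELS) {
      mm <- spec$modality_means[ch, ]
      img <- array(mm[["bg"]], c(nx, ny, nz))
      img[lumen] <- mm[["lumen"]]
      for (c in 1:3) img[labels == c] <- mm[[COMPONENTS[c]]]
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd[[ch]])
      channels[[ch]] <- img
    }
    images <- multimodal_stack(channels, spec$spacing_mm)
    invivo_geometry <- wall_geometry(lumen, outer, spec$spacing_mm)
    warp_seed <- subseed(spec$seed, 1)
    warped <- apply_misregistration(labels, invivo_geometry,
                                    spec$misreg_amplitude_mm, warp_seed)
    dice <- dice_per_slice(invivo_geometry$wall, warped$geometry$wall)
    structure(list(
      images = images, invivo_geometry = invivo_geometry,
      true_labels = labels, reference_labels = warped$labels,
      reference_geometry = warped$geometry,
      per_slice_dice = data.frame(slice = seq_len(nz), dice = dice),
      spec = spec
    ), class = "phantom_bundle")
  })
}

# Smooth in-plane displacement field for one slice: a sum of Gaussian bumps
# with random centers, widths and directions, rescaled to the requested peak
# magnitude. Returns the two displacement components (mm) on the slice grid.
bump_displacement <- function(co, center, amplitude_mm, n_bumps = 4) {
  nx <- length(co$x); ny <- length(co$y)
  ux <- matrix(0, nx, ny); uy <- matrix(0, nx, ny)
  for (b in seq_len(n_bumps)) {
    cx <- center[1] + stats::runif(1, -8, 8)
    cy <- center[2] + stats::runif(1, -8, 8)
    s <- stats::runif(1, 2.5, 5)
    ang <- stats::runif(1, 0, 2 * pi)
    a <- stats::runif(1, 0.5, 1)
    dx <- outer(co$x - cx, rep(1, ny))
    dy <- outer(rep(1, nx), co$y - cy)
    g <- a * exp(-(dx^2 + dy^2) / (2 * s^2))
    ux <- ux + g * cos(ang); uy <- uy + g * sin(ang)
  }
  peak <- max(sqrt(ux^2 + uy^2))
  if (peak > 0) {
    ux <- ux * amplitude_mm / peak
    uy <- uy * amplitude_mm / peak
  }
  list(ux = ux, uy = uy)
}

#' Apply a smooth misregistration to reference labels and geometry
#'
#' Warps the label map and the wall geometry with a smooth, low-frequency
#' in-plane displacement field (a sum of Gaussian bumps per slice) of peak
#' magnitude `amplitude_mm`. Labels and masks are pulled back jointly by
#' nearest-neighbour lookup of a single combined index map, so warped
#' component maps stay mutually exclusive and consistent with the warped
#' wall. Amplitude 0 returns the inputs unchanged.
#'
#' @param labels integer 3D label array (0 = background, 1..3 = components).
#' @param geometry a [wall_geometry()] on the same grid.
#' @param amplitude_mm peak displacement in mm, must be >= 0.
#' @param seed integer seed for the random field.
#' @return list with `labels` (warped label array) and `geometry` (warped
#'   [wall_geometry()]).
#' @export
apply_misregistration <- function(labels, geometry, amplitude_mm, seed) {
  if (amplitude_mm < 0)
    stop_validation("amplitude_mm must be >= 0")
  labels <- as_vol(labels)
  check_same_dim(labels, geometry$lumen, "labels and geometry")
  if (amplitude_mm == 0)
    return(list(labels = labels, geometry = geometry))
  with_seed(seed, {
    sp <- geometry$spacing
    nx <- dim(labels)[1]; ny <- dim(labels)[2]; nz <- dim(labels)[3]
    co <- list(x = (seq_len(nx) - 1) * sp[1], y = (seq_len(ny) - 1) * sp[2])
    # combined index map: 0 bg, 1..3 components, 4 lumen
    comb <- labels
    comb[geometry$lumen] <- 4L
    out <- array(0L, dim(comb))
    # center the bumps on the wall's center of mass
    wall_idx <- which(geometry$wall, arr.ind = TRUE)
    center <- c(mean(co$x[wall_idx[, 1]]), mean(co$y[wall_idx[, 2]]))
    ii <- matrix(rep(seq_len(nx), ny), nx, ny)
    jj <- matrix(rep(seq_len(ny), each = nx), nx, ny)
    for (k in seq_len(nz)) {
      u <- bump_displacement(co, center, amplitude_mm)
      si <- as.integer(round(ii + u$ux / sp[1]))
      sj <- as.integer(round(jj + u$uy / sp[2]))
      ok <- si >= 1 & si <= nx & sj >= 1 & sj <= ny
      sl <- matrix(0L, nx, ny)
      sl[ok] <- comb[, , k][cbind(si[ok], sj[ok])]
      out[, , k] <- sl
    }
    new_lumen <- out == 4L
    new_wall <- out >= 1L & out <= 3L
    new_labels <- out
    new_labels[new_lumen] <- 0L
    list(labels = new_labels,
         geometry = wall_geometry(new_lumen, new_lumen | new_wall, sp))
  })
}

#' Generate a cohort of phantom subjects
#'
#' Subjects share the spec's geometry and contrast model but differ in noise,
#' misregistration and (optionally) composition: per-subject component
#' fractions are jittered with Gaussian noise and renormalized to 100, and
#' the lumen radius is scaled by a small random factor, so relative volumes
#' vary across subjects as they do across patients.
#'
#' @param n_subjects number of subjects.
#' @param spec base [phantom_spec()].
#' @param seed master seed; each subject derives its own seed from it.
#' @param vary_fractions_sd SD (percentage points) of the composition jitter.
#' @param vary_geometry relative SD of the lumen-radius jitter.
#' @return list of `phantom_bundle` objects, named `S1`, `S2`, ...
#' @export
phantom_cohort <- function(n_subjects, spec = phantom_spec(), seed = 1,
                           vary_fractions_sd = 3, vary_geometry = 0.05) {
  with_seed(seed, {
    cohort <- list()
    for (s in seq_len(n_subjects)) {
      sp <- spec
      if (vary_fractions_sd > 0) {
        fr <- pmax(spec$component_fractions +
                     stats::rnorm(3, sd = vary_fractions_sd), 1)
        sp$component_fractions <- fr / sum(fr) * 100
      }
      if (vary_geometry > 0)
        sp$lumen_radius_mm <- spec$lumen_radius_mm *
          exp(stats::rnorm(1, sd = vary_geometry))
      sp$seed <- as.integer(subseed(seed, s) %% 2147483647)
      cohort[[paste0("S", s)]] <- generate_phantom(sp)
    }
    cohort
  })
}

#' Write a phantom bundle to disk
#'
#' Exports each channel, the lumen/outer masks of both spaces, the true and
#' reference label maps (NIfTI by default), and the per-slice Dice table as
#' CSV, in the layout expected by [validate_cohort()].
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @param format `"nii"` or `"mha"`.
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(bundle, dir, format = c("nii", "mha")) {
  format <- match.arg(format)
  ext <- if (format == "nii") ".nii.gz" else ".mha"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- bundle$images$spacing
  for (ch in names(bundle$images$channels))
    write_volume(bundle$images$channels[[ch]], sp, file.path(dir, paste0(ch, ext)))
  vols <- list(lumen = bundle$invivo_geometry$lumen * 1,
               outer = bundle$invivo_geometry$outer * 1,
               ref_lumen = bundle$reference_geometry$lumen * 1,
               ref_outer = bundle$reference_geometry$outer * 1,
               true_labels = bundle$true_labels,
               ref_labels = bundle$reference_labels)
  for (nm in names(vols))
    write_volume(vols[[nm]], sp, file.path(dir, paste0(nm, ext)))
  utils::write.csv(bundle$per_slice_dice, file.path(dir, "dice.csv"),
                   row.names = FALSE)
  invisible(dir)
}
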