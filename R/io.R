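# Volume I/O (NIfTI via RNifti, MetaImage natively) and cohort validation.

#' Read a volumetric image
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`).
#'
#' @param path file to read.
#' @return list with `data` (numeric array), `spacing` (mm) and `metadata`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_validation(paste("file not found:", path))
  ext <- tolower(sub(".*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop_format(paste("bad NIfTI file:",
                                                          conditionMessage(e))))
    arr <- array(as.numeric(img), dim(img))
    return(list(data = arr, spacing = RNifti::pixdim(img)[1:3],
                metadata = list(format = "nifti")))
  }
  if (ext %in% c(".mha", ".mhd")) return(read_metaimage(path))
  stop_format(paste("unknown volume format:", path))
}

#' Write a volumetric image
#'
#' @param data numeric 3D array.
#' @param spacing_mm voxel size in mm.
#' @param path output file; the extension selects the format (`.nii`,
#'   `.nii.gz`, `.mha`).
#' @return Invisibly, the path.
#' @export
write_volume <- function(data, spacing_mm, path) {
  data <- as_vol(data)
  if (length(spacing_mm) != 3 || any(is.na(spacing_mm)))
    stop_validation("spacing_mm must be three numbers")
  ext <- tolower(sub(".*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(array(as.numeric(data), dim(data)))
    RNifti::pixdim(img) <- spacing_mm
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext == ".mha") {
    write_metaimage(data, spacing_mm, path)
  } else {
    stop_format(paste("unknown volume format:", path))
  }
  invisible(path)
}

# MetaImage: plain-text header followed by raw little-endian data (MET_DOUBLE).
write_metaimage <- function(data, spacing_mm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(data), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing_mm, digits = 17),
                                           collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.numeric(data), con, size = 8, endian = "little")
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop_format("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_format("malformed MetaImage header line")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (is.null(hdr$DimSize) || is.null(hdr$ElementType))
    stop_format("MetaImage header missing DimSize or ElementType")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (any(is.na(dims)) || length(dims) < 2) stop_format("bad DimSize")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  else stop_validation("MetaImage header has no ElementSpacing")
  type <- hdr$ElementType
  size <- switch(type, MET_DOUBLE = 8, MET_FLOAT = 4, MET_SHORT = 2,
                 MET_USHORT = 2, MET_UCHAR = 1, MET_CHAR = 1,
                 stop_format(paste("unsupported ElementType:", type)))
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) numeric() else integer()
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  n <- prod(dims)
  v <- readBin(con, what, n = n, size = size,
               endian = if (msb) "big" else "little",
               signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  if (length(v) != n) stop_format("MetaImage data shorter than DimSize")
  list(data = array(as.numeric(v), dims), spacing = spacing,
       metadata = list(format = "metaimage", element_type = type))
}

#' Validate a cohort directory
#'
#' Checks each subject directory (as written by [write_phantom()]) for
#' channel completeness, grid and spacing consistency, and mask containment
#' (lumen inside outer wall). Returns the full list of problems instead of
#' stopping at the first.
#'
#' @param dir cohort directory: one subdirectory per subject.
#' @param subset feature subset the cohort must support (controls which
#'   channels are required).
#' @return Character vector of error messages (empty when valid).
#' @export
validate_cohort <- function(dir, subset = "all") {
  errors <- character(0)
  if (!dir.exists(dir)) return(paste("no such directory:", dir))
  subjects <- list.dirs(dir, recursive = FALSE)
  if (length(subjects) == 0) return(paste("no subject directories in", dir))
  need <- c(subset_channels(subset),
            if (subset_has_cta(subset)) "cta",
            "lumen", "outer", "ref_lumen", "ref_outer", "ref_labels")
  for (sd in subjects) {
    sid <- basename(sd)
    vols <- list()
    for (nm in need) {
      hits <- list.files(sd, pattern = paste0("^", nm, "\\.(nii(\\.gz)?|mha)$"),
                         full.names = TRUE)
      if (length(hits) == 0) {
        errors <- c(errors, sprintf("%s: missing volume '%s'", sid, nm))
        next
      }
      vols[[nm]] <- tryCatch(read_volume(hits[1]), error = function(e) {
        errors <<- c(errors, sprintf("%s: %s unreadable (%s)", sid, nm,
                                     conditionMessage(e)))
        NULL
      })
    }
    vols <- Filter(Negate(is.null), vols)
    if (length(vols) > 1) {
      ref <- vols[[1]]
      for (nm in names(vols)[-1]) {
        if (!identical(dim(vols[[nm]]$data), dim(ref$data)))
          errors <- c(errors, sprintf("%s: %s grid differs from %s", sid, nm,
                                      names(vols)[1]))
        if (max(abs(vols[[nm]]$spacing - ref$spacing)) > 1e-9)
          errors <- c(errors, sprintf("%s: %s spacing differs from %s", sid,
                                      nm, names(vols)[1]))
      }
    }
    for (pair in list(c("lumen", "outer"), c("ref_lumen", "ref_outer"))) {
      if (all(pair %in% names(vols)) &&
          identical(dim(vols[[pair[1]]]$data), dim(vols[[pair[2]]]$data))) {
        if (any(vols[[pair[1]]]$data != 0 & vols[[pair[2]]]$data == 0))
          errors <- c(errors, sprintf("%s: %s not contained in %s", sid,
                                      pair[1], pair[2]))
      }
    }
  }
  errors
}

#' Read a cohort directory into phantom-style bundles
#'
#' @param dir cohort directory previously validated by [validate_cohort()].
#' @param subset feature subset (controls required channels).
#' @return Named list of bundles usable by [loo_crossval()].
#' @export
read_cohort <- function(dir, subset = "all") {
  errs <- validate_cohort(dir, subset)
  if (length(errs))
    stop_validation(paste("invalid cohort:", paste(errs, collapse = "; ")))
  subjects <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (sd in subjects) {
    rd <- function(nm) {
      hits <- list.files(sd, pattern = paste0("^", nm, "\\.(nii(\\.gz)?|mha)$"),
                         full.names = TRUE)
      read_volume(hits[1])
    }
    chans <- c(subset_channels(subset), if (subset_has_cta(subset)) "cta")
    channels <- lapply(stats::setNames(chans, chans), function(nm) rd(nm)$data)
    sp <- rd("lumen")$spacing
    lumen <- rd("lumen")$data != 0; outer <- rd("outer")$data != 0
    rlum <- rd("ref_lumen")$data != 0; rout <- rd("ref_outer")$data != 0
    rlab <- rd("ref_labels")$data
    tl <- list.files(sd, pattern = "^true_labels\\.(nii(\\.gz)?|mha)$",
                     full.names = TRUE)
    true_labels <- if (length(tl)) read_volume(tl[1])$data else rlab
    out[[basename(sd)]] <- structure(list(
      images = multimodal_stack(channels, sp),
      invivo_geometry = wall_geometry(lumen, outer, sp),
      true_labels = true_labels,
      reference_labels = rlab,
      reference_geometry = wall_geometry(rlum, rout, sp),
      per_slice_dice = data.frame(slice = seq_len(dim(lumen)[3]),
                                  dice = dice_per_slice(outer & !lumen,
                                                        rout & !rlum))
    ), class = "phantom_bundle")
  }
  out
}
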