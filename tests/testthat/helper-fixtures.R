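# Shared fixtures: a small, fast phantom spec and toy sample tables.

small_spec <- function(...) {
  phantom_spec(n_slices = 4, grid_shape = c(48, 48),
               spacing_mm = c(0.5, 0.5, 1.5),
               lumen_radius_mm = 2.5, wall_thickness_mm = 3, ...)
}

# Build a sample_table directly from a feature matrix.
make_table <- function(X, labels = NULL, subject = 1L, slice = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  tab <- data.frame(subject = subject, slice = slice, voxel = seq_len(nrow(X)))
  for (j in colnames(X)) tab[[j]] <- X[, j]
  if (!is.null(labels))
    tab$hard_label <- factor(labels, levels = c("C", "F", "LRNC"))
  attr(tab, "feature_cols") <- colnames(X)
  class(tab) <- c("sample_table", "data.frame")
  tab
}

# Disc mask volume helper: radius in mm on a centered grid.
disc_mask <- function(n = 40, spacing = 0.5, radius = 5, nz = 1,
                      center = c(0, 0)) {
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  m <- outer(x - center[1], x - center[2],
             function(a, b) sqrt(a^2 + b^2)) < radius
  array(m, c(n, n, nz))
}
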