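# Volume-based evaluation: relative component volumes per slice and per
# subject, bias / absolute error / Spearman correlation against the
# reference, Friedman comparison of methods, and a forward-feature-selection
# diagnostic.

#' Relative component volumes
#'
#' Each component's voxel count as a percentage of the vessel-wall voxels,
#' per slice and pooled per subject. Slices with an empty wall are excluded
#' with a warning.
#'
#' @param labels integer 3D label array (1..3 = C/F/LRNC) defined on the
#'   wall voxels.
#' @param wall_mask binary wall mask on the same grid.
#' @param subject subject identifier for the output tables.
#' @return list with data.frames `per_slice` (subject, slice, component,
#'   percent) and `per_subject` (subject, component, percent).
#' @export
relative_volumes <- function(labels, wall_mask, subject = 1L) {
  labels <- as_vol(labels)
  wall <- as_mask(as_vol(wall_mask))
  check_same_dim(labels, wall, "labels and wall mask")
  per_slice <- list()
  for (k in seq_len(dim(wall)[3])) {
    n <- sum(wall[, , k])
    if (n == 0) {
      warning(sprintf("slice %d has an empty wall; excluded", k))
      next
    }
    lab <- labels[, , k][wall[, , k]]
    per_slice[[length(per_slice) + 1]] <- data.frame(
      subject = subject, slice = k, component = COMPONENTS,
      percent = 100 * vapply(1:3, function(c) sum(lab == c), numeric(1)) / n)
  }
  if (length(per_slice) == 0)
    stop_validation("no slice has wall voxels")
  per_slice <- do.call(rbind, per_slice)
  lab_all <- labels[wall]
  per_subject <- data.frame(
    subject = subject, component = COMPONENTS,
    percent = 100 * vapply(1:3, function(c) sum(lab_all == c),
                           numeric(1)) / length(lab_all))
  list(per_slice = per_slice, per_subject = per_subject)
}

# Relative volumes from a classified sample table (all rows of one subject's
# test mask), grouped per slice.
volumes_from_predictions <- function(table, labels, subject = NULL) {
  if (is.null(subject)) subject <- table$subject[1]
  lab <- factor(labels, levels = COMPONENTS)
  per_slice <- do.call(rbind, lapply(split(seq_len(nrow(table)), table$slice),
    function(rows) {
      data.frame(subject = subject, slice = table$slice[rows[1]],
                 component = COMPONENTS,
                 percent = 100 * as.vector(table(lab[rows])) / length(rows))
    }))
  rownames(per_slice) <- NULL
  per_subject <- data.frame(subject = subject, component = COMPONENTS,
                            percent = 100 * as.vector(table(lab)) / length(lab))
  list(per_slice = per_slice, per_subject = per_subject)
}

#' Volume agreement metrics
#'
#' Pairs predicted and reference relative volumes (on subject or
#' subject+slice level) and reports, per component: bias (mean of predicted
#' minus reference), mean absolute error, and Spearman rank correlation
#' (midrank ties). Spearman is `NA` (flagged) with fewer than 3 pairs.
#'
#' @param pred,truth data.frames with columns `subject`, optionally `slice`,
#'   `component`, `percent` (as produced by [relative_volumes()]).
#' @return data.frame with one row per component: `component`, `bias`,
#'   `abs_error`, `spearman`, `n`.
#' @export
volume_metrics <- function(pred, truth) {
  keys <- intersect(c("subject", "slice", "component"), names(pred))
  keys <- intersect(keys, names(truth))
  m <- merge(pred, truth, by = keys, suffixes = c("_pred", "_truth"))
  if (nrow(m) == 0) stop_validation("no paired observations")
  do.call(rbind, lapply(COMPONENTS, function(cc) {
    d <- m[m$component == cc, ]
    diff <- d$percent_pred - d$percent_truth
    rho <- if (nrow(d) >= 3)
      stats::cor(d$percent_pred, d$percent_truth, method = "spearman")
    else NA_real_
    data.frame(component = cc, bias = mean(diff), abs_error = mean(abs(diff)),
               spearman = rho, n = nrow(d))
  }))
}

#' Friedman comparison of methods on per-slice errors
#'
#' Ranks the methods within every slice (midrank ties) and computes the
#' Friedman chi-square statistic, the mean-rank table, and pairwise sign
#' tests with Bonferroni correction. Rows are slices, columns methods; the
#' per-slice values are expected to be the three components' absolute
#' volume errors averaged per slice. If every row is constant the problem
#' is degenerate: the statistic is 0 and `degenerate` is set.
#'
#' @param abs_errors numeric matrix (slices x methods) with column names.
#' @return list with `statistic`, `p_value`, `mean_ranks`, `pairwise`
#'   (data.frame of sign-test p-values, Bonferroni-adjusted), `degenerate`.
#' @export
friedman_compare <- function(abs_errors) {
  m <- as.matrix(abs_errors)
  if (ncol(m) < 2) stop_validation("need at least 2 methods")
  if (nrow(m) < 2) stop_validation("need multiple slices")
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  ranks <- t(apply(m, 1, rank))
  mean_ranks <- colMeans(ranks)
  degenerate <- all(apply(m, 1, function(r) max(r) - min(r) == 0))
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    ft <- stats::friedman.test(m)
    stat <- unname(ft$statistic); p <- ft$p.value
  }
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p2) {
    d <- m[, p2[1]] - m[, p2[2]]
    nz <- d != 0
    pv <- if (any(nz))
      stats::binom.test(sum(d[nz] > 0), sum(nz))$p.value else 1
    data.frame(method_a = p2[1], method_b = p2[2], p_value = pv)
  }))
  pw$p_adjusted <- pmin(pw$p_value * nrow(pw), 1)
  list(statistic = stat, p_value = p, mean_ranks = mean_ranks,
       pairwise = pw, degenerate = degenerate)
}

#' Forward feature selection for a component pair
#'
#' Greedy forward selection on the rows of two components, adding at each
#' step the feature that maximizes the training accuracy of a hard-label
#' linear discriminant on the selected set (ties broken by column order).
#'
#' @param table a `sample_table` with `hard_label`.
#' @param class_pair character vector of two component names.
#' @param k number of features to return (default 5).
#' @return Character vector of selected feature names, in selection order.
#' @export
forward_select <- function(table, class_pair, k = 5) {
  if (length(class_pair) != 2 || !all(class_pair %in% COMPONENTS))
    stop_validation("class_pair must name two components")
  rows <- table$hard_label %in% class_pair
  if (sum(table$hard_label[rows] == class_pair[1]) == 0 ||
      sum(table$hard_label[rows] == class_pair[2]) == 0)
    stop_validation("both classes must be present")
  X <- feature_matrix(table)[rows, , drop = FALSE]
  y <- droplevels(factor(table$hard_label[rows], levels = class_pair))
  feats <- colnames(X)
  if (k > length(feats)) {
    warning("fewer features than k; returning all")
    k <- length(feats)
  }
  W <- 1 * outer(as.character(y), class_pair, "==")
  colnames(W) <- class_pair
  selected <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(feats, selected)
    acc <- vapply(cand, function(f) {
      cols <- c(selected, f)
      model <- suppressMessages(fit_ldc(X[, cols, drop = FALSE], W))
      mean(predict_ldc(model, X[, cols, drop = FALSE])$labels == y)
    }, numeric(1))
    selected <- c(selected, cand[which.max(acc)])
  }
  selected
}
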