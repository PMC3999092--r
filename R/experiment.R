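# Leave-one-subject-out cross-validation with nested hyperparameter
# selection, reproducing the training/evaluation protocol on phantom
# cohorts: per subject, the classifier is trained on 10% of the voxels
# inside both the reference and the in vivo wall (labels from the reference
# segmentation, weighted by the configured uncertainty scheme) and tested on
# every voxel of the in vivo wall.

#' Experiment configuration
#'
#' @param method label-handling scheme: `"hard"` (one-hot labels),
#'   `"soft_dice"` (blurred soft labels weighted by Dice^n), `"contour"`
#'   (contour-distance weights), `"outlier"` (Gaussian outlier rejection).
#' @param classifier `"ldc"` or `"svm"`.
#' @param feature_subset one of the subsets accepted by
#'   [extract_features()].
#' @param sigma_grid,n_grid grids for the soft-label blur scale (mm) and
#'   Dice exponent, searched by nested cross-validation.
#' @param svm_C_grid,svm_gamma_grid grids for the SVM penalty and kernel
#'   coefficient.
#' @param training_fraction fraction of dual-wall voxels used for training.
#' @param reject_fraction fraction rejected per class by `method =
#'   "outlier"`.
#' @param target_spacing_mm in-plane resampling target (mm).
#' @param sigma_feature_mm Gaussian scale of the derivative features.
#' @param seed master seed; every random choice derives from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(method = c("hard", "soft_dice", "contour", "outlier"),
                              classifier = c("ldc", "svm"),
                              feature_subset = "all",
                              sigma_grid = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2),
                              n_grid = seq(0, 39, by = 3),
                              svm_C_grid = c(0.1, 1, 10, 100),
                              svm_gamma_grid = c(0.01, 0.1, 1),
                              training_fraction = 0.10,
                              reject_fraction = 0.10,
                              target_spacing_mm = 0.25,
                              sigma_feature_mm = 1,
                              seed = 1) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  if (!feature_subset %in% FEATURE_SUBSETS)
    stop_validation("unknown feature subset")
  if (length(sigma_grid) == 0 || length(n_grid) == 0 ||
      length(svm_C_grid) == 0 || length(svm_gamma_grid) == 0)
    stop_validation("hyperparameter grids must be nonempty")
  structure(list(method = method, classifier = classifier,
                 feature_subset = feature_subset, sigma_grid = sigma_grid,
                 n_grid = n_grid, svm_C_grid = svm_C_grid,
                 svm_gamma_grid = svm_gamma_grid,
                 training_fraction = training_fraction,
                 reject_fraction = reject_fraction,
                 target_spacing_mm = target_spacing_mm,
                 sigma_feature_mm = sigma_feature_mm,
                 seed = seed),
            class = "experiment_config")
}

#' Prepare one subject for training and testing
#'
#' Resamples all channels, masks and label maps in-plane to the target
#' spacing, normalizes the MR channels within the in vivo outer-wall ROI,
#' rebuilds both geometries on the resampled grid, extracts the training
#' table (voxels inside both walls, labels and distance features from the
#' reference segmentation, subsampled to the training fraction with a
#' subject-specific seed) and the testing table (all in vivo wall voxels,
#' distance features from the in vivo geometry), and computes the per-slice
#' wall Dice and the truth volumes.
#'
#' @param bundle a `phantom_bundle` (or an equivalently shaped list for real
#'   data).
#' @param config an [experiment_config()].
#' @param subject_id identifier used in the tables.
#' @param seed_index integer position of the subject in the cohort; together
#'   with the config seed it fixes the training subsample.
#' @return A `subject_prep` list; see Details in the source.
#' @export
prepare_subject <- function(bundle, config, subject_id = 1L, seed_index = 1L) {
  sp <- bundle$images$spacing
  tgt <- config$target_spacing_mm
  rs_lab <- function(x) resample_inplane(x, sp, tgt, labels = TRUE)$data
  # combined maps keep lumen/wall/label consistency through resampling
  iv_comb <- bundle$true_labels
  iv_comb[bundle$invivo_geometry$lumen] <- 4L
  ref_comb <- bundle$reference_labels
  ref_comb[bundle$reference_geometry$lumen] <- 4L
  iv_rs <- rs_lab(iv_comb)
  ref_rs <- rs_lab(ref_comb)
  newsp <- c(tgt, tgt, sp[3])
  iv_geom <- wall_geometry(iv_rs == 4L, iv_rs >= 1L, newsp)
  ref_geom <- wall_geometry(ref_rs == 4L, ref_rs >= 1L, newsp)
  true_labels <- iv_rs; true_labels[iv_rs == 4L] <- 0L
  ref_labels <- ref_rs; ref_labels[ref_rs == 4L] <- 0L
  channels <- lapply(bundle$images$channels,
                     function(ch) resample_inplane(ch, sp, tgt)$data)
  stack <- multimodal_stack(channels, newsp)
  stack <- prepare_stack(stack, iv_geom$outer)
  train_mask <- iv_geom$wall & ref_geom$wall
  train <- extract_features(stack, ref_geom, mask = train_mask,
                            sigma_mm = config$sigma_feature_mm,
                            subset = config$feature_subset,
                            subject = subject_id, labels = ref_labels)
  train <- train[!is.na(train$hard_label), , drop = FALSE]
  train <- subsample_training(train, config$training_fraction,
                              seed = subseed(config$seed, 1000 + seed_index))
  test <- extract_features(stack, iv_geom, mask = iv_geom$wall,
                           sigma_mm = config$sigma_feature_mm,
                           subset = config$feature_subset,
                           subject = subject_id, labels = true_labels)
  dice <- dice_per_slice(iv_geom$wall, ref_geom$wall)
  truth <- relative_volumes(true_labels, iv_geom$wall, subject = subject_id)
  structure(list(subject = subject_id, train = train, test = test,
                 truth = truth, dice = dice, ref_labels = ref_labels,
                 ref_geometry = ref_geom, invivo_geometry = iv_geom,
                 spacing = newsp, cache = new.env(parent = emptyenv())),
            class = "subject_prep")
}

# Per-class weight columns for one subject's training table under a scheme.
# Soft-label fields are cached per sigma so grid searches only blur once.
weight_training_table <- function(prep, method, params) {
  tab <- prep$train
  onehot <- 1 * outer(as.character(tab$hard_label), COMPONENTS, "==")
  tab$keep <- TRUE
  if (method %in% c("hard", "outlier")) {
    W <- onehot
  } else if (method == "soft_dice") {
    key <- sprintf("soft_%.6g", params$sigma)
    base <- prep$cache[[key]]
    if (is.null(base)) {
      fld <- soft_labels(prep$ref_labels, prep$dice, params$sigma, 0,
                         prep$spacing)
      base <- list(w = vapply(COMPONENTS,
                              function(cc) fld$w[[cc]][tab$voxel], numeric(nrow(tab))),
                   inc = fld$included[tab$voxel])
      if (nrow(tab) == 1) base$w <- matrix(base$w, nrow = 1)
      prep$cache[[key]] <- base
    }
    dice_n <- ifelse(is.na(prep$dice), 0, prep$dice)^params$n
    W <- base$w * dice_n[tab$slice]
    tab$keep <- base$inc
  } else if (method == "contour") {
    cw <- prep$cache[["contour"]]
    if (is.null(cw)) {
      cw <- contour_weights(prep$ref_geometry, prep$invivo_geometry)
      prep$cache[["contour"]] <- cw
    }
    W <- onehot * cw$w[tab$voxel]
    tab$keep <- !cw$excluded[tab$voxel]
  } else stop_validation("unknown method")
  tab$w_C <- W[, 1]; tab$w_F <- W[, 2]; tab$w_LRNC <- W[, 3]
  tab
}

# Pool the weighted training tables of several subjects; outlier rejection is
# applied on the pooled table (one rejection over the whole training set).
pooled_training <- function(preps, ids, method, params, reject_fraction) {
  tabs <- lapply(ids, function(i) weight_training_table(preps[[i]], method, params))
  fc <- attr(tabs[[1]], "feature_cols")
  pooled <- do.call(rbind, lapply(tabs, as.data.frame))
  attr(pooled, "feature_cols") <- fc
  class(pooled) <- c("sample_table", "data.frame")
  if (method == "outlier")
    pooled <- reject_outliers(pooled, reject_fraction)
  pooled
}

train_classifier <- function(pooled, config, params) {
  if (config$classifier == "ldc") {
    fit_ldc(pooled)
  } else {
    fit_svm(pooled, C = params$C, gamma = params$gamma)
  }
}

predict_labels <- function(model, test) {
  if (inherits(model, "ldc_model")) predict_ldc(model, test)$labels
  else predict_svm(model, test)
}

# All hyperparameter combinations relevant for a configuration, in the tie
# order smallest sigma, then n, then C, then gamma. Methods without tunable
# parameters get a single empty point.
param_grid <- function(config) {
  soft <- config$method == "soft_dice"
  svm <- config$classifier == "svm"
  sig <- if (soft) sort(config$sigma_grid) else NA
  nn <- if (soft) sort(config$n_grid) else NA
  cc <- if (svm) sort(config$svm_C_grid) else NA
  gg <- if (svm) sort(config$svm_gamma_grid) else NA
  g <- expand.grid(gamma = gg, C = cc, n = nn, sigma = sig)
  g <- g[, c("sigma", "n", "C", "gamma")]
  g[order(g$sigma, g$n, g$C, g$gamma), , drop = FALSE]
}

#' Pick hyperparameters minimizing an objective over a grid
#'
#' Exhaustive evaluation; ties resolve to the lexicographically smallest
#' parameter combination (smallest sigma, then n, then C, then gamma),
#' which is the order of the rows produced by the nested cross-validation.
#'
#' @param grid data.frame of parameter combinations (ordered).
#' @param objective numeric vector of objective values (lower is better),
#'   or a function applied to each row.
#' @return The chosen row of `grid` (single-row data.frame).
#' @export
select_hyperparams <- function(grid, objective) {
  if (is.function(objective))
    objective <- vapply(seq_len(nrow(grid)),
                        function(i) objective(grid[i, , drop = FALSE]),
                        numeric(1))
  if (length(objective) != nrow(grid))
    stop_validation("objective length must match the grid")
  if (all(!is.finite(objective)))
    stop_validation("all grid evaluations are degenerate")
  grid[which.min(objective), , drop = FALSE]
}

# Mean over slices of the three components' absolute volume errors for one
# model evaluated on the given subjects.
slice_error_objective <- function(model, preps, ids) {
  errs <- c()
  for (i in ids) {
    pred <- predict_labels(model, preps[[i]]$test)
    vols <- volumes_from_predictions(preps[[i]]$test, pred,
                                     subject = preps[[i]]$subject)
    m <- merge(vols$per_slice, preps[[i]]$truth$per_slice,
               by = c("subject", "slice", "component"),
               suffixes = c("_pred", "_truth"))
    per_slice <- tapply(abs(m$percent_pred - m$percent_truth),
                        m$slice, mean)
    errs <- c(errs, as.vector(per_slice))
  }
  mean(errs)
}

#' Leave-one-subject-out cross-validation
#'
#' For each held-out subject, hyperparameters (when the configuration has
#' any: blur scale and Dice exponent for `soft_dice`, C and gamma for the
#' SVM) are chosen by a nested leave-one-subject-out loop over the training
#' subjects that minimizes the mean over slices of the three components'
#' absolute volume errors; the classifier is then trained on the pooled
#' weighted training tables of all training subjects and every in vivo wall
#' voxel of the held-out subject is classified.
#'
#' @param cohort list of `phantom_bundle` objects (>= 3 subjects).
#' @param config an [experiment_config()].
#' @param preps optionally, precomputed [prepare_subject()] results.
#' @return list with `per_subject` / `per_slice` volume tables (predicted
#'   and truth percentages side by side), `metrics` (from
#'   [volume_metrics()], per level), `chosen` (hyperparameters per fold)
#'   and `config`.
#' @export
loo_crossval <- function(cohort, config, preps = NULL) {
  if (is.null(preps)) {
    if (length(cohort) < 3) stop_validation("need at least 3 subjects")
    ids <- names(cohort)
    if (is.null(ids)) ids <- paste0("S", seq_along(cohort))
    preps <- lapply(seq_along(cohort), function(i)
      prepare_subject(cohort[[i]], config, subject_id = ids[i], seed_index = i))
    names(preps) <- ids
  }
  ids <- names(preps)
  grid <- param_grid(config)
  chosen <- list()
  pred_slice <- list(); pred_subj <- list()
  truth_slice <- list(); truth_subj <- list()
  for (s in ids) {
    train_ids <- setdiff(ids, s)
    if (nrow(grid) > 1) {
      obj <- vapply(seq_len(nrow(grid)), function(gi) {
        p <- as.list(grid[gi, ])
        inner <- vapply(train_ids, function(t) {
          fit_ids <- setdiff(train_ids, t)
          pooled <- pooled_training(preps, fit_ids, config$method, p,
                                    config$reject_fraction)
          model <- suppressMessages(train_classifier(pooled, config, p))
          slice_error_objective(model, preps, t)
        }, numeric(1))
        mean(inner)
      }, numeric(1))
      pars <- select_hyperparams(grid, obj)
    } else {
      pars <- grid[1, , drop = FALSE]
    }
    p <- as.list(pars)
    pooled <- pooled_training(preps, train_ids, config$method, p,
                              config$reject_fraction)
    model <- suppressMessages(train_classifier(pooled, config, p))
    pred <- predict_labels(model, preps[[s]]$test)
    vols <- volumes_from_predictions(preps[[s]]$test, pred, subject = s)
    chosen[[s]] <- pars
    pred_slice[[s]] <- vols$per_slice
    pred_subj[[s]] <- vols$per_subject
    truth_slice[[s]] <- preps[[s]]$truth$per_slice
    truth_subj[[s]] <- preps[[s]]$truth$per_subject
  }
  pred_slice <- do.call(rbind, pred_slice)
  pred_subj <- do.call(rbind, pred_subj)
  truth_slice <- do.call(rbind, truth_slice)
  truth_subj <- do.call(rbind, truth_subj)
  rownames(pred_slice) <- rownames(pred_subj) <- NULL
  rownames(truth_slice) <- rownames(truth_subj) <- NULL
  merge_keys <- function(p, t, keys)
    merge(p, t, by = keys, suffixes = c("_pred", "_truth"))
  list(
    per_subject = merge_keys(pred_subj, truth_subj, c("subject", "component")),
    per_slice = merge_keys(pred_slice, truth_slice,
                           c("subject", "slice", "component")),
    metrics = list(
      per_subject = volume_metrics(pred_subj, truth_subj),
      per_slice = volume_metrics(pred_slice, truth_slice)),
    chosen = do.call(rbind, chosen),
    config = config)
}
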