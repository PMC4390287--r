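#' Cross-validation configuration
#'
#' @param n_folds number of outer folds (default 10)
#' @param stratified stratify folds by class label (default TRUE)
#' @param seed RNG seed for the fold assignment
#' @param C_grid,gamma_grid hyperparameter grids searched on an inner
#'   5-fold cross-validation within each training set
#' @param scaling z-score the features, with the scaler fitted on the
#'   training folds only
#' @param inner_folds folds of the inner grid-search CV
#' @return an object of class `cv_config`
#' @export
cv_config <- function(n_folds = 10L, stratified = TRUE, seed = 1L,
                      C_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(0.01, 0.1, 1, 10),
                      scaling = TRUE, inner_folds = 5L) {
  stopifnot(n_folds >= 2, length(C_grid) >= 1, length(gamma_grid) >= 1,
            inner_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed), C_grid = C_grid,
                 gamma_grid = gamma_grid, scaling = scaling,
                 inner_folds = as.integer(inner_folds)),
            class = "cv_config")
}

POSITIVE_CLASS <- "malignant"
NEGATIVE_CLASS <- "benign"

as_label_factor <- function(labels) {
  factor(as.character(labels), levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

feature_matrix <- function(features) {
  cols <- c("contrast", "correlation", "energy", "homogeneity", "entropy",
            "suvmax")
  if (is.matrix(features)) return(features)
  cols <- intersect(cols, names(features))
  if (length(cols) == 0) stop("no feature columns found")
  as.matrix(features[, cols, drop = FALSE])
}

#' Train an RBF-kernel SVM on candidate features
#'
#' Maximum-margin classification with a radial-basis-function kernel
#' ([e1071::svm()]); the z-score scaler is fitted here and bundled with
#' the model so that test data are scaled with training statistics.
#'
#' @param features data.frame with the feature columns (`contrast`,
#'   `correlation`, `energy`, `homogeneity`, `entropy`, `suvmax`) or a
#'   numeric matrix
#' @param labels class labels (`"malignant"` / `"benign"`); both classes
#'   must be present
#' @param C soft-margin cost
#' @param gamma RBF kernel width
#' @param scaling fit and apply a z-score scaler
#' @return an object of class `svm_model`; predict with
#'   [predict.svm_model()]
#' @export
train_svm <- function(features, labels, C = 1, gamma = 0.1, scaling = TRUE) {
  x <- feature_matrix(features)
  y <- as_label_factor(labels)
  stopifnot(!anyNA(x), !anyNA(y))
  if (nlevels(droplevels(y)) < 2)
    stop("training labels contain a single class")
  center <- scale_sd <- NULL
  if (scaling) {
    center <- colMeans(x)
    scale_sd <- apply(x, 2, stats::sd)
    scale_sd[scale_sd < 1e-12] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
  }
  fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale_sd = scale_sd,
                 C = C, gamma = gamma), class = "svm_model")
}

#' @rdname train_svm
#' @param object an `svm_model`
#' @param newdata features of the observations to classify
#' @param ... unused
#' @export
predict.svm_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2, object$center), 2, object$scale_sd, "/")
  stats::predict(object$fit, x)
}

# Deterministic stratified group folds: scans (groups) are shuffled within
# each class stratum and dealt round-robin, so every scan lands in exactly
# one fold and fold sizes differ by at most 1 per stratum.
make_group_folds <- function(scan_ids, scan_labels, n_folds, stratified, seed) {
  scans <- unique(scan_ids)
  if (length(scans) < n_folds)
    stop("fewer scans (", length(scans), ") than folds (", n_folds, ")")
  lab_of <- vapply(scans, function(s) {
    as.character(scan_labels[match(s, scan_ids)])
  }, character(1))
  fold_of <- integer(length(scans))
  names(fold_of) <- scans
  with_seed(seed, {
    strata <- if (stratified) split(scans, lab_of) else list(all = scans)
    offset <- 0L
    for (st in strata) {
      st <- sample(st)
      fold_of[st] <- ((seq_along(st) - 1L + offset) %% n_folds) + 1L
      offset <- offset + length(st)
    }
  })
  fold_of[as.character(scan_ids)]
}

#' Cross-validated SVM evaluation of candidate features
#'
#' Stratified k-fold cross-validation grouped by scan (no scan appears in
#' both a training and its test fold). Within each training set an inner
#' grid search over `(C, gamma)` picks the hyperparameters by inner-CV
#' accuracy; the tuned model predicts the held-out fold, and the pooled
#' test predictions over all folds form the report.
#'
#' @param features feature data.frame or matrix (see [train_svm()])
#' @param labels class labels per candidate
#' @param scan_ids grouping identifiers (default: one scan per candidate)
#' @param cv a [cv_config()]
#' @return an object of class `evaluation_report`: `sensitivity`,
#'   `specificity`, `accuracy`, `false_positives_per_scan`, confusion
#'   counts, `per_fold` (fold sizes, accuracy, selected C and gamma), and
#'   `predictions` (pooled out-of-fold labels in input order)
#' @export
cross_validate <- function(features, labels, scan_ids = NULL,
                           cv = cv_config()) {
  x <- feature_matrix(features)
  y <- as_label_factor(labels)
  n <- nrow(x)
  stopifnot(n >= cv$n_folds, length(y) == n)
  scan_ids <- scan_ids %||% paste0("scan_", seq_len(n))
  folds <- make_group_folds(scan_ids, y, cv$n_folds, cv$stratified, cv$seed)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  per_fold <- vector("list", cv$n_folds)
  for (k in seq_len(cv$n_folds)) {
    test <- folds == k
    x_tr <- x[!test, , drop = FALSE]; y_tr <- droplevels(y[!test])
    if (nlevels(y_tr) < 2)
      stop("training folds contain a single class; cannot fit the SVM")
    best <- tune_rbf(x_tr, y[!test], scan_ids[!test], cv)
    model <- train_svm(x_tr, y[!test], C = best$C, gamma = best$gamma,
                       scaling = cv$scaling)
    pred[test] <- predict(model, x[test, , drop = FALSE])
    per_fold[[k]] <- data.frame(
      fold = k, n_train = sum(!test), n_test = sum(test),
      C = best$C, gamma = best$gamma,
      accuracy = mean(pred[test] == y[test]))
  }
  rep <- confusion_report(pred, y, n_scans = length(unique(scan_ids)))
  rep$per_fold <- do.call(rbind, per_fold)
  rep$predictions <- pred
  rep
}

# Inner grid search: stratified group CV accuracy per (C, gamma).
tune_rbf <- function(x, y, scan_ids, cv) {
  y <- as_label_factor(y)
  n_inner <- min(cv$inner_folds, length(unique(scan_ids)))
  folds <- make_group_folds(scan_ids, y, n_inner, cv$stratified,
                            cv$seed + 1L)
  grid <- expand.grid(C = cv$C_grid, gamma = cv$gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (k in seq_len(n_inner)) {
      test <- folds == k
      if (!any(test) || nlevels(droplevels(y[!test])) < 2) next
      m <- train_svm(x[!test, , drop = FALSE], y[!test],
                     C = grid$C[i], gamma = grid$gamma[i],
                     scaling = cv$scaling)
      correct <- correct + sum(predict(m, x[test, , drop = FALSE]) == y[test])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best])
}

confusion_report <- function(pred, truth, n_scans) {
  tp <- sum(pred == POSITIVE_CLASS & truth == POSITIVE_CLASS)
  fp <- sum(pred == POSITIVE_CLASS & truth == NEGATIVE_CLASS)
  fn <- sum(pred == NEGATIVE_CLASS & truth == POSITIVE_CLASS)
  tn <- sum(pred == NEGATIVE_CLASS & truth == NEGATIVE_CLASS)
  structure(list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    accuracy = (tp + tn) / max(length(pred), 1L),
    false_positives_per_scan = if (n_scans > 0) fp / n_scans else 0,
    tp = tp, fp = fp, fn = fn, tn = tn, n_scans = n_scans),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report: sensitivity %.3f, specificity %.3f, ",
                     "accuracy %.3f, %.2f false positives/scan ",
                     "(TP %d FP %d FN %d TN %d over %d scans)\n"),
              x$sensitivity, x$specificity, x$accuracy,
              x$false_positives_per_scan, x$tp, x$fp, x$fn, x$tn, x$n_scans))
  invisible(x)
}

#' SUVmax threshold baseline classifier
#'
#' The clinical rule of thumb: a candidate is called malignant when its
#' SUVmax is at least 2.5 (the boundary value itself is positive).
#'
#' @param features data.frame with a `suvmax` column
#' @param threshold SUV cutoff (default 2.5)
#' @return factor of predicted labels
#' @export
suv_rule_baseline <- function(features, threshold = 2.5) {
  stopifnot("suvmax" %in% names(features))
  as_label_factor(ifelse(features$suvmax >= threshold,
                         POSITIVE_CLASS, NEGATIVE_CLASS))
}

#' Detection-level evaluation: sensitivity and false positives per scan
#'
#' A candidate predicted malignant counts as a true positive when its mask
#' centroid lies inside a true nodule of the malignant class on the same
#' scan (centroid-in-truth matching); each true malignant nodule can be
#' credited at most once. Positive predictions matching no malignant truth
#' nodule are false positives.
#'
#' @param predictions data.frame: `scan_id`, `centroid_row`,
#'   `centroid_col`, `predicted` (label)
#' @param truth data.frame of true nodules: `scan_id`, `row`, `col`,
#'   `radius`, `label`
#' @param n_scans total number of scans evaluated (>= 1)
#' @return an `evaluation_report` (its `tn` counts candidates predicted
#'   benign that match no malignant truth nodule)
#' @export
evaluate_detection <- function(predictions, truth, n_scans) {
  stopifnot(n_scans >= 1)
  truth_pos <- truth[truth$label == POSITIVE_CLASS, , drop = FALSE]
  matched <- rep(FALSE, nrow(truth_pos))
  fp <- 0L; tn <- 0L; fn_cand <- 0L
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    hit <- which(!matched &
                   truth_pos$scan_id == p$scan_id &
                   (truth_pos$row - p$centroid_row)^2 +
                   (truth_pos$col - p$centroid_col)^2 <= truth_pos$radius^2)
    any_hit <- length(which(
      truth_pos$scan_id == p$scan_id &
        (truth_pos$row - p$centroid_row)^2 +
        (truth_pos$col - p$centroid_col)^2 <= truth_pos$radius^2)) > 0
    if (p$predicted == POSITIVE_CLASS) {
      if (length(hit) > 0) matched[hit[1]] <- TRUE
      else if (!any_hit) fp <- fp + 1L
    } else {
      if (any_hit) fn_cand <- fn_cand + 1L else tn <- tn + 1L
    }
  }
  tp <- sum(matched)
  fn <- nrow(truth_pos) - tp
  structure(list(
    sensitivity = if (nrow(truth_pos) > 0) tp / nrow(truth_pos) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    accuracy = NA_real_,
    false_positives_per_scan = fp / n_scans,
    tp = tp, fp = fp, fn = fn, tn = tn, n_scans = n_scans),
    class = "evaluation_report")
}

#' Segmentation accuracy ratio (SAR)
#'
#' Percentage of manually segmented lesion pixels recovered by an
#' automatic segmentation: `100 * overlap_px / manual_px`.
#'
#' @param overlap_px pixels common to the automatic and manual masks
#' @param manual_px pixels of the manual (reference) mask
#' @return percentage in \[0, 100\]
#' @export
segmentation_accuracy <- function(overlap_px, manual_px) {
  stopifnot(manual_px > 0, overlap_px >= 0, overlap_px <= manual_px)
  100 * overlap_px / manual_px
}
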