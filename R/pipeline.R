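#' Default pipeline configuration
#'
#' Nested per-stage configuration with every default documented in the
#' stage functions: [segment_lung()], [register_rigid()],
#' [detect_pet_candidates()], [segment_nodule()], [extract_features()],
#' [cross_validate()].
#'
#' @param seed master seed for every stochastic stage (fold shuffling)
#' @return an object of class `pipeline_config`
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    lungseg = list(sigma = 0.5, max_iter = 100L, keep_components = 2L,
                   hole_area_max = 500),
    register = list(bins = 64L, interpolation = "bilinear", tol = 1e-3,
                    max_cycles = 50L, line_range = 15, line_tol = 0.05),
    watershed = list(suv_threshold = 2.5, k_seeds = 3L, connectivity = 8L,
                     margin_factor = 1.5, min_window = 16L, smooth_sigma = 1),
    features = list(levels = 16L, distance = 1L,
                    angles = c(0, 45, 90, 135), symmetric = TRUE),
    classify = list(n_folds = 10L, stratified = TRUE,
                    C_grid = c(0.1, 1, 10, 100),
                    gamma_grid = c(0.01, 0.1, 1, 10),
                    scaling = TRUE, inner_folds = 5L,
                    baseline_threshold = 2.5)
  ), class = "pipeline_config")
}

config_schema <- function() {
  list(
    seed = function(v) is.numeric(v) && v == round(v),
    lungseg = list(
      p0 = function(v) is.numeric(v),
      sigma = function(v) is.numeric(v) && v > 0,
      max_iter = function(v) is.numeric(v) && v >= 1,
      keep_components = function(v) is.numeric(v) && v >= 1,
      hole_area_max = function(v) is.numeric(v) && v >= 0,
      min_area = function(v) is.numeric(v) && v >= 0,
      min_solidity = function(v) is.numeric(v) && v >= 0 && v <= 1),
    register = list(
      bins = function(v) is.numeric(v) && v >= 2,
      interpolation = function(v) v %in% c("bilinear", "nearest"),
      tol = function(v) is.numeric(v) && v > 0,
      max_cycles = function(v) is.numeric(v) && v >= 1,
      line_range = function(v) is.numeric(v) && v > 0,
      line_tol = function(v) is.numeric(v) && v > 0),
    watershed = list(
      suv_threshold = function(v) is.numeric(v) && v > 0,
      k_seeds = function(v) is.numeric(v) && v >= 0,
      connectivity = function(v) v %in% c(4, 8),
      margin_factor = function(v) is.numeric(v) && v >= 1,
      min_window = function(v) is.numeric(v) && v >= 3,
      smooth_sigma = function(v) is.numeric(v) && v >= 0),
    features = list(
      levels = function(v) is.numeric(v) && v >= 2,
      distance = function(v) is.numeric(v) && v >= 1,
      angles = function(v) all(v %in% c(0, 45, 90, 135)),
      symmetric = function(v) is.logical(v)),
    classify = list(
      n_folds = function(v) is.numeric(v) && v >= 2,
      stratified = function(v) is.logical(v),
      C_grid = function(v) is.numeric(v) && length(v) >= 1 && all(v > 0),
      gamma_grid = function(v) is.numeric(v) && length(v) >= 1 && all(v > 0),
      scaling = function(v) is.logical(v),
      inner_folds = function(v) is.numeric(v) && v >= 2,
      baseline_threshold = function(v) is.numeric(v) && v > 0)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a (possibly nested, possibly partial) list or a path to a JSON
#' file; unknown keys are rejected and all type/range violations are
#' collected into a single error message. Missing keys take the
#' [default_config()] values, so `validate_config(list())` is the full
#' default configuration. Serialising the result to JSON and re-parsing
#' it validates back to the same configuration.
#'
#' @param raw list or JSON file path
#' @return a `pipeline_config`
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1)
    raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  if (inherits(raw, "pipeline_config")) raw <- unclass(raw)
  stopifnot(is.list(raw))
  schema <- config_schema()
  cfg <- unclass(default_config())
  errors <- character()
  for (key in names(raw)) {
    if (!key %in% names(schema)) {
      errors <- c(errors, paste0("unknown key: ", key))
      next
    }
    if (key == "seed") {
      if (!schema$seed(raw$seed)) errors <- c(errors, "seed: must be an integer")
      else cfg$seed <- as.integer(raw$seed)
      next
    }
    sub <- raw[[key]]
    if (!is.list(sub)) {
      errors <- c(errors, paste0(key, ": must be a list"))
      next
    }
    for (k2 in names(sub)) {
      check <- schema[[key]][[k2]]
      if (is.null(check)) {
        errors <- c(errors, paste0("unknown key: ", key, ".", k2))
      } else if (!isTRUE(check(sub[[k2]]))) {
        errors <- c(errors, paste0(key, ".", k2, ": invalid value (",
                                   paste(format(sub[[k2]]), collapse = ", "),
                                   ")"))
      } else {
        cfg[[key]][[k2]] <- sub[[k2]]
      }
    }
  }
  if (length(errors) > 0)
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

process_scan <- function(scan, config) {
  lung <- segment_lung(scan$ct, config$lungseg)
  reg <- register_rigid(scan$ct, scan$pet, config$register)
  det <- detect_pet_candidates(scan$pet, lung, reg$transform,
                               config$watershed$suv_threshold)
  rois <- list()
  feats <- list()
  for (cand in det$candidates) {
    roi <- segment_nodule(scan$ct, cand, det$markers, config$watershed)
    if (is.null(roi)) next
    fv <- extract_features(scan$ct, scan$pet, reg$transform, roi,
                           config$features)
    rois[[length(rois) + 1L]] <- roi
    feats[[length(feats) + 1L]] <- fv
  }
  list(lung = lung, transform = reg$transform, mi = reg$mi,
       rois = rois,
       features = if (length(feats)) do.call(rbind, feats) else NULL)
}

# Match a candidate centroid to a truth nodule (any class); returns the
# row index in the truth table or NA.
match_candidate <- function(centroid, truth_nodules) {
  if (nrow(truth_nodules) == 0) return(NA_integer_)
  d2 <- (truth_nodules$row - centroid[1])^2 +
    (truth_nodules$col - centroid[2])^2
  hit <- which(d2 <= truth_nodules$radius^2)
  if (length(hit) == 0) NA_integer_ else hit[which.min(d2[hit])]
}

#' Run the full CAD pipeline on a phantom cohort
#'
#' Executes the five stages consecutively on every scan of a cohort
#' written by [generate_cohort()]: lung segmentation, PET-CT registration,
#' watershed candidate segmentation, feature extraction, and
#' classification with evaluation. Per-scan failures are isolated (the
#' scan is skipped with a logged reason). Candidates are labelled by
#' centroid-in-truth matching; when both classes occur among the
#' candidates the RBF-SVM is evaluated by scan-grouped cross-validation,
#' otherwise the SUVmax-rule baseline classifies them. Detection
#' performance (sensitivity over true malignant nodules and false
#' positives per scan) is evaluated from the final positive calls.
#'
#' @param input_dir cohort directory containing `manifest.json`
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts)
#' @param out_dir optional output directory for `report.json`,
#'   `features.csv` and `run_manifest.json`
#' @return list with `report` (an `evaluation_report`), `features`
#'   (candidate table with truth labels, predictions and per-candidate
#'   segmentation accuracy), `classifier` (`"rbf-svm-cv"` or
#'   `"suv-rule"`), `cv_report` (when the SVM ran), `transforms`, and
#'   `manifest` (per-scan stage status log)
#' @export
run_pipeline <- function(input_dir, config = default_config(),
                         out_dir = NULL) {
  config <- validate_config(config)
  manifest <- read_manifest(input_dir)
  if (length(manifest$scans) == 0) stop("no scans found in ", input_dir)

  run_log <- list()
  cand_rows <- list()
  truth_rows <- list()
  transforms <- list()
  for (entry in manifest$scans) {
    t0 <- Sys.time()
    res <- tryCatch({
      scan <- read_scan(input_dir, entry)
      out <- process_scan(scan, config)
      truth <- scan$truth$nodules
      if (nrow(truth) > 0) {
        truth$scan_id <- entry$scan_id
        truth_rows[[length(truth_rows) + 1L]] <- truth
      }
      if (!is.null(out$features)) {
        fx <- out$features
        for (j in seq_len(nrow(fx))) {
          roi <- out$rois[[j]]
          cen <- mask_centroid(roi$mask)
          m <- match_candidate(cen, truth)
          fx$label[j] <- if (is.na(m)) "benign" else truth$label[m]
          fx$matched_nodule[j] <- if (is.na(m)) NA_integer_ else
            truth$nodule_id[m]
          fx$centroid_row[j] <- cen[1]
          fx$centroid_col[j] <- cen[2]
          fx$sar[j] <- if (is.na(m)) NA_real_ else {
            tmask <- scan$truth$nodule_label_mask == truth$nodule_id[m]
            segmentation_accuracy(sum(roi$mask & tmask), sum(tmask))
          }
        }
        cand_rows[[length(cand_rows) + 1L]] <- fx
      }
      transforms[[entry$scan_id]] <- out$transform
      list(status = "ok", n_candidates = length(out$rois))
    }, error = function(e) list(status = "failed",
                                reason = conditionMessage(e)))
    run_log[[entry$scan_id]] <- c(list(scan_id = entry$scan_id),
                                  res,
                                  list(seconds = round(as.numeric(
                                    Sys.time() - t0, units = "secs"), 2)))
  }
  n_scans <- length(manifest$scans)
  features <- if (length(cand_rows)) do.call(rbind, cand_rows) else NULL
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(scan_id = character(), row = numeric(), col = numeric(),
               radius = numeric(), label = character())

  cv_report <- NULL
  if (is.null(features) || nrow(features) == 0) {
    classifier <- "none"
    predictions <- data.frame(scan_id = character(), centroid_row = numeric(),
                              centroid_col = numeric(), predicted = character())
  } else {
    labels <- as_label_factor(features$label)
    if (nlevels(droplevels(labels)) == 2 &&
        length(unique(features$scan_id)) >= config$classify$n_folds &&
        min(table(droplevels(labels))) >= 2) {
      classifier <- "rbf-svm-cv"
      cvc <- cv_config(n_folds = config$classify$n_folds,
                       stratified = config$classify$stratified,
                       seed = config$seed,
                       C_grid = config$classify$C_grid,
                       gamma_grid = config$classify$gamma_grid,
                       scaling = config$classify$scaling,
                       inner_folds = config$classify$inner_folds)
      cv_report <- cross_validate(features, labels, features$scan_id, cvc)
      pred <- cv_report$predictions
    } else {
      classifier <- "suv-rule"
      pred <- suv_rule_baseline(features, config$classify$baseline_threshold)
    }
    features$predicted <- as.character(pred)
    predictions <- data.frame(scan_id = features$scan_id,
                              centroid_row = features$centroid_row,
                              centroid_col = features$centroid_col,
                              predicted = as.character(pred))
  }
  report <- evaluate_detection(predictions, truth, n_scans)
  mean_sar <- if (!is.null(features) && any(!is.na(features$sar)))
    mean(features$sar, na.rm = TRUE) else NA_real_

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(features))
      utils::write.csv(features, file.path(out_dir, "features.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(
      sensitivity = report$sensitivity,
      false_positives_per_scan = report$false_positives_per_scan,
      tp = report$tp, fp = report$fp, fn = report$fn, tn = report$tn,
      n_scans = n_scans, classifier = classifier,
      mean_segmentation_accuracy_pct = mean_sar,
      transforms = lapply(transforms, function(t)
        list(tx = t$tx, ty = t$ty, theta = t$theta))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unname(run_log),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, features = features, classifier = classifier,
       cv_report = cv_report, transforms = transforms,
       mean_segmentation_accuracy_pct = mean_sar, manifest = run_log)
}
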