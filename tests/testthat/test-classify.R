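test_that("the RBF SVM separates well-separated clusters", {
  tab <- synthetic_feature_table(n = 200, n_malignant = 100, seed = 3)
  m <- train_svm(tab, tab$label, C = 10, gamma = 0.1)
  pred <- predict(m, tab)
  expect_gte(mean(pred == tab$label), 0.99)
  # a duplicated training point keeps its own label
  expect_equal(as.character(predict(m, tab[1, , drop = FALSE])),
               tab$label[1])
  expect_error(train_svm(tab, rep("malignant", nrow(tab))), "single class")
})

test_that("ten-fold partitions of 219 candidates give 197/22 splits", {
  tab <- synthetic_feature_table()          # 219 = 120 + 99
  cv <- cross_validate(tab, tab$label, cv = cv_config(seed = 7))
  expect_true(all(cv$per_fold$n_test %in% 21:23))
  expect_true(all(cv$per_fold$n_train %in% 196:198))
  expect_equal(cv$per_fold$n_train + cv$per_fold$n_test, rep(219, 10))
  expect_equal(sum(cv$per_fold$n_test), 219)   # every candidate held out once
  expect_gte(cv$sensitivity, 0.95)             # separable features
})

test_that("scan grouping keeps candidates of one scan in one fold", {
  tab <- synthetic_feature_table(n = 60, n_malignant = 30, seed = 9)
  scan_ids <- rep(sprintf("s%02d", 1:30), each = 2)   # 2 candidates/scan
  # grouped labels must agree within a scan for stratification to be exact
  tab$label <- rep(tab$label[seq(1, 60, by = 2)], each = 2)
  cv <- cross_validate(tab, tab$label, scan_ids,
                       cv = cv_config(n_folds = 5, seed = 1))
  expect_gte(cv$sensitivity, 0.9)
  fold_assign <- spncad:::make_group_folds(scan_ids, tab$label, 5, TRUE, 1L)
  expect_true(all(tapply(fold_assign, scan_ids,
                         function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(fold_assign)), 1:5)
})

test_that("cross-validation is seeded and collapses under label permutation", {
  tab <- synthetic_feature_table(n = 120, n_malignant = 60, seed = 5)
  cv1 <- cross_validate(tab, tab$label, cv = cv_config(seed = 11))
  cv2 <- cross_validate(tab, tab$label, cv = cv_config(seed = 11))
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$sensitivity, cv2$sensitivity)

  set.seed(13)
  shuffled <- sample(tab$label)
  cvp <- cross_validate(tab, shuffled, cv = cv_config(seed = 11))
  balanced <- (cvp$sensitivity + cvp$specificity) / 2
  expect_lt(balanced, 0.65)                  # no signal left to learn
  expect_gt(cv1$accuracy, cvp$accuracy + 0.2)
})

test_that("the SUVmax rule applies the 2.5 cutoff inclusively", {
  tab <- data.frame(suvmax = c(7.1563, 3.2326, 2.7012, 2.4304, 2.3694, 2.5))
  pred <- suv_rule_baseline(tab)
  expect_equal(as.character(pred),
               c("malignant", "malignant", "malignant", "benign", "benign",
                 "malignant"))
})

test_that("the SVM does not fall below the SUV-rule baseline on clean classes", {
  tab <- synthetic_feature_table(seed = 17)
  base <- suv_rule_baseline(tab)
  base_sens <- mean(base[tab$label == "malignant"] == "malignant")
  cv <- cross_validate(tab, tab$label, cv = cv_config(seed = 17))
  expect_gte(cv$sensitivity, base_sens)
})

test_that("detection evaluation counts centroid-matched positives", {
  truth <- data.frame(scan_id = rep(c("a", "b"), each = 5),
                      row = rep(seq(20, 100, by = 20), 2),
                      col = rep(50, 10), radius = 5,
                      label = "malignant")
  # 9 of 10 nodules hit, plus 3 positives matching nothing
  hits <- truth[-10, ]
  preds <- data.frame(
    scan_id = c(hits$scan_id, "a", "b", "b"),
    centroid_row = c(hits$row + 1, 150, 160, 170),
    centroid_col = c(hits$col - 1, 50, 50, 50),
    predicted = "malignant")
  rep1 <- evaluate_detection(preds, truth, n_scans = 2)
  expect_equal(rep1$sensitivity, 0.9)
  expect_equal(rep1$false_positives_per_scan, 1.5)

  none <- preds[0, ]
  rep0 <- evaluate_detection(none, truth, n_scans = 2)
  expect_equal(rep0$sensitivity, 0)
  expect_equal(rep0$false_positives_per_scan, 0)

  all_hit <- data.frame(scan_id = truth$scan_id, centroid_row = truth$row,
                        centroid_col = truth$col, predicted = "malignant")
  rep2 <- evaluate_detection(all_hit, truth, n_scans = 2)
  expect_equal(rep2$sensitivity, 1)
  expect_equal(rep2$false_positives_per_scan, 0)
})

test_that("segmentation accuracy is the overlap-to-manual percentage", {
  expect_equal(segmentation_accuracy(50, 100), 50)
  expect_equal(segmentation_accuracy(984, 984), 100)
  expect_error(segmentation_accuracy(10, 0))
  expect_error(segmentation_accuracy(20, 10))
})
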