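separable_features <- function(n_per_group = 10, nv = 12, gap = 8,
                               seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_group * nv, mean = gap / 2), n_per_group, nv),
             matrix(rnorm(n_per_group * nv, mean = -gap / 2), n_per_group, nv))
  labels <- rep(c("patient", "control"), each = n_per_group)
  list(X = X, labels = labels)
}

test_that("feature matrix building is deterministic and strict about NAs", {
  mask <- mask_first_n(c(3, 1, 1), 3)
  maps <- list(map_from_values(c(1, 2, 3), mask),
               map_from_values(c(4, 5, 6), mask))
  fm <- build_feature_matrix(maps, mask, c("patient", "control"))
  expect_equal(unclass(fm)[, ], rbind(c(1, 2, 3), c(4, 5, 6)),
               ignore_attr = TRUE)
  fm2 <- build_feature_matrix(maps, mask, c("patient", "control"))
  expect_identical(fm, fm2)
  bad <- map_from_values(c(1, NA, 3), mask)
  expect_error(build_feature_matrix(list(maps[[1]], bad), mask,
                                    c("patient", "control")), "missing")
  expect_error(build_feature_matrix(maps, mask, c("patient", "patient")),
               "both classes")
})

test_that("confusion metrics satisfy their defining identities", {
  cm <- confusion_metrics(30, 17, 38, 9)
  expect_equal(round(cm$accuracy, 2), 72.34)
  expect_equal(round(cm$sensitivity, 2), 63.83)
  expect_equal(round(cm$specificity, 2), 80.85)
  set.seed(3)
  for (i in 1:10) {
    k <- sample(1:30, 4, replace = TRUE)
    cm <- confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(cm$accuracy, 100 * (k[1] + k[3]) / sum(k))
    expect_equal(cm$tp + cm$fn, k[1] + k[2])
  }
})

test_that("LOOCV separates two distant clouds perfectly and is deterministic", {
  fx <- separable_features()
  res <- loocv_classify(fx$X, fx$labels)
  expect_equal(res$metrics$accuracy, 100)
  expect_equal(res$auc, 1)
  expect_equal(res$n_folds, 10)
  expect_equal(unname(res$confusion), c(10, 0, 10, 0))
  res2 <- loocv_classify(fx$X, fx$labels)
  expect_identical(res, res2)
  # the gram-factor fit path gives the same answer as e1071 on raw features
  m <- e1071::svm(fx$X[-c(1, 11), ], factor(fx$labels[-c(1, 11)],
                                            c("control", "patient")),
                  kernel = "linear", cost = 1, scale = FALSE)
  pr <- attr(predict(m, fx$X[c(1, 11), ], decision.values = TRUE),
             "decision.values")
  dv_pkg <- res$folds$decision_value[res$folds$fold == 1]
  expect_equal(sort(abs(as.numeric(pr))), sort(abs(dv_pkg)),
               tolerance = 1e-3)   # libsvm stops at its working tolerance
})

test_that("label flips swap sensitivity/specificity and mirror the AUC", {
  # for fixed scores, relabeling mirrors the AUC exactly
  set.seed(7)
  sc <- rnorm(14)
  lb <- rep(c("patient", "control"), 7)
  lbf <- ifelse(lb == "patient", "control", "patient")
  expect_equal(roc_auc(sc, lbf), 1 - roc_auc(sc, lb), tolerance = 1e-12)
  # for a retrained classifier, each subject's decision value negates and
  # sensitivity/specificity swap (the AUC of the retrained model is then
  # unchanged, since scores and labels flip together)
  fx <- separable_features(gap = 1.5, seed = 7)
  res <- loocv_classify(fx$X, fx$labels)
  resf <- loocv_classify(fx$X, lbf <- ifelse(fx$labels == "patient",
                                             "control", "patient"))
  expect_equal(resf$metrics$sensitivity, res$metrics$specificity)
  expect_equal(resf$metrics$specificity, res$metrics$sensitivity)
  dv <- res$folds$decision_value[order(res$folds$subject)]
  dvf <- resf$folds$decision_value[order(resf$folds$subject)]
  expect_equal(dvf, -dv, tolerance = 1e-6)
  expect_equal(resf$auc, res$auc, tolerance = 1e-6)
})

test_that("shuffled labels on a separable fixture stay near chance", {
  fx <- separable_features()
  set.seed(41)
  yb <- sample(fx$labels)
  res <- loocv_classify(fx$X, yb)
  # central 95% binomial band around 50% for 20 held-out predictions
  expect_gte(res$metrics$accuracy, 100 * qbinom(0.025, 20, 0.5) / 20)
  expect_lte(res$metrics$accuracy, 100 * qbinom(0.975, 20, 0.5) / 20)
})

test_that("permutation p-values follow the add-one convention at both extremes", {
  fx <- separable_features(n_per_group = 6, nv = 6, gap = 10, seed = 2)
  # worst case: with constant features every labeling scores identically,
  # so no null draw is below the observed metric and p = (B+1)/(B+1) = 1
  Xc <- matrix(1, 12, 4)
  pt_worst <- permutation_test(Xc, fx$labels, n_permutations = 30,
                               rng_seed = 5, metrics = "accuracy")
  expect_equal(unname(pt_worst$p["accuracy"]), 1)
  # best case: perfectly separable observed; every null draw that is not a
  # relabeling of the true split scores below 100%
  pt_best <- permutation_test(fx$X, fx$labels, n_permutations = 99,
                              rng_seed = 5)
  n_hits <- sum(pt_best$null[, "accuracy"] >= 100)
  expect_equal(unname(pt_best$p["accuracy"]), (n_hits + 1) / 100)
  expect_lte(pt_best$p["accuracy"], 0.05)
  expect_error(permutation_test(fx$X, fx$labels, n_permutations = 0), ">= 1")
})

test_that("weight maps localize the discriminative voxel and obey the top rule", {
  mask <- mask_first_n(c(2, 1, 1), 2)
  # voxel 1 separates the classes, voxel 2 is pure noise
  set.seed(6)
  v1 <- c(rnorm(6, 3), rnorm(6, -3)); v2 <- rnorm(12, 0, 0.5)
  maps <- lapply(seq_len(12), function(i)
    map_from_values(c(v1[i], v2[i]), mask))
  labels <- rep(c("patient", "control"), each = 6)
  fm <- build_feature_matrix(maps, mask, labels)
  wm <- weight_map(fm, top_fraction = 1.0)
  expect_gt(abs(wm$weights[1]), abs(wm$weights[2]))
  expect_gt(wm$weights[1], 0)                         # patient-positive
  expect_equal(which(wm$top_mask), which(mask))       # top_fraction = 1

  # 20% of a 100-voxel mask is exactly 20 voxels
  mask100 <- mask_first_n(c(100, 1, 1), 100)
  maps100 <- lapply(seq_len(8), function(i)
    map_from_values(rnorm(100), mask100))
  fm100 <- build_feature_matrix(maps100, mask100,
                                rep(c("patient", "control"), 4))
  wm100 <- weight_map(fm100, top_fraction = 0.20)
  expect_equal(sum(wm100$top_mask), 20)

  # region summary needs a label image and sums to 100
  lab <- array(0L, c(100, 1, 1)); lab[1:50] <- 1L; lab[51:100] <- 2L
  wms <- weight_map(fm100, top_fraction = 0.20, label_img = lab,
                    label_names = data.frame(id = 1:2, name = c("A", "B")))
  expect_equal(sum(wms$region_summary$weight_percent), 100, tolerance = 1e-6)
  expect_error(weight_map(fm100, summarize_regions = TRUE), "label image")
})

test_that("rank-based AUC matches brute-force pair counting and pROC", {
  expect_equal(roc_auc(c(3, 2.5, 2, 1, 0.5, 0),
                       c("patient", "patient", "patient",
                         "control", "control", "control")), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("patient", "control"), 3)), 0.5)
  set.seed(14)
  scores <- round(rnorm(12), 1)                       # some ties likely
  labels <- rep(c("patient", "control"), each = 6)
  pos <- scores[labels == "patient"]; neg <- scores[labels == "control"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, labels), mean(pairs))
  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("control", "patient"),
    direction = "<")))
  expect_equal(roc_auc(scores, labels), as.numeric(pr))
  expect_error(roc_auc(1:3, rep("patient", 3)), "both classes")
})
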