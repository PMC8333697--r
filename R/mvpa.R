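#' Build the MVPA feature matrix
#'
#' Stacks per-subject maps (normally smoothed DC z-maps) into a
#' subjects-by-voxels matrix. Column order is the deterministic mask scan
#' order (column-major linear indices); the voxel lookup is attached so
#' classifier weights can be projected back into the volume.
#'
#' @param maps list of per-subject [volume_map]s.
#' @param mask logical 3D analysis mask.
#' @param labels character/factor vector of `"patient"` / `"control"`, one
#'   per map, in map order.
#' @return numeric matrix with attributes `voxel_idx` (linear indices),
#'   `grid_dim`, `affine`, and `labels` (factor).
#' @export
build_feature_matrix <- function(maps, mask, labels) {
  if (length(maps) != length(labels))
    stop("number of maps and labels differ", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(labels))
    stop("labels must be 'patient' or 'control'", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2)
    stop("labels must cover both classes", call. = FALSE)
  X <- maps_to_matrix(maps, mask)
  if (any(!is.finite(X)))
    stop("feature matrix has non-finite values inside the mask", call. = FALSE)
  attr(X, "voxel_idx") <- mask_indices(mask)
  attr(X, "grid_dim") <- dim(mask)
  attr(X, "affine") <- maps[[1]]$affine
  attr(X, "labels") <- labels
  X
}

# Fit a linear soft-margin SVM given the training Gram matrix. The dual
# problem depends on the data only through the Gram matrix, so fitting on
# its Cholesky factor reproduces the solution on the raw features exactly
# while keeping the problem size at n x n. Decision values for arbitrary
# rows follow from the dual coefficients:
#   f(x) = sum_i coef_i K(x, x_i) - rho,  positive => "patient".
fit_svm_gram <- function(K_tr, y_tr, C) {
  if (nlevels(droplevels(y_tr)) < 2)
    stop("a training fold has only one class present", call. = FALSE)
  R <- tryCatch(chol(K_tr),
                error = function(e)
                  chol(K_tr + diag(1e-8 * mean(diag(K_tr)), nrow(K_tr))))
  G <- t(R)
  m <- e1071::svm(G, y_tr, kernel = "linear", cost = C, scale = FALSE)
  # libsvm assigns the positive decision sign to the class of the first
  # training example
  flip <- if (as.character(y_tr[1]) == "patient") 1 else -1
  list(index = m$index, coefs = m$coefs * flip, rho = m$rho * flip)
}

svm_decision <- function(fit, K_te_tr) {
  as.numeric(K_te_tr[, fit$index, drop = FALSE] %*% fit$coefs - fit$rho)
}

#' Confusion-count classification metrics
#'
#' @param tp,fn,tn,fp confusion counts with patients as the positive class.
#' @return list with `accuracy`, `sensitivity`, `specificity` in percent,
#'   and the counts.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table", call. = FALSE)
  list(accuracy = 100 * (tp + tn) / total,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Leave-one-per-group-out SVM cross-validation
#'
#' Fold `k` holds out the k-th patient and the k-th control (by subject
#' order within each group; optionally seed-shuffled), trains a
#' linear-kernel soft-margin SVM on the remaining subjects, and records
#' the held-out predictions and signed decision values (positive =
#' patient). Metrics are computed from the pooled held-out predictions;
#' AUC from the pooled decision values. With `variant = "single"` each
#' fold instead holds out one subject.
#'
#' @param features matrix from [build_feature_matrix()] (or any numeric
#'   subjects-by-features matrix).
#' @param labels `"patient"`/`"control"` per row; taken from the feature
#'   matrix attribute when omitted.
#' @param svm_C soft-margin cost (default 1).
#' @param pairing `"ordered"` (deterministic, default) or `"shuffled"`
#'   (seeded permutation of each group's fold order).
#' @param variant `"pair"` (default, one subject from each group per fold)
#'   or `"single"` (one subject per fold).
#' @param rng_seed seed used only when `pairing = "shuffled"`.
#' @param gram optional precomputed Gram matrix `tcrossprod(features)`;
#'   supplying it avoids recomputation across repeated calls (permutation
#'   testing).
#' @return list of class `crossval_result`: `folds` (per-fold data.frame
#'   with subject, true and predicted label, decision value), `confusion`,
#'   `metrics` (percent), `auc`, `n_folds`, `svm_C`.
#' @export
loocv_classify <- function(features, labels = NULL, svm_C = 1,
                           pairing = c("ordered", "shuffled"),
                           variant = c("pair", "single"),
                           rng_seed = 1L, gram = NULL) {
  pairing <- match.arg(pairing)
  variant <- match.arg(variant)
  if (is.null(labels)) labels <- attr(features, "labels")
  y <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(y)) stop("labels must be 'patient' or 'control'", call. = FALSE)
  pat <- which(y == "patient"); con <- which(y == "control")
  if (length(pat) < 3 || length(con) < 3)
    stop("cross-validation needs at least 3 subjects per group", call. = FALSE)
  if (is.null(gram)) gram <- tcrossprod(features)
  if (pairing == "shuffled") {
    set.seed(rng_seed)
    pat <- pat[sample.int(length(pat))]
    con <- con[sample.int(length(con))]
  }
  fold_sets <- if (variant == "pair") {
    nf <- min(length(pat), length(con))
    lapply(seq_len(nf), function(k) c(pat[k], con[k]))
  } else {
    as.list(seq_along(y))
  }
  rows <- vector("list", length(fold_sets))
  for (k in seq_along(fold_sets)) {
    te <- fold_sets[[k]]
    tr <- setdiff(seq_along(y), te)
    fit <- fit_svm_gram(gram[tr, tr, drop = FALSE], droplevels(y[tr]), svm_C)
    dv <- svm_decision(fit, gram[te, tr, drop = FALSE])
    rows[[k]] <- data.frame(fold = k, subject = te,
                            true = as.character(y[te]),
                            predicted = ifelse(dv > 0, "patient", "control"),
                            decision_value = dv,
                            stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, rows)
  tp <- sum(folds$true == "patient" & folds$predicted == "patient")
  fn <- sum(folds$true == "patient" & folds$predicted == "control")
  tn <- sum(folds$true == "control" & folds$predicted == "control")
  fp <- sum(folds$true == "control" & folds$predicted == "patient")
  met <- confusion_metrics(tp, fn, tn, fp)
  auc <- roc_auc(folds$decision_value, folds$true)
  structure(list(folds = folds,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 metrics = met[c("accuracy", "sensitivity", "specificity")],
                 auc = auc, n_folds = length(fold_sets), svm_C = svm_C,
                 variant = variant),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds (%s variant), C = %g\n",
              x$n_folds, x$variant, x$svm_C))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.3f\n",
              x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity, x$auc))
  cat(sprintf("  confusion: TP %d FN %d TN %d FP %d\n",
              x$confusion["tp"], x$confusion["fn"],
              x$confusion["tn"], x$confusion["fp"]))
  invisible(x)
}

#' Permutation test of cross-validated classification metrics
#'
#' Repeats the full leave-one-per-group-out cross-validation under labels
#' permuted across the whole sample, and reports per-metric p-values with
#' the add-one Monte-Carlo convention `p = (#{null >= observed} + 1) /
#' (B + 1)`.
#'
#' @param features subjects-by-features matrix.
#' @param labels class labels (taken from the matrix attribute if omitted).
#' @param n_permutations number of label permutations (B).
#' @param svm_C soft-margin cost.
#' @param rng_seed seed for the permutation stream.
#' @param metrics which metrics to test.
#' @return list with `observed` (the unpermuted `crossval_result`), `p`
#'   (named per-metric p-values), and `null` (B x metrics matrix).
#' @export
permutation_test <- function(features, labels = NULL,
                             n_permutations = 1000L, svm_C = 1,
                             rng_seed = 1L,
                             metrics = c("accuracy", "sensitivity",
                                         "specificity", "auc")) {
  if (n_permutations < 1)
    stop("`n_permutations` must be >= 1", call. = FALSE)
  if (is.null(labels)) labels <- attr(features, "labels")
  y <- as.character(labels)
  gram <- tcrossprod(features)
  obs <- loocv_classify(features, y, svm_C = svm_C, gram = gram)
  getm <- function(res) {
    vapply(metrics, function(m) {
      if (m == "auc") res$auc else res$metrics[[m]]
    }, numeric(1))
  }
  obs_m <- getm(obs)
  B <- as.integer(n_permutations)
  null_m <- matrix(NA_real_, B, length(metrics),
                   dimnames = list(NULL, metrics))
  set.seed(rng_seed)
  for (b in seq_len(B)) {
    yb <- sample(y)
    null_m[b, ] <- getm(loocv_classify(features, yb, svm_C = svm_C,
                                       gram = gram))
  }
  p <- vapply(seq_along(metrics), function(j) {
    (sum(null_m[, j] >= obs_m[j]) + 1) / (B + 1)
  }, numeric(1))
  names(p) <- metrics
  list(observed = obs, p = p, null = null_m,
       n_permutations = B, rng_seed = as.integer(rng_seed))
}

#' SVM weight map and discriminative-pattern localization
#'
#' Trains the linear SVM on the full sample, projects the primal weight
#' vector back to voxel space (positive weights push toward the patient
#' class), and marks the voxels with the largest |weight| — by default the
#' top 20% of in-mask voxels, ties broken by the smaller linear voxel
#' index. With a user-supplied integer label image, the |weight| mass of
#' the top voxels is summarized per anatomical region as a percentage of
#' the total (summing to 100 over covered labels).
#'
#' @param features matrix from [build_feature_matrix()].
#' @param labels class labels (attribute default).
#' @param svm_C soft-margin cost.
#' @param top_fraction fraction of in-mask voxels retained (default 0.20).
#' @param label_img optional integer 3D array of anatomical labels on the
#'   same grid (0 = unlabeled).
#' @param label_names optional data.frame with columns `id`, `name`.
#' @param summarize_regions compute the per-region summary (requires
#'   `label_img`).
#' @return list of class `weight_map`: `weights` (per in-mask voxel),
#'   `map` (a [volume_map] of kind `"weight"`), `top_mask` (logical 3D
#'   array), `top_fraction`, `region_summary` (or `NULL`).
#' @export
weight_map <- function(features, labels = NULL, svm_C = 1,
                       top_fraction = 0.20, label_img = NULL,
                       label_names = NULL,
                       summarize_regions = !is.null(label_img)) {
  if (is.null(labels)) labels <- attr(features, "labels")
  y <- factor(as.character(labels), levels = c("control", "patient"))
  voxel_idx <- attr(features, "voxel_idx")
  grid_dim <- attr(features, "grid_dim")
  affine <- attr(features, "affine")
  if (is.null(voxel_idx))
    stop("`features` must come from build_feature_matrix()", call. = FALSE)
  if (summarize_regions && is.null(label_img))
    stop("a label image is required for the region summary", call. = FALSE)
  m <- e1071::svm(features, y, kernel = "linear", cost = svm_C,
                  scale = FALSE)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  if (as.character(y[1]) != "patient") w <- -w
  nv <- length(voxel_idx)
  ntop <- max(1L, round(top_fraction * nv))
  ord <- order(-abs(w), voxel_idx)
  top_lin <- voxel_idx[ord[seq_len(ntop)]]
  top_mask <- array(FALSE, grid_dim)
  top_mask[top_lin] <- TRUE
  arr <- array(NA_real_, grid_dim)
  arr[voxel_idx] <- w
  region_summary <- NULL
  if (summarize_regions) {
    if (!all(dim(label_img) == grid_dim))
      stop("label image does not share the feature grid", call. = FALSE)
    lab <- label_img[top_lin]
    aw <- abs(w[ord[seq_len(ntop)]])
    keep <- lab > 0
    if (any(keep)) {
      agg <- tapply(aw[keep], lab[keep], sum)
      pct <- 100 * agg / sum(agg)
      region_summary <- data.frame(label = as.integer(names(agg)),
                                   n_voxels = as.integer(table(lab[keep])),
                                   weight_percent = as.numeric(pct))
      if (!is.null(label_names)) {
        region_summary$name <-
          label_names$name[match(region_summary$label, label_names$id)]
      }
      region_summary <-
        region_summary[order(-region_summary$weight_percent), ]
      rownames(region_summary) <- NULL
    }
  }
  structure(list(weights = w, map = volume_map(arr, affine, "weight"),
                 top_mask = top_mask, top_fraction = top_fraction,
                 region_summary = region_summary),
            class = "weight_map")
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random patient
#' receives a higher score than a random control, ties counted 0.5.
#'
#' @param scores decision values (higher = more patient-like).
#' @param labels `"patient"`/`"control"` (or a logical vector marking
#'   positives).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) == "patient"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
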