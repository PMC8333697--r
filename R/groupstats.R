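#' Build a group-comparison design matrix
#'
#' Columns: intercept, group indicator (+1 patient / 0 control), then the
#' requested covariates. `sex` is converted to a 0/1 numeric covariate
#' (F = 0). Row order follows the phenotype table, which must match the
#' order of the subject maps.
#'
#' @param phenotype phenotype data.frame (see [read_phenotype()]).
#' @param covariates covariate column names (default age, sex, education).
#' @return Numeric matrix with attribute `"group_col"` marking the group
#'   indicator column.
#' @export
build_design <- function(phenotype, covariates = c("age", "sex", "education")) {
  validate_phenotype(phenotype)
  X <- cbind(intercept = 1,
             group = as.numeric(phenotype$group == "patient"))
  for (cv in covariates) {
    if (!cv %in% names(phenotype))
      stop(sprintf("covariate '%s' not found in phenotype table", cv),
           call. = FALSE)
    v <- phenotype[[cv]]
    if (cv == "sex") v <- sex_to_numeric(v)
    if (!is.numeric(v))
      stop(sprintf("covariate '%s' is not numeric", cv), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("covariate '%s' has missing values", cv), call. = FALSE)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  attr(X, "group_col") <- 2L
  X
}

# Stack per-subject maps into a subjects-by-voxels matrix.
maps_to_matrix <- function(maps, mask) {
  idx <- mask_indices(mask)
  aff <- maps[[1]]$affine
  Y <- matrix(NA_real_, length(maps), length(idx))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    stopifnot(inherits(m, "volume_map"))
    stop_unless_same_grid(dim(m$data), m$affine, dim(mask), aff,
                          sprintf("map %d and mask", i))
    Y[i, ] <- m$data[idx]
  }
  if (anyNA(Y))
    stop("subject maps contain missing values inside the mask", call. = FALSE)
  Y
}

# Per-voxel OLS t statistic for one design column. Y: subjects x voxels.
glm_tmap_matrix <- function(Y, X, gcol) {
  XtXi <- tryCatch(solve(crossprod(X)),
                   error = function(e)
                     stop("design matrix is rank deficient", call. = FALSE))
  B <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  coef <- B[gcol, ]
  tval <- coef / sqrt(pmax(sigma2, .Machine$double.xmin) * XtXi[gcol, gcol])
  # perfect-fit voxels: a zero residual with a zero effect is t = 0, with a
  # real effect it is unboundedly significant
  scale0 <- colMeans(Y^2) + 1
  degen <- sigma2 <= .Machine$double.eps^0.9 * scale0
  if (any(degen)) {
    tval[degen] <- ifelse(abs(coef[degen]) <=
                            sqrt(.Machine$double.eps) * sqrt(scale0[degen]),
                          0, sign(coef[degen]) * Inf)
  }
  list(t = tval, df = df)
}

#' Voxel-wise two-sample GLM t-test with covariates
#'
#' Fits, at every in-mask voxel, an ordinary least-squares model of the
#' subject map values on the design (intercept, group indicator,
#' covariates) and returns the t statistic of the group coefficient. This
#' is the covariate-adjusted two-sample t-test used to compare DC and FC
#' maps between groups.
#'
#' @param maps list of per-subject [volume_map]s sharing one grid.
#' @param design design matrix from [build_design()].
#' @param mask logical 3D analysis mask.
#' @return list with `t_map` (a [volume_map] of kind `"t_stat"`) and `df`
#'   (residual degrees of freedom, `n - rank(design)`).
#' @export
voxelwise_glm_ttest <- function(maps, design, mask) {
  gcol <- attr(design, "group_col") %||% 2L
  grp <- design[, gcol]
  if (sum(grp == 1) < 2 || sum(grp == 0) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient (a covariate is collinear with the group indicator or another covariate)",
         call. = FALSE)
  if (length(maps) != nrow(design))
    stop("number of maps and design rows differ", call. = FALSE)
  Y <- maps_to_matrix(maps, mask)
  fit <- glm_tmap_matrix(Y, design, gcol)
  out <- array(NA_real_, dim(mask))
  out[mask_indices(mask)] <- fit$t
  list(t_map = volume_map(out, maps[[1]]$affine, "t_stat"), df = fit$df)
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  as.matrix(g[keep, ])
}

# Connected components of the TRUE voxels of a logical 3D array.
# Returns an integer array (0 = background); label order is arbitrary.
label_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  labels <- array(0L, d)
  idx <- which(arr)
  if (!length(idx)) return(labels)
  offs <- neighbor_offsets(connectivity)
  coords <- arrayInd(idx, d)
  inset <- array(FALSE, d); inset[idx] <- TRUE
  nlab <- 0L
  stack <- integer(length(idx))
  for (s in idx) {
    if (labels[s] != 0L) next
    nlab <- nlab + 1L
    top <- 1L; stack[1L] <- s; labels[s] <- nlab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      ck <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      cj <- rem %/% d[1]; ci <- rem %% d[1]      # 0-based coords
      for (o in seq_len(nrow(offs))) {
        ni <- ci + offs[o, 1]; nj <- cj + offs[o, 2]; nk <- ck + offs[o, 3]
        if (ni < 0 || nj < 0 || nk < 0 ||
            ni >= d[1] || nj >= d[2] || nk >= d[3]) next
        nlin <- 1L + ni + d[1] * (nj + d[2] * nk)
        if (inset[nlin] && labels[nlin] == 0L) {
          labels[nlin] <- nlab
          top <- top + 1L; stack[top] <- nlin
        }
      }
    }
  }
  labels
}

#' Form supra-threshold clusters from a t-map
#'
#' Voxels with two-sided p below `voxel_p` are split by the sign of t and
#' grouped into connected components under the chosen neighborhood
#' (26 by default: faces, edges and corners). Cluster labels are
#' deterministic: sorted by descending extent, ties broken by the smallest
#' linear voxel index in the cluster.
#'
#' @param t_map [volume_map] of kind `"t_stat"`.
#' @param df residual degrees of freedom of the t statistics.
#' @param voxel_p two-sided cluster-forming p threshold (default 0.001).
#' @param connectivity 6, 18 or 26.
#' @param mask logical 3D analysis mask.
#' @return list of class `cluster_map`: `labels` (integer 3D array, 0 =
#'   background), `sign` (+1/-1 per cluster), `extent`, `t_threshold`,
#'   `voxel_p`, `df`, `connectivity`.
#' @export
form_clusters <- function(t_map, df, voxel_p = 0.001, connectivity = 26L,
                          mask = NULL) {
  stopifnot(inherits(t_map, "volume_map"))
  if (df <= 0) stop("`df` must be positive", call. = FALSE)
  if (voxel_p <= 0 || voxel_p >= 1)
    stop("`voxel_p` must lie in (0, 1)", call. = FALSE)
  thr <- stats::qt(1 - voxel_p / 2, df)
  arr <- t_map$data
  if (is.null(mask)) mask <- !is.na(arr)
  arr[is.na(arr)] <- 0
  pieces <- list(pos = arr > thr & mask, neg = arr < -thr & mask)
  labels <- array(0L, dim(arr))
  sign_vec <- integer(0); extent <- integer(0); minidx <- integer(0)
  nl <- 0L
  for (sgn in c(1, -1)) {
    part <- if (sgn == 1) pieces$pos else pieces$neg
    lab <- label_components(part, connectivity)
    k <- max(lab)
    if (k > 0) {
      for (cid in seq_len(k)) {
        vox <- which(lab == cid)
        nl <- nl + 1L
        labels[vox] <- nl
        sign_vec[nl] <- sgn
        extent[nl] <- length(vox)
        minidx[nl] <- min(vox)
      }
    }
  }
  if (nl > 0) {
    ord <- order(-extent, minidx)
    relab <- integer(nl); relab[ord] <- seq_len(nl)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    sign_vec <- sign_vec[ord]; extent <- extent[ord]
  }
  structure(list(labels = labels, sign = sign_vec, extent = extent,
                 t_threshold = thr, voxel_p = voxel_p, df = df,
                 connectivity = as.integer(connectivity)),
            class = "cluster_map")
}

# Largest component extent among voxels of tvec exceeding +/- thr,
# separately per sign; tvec is in mask scan order.
max_cluster_extents <- function(tvec, thr, mask, idx, connectivity) {
  out <- c(pos = 0L, neg = 0L)
  for (sgn in c(1, -1)) {
    supra <- if (sgn == 1) tvec > thr else tvec < -thr
    if (!any(supra)) next
    part <- array(FALSE, dim(mask))
    part[idx[supra]] <- TRUE
    lab <- label_components(part, connectivity)
    ext <- tabulate(lab[lab > 0L])
    out[if (sgn == 1) "pos" else "neg"] <- max(ext)
  }
  out
}

#' Permutation-based cluster-level FDR correction
#'
#' Each observed cluster receives a nonparametric p-value: the proportion
#' of group-label permutations whose maximum same-sign cluster extent (at
#' the same forming threshold) reaches the observed extent, with the
#' add-one correction `(b + 1) / (B + 1)`. Benjamini-Hochberg is then
#' applied across the observed clusters and clusters with adjusted
#' p < `q` are flagged significant. Permutations shuffle the group
#' indicator only, keeping each subject's covariates attached.
#'
#' @param maps list of per-subject [volume_map]s.
#' @param design design matrix from [build_design()].
#' @param clusters a `cluster_map` from [form_clusters()].
#' @param mask logical 3D analysis mask.
#' @param n_permutations number of label permutations (>= 100 recommended
#'   for inference; 0 is an error).
#' @param q FDR level (default 0.05).
#' @param rng_seed seed for the permutation stream.
#' @return A `cluster_report` data.frame with one row per observed
#'   cluster: id, sign, extent, peak t, peak world coordinates (mm),
#'   permutation p, BH-adjusted p, significance flag. Attributes carry
#'   df, forming threshold, connectivity and the permutation settings.
#' @export
cluster_fdr <- function(maps, design, clusters, mask,
                        n_permutations = 1000L, q = 0.05, rng_seed = 1L) {
  stopifnot(inherits(clusters, "cluster_map"))
  if (n_permutations < 1)
    stop("`n_permutations` must be >= 1; permutation inference is impossible with B = 0",
         call. = FALSE)
  gcol <- attr(design, "group_col") %||% 2L
  nclus <- length(clusters$extent)
  fit <- NULL
  report <- data.frame(cluster_id = integer(0), sign = integer(0),
                       extent = integer(0), peak_t = numeric(0),
                       peak_x = numeric(0), peak_y = numeric(0),
                       peak_z = numeric(0), p_perm = numeric(0),
                       p_fdr = numeric(0), significant = logical(0))
  if (nclus > 0) {
    Y <- maps_to_matrix(maps, mask)
    idx <- mask_indices(mask)
    thr <- clusters$t_threshold
    B <- as.integer(n_permutations)
    max_pos <- integer(B); max_neg <- integer(B)
    set.seed(rng_seed)
    n <- nrow(design)
    for (b in seq_len(B)) {
      Xp <- design
      Xp[, gcol] <- design[sample.int(n), gcol]
      tb <- glm_tmap_matrix(Y, Xp, gcol)$t
      me <- max_cluster_extents(tb, thr, mask, idx, clusters$connectivity)
      max_pos[b] <- me["pos"]; max_neg[b] <- me["neg"]
    }
    p_perm <- vapply(seq_len(nclus), function(ci) {
      null_max <- if (clusters$sign[ci] > 0) max_pos else max_neg
      (sum(null_max >= clusters$extent[ci]) + 1) / (B + 1)
    }, numeric(1))
    p_fdr <- stats::p.adjust(p_perm, method = "BH")
    fit <- voxelwise_glm_ttest(maps, design, mask)
    peaks <- peak_world_coordinates(clusters, fit$t_map, maps[[1]]$affine)
    report <- data.frame(cluster_id = seq_len(nclus),
                         sign = clusters$sign,
                         extent = clusters$extent,
                         peak_t = peaks$peak_t,
                         peak_x = peaks$world[, 1],
                         peak_y = peaks$world[, 2],
                         peak_z = peaks$world[, 3],
                         p_perm = p_perm, p_fdr = p_fdr,
                         significant = p_fdr < q)
  }
  structure(report, class = c("cluster_report", "data.frame"),
            df = clusters$df, t_threshold = clusters$t_threshold,
            voxel_p = clusters$voxel_p,
            connectivity = clusters$connectivity,
            n_permutations = as.integer(n_permutations), q = q,
            rng_seed = as.integer(rng_seed))
}

#' Peak voxel world coordinates per cluster
#'
#' The peak is the voxel of maximum |t| within each cluster (ties broken
#' by the smallest linear voxel index), mapped through the affine with
#' 0-based voxel indices to world mm.
#'
#' @param clusters a `cluster_map`.
#' @param t_map the t-statistic [volume_map] the clusters were formed from.
#' @param affine 4x4 voxel-to-world matrix.
#' @return list with `peak_t` (signed t at the peak) and `world`
#'   (n_clusters x 3 matrix of mm coordinates).
#' @export
peak_world_coordinates <- function(clusters, t_map, affine) {
  nclus <- length(clusters$extent)
  peak_t <- numeric(nclus)
  world <- matrix(NA_real_, nclus, 3)
  for (ci in seq_len(nclus)) {
    vox <- which(clusters$labels == ci)
    tv <- t_map$data[vox]
    best <- vox[order(-abs(tv), vox)][1]
    peak_t[ci] <- t_map$data[best]
    ijk0 <- arrayInd(best, dim(clusters$labels)) - 1L
    world[ci, ] <- voxel_to_world(affine, ijk0)
  }
  list(peak_t = peak_t, world = world)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' The classical equal-variance two-sample t, computable from
#' `(mean, sd, n)` per group, with two-sided p at `n1 + n2 - 2` degrees of
#' freedom.
#'
#' @param mean1,sd1,n1 first-group summary.
#' @param mean2,sd2,n2 second-group summary.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop("each group needs n >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Demographics and clinical summary tests
#'
#' For each continuous variable: group means/SDs, the pooled-variance
#' two-sample t-test, and a Kolmogorov-Smirnov normality flag per group
#' (computed on standardized values). Sex is tested with a 2x2 chi-square
#' with Yates continuity correction.
#'
#' @param table phenotype data.frame with a `group` column.
#' @param variables continuous columns to test (defaults to those present
#'   among age, education, SLEDAI, MoCA, BDI).
#' @return list with `continuous` (data.frame of per-variable results) and
#'   `sex` (counts, chi-square statistic, p).
#' @export
summary_stat_tests <- function(table,
                               variables = intersect(
                                 c("age", "education", "SLEDAI", "MoCA", "BDI"),
                                 names(table))) {
  validate_phenotype(table)
  gp <- table$group == "patient"
  if (sum(gp) < 2 || sum(!gp) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  rows <- lapply(variables, function(v) {
    x1 <- table[[v]][gp]; x2 <- table[[v]][!gp]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2)
      return(data.frame(variable = v, mean_patient = mean(x1),
                        sd_patient = stats::sd(x1), n_patient = length(x1),
                        mean_control = NA, sd_control = NA,
                        n_control = length(x2), t = NA, df = NA, p = NA,
                        ks_normal_patient = NA, ks_normal_control = NA))
    tt <- two_sample_t_summary(mean(x1), stats::sd(x1), length(x1),
                               mean(x2), stats::sd(x2), length(x2))
    ksp <- function(x) {
      suppressWarnings(stats::ks.test((x - mean(x)) / stats::sd(x),
                                      "pnorm")$p.value)
    }
    data.frame(variable = v,
               mean_patient = mean(x1), sd_patient = stats::sd(x1),
               n_patient = length(x1),
               mean_control = mean(x2), sd_control = stats::sd(x2),
               n_control = length(x2),
               t = tt$t, df = tt$df, p = tt$p,
               ks_normal_patient = ksp(x1) > 0.05,
               ks_normal_control = ksp(x2) > 0.05)
  })
  sex <- NULL
  if ("sex" %in% names(table)) {
    counts <- rbind(patient = c(M = sum(table$sex[gp] == "M"),
                                F = sum(table$sex[gp] == "F")),
                    control = c(M = sum(table$sex[!gp] == "M"),
                                F = sum(table$sex[!gp] == "F")))
    ct <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
    sex <- list(counts = counts, statistic = unname(ct$statistic),
                p = ct$p.value)
  }
  list(continuous = do.call(rbind, rows), sex = sex)
}
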