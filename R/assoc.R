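#' Extract per-subject cluster mean values
#'
#' Unweighted mean of each subject's map over the voxels of each cluster
#' in a cluster map (typically the significant clusters of the group
#' comparison, whose values are then correlated with clinical scores).
#'
#' @param maps list of per-subject [volume_map]s.
#' @param clusters a `cluster_map` from [form_clusters()], or an integer
#'   3D label array.
#' @param cluster_ids clusters to extract (default: all).
#' @param subject_ids optional row names.
#' @return data.frame with one row per subject and one `cluster_<id>`
#'   column per cluster.
#' @export
extract_cluster_means <- function(maps, clusters, cluster_ids = NULL,
                                  subject_ids = NULL) {
  labels <- if (inherits(clusters, "cluster_map")) clusters$labels else clusters
  if (is.null(cluster_ids)) {
    cluster_ids <- sort(unique(labels[labels > 0L]))
  }
  if (!length(cluster_ids))
    stop("no clusters to extract", call. = FALSE)
  vox <- lapply(cluster_ids, function(id) {
    v <- which(labels == id)
    if (!length(v))
      stop(sprintf("cluster id %s is empty", id), call. = FALSE)
    v
  })
  out <- matrix(NA_real_, length(maps), length(cluster_ids))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    stopifnot(inherits(m, "volume_map"))
    if (!all(dim(m$data) == dim(labels)))
      stop(sprintf("map %d does not share the cluster map grid", i),
           call. = FALSE)
    out[i, ] <- vapply(vox, function(v) mean(m$data[v]), numeric(1))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("cluster_", cluster_ids)
  if (!is.null(subject_ids)) out <- cbind(subject_id = subject_ids, out)
  out
}

#' Pearson correlation with a two-sided p-value
#'
#' The sample correlation coefficient, with significance from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both nonconstant.
#' @return list with `r`, `n`, `t`, `df`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation is undefined for a constant input", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- min(max(r, -1), 1)
  df <- n - 2
  if (abs(r) >= 1) {
    tval <- sign(r) * Inf; p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r = r, n = n, t = tval, df = df, p = p)
}

#' Correlate cluster values with clinical variables
#'
#' Pearson correlations between each extracted cluster column and each
#' clinical/neuropsychological variable, run in the patient group only by
#' default (the group in which clinical variation is meaningful). No
#' multiple-testing correction is applied by default; `adjust = "BH"` is
#' available as a documented deviation from the uncorrected p < 0.05
#' convention.
#'
#' @param roi_table output of [extract_cluster_means()] (rows aligned with
#'   `phenotype`).
#' @param phenotype phenotype data.frame.
#' @param variables clinical columns to correlate.
#' @param group `"patient"` (default), `"control"`, or `"all"`.
#' @param adjust p-adjustment method (`"none"` default, or any
#'   [stats::p.adjust] method).
#' @return data.frame of (cluster, variable, n, r, p, p_adj).
#' @export
correlate_clinical <- function(roi_table, phenotype,
                               variables = c("SLEDAI", "MoCA", "BDI"),
                               group = c("patient", "control", "all"),
                               adjust = "none") {
  group <- match.arg(group)
  if (nrow(roi_table) != nrow(phenotype))
    stop("roi_table and phenotype have different numbers of rows",
         call. = FALSE)
  keep <- if (group == "all") rep(TRUE, nrow(phenotype))
          else phenotype$group == group
  ccols <- grep("^cluster_", names(roi_table), value = TRUE)
  rows <- list()
  for (cc in ccols) {
    for (v in variables) {
      if (!v %in% names(phenotype)) next
      x <- roi_table[[cc]][keep]; y <- phenotype[[v]][keep]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) next
      pc <- pearson_correlation(x[ok], y[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cc, variable = v, n = pc$n, r = pc$r, p = pc$p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster = character(0), variable = character(0),
                         n = integer(0), r = numeric(0), p = numeric(0))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}
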