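#' Voxel-wise binarized degree centrality
#'
#' For every in-mask voxel i, counts the in-mask voxels j != i whose
#' time-course Pearson correlation with i exceeds `r_threshold` (strictly;
#' by default only positive correlations count, so an anti-correlated pair
#' contributes nothing). The result is the degree of voxel i in the
#' binarized whole-mask correlation graph, a voxel-level measure of network
#' hubness.
#'
#' Correlations are computed blockwise against the full standardized
#' voxel-by-time matrix, so memory stays bounded while the counts equal a
#' brute-force all-pairs computation.
#'
#' @param series a [bold_series], normally preprocessed but *unsmoothed*.
#' @param mask logical 3D gray-matter mask on the series grid.
#' @param r_threshold correlation cutoff (default 0.25).
#' @param positive_only if `TRUE` (default) count `r > r_threshold`; if
#'   `FALSE` count `|r| > r_threshold`.
#' @param block_size number of voxels correlated per block.
#' @return A [volume_map] of kind `"dc_count"` (`NA` outside the mask).
#' @export
degree_centrality <- function(series, mask, r_threshold = 0.25,
                              positive_only = TRUE, block_size = 1024L) {
  X <- series_matrix(series, mask)          # time x voxel
  nt <- nrow(X); nv <- ncol(X)
  if (nt < 3) stop("degree centrality needs at least 3 timepoints",
                   call. = FALSE)
  U <- standardize_columns(X, mask)
  counts <- integer(nv)
  blocks <- split(seq_len(nv), ceiling(seq_len(nv) / block_size))
  for (b in blocks) {
    R <- crossprod(U[, b, drop = FALSE], U)  # r between block and all voxels
    hit <- if (positive_only) R > r_threshold else abs(R) > r_threshold
    counts[b] <- as.integer(rowSums(hit))
    # remove the self-correlation (r = 1 on the diagonal) where it counted
    self <- R[cbind(seq_along(b), b)]
    self_hit <- if (positive_only) self > r_threshold else abs(self) > r_threshold
    counts[b] <- counts[b] - as.integer(self_hit)
  }
  out <- array(NA_real_, dim(mask))
  out[mask_indices(mask)] <- counts
  volume_map(out, series$affine, "dc_count")
}

# Center each column and scale to unit Euclidean norm; errors on
# zero-variance voxels because their correlation is undefined.
standardize_columns <- function(X, mask) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  bad <- nrm <= .Machine$double.eps * nrow(X)
  if (any(bad)) {
    idx <- mask_indices(mask)[bad]
    stop(sprintf(
      "zero-variance time course at in-mask voxel linear index(es): %s",
      paste(utils::head(idx, 10L), collapse = ", ")), call. = FALSE)
  }
  sweep(Xc, 2L, nrm, "/")
}

#' z-score a map over its mask
#'
#' Subtracts the in-mask mean and divides by the in-mask standard
#' deviation, using the population (divide-by-n) convention: the map is a
#' within-subject normalization, not an inferential statistic. The output
#' has in-mask mean 0 and SD 1.
#'
#' @param map a [volume_map] (e.g. kind `"dc_count"`).
#' @param mask logical 3D mask.
#' @return A [volume_map] of kind `"dc_z"`.
#' @export
zscore_map <- function(map, mask) {
  stopifnot(inherits(map, "volume_map"))
  idx <- mask_indices(mask)
  if (length(idx) < 2)
    stop("z-scoring needs at least 2 in-mask voxels", call. = FALSE)
  v <- map$data[idx]
  if (anyNA(v)) stop("map has missing values inside the mask", call. = FALSE)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= .Machine$double.eps * abs(m) + .Machine$double.eps)
    stop("map is constant over the mask; z-score undefined", call. = FALSE)
  out <- array(NA_real_, dim(mask))
  out[idx] <- (v - m) / s
  volume_map(out, map$affine, "dc_z")
}

#' Mean time series of a seed region
#'
#' @param series a [bold_series].
#' @param seed_mask logical 3D mask of the seed voxels.
#' @return Numeric vector of length `n_timepoints` (unweighted voxel mean
#'   at each timepoint).
#' @export
seed_mean_timeseries <- function(series, seed_mask) {
  idx <- mask_indices(seed_mask)
  if (length(idx) == 0) stop("seed mask is empty", call. = FALSE)
  X <- series_matrix(series, seed_mask)
  rowMeans(X)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)` with |r| clipped at `1 - 1e-7` so that perfectly correlated
#' voxels map to a large finite z instead of infinity.
#'
#' @param r correlations in `[-1, 1]`.
#' @return z values.
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -1), 1)
  clip <- 1 - 1e-7
  r <- sign(r) * pmin(abs(r), clip)
  atanh(r)
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation between the seed's mean time series and every
#' in-mask voxel, Fisher r-to-z transformed. Seed voxels are included in
#' the output (their correlation with the seed mean need not be 1).
#'
#' @param series a [bold_series] (for seed FC, normally smoothed).
#' @param seed_mask logical 3D seed mask (subset of `mask`).
#' @param mask logical 3D analysis mask.
#' @return A [volume_map] of kind `"fc_z"`.
#' @export
seed_fc_map <- function(series, seed_mask, mask) {
  s <- seed_mean_timeseries(series, seed_mask)
  if (stats::sd(s) == 0)
    stop("seed mean time series is constant; correlation undefined",
         call. = FALSE)
  X <- series_matrix(series, mask)
  U <- standardize_columns(X, mask)
  u_seed <- (s - mean(s)) / sqrt(sum((s - mean(s))^2))
  r <- as.numeric(crossprod(U, u_seed))
  out <- array(NA_real_, dim(mask))
  out[mask_indices(mask)] <- fisher_z(r)
  volume_map(out, series$affine, "fc_z")
}
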