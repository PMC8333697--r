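# Shared in-code fixtures: tiny grids, toy series, quick cohort runner.

toy_affine <- function(spacing = 1, origin = rep(0, 3)) {
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

# A bold_series whose in-mask voxel time courses are the columns of `mat`
# (time x voxel); remaining voxels are zero.
series_from_matrix <- function(mat, grid = NULL, tr = 2, spacing = 1) {
  nv <- ncol(mat); nt <- nrow(mat)
  if (is.null(grid)) grid <- c(nv, 1L, 1L)
  arr <- array(0, c(grid, nt))
  flat <- matrix(arr, prod(grid), nt)
  flat[seq_len(nv), ] <- t(mat)
  dim(flat) <- c(grid, nt)
  bold_series(flat, toy_affine(spacing), tr)
}

mask_first_n <- function(grid, n) {
  m <- array(FALSE, grid)
  m[seq_len(n)] <- TRUE
  m
}

map_from_values <- function(values, mask, kind = "dc_z", spacing = 1) {
  arr <- array(NA_real_, dim(mask))
  arr[which(mask)] <- values
  volume_map(arr, toy_affine(spacing), kind)
}

# Small end-to-end helper: preprocessed + smoothed DC z-maps for a cohort.
cohort_dcz <- function(cohort, n_drop = 10, fwhm = 6) {
  lapply(cohort$series, function(s) {
    p <- preprocess_bold(s, n_drop = n_drop)
    smooth_gaussian(zscore_map(degree_centrality(p, cohort$mask),
                               cohort$mask), fwhm)
  })
}

# Brute-force O(V^2) degree-centrality oracle.
dc_bruteforce <- function(mat, r_threshold = 0.25, positive_only = TRUE) {
  nv <- ncol(mat)
  counts <- integer(nv)
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (i == j) next
      r <- stats::cor(mat[, i], mat[, j])
      hit <- if (positive_only) r > r_threshold else abs(r) > r_threshold
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  counts
}
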