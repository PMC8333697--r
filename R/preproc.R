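#' Drop initial volumes
#'
#' Removes the first `n_drop` frames of a BOLD series (magnetization
#' equilibration); affine and TR are unchanged.
#'
#' @param series a [bold_series].
#' @param n_drop number of leading frames to remove.
#' @return The shortened [bold_series].
#' @export
drop_initial_volumes <- function(series, n_drop) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$data)[4]
  n_drop <- as.integer(n_drop)
  if (n_drop < 0) stop("`n_drop` must be >= 0", call. = FALSE)
  if (n_drop >= nt)
    stop(sprintf("cannot drop %d volumes from a %d-volume series",
                 n_drop, nt), call. = FALSE)
  if (n_drop == 0L) return(series)
  bold_series(series$data[, , , (n_drop + 1L):nt, drop = FALSE],
              series$affine, series$tr_seconds)
}

#' Remove a per-voxel linear trend
#'
#' Fits and subtracts an intercept-plus-slope least-squares line from each
#' voxel's time course. Output voxel means are zero.
#'
#' @param series a [bold_series].
#' @return Detrended [bold_series].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$data)[4]
  if (nt < 3) stop("detrending needs at least 3 timepoints", call. = FALSE)
  X <- cbind(1, seq_len(nt))
  apply_residual_projection(series, X)
}

#' Regress out nuisance series
#'
#' Per-voxel residuals of the least-squares projection onto an intercept
#' plus the supplied nuisance regressors (e.g. motion parameters, white
#' matter and CSF signals, or simulated drift/confound series).
#'
#' @param series a [bold_series].
#' @param nuisance numeric matrix with one column per regressor and one row
#'   per timepoint; may have zero columns (intercept-only projection, i.e.
#'   mean centering).
#' @return Residual [bold_series].
#' @export
regress_nuisance <- function(series, nuisance) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$data)[4]
  if (is.null(nuisance)) nuisance <- matrix(numeric(0), nrow = nt, ncol = 0)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nt)
    stop(sprintf("nuisance has %d rows but the series has %d timepoints",
                 nrow(nuisance), nt), call. = FALSE)
  X <- cbind(intercept = 1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    if (is.null(dropped)) dropped <- "unnamed"
    stop(sprintf("nuisance design is rank deficient (collinear column(s): %s)",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  apply_residual_projection(series, X)
}

# Project every voxel time course onto the orthogonal complement of
# colspace(X) in one matrix operation.
apply_residual_projection <- function(series, X) {
  d <- dim(series$data)
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  qrX <- qr(X)
  fitted <- t(qr.fitted(qrX, t(Y)))
  out <- Y - fitted
  dim(out) <- d
  bold_series(out, series$affine, series$tr_seconds)
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order 5, applied
#' to every voxel's time course. Zero phase preserves the temporal
#' alignment, and hence the correlation structure, of the series; the
#' passband default elsewhere in the package is 0.01-0.08 Hz, the band in
#' which resting-state network fluctuations concentrate.
#'
#' @param series a [bold_series].
#' @param low_hz,high_hz passband edges; must satisfy
#'   `0 <= low_hz < high_hz <= 1/(2 * tr_seconds)`.
#' @param order Butterworth order (each of the forward and backward passes).
#' @return Filtered [bold_series], same length as the input.
#' @export
bandpass <- function(series, low_hz, high_hz, order = 5L) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq))
    stop(sprintf(
      "band [%g, %g] Hz is invalid for TR %g s (need 0 <= low < high <= %g)",
      low_hz, high_hz, series$tr_seconds, nyq), call. = FALSE)
  if (low_hz == 0 && high_hz == nyq) return(series)
  filt <- if (low_hz == 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else if (high_hz == nyq) {
    signal::butter(order, low_hz / nyq, type = "high")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  d <- dim(series$data)
  Y <- t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
  # remove the temporal mean first: 0 Hz is outside every admissible band,
  # and a large offset would otherwise leak an end transient through the
  # zero-padded forward-backward pass
  Y <- sweep(Y, 2L, colMeans(Y), "-")
  out <- t(filtfilt_matrix(filt$b, filt$a, Y))
  dim(out) <- d
  bold_series(out, series$affine, series$tr_seconds)
}

# Zero-phase IIR filtering of every column of a matrix; matches
# signal::filtfilt (zero end-padding of 2*max(length(a), length(b))
# samples, forward pass, time reversal, second pass) applied column-wise.
filtfilt_matrix <- function(b, a, Y) {
  npad <- 2L * max(length(a), length(b))
  Yp <- rbind(Y, matrix(0, npad, ncol(Y)))
  f <- iir_filter_matrix(b, a, Yp)
  f <- iir_filter_matrix(b, a, f[nrow(f):1L, , drop = FALSE])
  f <- f[nrow(f):1L, , drop = FALSE]
  f[seq_len(nrow(Y)), , drop = FALSE]
}

# Direct-form IIR filter with zero initial conditions, vectorized across
# columns; the time recursion is the only loop.
iir_filter_matrix <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(X); nb <- length(b); na <- length(a)
  Yout <- matrix(0, n, ncol(X))
  for (t in seq_len(n)) {
    acc <- b[1] * X[t, ]
    if (nb > 1) {
      kmax <- min(nb - 1L, t - 1L)
      for (k in seq_len(kmax)) acc <- acc + b[k + 1L] * X[t - k, ]
    }
    if (na > 1) {
      kmax <- min(na - 1L, t - 1L)
      for (k in seq_len(kmax)) acc <- acc - a[k + 1L] * Yout[t - k, ]
    }
    Yout[t, ] <- acc
  }
  Yout
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis, expressed in mm and converted to voxels through the affine.
#' Boundaries use reflection ("symmetric") padding, which preserves
#' constant images and avoids edge darkening on small grids. 4D input is
#' smoothed frame by frame.
#'
#' @param x a [bold_series], [volume_map], or 3D/4D array.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is the
#'   identity.
#' @param affine required for bare arrays.
#' @return Same type and shape as the input.
#' @export
smooth_gaussian <- function(x, fwhm_mm, affine = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (inherits(x, "bold_series")) {
    out <- x
    out$data <- smooth_array(x$data, fwhm_mm, x$affine)
    return(out)
  }
  if (inherits(x, "volume_map")) {
    out <- x
    out$data <- smooth_array(x$data, fwhm_mm, x$affine)
    return(out)
  }
  if (is.null(affine))
    stop("`affine` is required when smoothing a bare array", call. = FALSE)
  smooth_array(x, fwhm_mm, affine)
}

smooth_array <- function(arr, fwhm_mm, affine) {
  if (fwhm_mm == 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_sizes(affine)
  nd <- length(dim(arr))
  if (nd == 4L) {
    out <- arr
    for (t in seq_len(dim(arr)[4]))
      out[, , , t] <- smooth_array(arr[, , , t], fwhm_mm, affine)
    return(out)
  }
  if (nd != 3L) stop("smoothing expects a 3D or 4D array", call. = FALSE)
  # NA voxels (outside-mask) are smoothed as values and restored afterwards
  na_idx <- is.na(arr)
  if (any(na_idx)) arr[na_idx] <- 0
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / vs[axis])
    if (length(k) > 1L) arr <- conv_axis_reflect(arr, k, axis)
  }
  if (any(na_idx)) arr[na_idx] <- NA_real_
  arr
}

# Discrete Gaussian taps out to 3 sigma (minimum radius 1), normalized to
# unit sum so constants are preserved exactly.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

conv_axis_reflect <- function(arr, k, axis) {
  n <- dim(arr)[axis]
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(arr))
  for (o in -r:r) {
    idx <- seq_len(n) + o
    # symmetric reflection about the grid edges
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    w <- k[o + r + 1L]
    out <- out + w * switch(axis,
                            arr[idx, , , drop = FALSE],
                            arr[, idx, , drop = FALSE],
                            arr[, , idx, drop = FALSE])
  }
  out
}

#' Temporal preprocessing chain
#'
#' Applies, in order: initial-volume dropping, per-voxel linear detrend,
#' nuisance regression, band-pass filtering. Spatial smoothing is *not*
#' part of this chain: series feeding degree centrality stay unsmoothed
#' (the DC z-map is smoothed instead), while series feeding seed-based
#' connectivity are smoothed afterwards with [smooth_gaussian].
#'
#' @param series a [bold_series].
#' @param n_drop initial volumes to remove.
#' @param nuisance optional per-timepoint nuisance matrix (rows must match
#'   the series length *after* dropping).
#' @param band passband `c(low, high)` in Hz, or `NULL` to skip filtering.
#' @return A [bold_series] with a `"provenance"` attribute listing the
#'   applied steps and parameters.
#' @export
preprocess_bold <- function(series, n_drop = 10L, nuisance = NULL,
                            band = c(0.01, 0.08)) {
  steps <- list()
  out <- drop_initial_volumes(series, n_drop)
  steps$drop_initial_volumes <- list(n_drop = as.integer(n_drop))
  out <- detrend_linear(out)
  steps$detrend_linear <- list()
  out <- regress_nuisance(out, nuisance)
  steps$regress_nuisance <-
    list(n_regressors = if (is.null(nuisance)) 0L else ncol(as.matrix(nuisance)))
  if (!is.null(band)) {
    out <- bandpass(out, band[1], band[2])
    steps$bandpass <- list(low_hz = band[1], high_hz = band[2], order = 5L)
  }
  attr(out, "provenance") <- steps
  out
}
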