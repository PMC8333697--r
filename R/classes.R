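#' BOLD time series container
#'
#' Bundles one subject's 4D BOLD signal grid with its voxel-to-world affine
#' and repetition time. All temporal operations in the package act on this
#' container and preserve the affine and TR.
#'
#' @param data 4D numeric array, dimensions `(x, y, z, t)`.
#' @param affine 4x4 voxel-to-world transform in mm. World coordinates are
#'   `affine %*% c(i, j, k, 1)` with *0-based* voxel indices `i, j, k`.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#'
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr_seconds) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("a BOLD series needs at least 2 timepoints", call. = FALSE)
  affine <- check_affine(affine)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  cat(sprintf("  voxel size %s mm\n",
              paste(signif(voxel_sizes(x$affine), 4), collapse = " x ")))
  invisible(x)
}

#' 3D scalar map container
#'
#' A single 3D statistical or connectivity map on a voxel grid, tagged with
#' the kind of quantity it holds. Values outside the analysis mask are `NA`.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param kind one of `"dc_count"`, `"dc_z"`, `"fc_r"`, `"fc_z"`,
#'   `"t_stat"`, `"p_value"`, `"weight"`.
#' @param mask_ref optional identifier of the mask the map is defined on.
#'
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(data, affine, kind, mask_ref = NULL) {
  kinds <- c("dc_count", "dc_z", "fc_r", "fc_z", "t_stat", "p_value", "weight")
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  affine <- check_affine(affine)
  kind <- match.arg(kind, kinds)
  if (kind == "fc_r") {
    v <- data[!is.na(data)]
    if (length(v) && (min(v) < -1 || max(v) > 1))
      stop("fc_r values must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(data = data, affine = affine, kind = kind,
                 mask_ref = mask_ref),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[!is.na(x$data)]
  cat(sprintf("<volume_map:%s> %d x %d x %d, %d in-mask voxels, range [%g, %g]\n",
              x$kind, d[1], d[2], d[3], length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 16)
    stop("`affine` must be invertible", call. = FALSE)
  storage.mode(affine) <- "double"
  unname(affine)
}

#' Voxel sizes (mm) implied by an affine
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(affine) {
  affine <- check_affine(affine)
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(affine, ijk) {
  affine <- check_affine(affine)
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# Shared-grid check used by every multi-image operation.
stop_unless_same_grid <- function(a_dim, a_aff, b_dim, b_aff, what = "inputs") {
  if (!all(a_dim[1:3] == b_dim[1:3]))
    stop(sprintf("grid mismatch: %s have dimensions %s vs %s", what,
                 paste(a_dim[1:3], collapse = "x"),
                 paste(b_dim[1:3], collapse = "x")), call. = FALSE)
  if (max(abs(a_aff - b_aff)) > 1e-4)
    stop(sprintf("grid mismatch: %s have different affines", what),
         call. = FALSE)
  invisible(TRUE)
}

# Deterministic in-mask scan order: column-major linear indices.
mask_indices <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  which(mask != 0 & !is.na(mask))
}

# Extract the in-mask time-by-voxel matrix from a bold_series.
series_matrix <- function(series, mask) {
  d <- dim(series$data)
  if (!all(d[1:3] == dim(mask)))
    stop(sprintf("grid mismatch: series is %s but mask is %s",
                 paste(d[1:3], collapse = "x"),
                 paste(dim(mask), collapse = "x")), call. = FALSE)
  idx <- mask_indices(mask)
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[idx, , drop = FALSE])
}
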