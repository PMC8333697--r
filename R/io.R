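#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 file and returns the data array together with
#' its voxel-to-world affine. 4D files are returned as [bold_series] (the
#' repetition time is taken from the 4th pixdim unless overridden); 3D
#' files are returned as a plain list with `data` and `affine`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr_seconds optional TR override for 4D files (seconds).
#' @return A [bold_series] for 4D input, otherwise `list(data, affine)`.
#' @export
read_volume <- function(path, tr_seconds = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  affine <- unclass(structure(RNifti::xform(img), code = NULL))
  attr(affine, "imagedim") <- NULL
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  if (length(dim(arr)) == 4L) {
    if (is.null(tr_seconds)) {
      tr_seconds <- RNifti::pixdim(img)[4]
      if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 1
    }
    bold_series(arr, affine, tr_seconds)
  } else {
    list(data = arr, affine = check_affine(affine))
  }
}

#' Write a volume or series to NIfTI
#'
#' Writes a [bold_series], [volume_map], or raw array (with an explicit
#' affine) to a NIfTI-1 file. The affine is stored in the sform; a
#' write-then-read round trip preserves data within single-float tolerance
#' and the affine exactly. `NA` values (outside-mask) are written as 0.
#'
#' @param x a [bold_series], [volume_map], logical/numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine required when `x` is a bare array.
#' @param tr_seconds stored in the time pixdim for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL, tr_seconds = NULL) {
  if (inherits(x, "bold_series")) {
    arr <- x$data; affine <- x$affine
    if (is.null(tr_seconds)) tr_seconds <- x$tr_seconds
  } else if (inherits(x, "volume_map")) {
    arr <- x$data; affine <- x$affine
  } else {
    arr <- x
    if (is.null(affine))
      stop("`affine` is required when writing a bare array", call. = FALSE)
  }
  affine <- check_affine(affine)
  storage.mode(arr) <- "double"
  arr[is.na(arr)] <- 0
  vs <- voxel_sizes(affine)
  pd <- if (length(dim(arr)) == 4L) c(vs, tr_seconds %||% 1) else vs
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D mask volume
#'
#' Nonzero voxels are `TRUE`; zero and `NA` voxels are `FALSE`.
#'
#' @param path NIfTI file.
#' @return `list(mask = logical 3D array, affine = 4x4 matrix)`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (inherits(v, "bold_series"))
    stop(sprintf("mask file %s is 4D; a 3D volume is required", path),
         call. = FALSE)
  m <- v$data != 0 & !is.na(v$data)
  dim(m) <- dim(v$data)
  list(mask = m, affine = v$affine)
}

#' Read a phenotype table
#'
#' Tab-separated with a header row. Expected columns: `subject_id`,
#' `group` (patient/control), `age`, `sex` (M/F), `education`, `SLEDAI`,
#' `MoCA`, `BDI`, and optionally `image_path` and `include_flag`.
#'
#' @param path TSV file.
#' @return data.frame with one row per subject.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_phenotype(tab)
  tab
}

#' @rdname read_phenotype
#' @param table phenotype data.frame.
#' @export
write_phenotype <- function(table, path) {
  validate_phenotype(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_phenotype <- function(tab) {
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("phenotype table lacks required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("subject_id values must be unique", call. = FALSE)
  bad <- !tab$group %in% c("patient", "control")
  if (any(bad))
    stop(sprintf("group must be 'patient' or 'control' (offending rows: %s)",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  invisible(tab)
}

#' Numeric covariate coding for sex
#'
#' `"F"` maps to 0 and `"M"` to 1 (the reference level is female, the
#' majority class in typical lupus cohorts).
#'
#' @param sex character vector of `"M"`/`"F"`.
#' @return numeric 0/1 vector.
#' @export
sex_to_numeric <- function(sex) {
  if (!all(sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'", call. = FALSE)
  as.numeric(sex == "M")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
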