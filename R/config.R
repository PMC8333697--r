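#' Pipeline configuration
#'
#' Collects every tunable stage parameter with defaults matching the
#' analysis this package implements: drop the first 10 volumes, band-pass
#' 0.01-0.08 Hz, 6 mm FWHM smoothing, degree-centrality threshold
#' r > 0.25, voxel-forming threshold p < 0.001, cluster threshold q < 0.05,
#' 1000 permutations, linear SVM with C = 1, top 20% of |weight| voxels.
#'
#' @param n_drop initial volumes removed for magnetization equilibrium.
#' @param band passband edges in Hz, `c(low, high)`.
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum (mm).
#' @param r_threshold correlation threshold for binarized degree centrality.
#' @param positive_only count only r > threshold (not `|r|`).
#' @param voxel_p two-sided voxel-level cluster-forming p threshold.
#' @param cluster_q FDR level for cluster-level correction.
#' @param connectivity neighborhood scheme for clustering: 6, 18 or 26.
#' @param n_permutations label permutations for cluster inference and MVPA.
#' @param svm_C soft-margin cost of the linear SVM.
#' @param top_fraction fraction of in-mask voxels kept in the weight-map
#'   summary.
#' @param rng_seed integer seed governing all randomness.
#' @param motion_limit_mm,motion_limit_deg head-motion exclusion limits
#'   recorded as metadata (realignment itself is upstream of this package;
#'   the limits are applied only as a phenotype `include_flag` filter).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_drop = 10L,
                            band = c(0.01, 0.08),
                            fwhm_mm = 6,
                            r_threshold = 0.25,
                            positive_only = TRUE,
                            voxel_p = 0.001,
                            cluster_q = 0.05,
                            connectivity = 26L,
                            n_permutations = 1000L,
                            svm_C = 1,
                            top_fraction = 0.20,
                            rng_seed = 1L,
                            motion_limit_mm = 2.5,
                            motion_limit_deg = 2.5) {
  cfg <- list(n_drop = as.integer(n_drop), band = as.numeric(band),
              fwhm_mm = fwhm_mm, r_threshold = r_threshold,
              positive_only = isTRUE(positive_only), voxel_p = voxel_p,
              cluster_q = cluster_q, connectivity = as.integer(connectivity),
              n_permutations = as.integer(n_permutations), svm_C = svm_C,
              top_fraction = top_fraction, rng_seed = as.integer(rng_seed),
              motion_limit_mm = motion_limit_mm,
              motion_limit_deg = motion_limit_deg)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  known <- c("n_drop", "band", "fwhm_mm", "r_threshold", "positive_only",
             "voxel_p", "cluster_q", "connectivity", "n_permutations",
             "svm_C", "top_fraction", "rng_seed", "motion_limit_mm",
             "motion_limit_deg")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  miss <- setdiff(known, names(cfg))
  if (length(miss))
    stop(sprintf("missing configuration key(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  stopifnot_cfg(cfg$n_drop >= 0, "n_drop must be >= 0")
  stopifnot_cfg(length(cfg$band) == 2 && cfg$band[1] >= 0 &&
                  cfg$band[1] < cfg$band[2],
                "band must be c(low, high) with 0 <= low < high")
  stopifnot_cfg(cfg$fwhm_mm >= 0, "fwhm_mm must be >= 0")
  stopifnot_cfg(cfg$r_threshold > -1 && cfg$r_threshold < 1,
                "r_threshold must lie in (-1, 1)")
  stopifnot_cfg(cfg$voxel_p > 0 && cfg$voxel_p < 1,
                "voxel_p must lie in (0, 1)")
  stopifnot_cfg(cfg$cluster_q > 0 && cfg$cluster_q < 1,
                "cluster_q must lie in (0, 1)")
  stopifnot_cfg(cfg$connectivity %in% c(6L, 18L, 26L),
                "connectivity must be 6, 18 or 26")
  stopifnot_cfg(cfg$n_permutations >= 0,
                "n_permutations must be >= 0")
  stopifnot_cfg(cfg$svm_C > 0, "svm_C must be > 0")
  stopifnot_cfg(cfg$top_fraction > 0 && cfg$top_fraction <= 1,
                "top_fraction must lie in (0, 1]")
  invisible(cfg)
}

stopifnot_cfg <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip: `read_config(write_config(cfg, path))` restores an
#' identical parameter set. Unknown keys in the file are rejected.
#'
#' @param cfg a [pipeline_config].
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-16s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
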