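#' Run the full analysis pipeline
#'
#' Executes, in order: temporal preprocessing -> voxel-wise degree
#' centrality (on unsmoothed series) -> DC z-scoring and smoothing ->
#' covariate-adjusted group comparison with permutation cluster-level FDR
#' -> seed-based FC (seeds = significant DC clusters) with its own group
#' comparison -> cluster-mean extraction and clinical correlation ->
#' linear-SVM MVPA with permutation significance and weight-map
#' localization. Every run writes a JSON provenance record (effective
#' configuration, config file hash, seed, package and R versions,
#' per-stage wall time).
#'
#' @param input either the list returned by [generate_cohort()], or a
#'   directory written by [write_cohort()] (containing `phenotype.tsv`
#'   with `image_path`, `gm_mask.nii.gz`).
#' @param config a [pipeline_config].
#' @param out_dir output directory; created if needed. `NULL` skips all
#'   file output and returns results in memory only.
#' @param nuisance optional list of per-subject nuisance matrices (rows
#'   matching the post-drop series length).
#' @param verbose print stage progress.
#' @return (invisibly) a list with elements `dcz_maps`, `dc_ttest`,
#'   `dc_clusters`, `dc_report`, `fc` (per-seed results), `assoc`,
#'   `mvpa`, `weights`, `phenotype`, `provenance`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         nuisance = NULL, verbose = TRUE) {
  validate_config(config)
  t_start <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  say("configuration:")
  if (verbose) for (k in names(config))
    message(sprintf("  %-16s %s", k, paste(format(config[[k]]), collapse = ", ")))

  # ---- load ----
  t0 <- tic()
  if (is.character(input)) {
    phen <- read_phenotype(file.path(input, "phenotype.tsv"))
    mk <- read_mask(file.path(input, "gm_mask.nii.gz"))
    mask <- mk$mask
    series <- lapply(phen$image_path, read_volume)
  } else {
    phen <- input$phenotype
    mask <- input$mask
    series <- input$series
  }
  if ("include_flag" %in% names(phen)) {
    keep <- as.logical(phen$include_flag)
    if (!all(keep)) {
      say("excluding %d subject(s) flagged by the motion criterion",
          sum(!keep))
      phen <- phen[keep, , drop = FALSE]
      series <- series[keep]
    }
  }
  n <- nrow(phen)
  timings$load <- toc(t0)
  say("stage load: %d subjects, %d in-mask voxels (%.1f s)",
      n, length(mask_indices(mask)), timings$load)

  # ---- preprocessing (unsmoothed; DC input) ----
  t0 <- tic()
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    nu <- if (is.null(nuisance)) NULL else nuisance[[i]]
    pre[[i]] <- tryCatch(
      preprocess_bold(series[[i]], n_drop = config$n_drop, nuisance = nu,
                      band = config$band),
      error = function(e) stop(sprintf("stage preproc, subject %s: %s",
                                       phen$subject_id[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  timings$preproc <- toc(t0)
  say("stage preproc done (%.1f s)", timings$preproc)

  # ---- degree centrality ----
  t0 <- tic()
  dcz <- vector("list", n)
  for (i in seq_len(n)) {
    dc <- tryCatch(
      degree_centrality(pre[[i]], mask, r_threshold = config$r_threshold,
                        positive_only = config$positive_only),
      error = function(e) stop(sprintf("stage dc, subject %s: %s",
                                       phen$subject_id[i],
                                       conditionMessage(e)), call. = FALSE))
    z <- zscore_map(dc, mask)
    dcz[[i]] <- smooth_gaussian(z, config$fwhm_mm)
  }
  timings$dc <- toc(t0)
  say("stage dc done (%.1f s)", timings$dc)

  # ---- DC group statistics ----
  t0 <- tic()
  design <- build_design(phen)
  fit <- voxelwise_glm_ttest(dcz, design, mask)
  dc_clusters <- form_clusters(fit$t_map, fit$df, voxel_p = config$voxel_p,
                               connectivity = config$connectivity,
                               mask = mask)
  dc_report <- cluster_fdr(dcz, design, dc_clusters, mask,
                           n_permutations = config$n_permutations,
                           q = config$cluster_q,
                           rng_seed = config$rng_seed)
  timings$groupstats_dc <- toc(t0)
  say("stage groupstats (DC): %d cluster(s), %d significant (%.1f s)",
      nrow(dc_report), sum(dc_report$significant), timings$groupstats_dc)

  # ---- seed-based FC on significant DC clusters ----
  t0 <- tic()
  sig_ids <- dc_report$cluster_id[dc_report$significant]
  fc_results <- list()
  if (length(sig_ids) == 0) {
    say("no significant DC cluster: seed-based FC stage skipped")
  } else {
    smoothed <- lapply(pre, smooth_gaussian, fwhm_mm = config$fwhm_mm)
    for (id in sig_ids) {
      seed_name <- sprintf("dc%d", id)
      seed_mask <- dc_clusters$labels == id
      fcz <- lapply(smoothed, seed_fc_map, seed_mask = seed_mask,
                    mask = mask)
      ffit <- voxelwise_glm_ttest(fcz, design, mask)
      fclus <- form_clusters(ffit$t_map, ffit$df, voxel_p = config$voxel_p,
                             connectivity = config$connectivity, mask = mask)
      frep <- cluster_fdr(fcz, design, fclus, mask,
                          n_permutations = config$n_permutations,
                          q = config$cluster_q, rng_seed = config$rng_seed)
      fc_results[[seed_name]] <- list(seed_mask = seed_mask, maps = fcz,
                                      ttest = ffit, clusters = fclus,
                                      report = frep)
      say("  seed %s: %d FC cluster(s), %d significant",
          seed_name, nrow(frep), sum(frep$significant))
    }
  }
  timings$seedfc <- toc(t0)

  # ---- clinical association ----
  t0 <- tic()
  assoc_tab <- NULL
  if (length(sig_ids)) {
    roi <- extract_cluster_means(dcz, dc_clusters, cluster_ids = sig_ids,
                                 subject_ids = phen$subject_id)
    assoc_tab <- correlate_clinical(roi, phen)
  }
  timings$assoc <- toc(t0)

  # ---- MVPA ----
  t0 <- tic()
  features <- build_feature_matrix(dcz, mask, phen$group)
  mv <- permutation_test(features, n_permutations = config$n_permutations,
                         svm_C = config$svm_C, rng_seed = config$rng_seed)
  wm <- weight_map(features, svm_C = config$svm_C,
                   top_fraction = config$top_fraction)
  timings$mvpa <- toc(t0)
  say("stage mvpa: accuracy %.2f%%, AUC %.3f, permutation p(accuracy) = %.4g (%.1f s)",
      mv$observed$metrics$accuracy, mv$observed$auc, mv$p["accuracy"],
      timings$mvpa)

  provenance <- list(
    package = "netdc",
    package_version = as.character(utils::packageVersion("netdc")),
    r_version = R.version.string,
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    rng_seed = config$rng_seed,
    n_subjects = n,
    stages = names(timings),
    stage_seconds = timings,
    notes = if (length(sig_ids) == 0)
      "no significant DC cluster; seed-based FC and association stages skipped"
    else sprintf("seed-based FC run on %d significant DC cluster(s)",
                 length(sig_ids)))

  result <- list(dcz_maps = dcz, dc_ttest = fit, dc_clusters = dc_clusters,
                 dc_report = dc_report, fc = fc_results, assoc = assoc_tab,
                 mvpa = mv, weights = wm, phenotype = phen, mask = mask,
                 design = design, provenance = provenance)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, config, out_dir)
    say("outputs written to %s", out_dir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phen <- result$phenotype
  aff <- result$dcz_maps[[1]]$affine
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  for (i in seq_len(nrow(phen)))
    write_volume(result$dcz_maps[[i]],
                 file.path(out_dir, sprintf("%s_dcz.nii.gz",
                                            phen$subject_id[i])))
  write_volume(result$dc_ttest$t_map, file.path(out_dir, "dc_tmap.nii.gz"))
  write_volume(result$dc_clusters$labels,
               file.path(out_dir, "dc_clusters.nii.gz"), affine = aff)
  write_cluster_report(result$dc_report, file.path(out_dir, "dc_clusters"))
  for (seed_name in names(result$fc)) {
    fr <- result$fc[[seed_name]]
    for (i in seq_len(nrow(phen)))
      write_volume(fr$maps[[i]],
                   file.path(out_dir, sprintf("%s_%s_fcz.nii.gz",
                                              phen$subject_id[i], seed_name)))
    write_volume(fr$ttest$t_map,
                 file.path(out_dir, sprintf("fc_%s_tmap.nii.gz", seed_name)))
    write_cluster_report(fr$report,
                         file.path(out_dir, sprintf("fc_%s_clusters",
                                                    seed_name)))
  }
  if (!is.null(result$assoc))
    utils::write.table(result$assoc, file.path(out_dir, "assoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  mv <- result$mvpa
  jsonlite::write_json(
    list(metrics = mv$observed$metrics, auc = mv$observed$auc,
         confusion = as.list(mv$observed$confusion),
         permutation_p = as.list(mv$p),
         n_permutations = mv$n_permutations),
    file.path(out_dir, "mvpa_metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(mv$observed$folds,
                     file.path(out_dir, "mvpa_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rp <- roc_points(mv$observed$folds$decision_value,
                   mv$observed$folds$true)
  utils::write.table(rp, file.path(out_dir, "mvpa_roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_volume(result$weights$map, file.path(out_dir, "svm_weights.nii.gz"))
  write_volume(result$weights$top_mask * 1,
               file.path(out_dir, "svm_top_mask.nii.gz"), affine = aff)
  if (!is.null(result$weights$region_summary))
    utils::write.table(result$weights$region_summary,
                       file.path(out_dir, "svm_region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- result$provenance
  prov$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

write_cluster_report <- function(report, stem) {
  utils::write.table(as.data.frame(report), paste0(stem, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(clusters = as.data.frame(report),
         df = attr(report, "df"),
         t_threshold = attr(report, "t_threshold"),
         voxel_p = attr(report, "voxel_p"),
         connectivity = attr(report, "connectivity"),
         n_permutations = attr(report, "n_permutations"),
         q = attr(report, "q")),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' ROC curve points from decision values
#'
#' @param scores decision values (higher = more patient-like).
#' @param labels `"patient"`/`"control"` per score.
#' @return data.frame of (threshold, fpr, tpr) sweeping the thresholds.
#' @export
roc_points <- function(scores, labels) {
  pos <- as.character(labels) == "patient"
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  data.frame(threshold = scores[ord],
             fpr = fp / sum(!pos), tpr = tp / sum(pos))
}
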