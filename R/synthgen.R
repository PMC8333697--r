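#' Latent-network model for synthetic BOLD cohorts
#'
#' The generator represents resting-state structure as a small set of
#' band-limited latent network signals. Each gray-matter voxel loads on one
#' network; a compact "hub" region additionally loads on `hub_networks` of
#' them, so its voxels correlate with a broad swath of gray matter. In the
#' patient group the hub loading is raised by `group_effect_delta`, pushing
#' hub-to-network correlations across the degree-centrality threshold and
#' thereby planting a recoverable hub-degree group difference.
#'
#' The defaults are chosen from the model's correlation algebra so that the
#' planted effect is unambiguous rather than threshold-marginal: a hub
#' voxel with loading `a` on `m` networks has population correlation
#' `r = a / (sqrt(m a^2 + sigma^2) * sqrt(1 + sigma^2))` with a voxel of
#' one of those networks, which saturates at `1 / (sqrt(m) sqrt(1 +
#' sigma^2))`. With `m = 2` and `sigma = 0.6` the cap is about 0.61, so
#' control hubs (`a = 0.02`, r about 0.03) sit far below the r = 0.25
#' degree threshold while patient hubs (`a = 0.92`, r about 0.55) sit far
#' above it — both in the flat tails of the sampling distribution of r.
#' The tails matter: 0.01-0.08 Hz band-limiting leaves roughly 60
#' effective temporal samples however long the series, so the sampling SD
#' of a voxel-pair correlation is about 0.12, and loadings that place
#' either group near the threshold produce large shared between-subject
#' swings in hub degree.
#'
#' @param n_networks number of latent network signals (>= 1).
#' @param hub_networks how many of the networks hub voxels couple to.
#' @param hub_loading baseline loading of hub voxels on each coupled
#'   network.
#' @param group_effect_delta additive hub-loading increase in patients;
#'   0 gives an exchangeable null cohort.
#' @param subject_loading_sd SD of the per-subject hub-loading jitter
#'   (gives patients individual "hub strength", the quantity clinical
#'   scores can be coupled to).
#' @param noise_sd white-noise SD (> 0).
#' @param drift_slope_sd SD of the per-voxel linear drift slope (signal
#'   units over the full scan).
#' @param band passband of the latent signals in Hz; the default matches
#'   the 0.01-0.08 Hz analysis band so the planted structure survives
#'   filtering.
#' @param hub_side edge length (voxels) of the central cubic hub when
#'   `hub_mask` is not supplied.
#' @param loading_map optional explicit voxel-by-network loading matrix
#'   (rows in mask scan order); `NULL` builds the octant assignment above.
#' @param hub_mask optional explicit logical 3D hub mask; must be a subset
#'   of the gray-matter mask.
#' @return A list of class `latent_network_model`.
#' @export
latent_network_model <- function(n_networks = 4L,
                                 hub_networks = 2L,
                                 hub_loading = 0.02,
                                 group_effect_delta = 0.9,
                                 subject_loading_sd = 0.05,
                                 noise_sd = 0.6,
                                 drift_slope_sd = 0.5,
                                 band = c(0.01, 0.08),
                                 hub_side = 4L,
                                 loading_map = NULL,
                                 hub_mask = NULL) {
  if (n_networks < 1) stop("`n_networks` must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (group_effect_delta < 0)
    stop("`group_effect_delta` must be >= 0", call. = FALSE)
  if (hub_networks < 1 || hub_networks > n_networks)
    stop("`hub_networks` must lie in [1, n_networks]", call. = FALSE)
  structure(list(n_networks = as.integer(n_networks),
                 hub_networks = as.integer(hub_networks),
                 hub_loading = hub_loading,
                 group_effect_delta = group_effect_delta,
                 subject_loading_sd = subject_loading_sd,
                 noise_sd = noise_sd, drift_slope_sd = drift_slope_sd,
                 band = band, hub_side = as.integer(hub_side),
                 loading_map = loading_map, hub_mask = hub_mask),
            class = "latent_network_model")
}

#' Synthetic cohort specification
#'
#' Describes a two-group resting-state cohort. The defaults mirror a
#' typical clinical rs-fMRI study design — 47 subjects per group, 240
#' volumes at TR 2 s — on a reduced 16^3 spatial grid suitable for
#' desk-scale simulation.
#'
#' @param n_per_group subjects per group.
#' @param grid_shape 3D grid dimensions (kept small; documented default
#'   <= 24^3).
#' @param n_timepoints volumes per subject (> 10, so dropping the first 10
#'   leaves a usable series).
#' @param tr_seconds repetition time.
#' @param rng_seed integer master seed; every output is a pure function of
#'   the spec.
#' @param model a [latent_network_model].
#' @param covariate_model phenotype distributions; see
#'   [default_covariate_model()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 47L,
                        grid_shape = c(16L, 16L, 16L),
                        n_timepoints = 240L,
                        tr_seconds = 2,
                        rng_seed = 1L,
                        model = latent_network_model(),
                        covariate_model = default_covariate_model()) {
  spec <- structure(list(n_per_group = as.integer(n_per_group),
                         grid_shape = as.integer(grid_shape),
                         n_timepoints = as.integer(n_timepoints),
                         tr_seconds = tr_seconds,
                         rng_seed = as.integer(rng_seed),
                         model = model, covariate_model = covariate_model),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 1)
    stop("configuration error in `n_per_group`: must be >= 1", call. = FALSE)
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 5))
    stop("configuration error in `grid_shape`: need 3 dimensions, each >= 5",
         call. = FALSE)
  if (any(spec$grid_shape > 24))
    stop("configuration error in `grid_shape`: grid above 24^3 is outside the supported desk-scale range",
         call. = FALSE)
  if (spec$n_timepoints <= 10)
    stop("configuration error in `n_timepoints`: must exceed 10 so that initial-volume dropping leaves a nonempty series",
         call. = FALSE)
  if (!inherits(spec$model, "latent_network_model"))
    stop("configuration error in `model`: not a latent_network_model",
         call. = FALSE)
  mask <- gm_mask_for(spec$grid_shape)
  hub <- spec$model$hub_mask
  if (!is.null(hub)) {
    if (!all(dim(hub) == spec$grid_shape))
      stop("configuration error in `model$hub_mask`: grid mismatch",
           call. = FALSE)
    if (any(hub & !mask))
      stop("configuration error in `model$hub_mask`: hub voxels fall outside the gray-matter mask",
           call. = FALSE)
  }
  invisible(spec)
}

#' Default phenotype distributions
#'
#' Truncated-normal clinical and demographic scores with means/SDs typical
#' of a young, predominantly female lupus cohort and matched controls
#' (approximately 1:4 male:female), plus optional linear coupling between a
#' patient's planted hub strength and the MoCA / SLEDAI scores.
#' `coupling` is the target correlation: a negative MoCA coupling makes
#' stronger-hub patients score lower.
#'
#' @param moca_coupling,sledai_coupling target correlation in `[-1, 1]`
#'   between the per-subject hub strength and the score (patients).
#' @return Nested list consumed by [sample_clinical_scores()].
#' @export
default_covariate_model <- function(moca_coupling = 0,
                                    sledai_coupling = 0) {
  list(
    age = list(patient = c(mean = 29.17, sd = 9.23),
               control = c(mean = 27.02, sd = 5.25),
               range = c(18, 60), coupling = 0),
    education = list(patient = c(mean = 12.32, sd = 2.62),
                     control = c(mean = 12.98, sd = 2.49),
                     range = c(6, 20), coupling = 0),
    sex = list(patient_male_prob = 9 / 47, control_male_prob = 11 / 47),
    SLEDAI = list(patient = c(mean = 13.23, sd = 7.12), control = NULL,
                  range = c(0, 40), coupling = sledai_coupling),
    MoCA = list(patient = c(mean = 26.72, sd = 1.25),
                control = c(mean = 28.49, sd = 1.14),
                range = c(0, 30), coupling = moca_coupling),
    BDI = list(patient = c(mean = 10.04, sd = 2.78),
               control = c(mean = 6.40, sd = 2.10),
               range = c(0, 63), coupling = 0)
  )
}

# Gray matter = grid interior (one-voxel non-brain border).
gm_mask_for <- function(grid_shape) {
  m <- array(FALSE, grid_shape)
  m[2:(grid_shape[1] - 1), 2:(grid_shape[2] - 1), 2:(grid_shape[3] - 1)] <- TRUE
  m
}

hub_mask_for <- function(spec) {
  if (!is.null(spec$model$hub_mask)) return(spec$model$hub_mask)
  g <- spec$grid_shape
  side <- spec$model$hub_side
  m <- array(FALSE, g)
  lo <- pmax(2L, floor((g - side) / 2) + 1L)
  hi <- pmin(g - 1L, lo + side - 1L)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# Each non-hub voxel loads 1 on the network of its spatial octant; hub
# voxels load `hub_loading` on the first `hub_networks` networks (patient
# hubs get + delta).
build_loading_map <- function(spec, mask, hub) {
  K <- spec$model$n_networks
  idx <- mask_indices(mask)
  if (!is.null(spec$model$loading_map)) {
    L <- spec$model$loading_map
    if (nrow(L) != length(idx) || ncol(L) != K)
      stop("configuration error in `model$loading_map`: expected ",
           length(idx), " x ", K, " matrix", call. = FALSE)
    return(L)
  }
  g <- spec$grid_shape
  co <- arrayInd(idx, g)
  ctr <- (g + 1) / 2
  octant <- (co[, 1] >= ctr[1]) + 2 * (co[, 2] >= ctr[2]) +
    4 * (co[, 3] >= ctr[3])
  net <- (octant %% K) + 1L
  L <- matrix(0, length(idx), K)
  L[cbind(seq_along(idx), net)] <- 1
  hub_rows <- which(hub[idx])
  L[hub_rows, ] <- 0
  L[hub_rows, seq_len(spec$model$hub_networks)] <- spec$model$hub_loading
  L
}

derive_seed <- function(rng_seed, counter, salt = 0L) {
  s <- (as.double(rng_seed) + 1000003 * counter + 97003 * salt) %% 2147483646
  as.integer(s) + 1L
}

cohort_affine <- function(grid_shape, voxel_mm = 3) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  aff
}

# Band-limited unit-variance latent signals (white noise -> zero-phase
# Butterworth band-pass -> column standardization).
latent_signals <- function(nt, K, tr, band) {
  S <- matrix(stats::rnorm(nt * K), nt, K)
  nyq <- 1 / (2 * tr)
  hi <- min(band[2], nyq * 0.99)
  filt <- signal::butter(5, c(band[1], hi) / nyq, type = "pass")
  S <- filtfilt_matrix(filt$b, filt$a, S)
  sweep(sweep(S, 2L, colMeans(S), "-"), 2L, apply(S, 2L, stats::sd), "/")
}

#' Generate a synthetic two-group cohort
#'
#' Simulates each subject's 4D series as
#' `loadings x latent network signals + linear drift + white noise`, with
#' patient hub voxels coupled more broadly per the model's
#' `group_effect_delta`. Subjects are ordered patients first, then
#' controls; subject `i` uses an RNG stream derived from
#' `rng_seed` and the subject counter, so any subject is reproducible
#' independently of cohort size.
#'
#' @param spec a [cohort_spec].
#' @return A list with elements `series` (list of [bold_series]),
#'   `phenotype` (data.frame, one row per subject), `mask` (gray-matter
#'   logical array), `hub_mask` (ground-truth hub voxels), `hub_strength`
#'   (per-subject realized hub loading) and `affine`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  g <- spec$grid_shape
  mask <- gm_mask_for(g)
  hub <- hub_mask_for(spec)
  L <- build_loading_map(spec, mask, hub)
  idx <- mask_indices(mask)
  hub_rows <- which(hub[idx])
  aff <- cohort_affine(g)
  n <- spec$n_per_group
  groups <- rep(c("patient", "control"), each = n)
  series <- vector("list", 2L * n)
  hub_strength <- numeric(2L * n)
  nt <- spec$n_timepoints
  mdl <- spec$model
  for (i in seq_len(2L * n)) {
    set.seed(derive_seed(spec$rng_seed, i))
    jit <- stats::rnorm(1, 0, mdl$subject_loading_sd)
    a_i <- mdl$hub_loading + mdl$group_effect_delta * (groups[i] == "patient") + jit
    hub_strength[i] <- a_i
    S <- latent_signals(nt, mdl$n_networks, spec$tr_seconds, mdl$band)
    Li <- L
    if (length(hub_rows)) {
      Li[hub_rows, ] <- 0
      Li[hub_rows, seq_len(mdl$hub_networks)] <- a_i
    }
    Y <- S %*% t(Li)
    slopes <- stats::rnorm(length(idx), 0, mdl$drift_slope_sd)
    tt <- seq(-1, 1, length.out = nt)
    Y <- Y + outer(tt, slopes)
    Y <- Y + matrix(stats::rnorm(nt * length(idx), 0, mdl$noise_sd),
                    nt, length(idx))
    arr <- matrix(0, prod(g), nt)
    arr[idx, ] <- t(Y)
    dim(arr) <- c(g, nt)
    series[[i]] <- bold_series(arr, aff, spec$tr_seconds)
  }
  phen <- sample_clinical_scores(spec, hub_strength = hub_strength)
  list(series = series, phenotype = phen, mask = mask, hub_mask = hub,
       hub_strength = hub_strength, affine = aff)
}

#' Sample phenotype and clinical score columns
#'
#' Truncated-normal scores per the spec's covariate model, with optional
#' linear coupling between a subject's planted hub strength and the MoCA /
#' SLEDAI scores (so correlation-recovery analyses have a ground truth).
#' A pure function of the spec: when `hub_strength` is omitted, the same
#' per-subject streams used by [generate_cohort()] are replayed.
#'
#' @param spec a [cohort_spec].
#' @param hub_strength optional per-subject realized hub loadings (as
#'   returned by [generate_cohort()]).
#' @return data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `education`, `SLEDAI`, `MoCA`, `BDI`, `include_flag`.
#' @export
sample_clinical_scores <- function(spec, hub_strength = NULL) {
  validate_cohort_spec(spec)
  n <- spec$n_per_group
  groups <- rep(c("patient", "control"), each = n)
  mdl <- spec$model
  if (is.null(hub_strength)) {
    hub_strength <- vapply(seq_len(2L * n), function(i) {
      set.seed(derive_seed(spec$rng_seed, i))
      mdl$hub_loading + stats::rnorm(1, 0, mdl$subject_loading_sd) +
        mdl$group_effect_delta * (groups[i] == "patient")
    }, numeric(1))
  }
  cm <- spec$covariate_model
  # standardized hub strength (exact model moments, so coupling is the
  # target correlation regardless of sample size)
  zhub <- if (mdl$subject_loading_sd > 0) {
    (hub_strength - mdl$hub_loading -
       mdl$group_effect_delta * (groups == "patient")) /
      mdl$subject_loading_sd
  } else {
    rep(0, length(hub_strength))
  }
  draw <- function(i, var) {
    par <- cm[[var]][[groups[i]]]
    if (is.null(par)) return(NA_real_)
    rng <- cm[[var]]$range
    cpl <- cm[[var]]$coupling %||% 0
    if (groups[i] != "patient") cpl <- 0
    for (try in 1:200) {
      eps <- stats::rnorm(1)
      x <- par["mean"] + par["sd"] * (cpl * zhub[i] + sqrt(1 - cpl^2) * eps)
      if (x >= rng[1] && x <= rng[2]) return(unname(x))
    }
    unname(min(max(x, rng[1]), rng[2]))
  }
  out <- lapply(seq_len(2L * n), function(i) {
    set.seed(derive_seed(spec$rng_seed, i, salt = 1L))
    male_p <- if (groups[i] == "patient") cm$sex$patient_male_prob
              else cm$sex$control_male_prob
    data.frame(
      subject_id = sprintf("sub%03d", i),
      group = groups[i],
      age = draw(i, "age"),
      sex = if (stats::runif(1) < male_p) "M" else "F",
      education = draw(i, "education"),
      SLEDAI = draw(i, "SLEDAI"),
      MoCA = draw(i, "MoCA"),
      BDI = draw(i, "BDI"),
      include_flag = TRUE,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a generated cohort to disk
#'
#' Per-subject 4D NIfTI files, the gray-matter and ground-truth hub masks,
#' a tab-separated phenotype table (with `image_path` filled in), and a
#' JSON sidecar recording the full cohort specification.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param spec the [cohort_spec] used (recorded in the sidecar).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phen <- cohort$phenotype
  paths <- character(nrow(phen))
  for (i in seq_len(nrow(phen))) {
    paths[i] <- file.path(dir, sprintf("%s_bold.nii.gz", phen$subject_id[i]))
    write_volume(cohort$series[[i]], paths[i])
  }
  phen$image_path <- paths
  write_volume(cohort$mask * 1, file.path(dir, "gm_mask.nii.gz"),
               affine = cohort$affine)
  write_volume(cohort$hub_mask * 1, file.path(dir, "hub_truth.nii.gz"),
               affine = cohort$affine)
  write_phenotype(phen, file.path(dir, "phenotype.tsv"))
  if (!is.null(spec)) {
    ser <- unclass(spec)
    ser$model <- unclass(ser$model)
    jsonlite::write_json(ser, file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(dir)
}
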