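small_spec <- function(...) {
  cohort_spec(n_per_group = 3, grid_shape = c(8, 8, 8), n_timepoints = 30,
              rng_seed = 4, ...)
}

test_that("cohort generation is a pure function of the spec", {
  co1 <- generate_cohort(small_spec())
  co2 <- generate_cohort(small_spec())
  expect_identical(co1$series[[1]]$data, co2$series[[1]]$data)
  expect_identical(co1$series[[6]]$data, co2$series[[6]]$data)
  expect_identical(co1$phenotype, co2$phenotype)
  expect_identical(co1$hub_strength, co2$hub_strength)
  # a different seed changes the data
  co3 <- generate_cohort(cohort_spec(n_per_group = 3, grid_shape = c(8, 8, 8),
                                     n_timepoints = 30, rng_seed = 5))
  expect_false(identical(co1$series[[1]]$data, co3$series[[1]]$data))
  # subject streams are independent of cohort size: subject 1 is identical
  # in a cohort with more subjects per group... for the imaging data the
  # patient block matches; controls shift position, so compare patient 1
  co4 <- generate_cohort(cohort_spec(n_per_group = 4, grid_shape = c(8, 8, 8),
                                     n_timepoints = 30, rng_seed = 4))
  expect_identical(co1$series[[1]]$data, co4$series[[1]]$data)
})

test_that("structural invariants hold: masks nest and groups label correctly", {
  co <- generate_cohort(small_spec())
  expect_true(all(co$hub_mask[co$hub_mask] & co$mask[co$hub_mask]))
  expect_false(any(co$hub_mask & !co$mask))
  expect_equal(co$phenotype$group, rep(c("patient", "control"), each = 3))
  expect_equal(nrow(co$phenotype), length(co$series))
  expect_true(all(!is.na(co$phenotype$SLEDAI[1:3])))
  expect_true(all(is.na(co$phenotype$SLEDAI[4:6])))   # controls unscored
  expect_true(all(co$phenotype$MoCA <= 30))
})

test_that("a noiseless single-factor cohort correlates at r = 1 everywhere", {
  g <- c(6, 6, 6)
  mask <- netdc:::gm_mask_for(g)
  nv <- sum(mask)
  spec <- cohort_spec(
    n_per_group = 1, grid_shape = g, n_timepoints = 40, rng_seed = 2,
    model = latent_network_model(n_networks = 1, hub_networks = 1,
                                 noise_sd = 1e-8, drift_slope_sd = 0,
                                 subject_loading_sd = 0,
                                 group_effect_delta = 0,
                                 loading_map = matrix(1, nv, 1),
                                 hub_mask = array(FALSE, g)))
  co <- generate_cohort(spec)
  dc <- degree_centrality(co$series[[1]], co$mask)
  expect_true(all(dc$data[co$mask] == nv - 1))
})

test_that("invalid specs fail with errors naming the offending field", {
  expect_error(cohort_spec(n_timepoints = 10), "n_timepoints")
  expect_error(cohort_spec(grid_shape = c(30, 30, 30)), "grid_shape")
  bad_hub <- array(TRUE, c(8, 8, 8))                  # touches the border
  expect_error(
    cohort_spec(grid_shape = c(8, 8, 8),
                model = latent_network_model(hub_mask = bad_hub)),
    "hub_mask")
  expect_error(latent_network_model(noise_sd = 0), "noise_sd")
  expect_error(latent_network_model(n_networks = 0), "n_networks")
  expect_error(latent_network_model(hub_networks = 9), "hub_networks")
})

test_that("the planted hub degree difference grows with the group effect", {
  deltas <- c(0, 0.25, 0.9)
  gaps <- vapply(deltas, function(d) {
    spec <- cohort_spec(n_per_group = 5, grid_shape = c(10, 10, 10),
                        n_timepoints = 100, rng_seed = 31,
                        model = latent_network_model(group_effect_delta = d))
    co <- generate_cohort(spec)
    hub_dc <- vapply(co$series, function(s) {
      p <- preprocess_bold(s, n_drop = 5)
      mean(degree_centrality(p, co$mask)$data[co$hub_mask])
    }, numeric(1))
    mean(hub_dc[1:5]) - mean(hub_dc[6:10])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[3], 100)                             # strong effect is large
})

test_that("clinical scores replay identically from the spec alone", {
  spec <- small_spec()
  co <- generate_cohort(spec)
  ph2 <- sample_clinical_scores(spec)
  expect_identical(co$phenotype, ph2)
})

test_that("written cohorts round-trip through NIfTI and TSV", {
  dir <- file.path(tempdir(), "cohort_rt")
  spec <- small_spec()
  co <- generate_cohort(spec)
  write_cohort(co, dir, spec = spec)
  phen <- read_phenotype(file.path(dir, "phenotype.tsv"))
  expect_equal(nrow(phen), 6)
  expect_true(all(file.exists(phen$image_path)))
  s1 <- read_volume(phen$image_path[1])
  expect_lt(max(abs(s1$data - co$series[[1]]$data)), 1e-6)
  mk <- read_mask(file.path(dir, "gm_mask.nii.gz"))
  expect_identical(mk$mask, co$mask)
  sidecar <- jsonlite::read_json(file.path(dir, "cohort_spec.json"),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$n_per_group, 3)
  expect_equal(sidecar$model$group_effect_delta,
               spec$model$group_effect_delta)
  unlink(dir, recursive = TRUE)
})
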