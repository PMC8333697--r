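make_maps <- function(Y, mask) {
  lapply(seq_len(nrow(Y)), function(i) map_from_values(Y[i, ], mask))
}

test_that("voxelwise GLM reduces to the pooled two-sample t without covariates", {
  set.seed(12)
  mask <- mask_first_n(c(5, 1, 1), 5)
  Y <- matrix(rnorm(12 * 5), 12, 5)
  grp <- rep(c("patient", "control"), each = 6)
  des <- cbind(intercept = 1, group = as.numeric(grp == "patient"))
  attr(des, "group_col") <- 2L
  fit <- voxelwise_glm_ttest(make_maps(Y, mask), des, mask)
  expect_equal(fit$df, 10)
  for (v in 1:5) {
    tt <- stats::t.test(Y[1:6, v], Y[7:12, v], var.equal = TRUE)
    expect_equal(fit$t_map$data[v, 1, 1], unname(tt$statistic),
                 tolerance = 1e-10)
  }
  # identical maps in both groups give t = 0 everywhere
  Yc <- matrix(rep(rnorm(5), each = 12), 12, 5)
  fit0 <- voxelwise_glm_ttest(make_maps(Yc, mask), des, mask)
  expect_equal(fit0$t_map$data[mask], rep(0, 5))
  # intercept absorbs a constant shift of every subject map
  fit_sh <- voxelwise_glm_ttest(make_maps(Y + 100, mask), des, mask)
  expect_equal(fit_sh$t_map$data[mask], fit$t_map$data[mask],
               tolerance = 1e-8)
})

test_that("covariates adjust the group contrast and collinearity errors out", {
  set.seed(13)
  mask <- mask_first_n(c(4, 1, 1), 4)
  n <- 16
  grp <- rep(c(1, 0), each = n / 2)
  age <- rnorm(n, 30, 6)
  Y <- outer(age, rnorm(4)) + matrix(rnorm(n * 4), n, 4)
  des <- cbind(intercept = 1, group = grp, age = age)
  attr(des, "group_col") <- 2L
  fit <- voxelwise_glm_ttest(make_maps(Y, mask), des, mask)
  expect_equal(fit$df, n - 3)
  for (v in 1:4) {                                   # lm oracle
    sm <- summary(stats::lm(Y[, v] ~ grp + age))
    expect_equal(fit$t_map$data[v, 1, 1], sm$coefficients["grp", "t value"],
                 tolerance = 1e-8)
  }
  des_bad <- cbind(intercept = 1, group = grp, twice_group = 2 * grp)
  attr(des_bad, "group_col") <- 2L
  expect_error(voxelwise_glm_ttest(make_maps(Y, mask), des_bad, mask),
               "rank deficient")
  phen <- data.frame(subject_id = sprintf("s%02d", 1:4),
                     group = rep(c("patient", "control"), 2),
                     age = c(20, 30, 40, 50), sex = c("F", "M", "F", "F"),
                     education = c(10, 12, 14, 16))
  X <- build_design(phen)
  expect_equal(colnames(X), c("intercept", "group", "age", "sex", "education"))
  expect_equal(X[, "group"], c(1, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(X[, "sex"], c(0, 1, 0, 0), ignore_attr = TRUE)
})

test_that("cluster formation splits by sign and honors connectivity", {
  mask <- array(TRUE, c(5, 5, 3))
  tarr <- array(0, c(5, 5, 3))
  # two L-shaped blobs touching only diagonally (within plane z = 1)
  blob1 <- rbind(c(1, 1), c(2, 1), c(2, 2))
  blob2 <- rbind(c(3, 3), c(3, 4), c(4, 4))
  for (p in seq_len(nrow(blob1))) tarr[blob1[p, 1], blob1[p, 2], 1] <- 10
  for (p in seq_len(nrow(blob2))) tarr[blob2[p, 1], blob2[p, 2], 1] <- 10
  tmap <- volume_map(tarr, toy_affine(), "t_stat")
  cl6 <- form_clusters(tmap, df = 20, voxel_p = 0.001, connectivity = 6,
                       mask = mask)
  cl26 <- form_clusters(tmap, df = 20, voxel_p = 0.001, connectivity = 26,
                        mask = mask)
  expect_equal(length(cl6$extent), 2)
  expect_equal(cl6$extent, c(3, 3))
  expect_equal(length(cl26$extent), 1)
  expect_equal(cl26$extent, 6)

  # all-zero map: no clusters; single supra voxel: one cluster of extent 1
  zero <- volume_map(array(0, c(4, 4, 4)), toy_affine(), "t_stat")
  expect_equal(length(form_clusters(zero, 20, mask = array(TRUE, c(4, 4, 4)))$extent), 0)
  one <- array(0, c(4, 4, 4)); one[2, 3, 2] <- -9
  cl1 <- form_clusters(volume_map(one, toy_affine(), "t_stat"), 20,
                       mask = array(TRUE, c(4, 4, 4)))
  expect_equal(cl1$extent, 1)
  expect_equal(cl1$sign, -1L)

  # labels are sorted by descending extent
  mixed <- array(0, c(6, 1, 1)); mixed[1:2] <- 8; mixed[4:6] <- -8
  clm <- form_clusters(volume_map(mixed, toy_affine(), "t_stat"), 15,
                       mask = array(TRUE, c(6, 1, 1)), connectivity = 6)
  expect_equal(clm$extent, c(3, 2))
  expect_equal(clm$sign, c(-1L, 1L))
})

test_that("peak coordinates map the max-|t| voxel through the affine", {
  mask <- array(TRUE, c(4, 4, 4))
  tarr <- array(0, c(4, 4, 4))
  tarr[2, 3, 4] <- 7; tarr[3, 3, 4] <- 6.5
  tmap <- volume_map(tarr, toy_affine(), "t_stat")
  cl <- form_clusters(tmap, 20, mask = mask)
  pk <- peak_world_coordinates(cl, tmap, toy_affine())
  expect_equal(pk$peak_t, 7)
  expect_equal(pk$world[1, ], c(1, 2, 3))            # identity affine, 0-based
  aff <- toy_affine(3, origin = c(-6, -6, -6))
  pk2 <- peak_world_coordinates(cl, tmap, aff)
  expect_equal(pk2$world[1, ], c(-3, 0, 3))
  # tie on |t| resolves to the smaller linear index
  tarr[3, 3, 4] <- -7
  tmap2 <- volume_map(tarr, toy_affine(), "t_stat")
  cl2 <- form_clusters(tmap2, 20, mask = mask)
  # two clusters now (opposite signs); both peaks deterministic
  pkt <- peak_world_coordinates(cl2, tmap2, toy_affine())
  expect_equal(sort(pkt$peak_t), c(-7, 7))
})

test_that("permutation cluster FDR behaves sanely and BH is monotone", {
  set.seed(77)
  mask <- mask_first_n(c(6, 6, 1), 36)
  n <- 12
  grp <- rep(c("patient", "control"), each = n / 2)
  des <- cbind(intercept = 1, group = as.numeric(grp == "patient"))
  attr(des, "group_col") <- 2L
  # plant a strong blob in patients
  Y <- matrix(rnorm(n * 36, sd = 0.2), n, 36)
  Y[grp == "patient", 1:6] <- Y[grp == "patient", 1:6] + 5
  maps <- make_maps(Y, mask)
  fit <- voxelwise_glm_ttest(maps, des, mask)
  cl <- form_clusters(fit$t_map, fit$df, voxel_p = 0.01, mask = mask)
  expect_gte(length(cl$extent), 1)
  rep_ <- cluster_fdr(maps, des, cl, mask, n_permutations = 99, rng_seed = 4)
  expect_true(all(rep_$p_fdr >= rep_$p_perm - 1e-12))
  expect_true(all(rep_$p_perm >= 1 / 100))
  expect_true(rep_$significant[1])
  expect_equal(order(rep_$p_fdr), order(rep_$p_perm))  # BH keeps the order
  expect_error(cluster_fdr(maps, des, cl, mask, n_permutations = 0),
               "impossible")
  # no clusters -> empty report, not an error
  cl0 <- form_clusters(volume_map(array(0, dim(mask)), toy_affine(),
                                  "t_stat"), fit$df, mask = mask)
  rep0 <- cluster_fdr(maps, des, cl0, mask, n_permutations = 10)
  expect_equal(nrow(rep0), 0)
})

test_that("summary tests agree with classical pooled-t and Yates chi-square", {
  tt <- two_sample_t_summary(29.17, 9.23, 47, 27.02, 5.25, 47)
  expect_equal(round(tt$t, 2), 1.39)
  expect_equal(round(tt$p, 2), 0.17)
  expect_equal(tt$df, 92)
  same <- two_sample_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(40)
  phen <- data.frame(
    subject_id = sprintf("s%03d", 1:94),
    group = rep(c("patient", "control"), each = 47),
    age = c(rnorm(47, 29, 9), rnorm(47, 27, 5)),
    sex = c(rep(c("M", "F"), c(9, 38)), rep(c("M", "F"), c(11, 36))),
    stringsAsFactors = FALSE)
  res <- summary_stat_tests(phen, variables = "age")
  expect_equal(round(res$sex$p, 2), 0.80)
  # the continuous row agrees with t.test's pooled variant on the raw data
  tt2 <- stats::t.test(age ~ factor(group, c("patient", "control")),
                       data = phen, var.equal = TRUE)
  expect_equal(res$continuous$t, unname(tt2$statistic), tolerance = 1e-10)
  expect_equal(res$continuous$p, tt2$p.value, tolerance = 1e-10)
})
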