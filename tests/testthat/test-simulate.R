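test_that("invalid configuration fields are named in errors", {
  expect_error(sim_config(n_reference = 0), "n_reference")
  expect_error(sim_config(age_range = c(90, 40)), "age_range")
  expect_error(sim_config(kurt_delta = -1), "kurt_delta")
  expect_error(sim_config(site_effect_sd = -0.1), "site_effect_sd")
  expect_error(group_spec(n = 1, burden = 2, effect = -1), "n")
  expect_error(group_spec(n = 10, burden = 2, effect = -1, heterogeneity = 2),
               "heterogeneity")
})

test_that("identical seed and config give byte-identical cohorts", {
  cfg <- sim_config(n_reference = 80, index = region_index()[1:5, ], seed = 9,
                    group_specs = list(g = group_spec(n = 6, burden = 2, effect = -2)),
                    clinical_sites = c(clin_a = 12L))
  a <- generate_reference_cohort(cfg)
  b <- generate_reference_cohort(cfg)
  expect_identical(a, b)
  ca <- generate_clinical_cohort(cfg, a$truth)
  cb <- generate_clinical_cohort(cfg, b$truth)
  expect_identical(ca, cb)
})

test_that("identity warp yields Gaussian residuals; skewed warp matches a Monte-Carlo oracle", {
  cfg <- flat_config(n = 5000, regions = 3, eps = 0, delta = 1, seed = 3)
  ref <- generate_reference_cohort(cfg)
  res <- std_residuals(ref$cohort, ref$truth)
  for (j in 1:3) expect_lt(abs(skewness(res[, j])), 0.1)

  # one region with eps = 0.5: skewness vs 1e6 draws through the same
  # inverse transform, written out independently here
  cfg2 <- flat_config(n = 5000, regions = 1, eps = 0.5, delta = 1, seed = 4)
  ref2 <- generate_reference_cohort(cfg2)
  emp <- skewness(std_residuals(ref2$cohort, ref2$truth)[, 1])
  set.seed(99)
  oracle <- skewness(sinh((asinh(rnorm(1e6)) + 0.5) / 1))
  expect_lt(abs(emp - oracle), 0.1)
})

test_that("ages stay in range and sexes are balanced per site", {
  cfg <- sim_config(n_reference = 400, n_sites = 4, age_range = c(45, 80),
                    index = region_index()[1:2, ], seed = 5)
  ref <- generate_reference_cohort(cfg)
  expect_true(all(ref$cohort$age >= 45 & ref$cohort$age <= 80))
  tab <- table(ref$cohort$site, ref$cohort$sex)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
})

test_that("injected atrophy matches the closed-form normal-tail count oracle", {
  # identity warp, flat trajectory: the standardized residual IS the true
  # z-score, so expected count = k*pnorm(-1.96 + 3) + (R - k)*pnorm(-1.96)
  R <- 40; k <- 5
  idx <- region_index()[seq_len(R), ]
  cfg <- sim_config(n_reference = 10, skew_eps = 0, kurt_delta = 1,
                    sex_effect = 0, site_effect_sd = 0, n_sites = 1,
                    trajectory_coeffs = matrix(0, R, 3), index = idx,
                    group_specs = list(
                      atro = group_spec(n = 400, burden = k, effect = -3,
                                        heterogeneity = 0)),
                    clinical_sites = c(clin_a = 10L), seed = 21)
  ref <- generate_reference_cohort(cfg)
  clin <- generate_clinical_cohort(cfg, ref$truth)
  pat <- clin$cohort[clin$cohort$group == "atro", ]
  z_true <- std_residuals(pat, clin$truth)
  counts <- rowSums(z_true < -1.96)
  expected <- k * pnorm(-1.96 + 3) + (R - k) * pnorm(-1.96)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05)
})

test_that("zero heterogeneity gives identical affected sets", {
  cfg <- flat_config(n = 10, regions = 30, seed = 8,
                     groups = list(g = group_spec(n = 12, burden = 6,
                                                  effect = -6,
                                                  heterogeneity = 0)),
                     clinical_sites = c(clin_a = 10L))
  cfg$index <- region_index()[1:30, ]
  ref <- generate_reference_cohort(cfg)
  clin <- generate_clinical_cohort(cfg, ref$truth)
  aff <- clin$truth$affected[clin$cohort$group == "g"]
  for (a in aff) expect_setequal(a, aff[[1]])
  # with a -6 SD effect the affected regions are outliers for everyone, so
  # they contribute nothing to within-group Hamming distance
  pat <- clin$cohort[clin$cohort$group == "g", ]
  z_true <- std_residuals(pat, clin$truth)
  o <- (z_true < -1.96)
  cols <- match(aff[[1]], colnames(z_true))
  expect_true(all(o[, cols]))
})

test_that("mean outlier count is monotone in effect size and burden", {
  mk <- function(effect, burden) {
    cfg <- flat_config(n = 10, regions = 30, seed = 13,
                       groups = list(g = group_spec(n = 150, burden = burden,
                                                    effect = effect,
                                                    heterogeneity = 0.5)),
                       clinical_sites = c(clin_a = 10L))
    ref <- generate_reference_cohort(cfg)
    clin <- generate_clinical_cohort(cfg, ref$truth)
    pat <- clin$cohort[clin$cohort$group == "g", ]
    mean(rowSums(std_residuals(pat, clin$truth) < -1.96))
  }
  by_effect <- c(mk(0, 6), mk(-1.5, 6), mk(-3, 6))
  expect_true(all(diff(by_effect) > 0))
  by_burden <- c(mk(-2.5, 2), mk(-2.5, 8), mk(-2.5, 16))
  expect_true(all(diff(by_burden) > 0))
})

test_that("clinical scores load on true burden with group-specific loadings", {
  cfg <- flat_config(n = 10, regions = 30, seed = 17,
                     groups = list(
                       vp = group_spec(n = 150, burden = 8, effect = -2.5,
                                       heterogeneity = 1,
                                       loadings = c(visuoperception = 0.3)),
                       cog = group_spec(n = 150, burden = 8, effect = -2.5,
                                        heterogeneity = 1,
                                        loadings = c(cognitive = 0.1))),
                     clinical_sites = c(clin_a = 10L))
  ref <- generate_reference_cohort(cfg)
  clin <- generate_clinical_cohort(cfg, ref$truth)
  co <- clin$cohort; b <- clin$truth$burden
  vp <- co$group == "vp"
  expect_lt(cor(co$visuoperception[vp], b[vp]), -0.5)
  cg <- co$group == "cog"
  expect_lt(cor(co$cog_memory[cg], b[cg]), -0.3)
  expect_gt(cor(co$visuoperception[cg], b[cg]), -0.3)
})

test_that("unknown clinical site in a group spec is a configuration error", {
  cfg <- flat_config(n = 10, regions = 2, seed = 1,
                     groups = list(g = group_spec(n = 5, burden = 1,
                                                  effect = -1,
                                                  sites = "nowhere")),
                     clinical_sites = c(clin_a = 10L))
  ref <- generate_reference_cohort(cfg)
  expect_error(generate_clinical_cohort(cfg, ref$truth), "nowhere")
})
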