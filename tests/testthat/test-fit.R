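test_that("identity-warp marginal likelihood matches the closed-form evidence", {
  # 5-point toy problem, direct matrix evaluation as the oracle
  set.seed(1)
  X <- cbind(1, c(-2, -1, 0, 1, 2), runif(5))
  ys <- c(0.3, -0.5, 0.1, 0.9, -1.2)
  for (ab in list(c(1, 1), c(0.3, 4), c(10, 0.2))) {
    expect_equal(warped_blr_evidence(ys, X, ab[1], ab[2], eps = 0, delta = 1),
                 as.numeric(gauss_blr_evidence(ys, X, ab[1], ab[2])),
                 tolerance = 1e-8)
  }
})

test_that("warped evidence equals Gaussian evidence of warped data plus log-Jacobian", {
  set.seed(2)
  X <- cbind(1, rnorm(8))
  ys <- rnorm(8)
  eps <- 0.4; delta <- 1.3
  direct <- as.numeric(gauss_blr_evidence(warp(ys, eps, delta), X, 2, 1.5)) +
    sum(log(warp_deriv(ys, eps, delta)))
  expect_equal(warped_blr_evidence(ys, X, 2, 1.5, eps, delta), direct,
               tolerance = 1e-8)
})

test_that("fit recovers trajectory, sex effect and identity warp on clean data", {
  cfg <- sim_config(n_reference = 1500, n_sites = 1, site_effect_sd = 0,
                    sex_effect = 0.4, skew_eps = 0, kurt_delta = 1,
                    trajectory_coeffs = matrix(c(-0.6, -0.2, 0), 1, 3),
                    index = region_index()[1, , drop = FALSE], seed = 31)
  ref <- generate_reference_cohort(cfg)
  rc <- ref$cohort
  reg <- region_names()[1]
  m <- fit_region_model(rc[[reg]], rc$age, rc$sex, rc$site, region = reg)
  expect_lt(abs(m$eps), 0.1)
  expect_lt(abs(m$delta - 1), 0.15)
  # sex weight within 2 posterior SE of the standardized truth
  j <- match("sex", m$col_names)
  truth_std <- 0.4 * ref$truth$region_params$scale[1] / m$y_scale
  se <- sqrt(m$A_inv[j, j])
  expect_lt(abs(m$weights[j] - truth_std), 2 * se)
  # fitted age trajectory tracks the generative curve (0.1 residual SD)
  ages <- seq(45, 85, by = 5)
  Xp <- normdev:::.predict_design(m, ages, rep(0, length(ages)))
  fitted_std <- (drop(Xp %*% m$weights) * m$y_scale + m$y_shift -
                   ref$truth$region_params$mu[1]) /
    ref$truth$region_params$scale[1]
  u <- (ages - 65) / 25
  truth_traj <- -0.6 * u - 0.2 * u^2
  expect_lt(max(abs(fitted_std - truth_traj)), 0.12)
})

test_that("skew recovery: injected warp eps is estimated on flat data", {
  cfg <- flat_config(n = 2000, regions = 1, eps = 0.5, delta = 1.1, seed = 41)
  ref <- generate_reference_cohort(cfg)
  rc <- ref$cohort
  reg <- region_names()[1]
  m <- fit_region_model(rc[[reg]], rc$age, rc$sex, rc$site, region = reg)
  expect_lt(abs(m$eps - 0.5), 0.15)
})

test_that("duplicating every observation leaves the fitted mean unchanged", {
  cfg <- flat_config(n = 120, regions = 1, seed = 51)
  ref <- generate_reference_cohort(cfg)
  rc <- ref$cohort
  reg <- region_names()[1]
  m1 <- fit_region_model(rc[[reg]], rc$age, rc$sex, rc$site,
                         warp_type = "identity", region = reg)
  i2 <- rep(seq_len(nrow(rc)), 2)
  m2 <- fit_region_model(rc[[reg]][i2], rc$age[i2], rc$sex[i2], rc$site[i2],
                         spec = m1$basis, warp_type = "identity", region = reg)
  ages <- seq(45, 85, by = 5)
  f1 <- drop(normdev:::.predict_design(m1, ages, rep(0, 9)) %*% m1$weights)
  f2 <- drop(normdev:::.predict_design(m2, ages, rep(0, 9)) %*% m2$weights)
  expect_equal(f1, f2, tolerance = 0.02)
})

test_that("fitting contracts: sample size, finiteness, degenerate input", {
  expect_error(fit_region_model(rnorm(10), runif(10, 40, 90),
                                rep(0:1, 5), rep("a", 10), region = "r1"),
               "fitting error")
  y <- rnorm(60); y[7] <- NA
  expect_error(fit_region_model(y, runif(60, 40, 90), rep(0:1, 30),
                                rep(c("a", "b"), 30), region = "lh_G_cuneus"),
               "lh_G_cuneus.*7")
  expect_error(fit_region_model(rnorm(60), rep(50, 60), rep(0:1, 30),
                                rep("a", 60), region = "r1"),
               "constant")
  expect_error(fit_region_model(rnorm(60), runif(60, 40, 90), rep(0:1, 30),
                                c(rep("a", 59), "b"), region = "r1"),
               ">= 2 controls")
})

test_that("model JSON round-trip reproduces z-scores exactly", {
  cfg <- flat_config(n = 150, regions = 3, n_sites = 2, site_effect_sd = 0.2,
                     seed = 61)
  ref <- generate_reference_cohort(cfg)
  m <- fit_normative_model(ref$cohort, index = cfg$index, min_controls = 50)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  newdata <- ref$cohort[1:20, ]
  expect_equal(predict_zscores(m2, newdata)$z,
               predict_zscores(m, newdata)$z, tolerance = 1e-12)
})
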