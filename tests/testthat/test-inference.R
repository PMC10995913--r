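test_that("adjusted regression matches a closed-form OLS oracle", {
  # mutually orthogonal centred columns: beta = cov(y, x) / var(x)
  x <- c(-1, -1, -1, 1, 1, 1)
  age <- c(-1, 0, 1, -1, 0, 1)
  sex <- c(0.5, -1, 0.5, 0.5, -1, 0.5)
  stopifnot(sum(x * age) == 0, sum(x * sex) == 0, sum(age * sex) == 0)
  y <- c(2.1, 1.3, 0.8, 3.0, 2.4, 3.3)
  r <- adjusted_regression(y, x, age, sex)
  expect_equal(r$beta, sum((y - mean(y)) * x) / sum(x^2), tolerance = 1e-12)
  # full normal-equation solve as a second, independent route
  X <- cbind(1, x, age, sex)
  beta_ne <- solve(crossprod(X), crossprod(X, y))
  expect_equal(r$beta, beta_ne[2], tolerance = 1e-12)
  expect_equal(r$n, 6L)
})

test_that("regression type-I error is close to nominal under the null", {
  set.seed(77)
  rejections <- 0L
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    g <- rep(0:1, each = 250)
    age <- runif(500, 50, 80)
    sex <- rep_len(0:1, 500)
    y <- rnorm(500) + 0.02 * age
    if (adjusted_regression(y, g, age, sex)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.03)
  expect_lt(rejections / n_rep, 0.07)
})

test_that("regression errors: constant predictor, collinearity, tiny n", {
  expect_error(adjusted_regression(rnorm(20), rep(1, 20), runif(20),
                                   rep_len(0:1, 20)), "constant")
  age <- runif(20, 40, 80)
  expect_error(adjusted_regression(rnorm(20), age, age, rep_len(0:1, 20)),
               "singularity|collinear")
  expect_error(adjusted_regression(rnorm(3), rnorm(3), rnorm(3), c(0, 1, 0)),
               "too few")
})

test_that("Mann-Whitney: U convention and exact p for the printed example", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$W, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration for sizes <= 6", {
  set.seed(101)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2) + 0.5
    r <- mann_whitney(x, y)
    or <- mw_enumeration(x, y)
    expect_equal(r$W, or$U)
    expect_equal(r$p, or$p, tolerance = 1e-12)
    expect_gte(r$W, 0); expect_lte(r$W, n1 * n2)
  }
})

test_that("identical tied samples give U = n^2/2 and p near 1", {
  x <- c(1, 1, 2, 2, 3)
  r <- mann_whitney(x, x)
  expect_equal(r$W, length(x)^2 / 2)
  expect_gt(r$p, 0.9)
  expect_false(r$exact)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(55)
  ps <- replicate(1000, mann_whitney(rnorm(30), rnorm(30))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH q-values match the hand step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 6)), rep(1, 6))
  set.seed(123)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^2
    q <- fdr_adjust(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p order
  }
  expect_error(fdr_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("composite cognitive score standardizes against control norms", {
  means <- c(a = 10, b = 20, c = 5)
  sds <- c(a = 2, b = 5, c = 1)
  s <- rbind(c(10, 20, 5),      # at control means -> 0
             c(12, 15, 5),      # z = {+1, -1, 0} -> 0
             c(12, 25, 6))      # all +1 SD -> 1
  colnames(s) <- c("a", "b", "c")
  expect_equal(composite_cognitive_score(s, means, sds), c(0, 0, 1))
  s_na <- rbind(c(12, NA, NA), c(NA, NA, NA))
  colnames(s_na) <- c("a", "b", "c")
  comp <- composite_cognitive_score(s_na, means, sds)
  expect_equal(comp[1], 1)
  expect_true(is.na(comp[2]))
  expect_error(composite_cognitive_score(s, means, c(a = 2, b = 0, c = 1)),
               "> 0")
  expect_error(composite_cognitive_score(s[, 1:2], means[1], sds[1]), "missing")
})

test_that("extreme-count flagging reproduces the far-outlier rule", {
  # right-skewed counts spanning 0-24 (as group-level count distributions
  # are) plus one participant at 45: only the latter is flagged
  counts <- c(rep(1, 6), rep(2, 8), rep(3, 6), rep(4, 4), rep(6, 4),
              rep(8, 6), 10, 12, 15, 20, 24, 45)
  ids <- paste0("p", seq_along(counts))
  expect_equal(flag_extreme_participants(counts, ids = ids),
               ids[counts == 45])
  expect_length(flag_extreme_participants(rep(4, 30)), 0)
  # brute-force quartile oracle on random instances
  set.seed(31)
  for (i in 1:10) {
    x <- rpois(40, 5) + c(rep(0, 38), 30, 50)
    ids <- as.character(seq_along(x))
    q1 <- quantile(x, 0.25, names = FALSE); q3 <- quantile(x, 0.75, names = FALSE)
    expect_setequal(flag_extreme_participants(x, ids = ids),
                    ids[x > q3 + 3 * (q3 - q1)])
  }
  # per-group flagging keeps groups separate: 20 is extreme among the "a"
  # counts but unremarkable on the pooled scale of "b"
  counts <- c(rep(2, 10), 20, 26:35, 40)
  grp <- rep(c("a", "b"), c(11, 11))
  ids <- paste0("p", 1:22)
  expect_equal(flag_extreme_participants(counts, grp, ids), "p11")
})
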