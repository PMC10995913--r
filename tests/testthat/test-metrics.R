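test_that("binarization uses a strict lower-tail cut", {
  z <- matrix(c(-2.50, -1.96, -1.00, 0.30, -3.10), 1)
  o <- binarize_outliers(z, threshold = -1.96)
  expect_equal(unname(o$o[1, ]), c(1L, 0L, 0L, 0L, 1L))  # boundary excluded
  expect_equal(unname(binarize_outliers(matrix(0, 2, 5))$o),
               matrix(0L, 2, 5))
  expect_error(binarize_outliers(z, threshold = 1.96), "negative")
  expect_error(binarize_outliers(z, threshold = 0), "negative")
})

test_that("a liberal threshold flags a superset and never lowers counts", {
  set.seed(5)
  z <- matrix(rnorm(40 * 169), 40, 169)
  strict <- binarize_outliers(z, -1.96)
  liberal <- binarize_outliers(z, -1.282)
  expect_true(all(liberal$o >= strict$o))
  expect_true(all(rowSums(liberal$o) >= rowSums(strict$o)))
})

test_that("two-tailed mode is opt-in and flags symmetric positive deviations", {
  z <- matrix(c(-2.5, 2.5, 0), 1)
  expect_equal(unname(binarize_outliers(z)$o[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(binarize_outliers(z, two_tailed = TRUE)$o[1, ]),
               c(1L, 1L, 0L))
})

test_that("participant summaries: counts, means, full-index extremes", {
  z <- matrix(c(-2.50, -1.96, -1.00, 0.30, -3.10), 1)
  s <- summarize_participants(z)
  expect_equal(s$total_outlier_count, 2L)
  expect_equal(s$mean_regional_z, mean(z))
  z0 <- matrix(0, 3, 169)
  s0 <- summarize_participants(z0)
  expect_equal(s0$total_outlier_count, rep(0L, 3))
  expect_equal(s0$mean_regional_z, rep(0, 3))
  zf <- matrix(-2.5, 2, 169)
  expect_equal(summarize_participants(zf)$total_outlier_count, c(169L, 169L))
  expect_error(summarize_participants(z0, binarize_outliers(matrix(0, 3, 5))),
               "shape error")
})

test_that("regional proportions match brute-force counting", {
  set.seed(7)
  z <- matrix(rnorm(12 * 6, sd = 1.5), 12, 6,
              dimnames = list(paste0("p", 1:12), paste0("r", 1:6)))
  out <- binarize_outliers(z)
  grp <- rep(c("a", "b"), each = 6)
  res <- regional_outlier_proportion(out, grp)
  for (g in c("a", "b"))
    for (j in 1:6)
      expect_equal(res$proportions[[g]][j],
                   sum(z[grp == g, j] < -1.96) / 6)
  # one outlier among four participants -> 0.25
  o4 <- binarize_outliers(matrix(c(-3, 0, 0, 0), 4, 1))
  expect_equal(regional_outlier_proportion(o4, rep("g", 4))$proportions$g, 0.25)
  # peak region bookkeeping
  pk <- res$peaks
  expect_equal(nrow(pk), 2L)
  expect_true(all(pk$n_outliers >= 0))
})

test_that("Hamming distances: identities, complements, toy example", {
  # identical all-outlier rows
  h <- hamming_matrix(binarize_outliers(matrix(-3, 2, 169)))$all
  expect_equal(unname(h$distances), matrix(0L, 2, 2))
  # complementary rows over the full 169-region index span the whole range
  z <- rbind(rep(-3, 169), rep(0, 169))
  h2 <- hamming_matrix(binarize_outliers(z))$all
  expect_equal(h2$distances[1, 2], 169L)
  # toy 4-region index
  z3 <- rbind(c(-3, 0, -3, 0), c(-3, -3, 0, 0))
  h3 <- hamming_matrix(binarize_outliers(z3))$all
  expect_equal(h3$distances[1, 2], 2L)
  expect_error(hamming_matrix(binarize_outliers(z3), group = c("a", "b")),
               "single participant")
})

test_that("Hamming matrix is a metric and matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:7, 1); R <- sample(4:12, 1)
    z <- matrix(rnorm(n * R, sd = 2), n, R)
    out <- binarize_outliers(z)
    D <- hamming_matrix(out)$all$distances
    expect_equal(unname(diag(D)), rep(0L, n))
    expect_equal(D, t(D))
    for (i in 1:n) for (j in 1:n) {
      expect_equal(D[i, j], hamming_brute(out$o[i, ], out$o[j, ]))
      for (k in 1:n) expect_lte(D[i, j], D[i, k] + D[k, j])
    }
    # total outlier count = Hamming distance to the all-zero vector
    expect_equal(rowSums(out$o), apply(out$o, 1, hamming_brute,
                                       b = rep(0L, R)))
  }
})

test_that("median over an even number of distances averages the middle pair", {
  # 5 participants -> 4 distances each; construct known distances
  o <- rbind(rep(1L, 8), rep(0L, 8),
             c(1L, rep(0L, 7)), c(1L, 1L, rep(0L, 6)), c(rep(1L, 3), rep(0L, 5)))
  out <- structure(list(ids = paste0("p", 1:5), regions = paste0("r", 1:8),
                        o = o, threshold = -1.96), class = "outlier_table")
  h <- hamming_matrix(out)$all
  d1 <- sort(h$distances[1, -1])
  expect_equal(h$medians$median_distance[1], mean(d1[2:3]))
})
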