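# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: recursions, enumerations and direct matrix
# algebra written from the textbook definitions.

# Cox-de Boor recursion for B-spline basis functions on a full knot vector
cox_de_boor <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) {
    for (ix in seq_along(x)) {
      B[ix, j] <- cdb_one(x[ix], j, degree, knots)
    }
  }
  # right-boundary convention: last basis function is 1 at the last knot
  at_end <- x == knots[length(knots)]
  if (any(at_end)) { B[at_end, ] <- 0; B[at_end, nb] <- 1 }
  B
}
cdb_one <- function(x, j, d, knots) {
  if (d == 0) return(as.numeric(x >= knots[j] && x < knots[j + 1]))
  a <- 0
  if (knots[j + d] > knots[j])
    a <- (x - knots[j]) / (knots[j + d] - knots[j]) * cdb_one(x, j, d - 1, knots)
  b <- 0
  if (knots[j + d + 1] > knots[j + 1])
    b <- (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) *
      cdb_one(x, j + 1, d - 1, knots)
  a + b
}

# Exhaustive-permutation Mann-Whitney: U statistic for the first sample and
# exact two-sided p over all labelings
mw_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_stat <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  }
  obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n, n1), 2, u_stat)
  p_lo <- mean(all_u <= obs); p_hi <- mean(all_u >= obs)
  list(U = obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Benjamini-Hochberg step-up applied literally to the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  if (m >= 2)
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# position-wise Hamming distance
hamming_brute <- function(a, b) sum(a != b)

# closed-form Gaussian BLR log evidence by direct matrix algebra
gauss_blr_evidence <- function(t, X, alpha, beta) {
  n <- nrow(X); d <- ncol(X)
  A <- alpha * diag(d) + beta * crossprod(X)
  m <- beta * solve(A, crossprod(X, t))
  0.5 * d * log(alpha) + 0.5 * n * log(beta) -
    0.5 * determinant(A, logarithm = TRUE)$modulus -
    0.5 * n * log(2 * pi) - 0.5 * beta * sum((t - X %*% m)^2) -
    0.5 * alpha * sum(m^2)
}

# sample skewness g1
skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / mean(x^2)^1.5
}

# small flat-trajectory sim config on a region subset: identity generative
# mean apart from requested effects, so (value - mu) / scale is the residual
flat_config <- function(n, regions = 3L, eps = 0, delta = 1, sex_effect = 0,
                        site_effect_sd = 0, n_sites = 1L, seed = 1L,
                        groups = list(), clinical_sites = c(clin_a = 50L)) {
  idx <- region_index()[seq_len(regions), ]
  sim_config(n_reference = n, n_sites = n_sites,
             site_effect_sd = site_effect_sd, sex_effect = sex_effect,
             skew_eps = eps, kurt_delta = delta,
             trajectory_coeffs = matrix(0, regions, 3),
             group_specs = groups, clinical_sites = clinical_sites,
             index = idx, seed = seed)
}

# residuals on the standardized generative scale
std_residuals <- function(cohort, truth) {
  p <- truth$region_params
  vals <- as.matrix(cohort[, p$name, drop = FALSE])
  sweep(sweep(vals, 2, p$mu, `-`), 2, p$scale, `/`)
}

# write a FreeSurfer-dialect stats file with given values
write_fs_stats <- function(path, labels, values, value_col,
                           extra_cols = c("NumVert", "SurfArea")) {
  all_cols <- c("StructName", extra_cols, value_col)
  lines <- c("# Table of FreeSurfer cortical parcellation anatomical statistics",
             "# generated for testing",
             paste("# ColHeaders ", paste(all_cols, collapse = " ")))
  for (i in seq_along(labels)) {
    fillers <- round(seq(100, 200, length.out = length(extra_cols)) + i)
    lines <- c(lines, paste(labels[i], paste(fillers, collapse = "  "),
                            format(values[i], nsmall = 3), sep = "  "))
  }
  writeLines(lines, path)
  path
}
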