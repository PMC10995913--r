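# Group-level statistics: age/sex-adjusted regressions, Mann-Whitney U
# tests with FDR correction, composite cognitive scoring, and flagging of
# extreme total-outlier-count participants for sensitivity reruns.

#' Age- and sex-adjusted linear regression
#'
#' Ordinary least squares of an outcome on `[intercept, predictor, age,
#' sex]`, reporting the Wald t test of the predictor coefficient — the test
#' used both for group differences (predictor = group indicator) and for
#' clinical associations (predictor = a continuous measure).
#'
#' @param outcome Numeric outcome per participant.
#' @param predictor Group indicator (0/1) or continuous score.
#' @param age,sex Adjustment covariates.
#' @param predictor_name Label used in the result.
#' @return An `association_result` data frame row: `predictor`, `beta`,
#'   `se`, `t`, `p` (two-sided), `n`, `covariates`.
#' @export
adjusted_regression <- function(outcome, predictor, age, sex,
                                predictor_name = "predictor") {
  keep <- stats::complete.cases(outcome, predictor, age, sex)
  d <- data.frame(outcome = outcome, predictor = predictor,
                  age = age, sex = sex)[keep, ]
  if (nrow(d) <= 4L)
    stop("too few complete observations (", nrow(d), ") for a 4-parameter model",
         call. = FALSE)
  if (stats::var(d$predictor) == 0)
    stop("predictor is constant; group effect not estimable", call. = FALSE)
  fit <- stats::lm(outcome ~ predictor + age + sex, data = d)
  if (fit$rank < 4L) {
    dropped <- names(which(is.na(stats::coef(fit))))
    stop("singularity error: collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)$coefficients["predictor", ]
  structure(data.frame(predictor = predictor_name, beta = s[["Estimate"]],
                       se = s[["Std. Error"]], t = s[["t value"]],
                       p = s[["Pr(>|t|)"]], n = nrow(d),
                       covariates = "age+sex", stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("association_result", "data.frame"))
}

#' Mann-Whitney U test
#'
#' Two-sample rank test reported in the U convention for the first sample
#' (`U = W` as returned by [stats::wilcox.test()]; `0 <= U <= n1*n2`).
#' The p-value is exact (permutation distribution) when the samples are
#' untied and the number of labelings `choose(n1+n2, n1)` is at most
#' 20,000; otherwise the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return A `rank_test_result` data frame row: `W` (the U statistic for
#'   `x`), `p` (two-sided), `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && choose(length(x) + length(y), length(x)) <= 20000
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  # degenerate case (e.g., every pooled value identical): no evidence at all
  if (!is.finite(wt$p.value)) wt$p.value <- 1
  structure(data.frame(W = unname(wt$statistic), p = wt$p.value,
                       n1 = length(x), n2 = length(y), exact = exact,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("rank_test_result", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate q-values, returned in the input order.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values (`q >= p`, order-preserving).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Composite cognitive score
#'
#' Standardizes each cognitive subtest against control reference means/SDs
#' and averages the available subtest z-scores per participant, giving a
#' single global-cognition measure on the control z-scale. Participants
#' missing every subtest get `NA`.
#'
#' @param scores Data frame or matrix of subtest scores (participants x
#'   subtests).
#' @param control_means,control_sds Named reference statistics per subtest
#'   (e.g., from the control group); SDs must be positive.
#' @return Numeric vector of composite scores.
#' @export
composite_cognitive_score <- function(scores, control_means, control_sds) {
  scores <- as.matrix(scores)
  if (!ncol(scores)) stop("need at least one subtest", call. = FALSE)
  subtests <- colnames(scores)
  if (!all(subtests %in% names(control_means)) ||
      !all(subtests %in% names(control_sds)))
    stop("control reference missing for subtest(s): ",
         paste(setdiff(subtests, intersect(names(control_means),
                                           names(control_sds))),
               collapse = ", "), call. = FALSE)
  sds <- control_sds[subtests]
  if (any(sds <= 0)) stop("control SDs must be > 0", call. = FALSE)
  z <- sweep(sweep(scores, 2, control_means[subtests], `-`), 2, sds, `/`)
  comp <- rowMeans(z, na.rm = TRUE)
  comp[!rowSums(is.finite(z))] <- NA_real_
  comp
}

#' Flag participants with extreme total outlier counts
#'
#' Reproducible replacement for visual identification of participants whose
#' total outlier count is far above the rest of their group: counts above
#' `Q3 + k * IQR` within group are flagged (default `k = 3`, the
#' far-outlier convention). Flagged participants can be excluded in a
#' sensitivity rerun of all group comparisons and associations.
#'
#' @param counts Total outlier counts.
#' @param group Group label per participant (single group if omitted).
#' @param ids Participant ids (defaults to indices).
#' @param k IQR multiplier.
#' @return Character vector of flagged participant ids (possibly empty).
#' @export
flag_extreme_participants <- function(counts, group = rep("all", length(counts)),
                                      ids = as.character(seq_along(counts)),
                                      k = 3) {
  flagged <- character(0)
  for (g in unique(group)) {
    i <- which(group == g)
    q <- stats::quantile(counts[i], c(0.25, 0.75), names = FALSE, type = 7)
    cut <- q[2] + k * (q[2] - q[1])
    flagged <- c(flagged, ids[i][counts[i] > cut])
  }
  flagged
}
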