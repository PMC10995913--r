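#' Age-basis specification
#'
#' The normative mean trajectory over age is a clamped cubic B-spline.
#' Interior knots are placed at quantiles of the reference ages so the basis
#' stays identifiable at moderate cohort sizes; boundary knots are clamped
#' (repeated degree+1 times), so the basis forms a partition of unity and the
#' leftmost basis function equals 1 exactly at the lower boundary.
#'
#' @param ages Numeric vector of reference ages (years) used to place knots.
#' @param n_interior Number of interior knots (default 3).
#' @param degree Spline degree (default 3, cubic).
#' @return A `basis_spec` list with `boundary`, `interior` and `degree`.
#' @export
basis_spec <- function(ages, n_interior = 3L, degree = 3L) {
  stopifnot(is.numeric(ages), length(ages) >= 2L, n_interior >= 0L)
  lo <- min(ages); hi <- max(ages)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("ages must span a non-degenerate range", call. = FALSE)
  probs <- seq_len(n_interior) / (n_interior + 1)
  interior <- as.numeric(stats::quantile(ages, probs, names = FALSE, type = 7))
  structure(list(boundary = c(lo, hi), interior = interior,
                 degree = as.integer(degree)),
            class = "basis_spec")
}

# Internal: evaluate the clamped B-spline basis at given ages.
# Ages outside the knot span are clipped to it with a warning: clamped
# splines extrapolate poorly, so out-of-support participants are scored at
# the nearest supported age.
spline_basis <- function(age, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  out_of_range <- age < lo | age > hi
  if (any(out_of_range)) {
    warning(sprintf("%d age value(s) outside the basis support [%.1f, %.1f]; clipped",
                    sum(out_of_range), lo, hi), call. = FALSE)
    age <- pmin(pmax(age, lo), hi)
  }
  ord <- spec$degree + 1L
  knots <- c(rep(lo, ord), spec$interior, rep(hi, ord))
  B <- splines::splineDesign(knots, age, ord = ord, outer.ok = FALSE)
  colnames(B) <- paste0("bs", seq_len(ncol(B)))
  B
}

#' Build the covariate design matrix
#'
#' One row per participant: clamped cubic B-spline basis over age, the sex
#' indicator (0/1), an explicit intercept column, and optionally one dummy
#' column per non-reference site (used when fitting on the multi-site
#' reference cohort; site columns are zero at prediction time because new
#' sites are handled by post-hoc recalibration).
#'
#' @param age Numeric vector of ages in years.
#' @param sex Integer/numeric vector of 0/1 sex codes.
#' @param spec A [basis_spec()].
#' @param site Optional factor/character vector of site labels.
#' @param site_levels Optional character vector fixing the site dummy layout;
#'   the first level is the reference site (no column).
#' @return Numeric matrix with named columns.
#' @export
build_design_matrix <- function(age, sex, spec, site = NULL, site_levels = NULL) {
  if (!all(sex %in% c(0, 1)))
    stop("sex must be coded 0/1", call. = FALSE)
  B <- spline_basis(age, spec)
  X <- cbind(B, sex = as.numeric(sex), intercept = 1)
  if (!is.null(site_levels) && length(site_levels) > 1L) {
    S <- matrix(0, nrow = length(age), ncol = length(site_levels) - 1L,
                dimnames = list(NULL, paste0("site_", site_levels[-1L])))
    if (!is.null(site)) {
      site <- as.character(site)
      unknown <- setdiff(unique(site), site_levels)
      if (length(unknown))
        stop("unknown site(s): ", paste(unknown, collapse = ", "), call. = FALSE)
      for (j in seq_along(site_levels)[-1L])
        S[site == site_levels[j], j - 1L] <- 1
    }
    X <- cbind(X, S)
  }
  X
}
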