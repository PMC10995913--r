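# Whole-index normative model: one region_model per feature column.

#' Fit the full normative model
#'
#' Fits one warped Bayesian linear regression per region on a reference
#' cohort of healthy controls. All regions share the age-basis layout
#' (knots from the reference ages) and the site dummy layout.
#'
#' @param cohort Cohort data frame (see [generate_reference_cohort()] /
#'   [read_roi_table()]) containing `age`, `sex`, `site` and the region
#'   columns.
#' @param regions Character vector of region names to fit; default all
#'   regions of `index` present in the cohort.
#' @param index Region index; defaults to the canonical 169.
#' @param warp_type Passed to [fit_region_model()].
#' @param min_controls Minimum reference size per region.
#' @return A `normative_model`: list of `region_model`s plus shared layout.
#' @export
fit_normative_model <- function(cohort, regions = NULL, index = region_index(),
                                warp_type = "sinh-arcsinh", min_controls = 50L) {
  validate_region_index(index)
  if (is.null(regions)) regions <- intersect(index$name, names(cohort))
  missing <- setdiff(regions, names(cohort))
  if (length(missing))
    stop("cohort lacks region column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  spec <- basis_spec(cohort$age)
  models <- stats::setNames(vector("list", length(regions)), regions)
  for (r in regions)
    models[[r]] <- fit_region_model(cohort[[r]], cohort$age, cohort$sex,
                                    cohort$site, spec = spec,
                                    warp_type = warp_type, region = r,
                                    min_controls = min_controls)
  structure(list(regions = models, region_names = regions, basis = spec,
                 site_levels = models[[1]]$site_levels),
            class = "normative_model")
}

#' Recalibrate a full model to a new site
#'
#' Applies [recalibrate_site()] to every regional model using control rows
#' from one target site.
#'
#' @param model A `normative_model`.
#' @param controls Data frame of control participants from a single site
#'   (must contain `age`, `sex`, `site` and all fitted region columns).
#' @param site Site label; defaults to the single site present in `controls`.
#' @param min_controls Passed through to [recalibrate_site()].
#' @return An updated copy of the model.
#' @export
recalibrate_model <- function(model, controls, site = NULL, min_controls = 10L) {
  stopifnot(inherits(model, "normative_model"))
  sites <- unique(as.character(controls$site))
  if (is.null(site)) {
    if (length(sites) != 1L)
      stop("calibration error: controls span ", length(sites),
           " sites; pass one site at a time", call. = FALSE)
    site <- sites
  } else {
    controls <- controls[as.character(controls$site) == site, , drop = FALSE]
  }
  missing <- setdiff(model$region_names, names(controls))
  if (length(missing))
    stop("calibration error: control table lacks region column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  if (nrow(controls) < 20L)
    warning("site ", site, " has only ", nrow(controls),
            " controls; corrections may be unstable", call. = FALSE)
  for (r in model$region_names)
    model$regions[[r]] <- suppressWarnings(
      recalibrate_site(model$regions[[r]], controls[[r]], controls$age,
                       controls$sex, site, min_controls = min_controls))
  model
}

#' Deviation z-scores for a cohort
#'
#' Scores every participant against the recalibrated normative model,
#' producing the participants x regions matrix of deviation z-scores.
#'
#' @param model A `normative_model` whose `site_corrections` cover every
#'   site in `cohort`.
#' @param cohort Data frame with `participant_id`, `age`, `sex`, `site` and
#'   the fitted region columns.
#' @return A `deviation_table`: list with `ids`, `regions` and the numeric
#'   matrix `z` (rows = participants in cohort order, columns = regions in
#'   canonical order).
#' @export
predict_zscores <- function(model, cohort) {
  stopifnot(inherits(model, "normative_model"))
  missing <- setdiff(model$region_names, names(cohort))
  if (length(missing))
    stop("cohort lacks region column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  z <- matrix(NA_real_, nrow(cohort), length(model$region_names),
              dimnames = list(cohort$participant_id, model$region_names))
  for (r in model$region_names)
    z[, r] <- predict_region_z(model$regions[[r]], cohort[[r]], cohort$age,
                               cohort$sex, cohort$site)
  if (any(!is.finite(z)))
    stop("non-finite z-scores produced; check input responses", call. = FALSE)
  structure(list(ids = as.character(cohort$participant_id),
                 regions = model$region_names, z = z),
            class = "deviation_table")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative model:", length(x$region_names), "regions;",
      length(x$site_levels), "reference site(s);",
      "calibrated sites:",
      paste(names(x$regions[[1]]$site_corrections), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.deviation_table <- function(x, ...) {
  cat("Deviation table:", length(x$ids), "participants x",
      length(x$regions), "regions\n")
  invisible(x)
}

#' Serialize a normative model to JSON
#'
#' Writes every regional model (weights, precisions, warp, standardization,
#' posterior covariance, knots and site corrections) to a single JSON file
#' at full numeric precision, so a reloaded model reproduces z-scores
#' exactly.
#'
#' @param model A `normative_model`.
#' @param path Output file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  ser <- list(
    format = "normdev-model-1",
    basis = list(boundary = model$basis$boundary,
                 interior = model$basis$interior,
                 degree = model$basis$degree),
    site_levels = model$site_levels,
    regions = lapply(model$regions, function(m)
      list(region = m$region, weights = as.list(m$weights),
           alpha = m$alpha, beta = m$beta, eps = m$eps, delta = m$delta,
           y_shift = m$y_shift, y_scale = m$y_scale,
           A_inv = m$A_inv, col_names = m$col_names,
           site_corrections = m$site_corrections, logml = m$logml))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized normative model
#'
#' @param path Path to a file written by [write_model_json()].
#' @return A `normative_model`.
#' @export
read_model_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "normdev-model-1"))
    stop("not a normdev model file: ", path, call. = FALSE)
  spec <- structure(list(boundary = ser$basis$boundary,
                         interior = ser$basis$interior,
                         degree = as.integer(ser$basis$degree)),
                    class = "basis_spec")
  regions <- lapply(ser$regions, function(m) {
    sc <- lapply(m$site_corrections, function(s)
      list(offset = s$offset, scale = s$scale))
    structure(list(region = m$region,
                   weights = stats::setNames(unlist(m$weights), m$col_names),
                   alpha = m$alpha, beta = m$beta, eps = m$eps,
                   delta = m$delta, y_shift = m$y_shift, y_scale = m$y_scale,
                   A_inv = matrix(unlist(m$A_inv), length(m$col_names),
                                  length(m$col_names)),
                   basis = spec, site_levels = ser$site_levels,
                   col_names = m$col_names, site_corrections = sc,
                   logml = m$logml),
              class = "region_model")
  })
  structure(list(regions = regions, region_names = names(regions),
                 basis = spec, site_levels = ser$site_levels),
            class = "normative_model")
}
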