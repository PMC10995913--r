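# Multi-site synthetic cohort generator with known ground truth.
#
# Regional values are drawn from the same generative family the normative
# model assumes: a smooth lifespan trajectory in age, an additive sex offset,
# additive per-site batch offsets, and skewed/heavy-tailed residuals obtained
# by passing standard-normal draws through the inverse sinh-arcsinh warp.
# Patient groups additionally receive a participant-specific set of
# "affected" regions shifted downward by a stated effect size, and clinical
# scores generated as linear-Gaussian functions of the injected atrophy
# burden.

#' Group specification for the clinical simulator
#'
#' @param n Number of participants in the group (>= 2).
#' @param burden Mean number of affected (atrophic) regions per participant.
#' @param effect Shift applied to affected regions, in residual-SD units;
#'   negative for atrophy.
#' @param heterogeneity Dispersion of affected-region sets in `[0, 1]`:
#'   0 gives every participant the identical core set, 1 draws each
#'   participant's set independently at random.
#' @param sites Character vector of clinical site names the group is
#'   recruited from (participants are assigned cyclically).
#' @param loadings Named numeric vector of clinical-score loadings per unit
#'   of injected burden (SD units): `cognitive`, `visuoperception`, `moca`.
#' @param age_range Optional two-vector overriding the cohort age range for
#'   this group.
#' @return A `group_spec` list.
#' @export
group_spec <- function(n, burden, effect, heterogeneity = 0.8,
                       sites = "clin_a",
                       loadings = c(cognitive = 0, visuoperception = 0, moca = 0),
                       age_range = NULL) {
  if (!is.numeric(n) || n < 2)
    stop("invalid group spec: `n` must be >= 2", call. = FALSE)
  if (burden < 0)
    stop("invalid group spec: `burden` must be >= 0", call. = FALSE)
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("invalid group spec: `heterogeneity` must be in [0, 1]", call. = FALSE)
  ld <- c(cognitive = 0, visuoperception = 0, moca = 0)
  ld[names(loadings)] <- loadings
  structure(list(n = as.integer(n), burden = burden, effect = effect,
                 heterogeneity = heterogeneity, sites = sites,
                 loadings = ld, age_range = age_range),
            class = "group_spec")
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic multi-site cohort generator. The seed
#' fully determines the generated tables. Regional heterogeneity (trajectory
#' shapes, typical levels, warp parameters) is itself drawn once per region
#' from documented priors, deterministically from the seed.
#'
#' @param n_reference Reference-cohort size.
#' @param n_sites Number of reference sites.
#' @param site_effect_sd SD of additive per-site, per-region offsets on the
#'   standardized scale.
#' @param age_range Two-vector `(lo, hi)` of ages in years; ages are uniform.
#' @param sex_effect Additive standardized offset for sex = 1.
#' @param skew_eps Residual skew: a scalar recycled over regions, a vector of
#'   length 169, or `"random"` to draw per-region values uniformly on
#'   \[-0.3, 0.3\].
#' @param kurt_delta Residual tail-weight (> 0): scalar, vector, or
#'   `"random"` for per-region draws on \[0.9, 1.2\].
#' @param trajectory_coeffs Optional regions x 3 matrix of cubic polynomial
#'   coefficients (linear, quadratic, cubic in scaled age); by default drawn
#'   per region from Gaussian priors centred on an ageing-related decline.
#' @param group_specs Named list of [group_spec()] objects (clinical groups).
#' @param clinical_sites Named integer vector: control count per clinical
#'   site (these controls are the recalibration data).
#' @param clinical_noise_sd SD of clinical-score noise, in score units.
#' @param index Region index data frame; defaults to the canonical 169.
#' @param seed Integer seed; fully determines all output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reference = 2000L, n_sites = 4L, site_effect_sd = 0.2,
                       age_range = c(40, 90), sex_effect = 0.3,
                       skew_eps = "random", kurt_delta = "random",
                       trajectory_coeffs = NULL,
                       group_specs = list(),
                       clinical_sites = c(clin_a = 50L, clin_b = 100L),
                       clinical_noise_sd = 0.5,
                       index = region_index(),
                       seed = 1L) {
  if (!is.numeric(n_reference) || n_reference < 1)
    stop("invalid config field `n_reference`: must be a positive count", call. = FALSE)
  if (!is.numeric(n_sites) || n_sites < 1)
    stop("invalid config field `n_sites`: must be a positive count", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("invalid config field `age_range`: need lo < hi", call. = FALSE)
  if (site_effect_sd < 0)
    stop("invalid config field `site_effect_sd`: must be >= 0", call. = FALSE)
  if (is.numeric(kurt_delta) && any(kurt_delta <= 0))
    stop("invalid config field `kurt_delta`: must be > 0", call. = FALSE)
  if (length(group_specs) && is.null(names(group_specs)))
    stop("invalid config field `group_specs`: must be a named list", call. = FALSE)
  for (g in group_specs)
    if (!inherits(g, "group_spec"))
      stop("invalid config field `group_specs`: entries must be group_spec objects",
           call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("invalid config field `seed`: must be a finite integer", call. = FALSE)
  validate_region_index(index)
  structure(list(n_reference = as.integer(n_reference),
                 n_sites = as.integer(n_sites),
                 site_effect_sd = site_effect_sd, age_range = age_range,
                 sex_effect = sex_effect, skew_eps = skew_eps,
                 kurt_delta = kurt_delta,
                 trajectory_coeffs = trajectory_coeffs,
                 group_specs = group_specs, clinical_sites = clinical_sites,
                 clinical_noise_sd = clinical_noise_sd, index = index,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Per-region generative parameters, drawn once from documented priors.
# Typical levels: cortical thickness ~ 2-3 mm with ~0.15 mm residual SD;
# subcortical volumes log-uniform over 1e3-1.6e4 mm^3 with 8% residual SD.
draw_region_params <- function(config) {
  idx <- config$index
  R <- nrow(idx)
  cortical <- idx$kind == "cortical_thickness"
  mu <- numeric(R)
  mu[cortical] <- stats::runif(sum(cortical), 2.0, 3.0)
  mu[!cortical] <- 10^stats::runif(sum(!cortical), 3.0, 4.2)
  scale <- ifelse(cortical, 0.15, 0.08 * mu)
  if (is.null(config$trajectory_coeffs)) {
    tc <- cbind(c1 = stats::rnorm(R, -0.5, 0.2),
                c2 = stats::rnorm(R, -0.2, 0.15),
                c3 = stats::rnorm(R, 0, 0.1))
  } else {
    tc <- config$trajectory_coeffs
    if (!is.matrix(tc) || nrow(tc) != R || ncol(tc) != 3L)
      stop("invalid config field `trajectory_coeffs`: need a ", R, " x 3 matrix",
           call. = FALSE)
    colnames(tc) <- c("c1", "c2", "c3")
  }
  eps <- if (identical(config$skew_eps, "random"))
    stats::runif(R, -0.3, 0.3) else rep_len(config$skew_eps, R)
  delta <- if (identical(config$kurt_delta, "random"))
    stats::runif(R, 0.9, 1.2) else rep_len(config$kurt_delta, R)
  data.frame(name = idx$name, mu = mu, scale = scale, tc, eps = eps,
             delta = delta, stringsAsFactors = FALSE)
}

# trajectory on the standardized scale; age scaled to [-1, 1]
eval_trajectory <- function(age, params, age_range) {
  u <- (age - mean(age_range)) / (diff(age_range) / 2)
  outer(u, params$c1) + outer(u^2, params$c2) + outer(u^3, params$c3)
}

# Draw the standardized-scale value matrix for given covariates.
draw_values_std <- function(age, sex, site, params, site_offsets, config) {
  n <- length(age); R <- nrow(params)
  traj <- eval_trajectory(age, params, config$age_range)
  noise <- matrix(stats::rnorm(n * R), n, R)
  for (r in seq_len(R))
    noise[, r] <- inverse_warp(noise[, r], params$eps[r], params$delta[r])
  traj + config$sex_effect * outer(sex, rep(1, R)) +
    site_offsets[site, , drop = FALSE] + noise
}

std_to_natural <- function(std, params) {
  sweep(sweep(std, 2, params$scale, `*`), 2, params$mu, `+`)
}

# balanced covariate draw: ages uniform, sexes alternating within site
draw_covariates <- function(n, sites, age_range) {
  site <- rep_len(sites, n)
  ord <- order(site)
  sex <- integer(n)
  for (s in unique(site)) {
    i <- which(site == s)
    sex[i] <- rep_len(c(0L, 1L), length(i))
  }
  list(age = stats::runif(n, age_range[1], age_range[2]), sex = sex,
       site = site)
}

#' Generate the synthetic reference cohort
#'
#' Draws `n_reference` healthy controls across `n_sites` reference sites
#' from the generative model described in [sim_config()]. Intended as the
#' training data for [fit_normative_model()].
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (data frame: participant_id, age, sex, site,
#'   group, then the 169 region columns in canonical order) and `truth`
#'   (a `ground_truth` list carrying the per-region generative parameters,
#'   site offsets and simulation seed).
#' @examples
#' ref <- generate_reference_cohort(sim_config(n_reference = 100, seed = 7))
#' dim(ref$cohort)
#' @export
generate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  params <- draw_region_params(config)
  sites <- paste0("ref_", seq_len(config$n_sites))
  site_offsets <- matrix(stats::rnorm(config$n_sites * nrow(params),
                                      0, config$site_effect_sd),
                         config$n_sites, nrow(params),
                         dimnames = list(sites, params$name))
  cv <- draw_covariates(config$n_reference, sites, config$age_range)
  std <- draw_values_std(cv$age, cv$sex, cv$site, params, site_offsets, config)
  vals <- std_to_natural(std, params)
  colnames(vals) <- params$name
  cohort <- data.frame(participant_id = sprintf("ref_%04d", seq_len(config$n_reference)),
                       age = cv$age, sex = cv$sex, site = cv$site,
                       group = "Control", stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(vals))
  truth <- structure(list(region_params = params, site_offsets = site_offsets,
                          sex_effect = config$sex_effect,
                          age_range = config$age_range,
                          affected = list(), burden = numeric(0),
                          loadings = list(), seed = config$seed),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

# affected-region set for one patient
draw_affected_set <- function(spec, core, region_names) {
  if (spec$heterogeneity == 0 || spec$burden == 0)
    return(core)
  k <- min(stats::rpois(1L, spec$burden), length(region_names))
  n_core <- min(round((1 - spec$heterogeneity) * k), length(core), k)
  chosen <- if (n_core > 0) sample(core, n_core) else character(0)
  c(chosen, sample(setdiff(region_names, chosen), k - n_core))
}

#' Generate the synthetic clinical cohort
#'
#' Draws site controls and patient groups at new (clinical) sites from the
#' reference generative model, with fresh site offsets, injected regional
#' atrophy for patients, and clinical scores (three cognitive subtests, a
#' MoCA-like global score and a visuo-perception score) that load linearly
#' on each participant's true atrophy burden.
#'
#' @param config A [sim_config()] with non-empty `group_specs`.
#' @param reference_truth The `truth` element returned by
#'   [generate_reference_cohort()] (supplies the per-region generative
#'   parameters so clinical and reference data share one normative surface).
#' @return A list with `cohort` (covariates, clinical scores and 169 region
#'   columns) and `truth` (affected-region sets, per-participant burden in
#'   SD units, group effect sizes and clinical loadings).
#' @export
generate_clinical_cohort <- function(config, reference_truth) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference_truth, "ground_truth"))
  if (!length(config$group_specs))
    stop("config has no group_specs", call. = FALSE)
  bad_sites <- setdiff(unlist(lapply(config$group_specs, `[[`, "sites")),
                       names(config$clinical_sites))
  if (length(bad_sites))
    stop("group spec references unknown clinical site(s): ",
         paste(bad_sites, collapse = ", "), call. = FALSE)
  set.seed(config$seed + 1L)
  params <- reference_truth$region_params
  R <- nrow(params)
  csites <- names(config$clinical_sites)
  site_offsets <- matrix(stats::rnorm(length(csites) * R, 0, config$site_effect_sd),
                         length(csites), R, dimnames = list(csites, params$name))

  # assemble covariate frame: controls per clinical site, then groups
  frames <- list()
  for (s in csites) {
    n <- config$clinical_sites[[s]]
    cv <- draw_covariates(n, s, config$age_range)
    frames[[length(frames) + 1L]] <-
      data.frame(age = cv$age, sex = cv$sex, site = cv$site, group = "Control",
                 stringsAsFactors = FALSE)
  }
  for (g in names(config$group_specs)) {
    spec <- config$group_specs[[g]]
    rng <- if (is.null(spec$age_range)) config$age_range else spec$age_range
    cv <- draw_covariates(spec$n, spec$sites, rng)
    frames[[length(frames) + 1L]] <-
      data.frame(age = cv$age, sex = cv$sex, site = cv$site, group = g,
                 stringsAsFactors = FALSE)
  }
  cov <- do.call(rbind, frames)
  n <- nrow(cov)
  cov$participant_id <- sprintf("clin_%04d", seq_len(n))

  std <- draw_values_std(cov$age, cov$sex, cov$site, params, site_offsets, config)

  # inject atrophy: per-participant affected sets
  affected <- stats::setNames(vector("list", n), cov$participant_id)
  burden <- stats::setNames(numeric(n), cov$participant_id)
  cores <- lapply(config$group_specs, function(spec)
    sample(params$name, min(round(spec$burden), R)))
  for (i in seq_len(n)) {
    g <- cov$group[i]
    if (g == "Control") { affected[[i]] <- character(0); next }
    spec <- config$group_specs[[g]]
    regs <- draw_affected_set(spec, cores[[g]], params$name)
    affected[[i]] <- regs
    std[i, match(regs, params$name)] <-
      std[i, match(regs, params$name)] + spec$effect
    burden[i] <- length(regs) * abs(spec$effect)
  }

  # clinical scores: linear-Gaussian in true burden
  ld <- function(g, what) {
    if (g == "Control") 0 else config$group_specs[[g]]$loadings[[what]]
  }
  noise <- function() stats::rnorm(n, 0, config$clinical_noise_sd)
  l_cog <- vapply(cov$group, ld, numeric(1), what = "cognitive")
  l_vp  <- vapply(cov$group, ld, numeric(1), what = "visuoperception")
  l_mo  <- vapply(cov$group, ld, numeric(1), what = "moca")
  scores <- data.frame(
    moca = 28 - l_mo * burden + 1.5 * noise(),
    visuoperception = 26 - l_vp * burden + 2 * noise(),
    cog_memory = -l_cog * burden + noise(),
    cog_executive = -l_cog * burden + noise(),
    cog_attention = -l_cog * burden + noise()
  )

  vals <- std_to_natural(std, params)
  colnames(vals) <- params$name
  cohort <- cbind(cov[c("participant_id", "age", "sex", "site", "group")],
                  scores, as.data.frame(vals))
  rownames(cohort) <- NULL
  effects <- data.frame(group = names(config$group_specs),
                        effect = vapply(config$group_specs, `[[`, numeric(1), "effect"),
                        burden = vapply(config$group_specs, `[[`, numeric(1), "burden"),
                        row.names = NULL)
  truth <- structure(list(region_params = params, site_offsets = site_offsets,
                          sex_effect = config$sex_effect,
                          age_range = config$age_range,
                          affected = affected, burden = burden,
                          group_effects = effects,
                          loadings = lapply(config$group_specs, `[[`, "loadings"),
                          seed = config$seed),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}
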