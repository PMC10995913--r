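# End-to-end orchestration: simulate/ingest -> fit -> recalibrate ->
# predict -> deviation metrics -> group inference -> report.

#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `input` (paths to
#' reference and clinical ROI tables) must be supplied.
#'
#' @param simulation A [sim_config()], or `NULL` when reading tables.
#' @param input List with `reference` and `clinical` CSV/TSV paths, or
#'   `NULL` when simulating.
#' @param z_threshold Primary outlier threshold (negative; default -1.96).
#' @param alt_threshold Alternate threshold for the sensitivity rerun
#'   (default -1.282); set `NULL` to skip.
#' @param two_tailed Flag symmetric positive deviations too (default off).
#' @param exclude_extremes Exclude participants flagged by
#'   [flag_extreme_participants()] from the *primary* statistics (a
#'   sensitivity table without them is always produced).
#' @param min_site_controls Minimum controls for site recalibration.
#' @param warp_type `"sinh-arcsinh"` or `"identity"`.
#' @param regions Optional subset of region names to model.
#' @param contrasts List of two-group contrasts `c(first, reference)`; the
#'   reported coefficient is first-minus-reference. Default: all pairs of
#'   patient groups in order of appearance.
#' @param clinical_measures Clinical columns tested for association with
#'   total outlier count (per patient group).
#' @param seed Integer seed controlling all randomness of the run.
#' @param out_dir Output directory (created); `NULL` to skip writing files.
#' @param index Region index.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, input = NULL,
                       z_threshold = -1.96, alt_threshold = -1.282,
                       two_tailed = FALSE, exclude_extremes = FALSE,
                       min_site_controls = 10L,
                       warp_type = "sinh-arcsinh", regions = NULL,
                       contrasts = NULL,
                       clinical_measures = c("composite_cognition", "moca",
                                             "visuoperception"),
                       seed = 1L, out_dir = NULL, index = region_index()) {
  if (is.null(simulation) == is.null(input))
    stop("exactly one of `simulation` or `input` must be given", call. = FALSE)
  if (z_threshold >= 0 || (!is.null(alt_threshold) && alt_threshold >= 0))
    stop("outlier thresholds must be negative", call. = FALSE)
  structure(list(simulation = simulation, input = input,
                 z_threshold = z_threshold, alt_threshold = alt_threshold,
                 two_tailed = two_tailed, exclude_extremes = exclude_extremes,
                 min_site_controls = as.integer(min_site_controls),
                 warp_type = warp_type, regions = regions,
                 contrasts = contrasts, clinical_measures = clinical_measures,
                 seed = as.integer(seed), out_dir = out_dir, index = index),
            class = "run_config")
}

# metrics + inference for one threshold; shared by primary and alternate runs
.metrics_bundle <- function(dev, clinical, config) {
  patients <- clinical$group != "Control"
  out <- binarize_outliers(dev, threshold = config$z_threshold,
                           two_tailed = config$two_tailed)
  summ <- summarize_participants(dev, out)
  summ$group <- clinical$group
  summ$age <- clinical$age
  summ$sex <- clinical$sex

  p_ids <- summ$participant_id[patients]
  out_p <- binarize_outliers(dev$z[patients, , drop = FALSE],
                             threshold = config$z_threshold,
                             two_tailed = config$two_tailed)
  props <- regional_outlier_proportion(out_p, clinical$group[patients])
  ham <- hamming_matrix(out_p, clinical$group[patients])
  med <- do.call(rbind, lapply(names(ham), function(g)
    cbind(group = g, ham[[g]]$medians)))
  list(outliers = out, summaries = summ, proportions = props, hamming = ham,
       hamming_medians = med)
}

.group_statistics <- function(summ, contrasts, dev_regions, out, exclude = character(0)) {
  keep <- !(summ$participant_id %in% exclude)
  rows <- list(); rank_rows <- list(); regional <- list()
  for (ct in contrasts) {
    sel <- keep & summ$group %in% ct
    d <- summ[sel, ]
    ind <- as.numeric(d$group == ct[1])      # reference = second-listed
    label <- paste(ct[1], "vs", ct[2])
    for (m in c("total_outlier_count", "mean_regional_z")) {
      r <- adjusted_regression(d[[m]], ind, d$age, d$sex, predictor_name = label)
      r$outcome <- m
      rows[[length(rows) + 1L]] <- r
    }
    # Hamming medians compared by Mann-Whitney
    hm <- out$hamming_medians[!(out$hamming_medians$participant_id %in% exclude), ]
    med1 <- hm$median_distance[hm$group == ct[1]]
    med2 <- hm$median_distance[hm$group == ct[2]]
    mw <- mann_whitney(med1, med2)
    mw$contrast <- label; mw$outcome <- "median_hamming_distance"
    rank_rows[[length(rank_rows) + 1L]] <- mw
    # per-region outlier comparison with FDR over regions
    g1 <- sel & summ$group == ct[1]; g2 <- sel & summ$group == ct[2]
    o <- out$outliers$o
    reg <- do.call(rbind, lapply(seq_along(dev_regions), function(j) {
      mwj <- mann_whitney(o[g1, j], o[g2, j])
      data.frame(contrast = label, region = dev_regions[j], W = mwj$W,
                 p = mwj$p, stringsAsFactors = FALSE)
    }))
    reg$q <- fdr_adjust(reg$p)
    regional[[length(regional) + 1L]] <- reg
  }
  list(group_stats = do.call(rbind, rows),
       rank_stats = do.call(rbind, rank_rows),
       regional_tests = do.call(rbind, regional))
}

.association_statistics <- function(summ, clinical, measures, exclude = character(0)) {
  keep <- !(summ$participant_id %in% exclude) & summ$group != "Control"
  rows <- list()
  for (g in unique(summ$group[keep])) {
    sel <- keep & summ$group == g
    for (m in intersect(measures, names(clinical))) {
      r <- tryCatch(
        adjusted_regression(clinical[[m]][sel], summ$total_outlier_count[sel],
                            summ$age[sel], summ$sex[sel],
                            predictor_name = "total_outlier_count"),
        error = function(e) NULL)
      if (is.null(r)) next
      r$group <- g; r$measure <- m
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Run the full deviation-mapping pipeline
#'
#' Executes every stage: obtain reference and clinical cohorts (simulated
#' or read from disk), fit the per-region normative models on reference
#' controls, recalibrate to each clinical site from that site's controls,
#' predict deviation z-scores for all clinical participants, derive outlier
#' metrics (total counts, regional proportions, within-group Hamming
#' dissimilarity), and run the adjusted group comparisons, rank tests with
#' FDR correction and clinical-association regressions — plus an
#' alternate-threshold rerun and an extreme-participant sensitivity rerun.
#' Identical config + seed reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list with the cohorts, fitted `model`,
#'   `deviations`, primary `metrics`, `stats` (group, rank, regional,
#'   association and sensitivity tables), `extremes`, and the alternate
#'   threshold bundle `alt` (if requested). When `config$out_dir` is set,
#'   all interface CSV/JSON files plus `run_log.txt` and `report.md` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  index <- config$index

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    ref <- generate_reference_cohort(sim)
    clin <- generate_clinical_cohort(sim, ref$truth)
    reference <- ref$cohort; clinical <- clin$cohort
    truth <- clin$truth
  } else {
    reference <- read_roi_table(config$input$reference, index)
    clinical <- read_roi_table(config$input$clinical, index)
    truth <- NULL
  }

  regions <- if (is.null(config$regions)) intersect(index$name, names(reference))
             else config$regions
  model <- fit_normative_model(reference[reference$group == "Control", ],
                               regions = regions, index = index,
                               warp_type = config$warp_type)
  clin_sites <- unique(clinical$site)
  controls <- clinical[clinical$group == "Control", ]
  for (s in clin_sites)
    model <- recalibrate_model(model, controls, site = s,
                               min_controls = config$min_site_controls)
  dev <- predict_zscores(model, clinical)

  # composite cognition standardized on clinical-site controls
  subtests <- grep("^cog_", names(clinical), value = TRUE)
  if (length(subtests)) {
    ctrl <- clinical$group == "Control"
    cm <- vapply(clinical[ctrl, subtests, drop = FALSE], mean, numeric(1))
    cs <- vapply(clinical[ctrl, subtests, drop = FALSE], stats::sd, numeric(1))
    clinical$composite_cognition <-
      composite_cognitive_score(clinical[, subtests, drop = FALSE], cm, cs)
  }

  metrics <- .metrics_bundle(dev, clinical, config)
  groups <- setdiff(unique(clinical$group), "Control")
  contrasts <- config$contrasts %||%
    (if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE)
     else list())
  patients <- metrics$summaries[metrics$summaries$group != "Control", ]
  extremes <- flag_extreme_participants(patients$total_outlier_count,
                                        patients$group,
                                        patients$participant_id)
  primary_excl <- if (config$exclude_extremes) extremes else character(0)
  stats_primary <- .group_statistics(metrics$summaries, contrasts,
                                     dev$regions, metrics, primary_excl)
  assoc <- .association_statistics(metrics$summaries, clinical,
                                   config$clinical_measures, primary_excl)
  stats_sens <- .group_statistics(metrics$summaries, contrasts, dev$regions,
                                  metrics, extremes)
  assoc_sens <- .association_statistics(metrics$summaries, clinical,
                                        config$clinical_measures, extremes)

  alt <- NULL
  if (!is.null(config$alt_threshold)) {
    alt_config <- config
    alt_config$z_threshold <- config$alt_threshold
    alt <- .metrics_bundle(dev, clinical, alt_config)
  }

  result <- structure(list(config = config, reference = reference,
                           clinical = clinical, truth = truth, model = model,
                           deviations = dev, metrics = metrics,
                           stats = list(group = stats_primary$group_stats,
                                        rank = stats_primary$rank_stats,
                                        regional = stats_primary$regional_tests,
                                        associations = assoc,
                                        group_sensitivity = stats_sens$group_stats,
                                        associations_sensitivity = assoc_sens),
                           extremes = extremes, alt = alt),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# write the full interface-file bundle
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- result$config
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  write_model_json(result$model, file.path(out_dir, "model.json"))
  dev_df <- data.frame(participant_id = result$deviations$ids,
                       result$deviations$z, check.names = FALSE)
  w(dev_df, "deviations.csv")

  write_metrics <- function(m, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(m$summaries[c("participant_id", "group",
                                   "total_outlier_count", "mean_regional_z")],
                     file.path(dir, "participant_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(m$proportions$proportions,
                     file.path(dir, "regional_proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(m$hamming_medians, file.path(dir, "hamming_medians.csv"),
                     row.names = FALSE)
    for (g in names(m$hamming))
      utils::write.csv(data.frame(participant_id = rownames(m$hamming[[g]]$distances),
                                  m$hamming[[g]]$distances, check.names = FALSE),
                       file.path(dir, paste0("hamming_", g, ".csv")),
                       row.names = FALSE)
  }
  write_metrics(result$metrics, out_dir)
  if (!is.null(result$alt))
    write_metrics(result$alt, file.path(out_dir, "alt_threshold"))

  w(result$stats$group, "group_stats.csv")
  w(result$stats$rank, "rank_stats.csv")
  w(result$stats$regional, "regional_tests.csv")
  if (!is.null(result$stats$associations)) w(result$stats$associations, "associations.csv")
  w(result$stats$group_sensitivity, "group_stats_sensitivity.csv")
  if (!is.null(result$stats$associations_sensitivity))
    w(result$stats$associations_sensitivity, "associations_sensitivity.csv")

  cfg_echo <- config
  cfg_echo$index <- NULL
  cfg_echo$out_dir <- NULL
  yaml::write_yaml(.config_to_list(cfg_echo), file.path(out_dir, "config_echo.yaml"))
  log_lines <- c(
    paste0("normdev ", as.character(utils::packageVersion("normdev"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed: ", config$seed),
    paste0("regions modelled: ", length(result$model$region_names)),
    paste0("z threshold: ", config$z_threshold),
    paste0("alternate threshold: ", config$alt_threshold %||% "none"),
    paste0("extreme participants flagged: ",
           if (length(result$extremes)) paste(result$extremes, collapse = ", ")
           else "none"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  writeLines(.render_report(result), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

.config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) {
    sim <- unclass(out$simulation)
    sim$index <- NULL
    sim$group_specs <- lapply(sim$group_specs, function(g) {
      g <- unclass(g); g$loadings <- as.list(g$loadings); g
    })
    sim$clinical_sites <- as.list(sim$clinical_sites)
    out$simulation <- sim
  }
  out
}

.render_report <- function(result) {
  summ <- result$metrics$summaries
  by_group <- stats::aggregate(total_outlier_count ~ group, summ, function(x)
    c(mean = mean(x), sd = stats::sd(x)))
  gs <- result$stats$group
  lines <- c("# Normative deviation report", "",
             "## Total outlier count by group", "")
  for (i in seq_len(nrow(by_group)))
    lines <- c(lines, sprintf("- %s: mean %.2f (SD %.2f)", by_group$group[i],
                              by_group$total_outlier_count[i, "mean"],
                              by_group$total_outlier_count[i, "sd"]))
  lines <- c(lines, "", "## Adjusted group contrasts", "",
             "| contrast | outcome | beta | SE | t | p |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(gs)))
    lines <- c(lines, sprintf("| %s | %s | %.3f | %.3f | %.2f | %.3g |",
                              gs$predictor[i], gs$outcome[i], gs$beta[i],
                              gs$se[i], gs$t[i], gs$p[i]))
  if (length(result$extremes))
    lines <- c(lines, "", paste0("Extreme-count participants flagged: ",
                                 paste(result$extremes, collapse = ", "),
                                 " (sensitivity tables exclude them)."))
  lines
}

#' Read a YAML run configuration
#'
#' Builds a [run_config()] from a YAML file. A `simulation:` block is
#' converted to a [sim_config()] (with `groups:` entries becoming
#' [group_spec()]s); otherwise an `input:` block with `reference` and
#' `clinical` paths is expected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    groups <- lapply(s$groups, function(g) {
      # YAML 1.1 reads a bare `n:` key as a boolean; map it back
      names(g)[names(g) == "FALSE"] <- "n"
      group_spec(n = g$n, burden = g$burden, effect = g$effect,
                 heterogeneity = g$heterogeneity %||% 0.8,
                 sites = unlist(g$sites) %||% "clin_a",
                 loadings = unlist(g$loadings) %||% c(cognitive = 0))
    })
    simulation <- sim_config(
      n_reference = s$n_reference %||% 2000L,
      n_sites = s$n_sites %||% 4L,
      site_effect_sd = s$site_effect_sd %||% 0.2,
      age_range = unlist(s$age_range) %||% c(40, 90),
      sex_effect = s$sex_effect %||% 0.3,
      skew_eps = s$skew_eps %||% "random",
      kurt_delta = s$kurt_delta %||% "random",
      group_specs = groups,
      clinical_sites = unlist(s$clinical_sites) %||% c(clin_a = 50L, clin_b = 100L),
      clinical_noise_sd = s$clinical_noise_sd %||% 0.5,
      seed = y$seed %||% 1L)
  }
  run_config(simulation = simulation, input = y$input,
             z_threshold = y$z_threshold %||% -1.96,
             alt_threshold = y$alt_threshold %||% -1.282,
             two_tailed = y$two_tailed %||% FALSE,
             exclude_extremes = y$exclude_extremes %||% FALSE,
             min_site_controls = y$min_site_controls %||% 10L,
             warp_type = y$warp_type %||% "sinh-arcsinh",
             regions = unlist(y$regions),
             seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Default synthetic study configuration
#'
#' The simulation settings used throughout the package's examples and
#' reports: a 4-site reference cohort, two clinical sites providing
#' recalibration controls, and three patient groups with ordered atrophy
#' burden — PD high visual performers (lightest), PD low visual performers,
#' and DLB (heaviest) — whose clinical-score loadings reproduce the
#' qualitative association pattern (global cognition tracks burden in DLB,
#' visuo-perception tracks burden in PD).
#'
#' @param n_reference Reference cohort size (default 1200).
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
default_study_config <- function(n_reference = 1200L, seed = 1L) {
  sim_config(
    n_reference = n_reference, n_sites = 4L, site_effect_sd = 0.2,
    age_range = c(40, 90), sex_effect = 0.3,
    group_specs = list(
      PD_high = group_spec(n = 62, burden = 2, effect = -2.5,
                           heterogeneity = 0.7, sites = "clin_a",
                           loadings = c(cognitive = 0.02, visuoperception = 0.25,
                                        moca = 0.03)),
      PD_low = group_spec(n = 34, burden = 6, effect = -2.5,
                          heterogeneity = 0.8, sites = "clin_a",
                          loadings = c(cognitive = 0.02, visuoperception = 0.25,
                                       moca = 0.03),
                          age_range = c(50, 90)),
      DLB = group_spec(n = 61, burden = 14, effect = -2.5,
                       heterogeneity = 0.9, sites = c("clin_a", "clin_b"),
                       loadings = c(cognitive = 0.04, visuoperception = 0.01,
                                    moca = 0.12),
                       age_range = c(55, 90))),
    clinical_sites = c(clin_a = 50L, clin_b = 100L),
    seed = seed)
}
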