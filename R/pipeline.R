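#' Analysis configuration
#'
#' @param synthetic A [synthetic_config()] used to generate the input
#'   table, or `NULL` when `table` is supplied.
#' @param table Optional observation table (overrides `synthetic`).
#' @param parameters Subset of `c("FEV1", "FVC", "FEV1/FVC")`.
#' @param sexes Subset of `c("F", "M")`.
#' @param strata Subset of `c("main", "never_vs_persistent_asthma",
#'   "never_vs_persistent_smoker")`.
#' @param kmin,kmax Knot-selection range. The default excludes the
#'   one-knot model: a single-knot natural spline cannot represent a
#'   growth-peak-decline trajectory, and its inclusion only distorts the
#'   elbow geometry of the BIC curve.
#' @param profile_mode Prediction profile mode.
#' @param cp Changepoint options: list with `prior`, `n_samples`,
#'   `mag_thresh`, `prob_thresh`, `zero_band`.
#' @param sensitivity List with `exclude_study` (label or `NULL`),
#'   `weighting` (`"none"`, `"MCAR"`, `"MAR"`), `healthy_restricted`
#'   (logical).
#' @param seed Master seed.
#' @export
analysis_config <- function(synthetic = synthetic_config(),
                            table = NULL,
                            parameters = c("FEV1", "FVC"),
                            sexes = c("F", "M"),
                            strata = "main",
                            kmin = 2, kmax = 6,
                            profile_mode = "marginal",
                            cp = list(prior = cp_prior(), n_samples = 2000,
                                      mag_thresh = 0.1, prob_thresh = 0.5,
                                      zero_band = 0.005),
                            sensitivity = list(exclude_study = NULL,
                                               weighting = "none",
                                               healthy_restricted = FALSE),
                            seed = 1L) {
  structure(list(synthetic = synthetic, table = table,
                 parameters = parameters, sexes = sexes, strata = strata,
                 kmin = kmin, kmax = kmax, profile_mode = profile_mode,
                 cp = cp, sensitivity = sensitivity,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# one sex x parameter x participant-subset analysis
run_analysis <- function(table, parameter, config, weights_df = NULL,
                         label = "main") {
  inc <- apply_inclusion(table, parameter)
  std <- standardize_lf(inc, parameter)
  w <- if (is.null(weights_df)) NULL else observation_weights(std, weights_df)
  sel <- select_knots(std, config$kmin, config$kmax, weights = w)
  fit <- fit_ccmm(std, sel$k, "REML", weights = w)
  pred <- predict_trajectory(fit, std, config$profile_mode)
  series <- trend_series(pred$age, pred$mean)
  post <- decompose_trend(series, config$cp$prior, config$cp$n_samples,
                          seed = config$seed + 104729L)
  bps <- call_breakpoints(post, config$cp$mag_thresh,
                          config$cp$prob_thresh)
  list(label = label, parameter = parameter,
       n_participants = length(unique(std$participant_id)),
       n_obs = nrow(std), k = sel$k, bic = sel$bic, fit = fit,
       predicted = pred, posterior = post, breakpoints = bps,
       slopes = segment_slopes(series, post, bps),
       plateaus = plateau_scan(post, config$cp$zero_band),
       sign_probs = sign_probabilities(post, config$cp$zero_band),
       peak = peak_estimate(series, post, bps))
}

#' Run the full trajectory pipeline
#'
#' For each sex, lung-function parameter and stratum: inclusion,
#' life-course classification, height/study standardisation, BIC knot
#' selection, REML refit, integer-age prediction and changepoint summary.
#' The FEV1/FVC ratio is computed per observation before standardisation,
#' never as the ratio of two fitted trajectories.
#'
#' @param config An [analysis_config()].
#' @return Nested list of analysis results keyed
#'   `"<sex>.<parameter>.<stratum>"`, plus the input `table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  table <- if (!is.null(config$table)) config$table
           else simulate_accelerated(config$synthetic)
  table <- ensure_obesity(ensure_birth_decade(table))
  out <- list()
  for (sex in config$sexes) {
    tab_s <- table[table$sex == sex, , drop = FALSE]
    for (param in config$parameters) {
      inc <- apply_inclusion(tab_s, param)
      cats <- life_course_categories(inc)
      for (stratum in config$strata) {
        subsets <- switch(stratum,
          main = list(main = unique(inc$participant_id)),
          never_vs_persistent_asthma = list(
            never_asthma = cats$participant_id[cats$asthma_cat == "never"],
            persistent_asthma =
              cats$participant_id[cats$asthma_cat == "persistent"]),
          never_vs_persistent_smoker = list(
            never_smoker = cats$participant_id[cats$smoking_cat == "never"],
            persistent_smoker =
              cats$participant_id[cats$smoking_cat == "persistent"]),
          stop(sprintf("unknown stratum: %s", stratum)))
        for (lev in names(subsets)) {
          sub <- tab_s[tab_s$participant_id %in% subsets[[lev]], ,
                       drop = FALSE]
          res <- run_analysis(sub, param, config, label = lev)
          res$sex <- sex
          out[[paste(sex, param, lev, sep = ".")]] <- res
        }
      }
    }
  }
  out$table <- table
  out
}

#' Sensitivity variants of the pipeline
#'
#' One variant per enabled option: excluding a named study, reweighting by
#' covariate-balancing retention propensities (MCAR mode gives uniform
#' weights), and restriction to participants who never had asthma, never
#' smoked and never had obesity. Returns each variant's full result set
#' and a per-age comparison table of predicted means.
#'
#' @param config An [analysis_config()] with its `sensitivity` options
#'   set.
#' @param base Optional precomputed [run_pipeline()] result for the base
#'   configuration.
#' @export
sensitivity_suite <- function(config, base = NULL) {
  if (is.null(base)) base <- run_pipeline(config)
  table <- base$table
  variants <- list(base = base)
  sens <- config$sensitivity
  if (!is.null(sens$exclude_study)) {
    if (!sens$exclude_study %in% table$study)
      stop(sprintf("excluded study '%s' not present", sens$exclude_study))
    cfg <- config
    cfg$table <- table[table$study != sens$exclude_study, , drop = FALSE]
    variants$exclude_study <- run_pipeline(cfg)
  }
  if (!identical(sens$weighting, "none")) {
    prob <- retention_problem(table)
    wdf <- cbps_weights(prob, mode = sens$weighting)
    cfg <- config; cfg$table <- table
    res <- list()
    for (sex in cfg$sexes) {
      tab_s <- table[table$sex == sex, , drop = FALSE]
      for (param in cfg$parameters) {
        r <- run_analysis(tab_s, param, cfg, weights_df = wdf,
                          label = "weighted")
        r$sex <- sex
        res[[paste(sex, param, "weighted", sep = ".")]] <- r
      }
    }
    res$table <- table
    variants$weighted <- res
  }
  if (isTRUE(sens$healthy_restricted)) {
    keep <- character(0)
    for (sex in config$sexes) {
      tab_s <- table[table$sex == sex, , drop = FALSE]
      inc <- apply_inclusion(tab_s)
      cats <- life_course_categories(inc)
      keep <- c(keep, cats$participant_id[cats$asthma_cat == "never" &
                                            cats$smoking_cat == "never" &
                                            cats$obesity_cat == "never"])
    }
    cfg <- config
    cfg$table <- table[table$participant_id %in% keep, , drop = FALSE]
    variants$healthy_restricted <- run_pipeline(cfg)
  }
  # per-age predicted-mean comparison across variants
  keys <- setdiff(names(base), "table")
  comp <- do.call(rbind, lapply(names(variants), function(v) {
    res <- variants[[v]]
    do.call(rbind, lapply(setdiff(names(res), "table"), function(k) {
      data.frame(variant = v, analysis = k, age = res[[k]]$predicted$age,
                 mean = res[[k]]$predicted$mean)
    }))
  }))
  variants$comparison <- comp
  variants
}

#' Write a trajectory summary as JSON and its curves as CSV
#'
#' @param res One analysis result from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, gsub("/", "_", paste(res$sex, res$parameter,
                                              res$label, sep = "_")))
  js <- list(sex = res$sex, parameter = res$parameter,
             stratum = res$label, n_participants = res$n_participants,
             n_obs = res$n_obs, knots = res$k,
             bic = as.list(res$bic),
             variance_components = as.list(res$fit$vc),
             logLik = res$fit$logLik,
             breakpoints = res$breakpoints, slopes = res$slopes,
             plateaus = res$plateaus, peak = res$peak)
  jsonlite::write_json(js, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$predicted, paste0(stem, "_trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(res$sign_probs, paste0(stem, "_sign_probs.csv"),
                   row.names = FALSE)
  invisible(c(paste0(stem, "_summary.json"),
              paste0(stem, "_trajectory.csv"),
              paste0(stem, "_sign_probs.csv")))
}

#' Read an analysis configuration from a YAML file
#'
#' Supports the scalar options of [analysis_config()] (parameters, sexes,
#' strata, knot range, profile mode, changepoint thresholds, sensitivity
#' switches, seed); the synthetic-cohort component uses the package
#' defaults scaled to `n_per_sex`.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- synthetic_config(
    designs = default_designs(y$n_per_sex %||% 6000),
    attrition = attrition_model(y$attrition %||% "none"),
    seed = y$seed %||% 1L)
  cp <- analysis_config()$cp
  for (nm in intersect(names(y), c("mag_thresh", "prob_thresh",
                                   "zero_band", "n_samples")))
    cp[[nm]] <- y[[nm]]
  analysis_config(
    synthetic = syn,
    parameters = y$parameters %||% c("FEV1", "FVC"),
    sexes = y$sexes %||% c("F", "M"),
    strata = y$strata %||% "main",
    kmin = y$kmin %||% 2, kmax = y$kmax %||% 6,
    profile_mode = y$profile_mode %||% "marginal",
    cp = cp,
    sensitivity = list(
      exclude_study = y$exclude_study,
      weighting = y$weighting %||% "none",
      healthy_restricted = isTRUE(y$healthy_restricted)),
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
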