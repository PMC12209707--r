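#' Cohort design for the synthetic accelerated cohort
#'
#' Describes one source study: how many participants, which age window it
#' observes, its planned visit ages (jittered by +/- 1 year at simulation
#' time) and the birth-year range of its members.
#'
#' @param study_label Study name.
#' @param n_participants Number of participants (both sexes).
#' @param age_window Length-2 numeric, inside `[4, 80]`.
#' @param visit_ages Planned visit ages (2 to 8). For a child birth
#'   cohort these are absolute ages; for an adult study with an
#'   `entry_age_range` they are offsets from the participant's entry age
#'   (first offset 0), so entry ages spread observations continuously
#'   over the study's age window, as in a rolling-enrolment cohort.
#' @param birth_year_range Length-2 integer range of birth years.
#' @param entry_age_range Optional length-2 range of entry ages; `NULL`
#'   for a fixed-age (birth-cohort) schedule.
#' @param collect_fvc Whether the study measures FVC (one design may be
#'   FEV1-only, mirroring a study that collected slow rather than forced
#'   vital capacity).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(study_label, n_participants, age_window,
                          visit_ages, birth_year_range,
                          entry_age_range = NULL, collect_fvc = TRUE) {
  stopifnot(length(age_window) == 2, age_window[1] >= 4, age_window[2] <= 80,
            n_participants >= 0)
  nv <- length(visit_ages)
  if (nv < 2 || nv > 8) stop("planned visits must number 2 to 8")
  if (is.null(entry_age_range)) {
    if (any(visit_ages < age_window[1] | visit_ages > age_window[2]))
      stop("visit_ages must lie inside age_window")
  } else {
    stopifnot(length(entry_age_range) == 2,
              entry_age_range[1] >= age_window[1],
              entry_age_range[2] <= age_window[2])
    if (visit_ages[1] != 0) stop("first visit offset must be 0")
  }
  structure(list(study_label = study_label,
                 n_participants = as.integer(n_participants),
                 age_window = as.numeric(age_window),
                 visit_ages = sort(as.numeric(visit_ages)),
                 birth_year_range = as.integer(birth_year_range),
                 entry_age_range = entry_age_range,
                 collect_fvc = isTRUE(collect_fvc)),
            class = "cohort_design")
}

#' Random-effect standard deviations for the generator
#' @param sd_individual,sd_study,sd_birth_decade,sd_residual Standard
#'   deviations in litres; all non-negative.
#' @export
random_effect_spec <- function(sd_individual = 0.25, sd_study = 0.05,
                               sd_birth_decade = 0.03, sd_residual = 0.15) {
  x <- c(sd_individual = sd_individual, sd_study = sd_study,
         sd_birth_decade = sd_birth_decade, sd_residual = sd_residual)
  if (any(x < 0)) stop("random-effect SDs must be >= 0")
  structure(as.list(x), class = "random_effect_spec")
}

# piecewise-linear prevalence curve evaluated at arbitrary ages
prevalence_fun <- function(knot_ages, knot_prev) {
  stopifnot(all(knot_prev >= 0 & knot_prev <= 1))
  function(age) stats::approx(knot_ages, knot_prev, xout = age,
                              rule = 2)$y
}

#' Covariate processes (asthma, smoking, obesity) for the generator
#'
#' Each factor has an age-indexed marginal prevalence curve, a first-order
#' within-person persistence probability (calibrated so the marginal tracks
#' the curve), and additive litre offsets on FEV1 and FVC.
#'
#' @param asthma,smoking,obesity Lists with elements `prev` (function of
#'   age returning a probability), `persistence` (in \[0,1\]) and `effect`
#'   (named numeric: offsets in litres on FEV1 / FVC; smoking has separate
#'   `active` and `former` offsets).
#' @export
covariate_process <- function(
    asthma = list(prev = prevalence_fun(c(4, 10, 20, 60, 80),
                                        c(0.14, 0.14, 0.08, 0.08, 0.06)),
                  persistence = 0.70,
                  effect = c(FEV1 = -0.12, FVC = -0.04)),
    smoking = list(prev = prevalence_fun(c(4, 13, 18, 25, 45, 65, 80),
                                         c(0, 0, 0.20, 0.40, 0.40, 0.20, 0.12)),
                   persistence = 0.90,
                   effect = c(FEV1_active = -0.08, FVC_active = -0.04,
                              FEV1_former = -0.04, FVC_former = -0.02)),
    obesity = list(prev = prevalence_fun(c(4, 10, 20, 40, 65, 80),
                                         c(0.04, 0.04, 0.10, 0.20, 0.32, 0.30)),
                   persistence = 0.85,
                   effect = c(FEV1 = -0.05, FVC = -0.10))) {
  for (f in list(asthma, smoking, obesity))
    if (f$persistence < 0 || f$persistence > 1)
      stop("persistence must be in [0,1]")
  structure(list(asthma = asthma, smoking = smoking, obesity = obesity),
            class = "covariate_process")
}

#' Attrition model for the generator
#' @param mode One of `"none"`, `"MCAR"`, `"MAR"`.
#' @param mcar_rate Per-follow-up-visit drop probability (MCAR).
#' @param mar_coefficients Named coefficients of a logistic retention model
#'   on baseline covariates (`intercept`, `age`, `asthma`, `smoking`,
#'   `obesity`); non-retained participants keep only their first visit.
#' @export
attrition_model <- function(mode = c("none", "MCAR", "MAR"),
                            mcar_rate = 0.15,
                            mar_coefficients = c(intercept = 2.2,
                                                 age = -0.01, asthma = -0.5,
                                                 smoking = -0.7,
                                                 obesity = -0.5)) {
  mode <- match.arg(mode)
  if (mcar_rate < 0 || mcar_rate > 1) stop("mcar_rate must be in [0,1]")
  structure(list(mode = mode, mcar_rate = mcar_rate,
                 mar_coefficients = mar_coefficients),
            class = "attrition_model")
}

# logistic height growth to an adult asymptote, by sex
height_model_default <- function() {
  list(mean = function(age, sex) {
    adult <- ifelse(sex == "M", 177, 164)
    h4 <- ifelse(sex == "M", 101, 100)
    centre <- ifelse(sex == "M", 11.5, 10.5)
    h4 + (adult - h4) / (1 + exp(-(age - centre) / 2.2))
  },
  sd_individual = 5, sd_visit = 1.5)
}

#' Default eight-study accelerated-cohort designs
#'
#' Eight overlapping designs jointly covering ages 4-80, with sizes
#' proportional to the pooled study they emulate, scaled so that the
#' default accelerated cohort holds roughly `2 * n_per_sex` participants.
#'
#' @param n_per_sex Approximate participants per sex in the pooled cohort.
#' @export
default_designs <- function(n_per_sex = 6000) {
  s <- n_per_sex / 6000
  list(
    cohort_design("INMA",     round(360 * s), c(4, 11),  c(4, 7, 9, 11),    c(1998, 2006)),
    cohort_design("PIAMA",    round(340 * s), c(4, 16),  c(4, 8, 12, 16),   c(1990, 1998)),
    cohort_design("BAMSE",    round(800 * s), c(4, 24),  c(4, 8, 16, 24),   c(1985, 1996)),
    cohort_design("ALSPAC",   round(1400 * s), c(8, 24), c(8, 15, 24),      c(1985, 1993)),
    cohort_design("TAHS",     round(1180 * s), c(5, 53), c(7, 13, 18, 32, 43, 53), c(1955, 1965)),
    cohort_design("ECRHS",    round(3440 * s), c(20, 64), c(0, 9, 19),      c(1940, 1975),
                  entry_age_range = c(20, 44)),
    cohort_design("SAPALDIA", round(2600 * s), c(18, 80), c(0, 11, 20),     c(1925, 1972),
                  entry_age_range = c(18, 60)),
    cohort_design("VlaVla",   round(1880 * s), c(15, 80), c(0, 3, 6, 9, 12, 15, 19, 24), c(1901, 1965),
                  entry_age_range = c(15, 55), collect_fvc = FALSE))
}

#' Full synthetic-cohort configuration
#'
#' @param designs List of [cohort_design()] objects.
#' @param truths Named list of [true_trajectory()] keyed
#'   `"<parameter>.<sex>"`; defaults to the packaged paper-calibrated
#'   fixtures.
#' @param re_spec A [random_effect_spec()].
#' @param covariates A [covariate_process()].
#' @param attrition An [attrition_model()].
#' @param height_model List with `mean(age, sex)`, `sd_individual`,
#'   `sd_visit`.
#' @param seed Integer seed; together with the config it fully determines
#'   the output.
#' @export
synthetic_config <- function(designs = default_designs(),
                             truths = default_trajectories(),
                             re_spec = random_effect_spec(),
                             covariates = covariate_process(),
                             attrition = attrition_model("none"),
                             height_model = height_model_default(),
                             seed = 1L) {
  structure(list(designs = designs, truths = truths, re_spec = re_spec,
                 covariates = covariates, attrition = attrition,
                 height_model = height_model, seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic decorrelated sub-seeds for each design
design_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

empty_observation_table <- function() {
  data.frame(participant_id = character(), study = character(),
             sex = character(), birth_year = integer(),
             visit_index = integer(), age_years = numeric(),
             height_cm = numeric(), bmi = numeric(), fev1_L = numeric(),
             fvc_L = numeric(), asthma = integer(),
             smoking = character(), stringsAsFactors = FALSE)
}

# first-order two-state chain whose marginal tracks prev(age):
# P(present_j | present_{j-1}) = rho + (1-rho) p_j ; else (1-rho) p_j
covariate_chain <- function(ages, prev_fun, rho) {
  p <- prev_fun(ages)
  s <- logical(length(ages))
  s[1] <- stats::runif(1) < p[1]
  if (length(ages) > 1) for (j in 2:length(ages)) {
    pj <- rho * s[j - 1] + (1 - rho) * p[j]
    s[j] <- stats::runif(1) < pj
  }
  s
}

# BMI consistent with an obesity status, via the packaged child reference
draw_bmi <- function(age, sex, obese, ref) {
  n <- length(age)
  bmi <- numeric(n)
  for (i in seq_len(n)) {
    if (age[i] >= 19) {
      bmi[i] <- if (obese[i]) 30.5 + stats::rexp(1, 1 / 3)
                else min(29.5, stats::rnorm(1, 23.5, 2.2))
      bmi[i] <- max(bmi[i], 15)
    } else {
      m <- ref$median(age[i], sex[i]); s <- ref$sd(age[i], sex[i])
      z <- if (obese[i]) 2.1 + stats::rexp(1, 1.2)
           else min(1.9, stats::rnorm(1, 0.2, 0.9))
      bmi[i] <- m + s * min(z, 4)
    }
  }
  bmi
}

#' Simulate one source study
#'
#' Generates the realised person-visit table for a single cohort design:
#' visit ages are the planned ages with uniform +/- 1 year jitter (clipped
#' to the design's age window), lung function is the ground-truth curve
#' plus individual, study and birth-decade intercepts, covariate offsets
#' and residual noise, and covariate status evolves by a persistence chain
#' calibrated to the configured marginal prevalence curves.
#'
#' @param design A [cohort_design()].
#' @param truths,re_spec,covariates,attrition As in [synthetic_config()].
#' @param seed Integer seed.
#' @param height_model As in [synthetic_config()].
#' @param decade_effects Optional named numeric of birth-decade intercepts
#'   (names like `"1950"`); drawn internally when `NULL`. Supplied by
#'   [simulate_accelerated()] so the decade factor is shared across
#'   studies.
#' @param study_effect Optional study intercept (litres); drawn when
#'   `NULL`.
#' @return An observation table (one row per realised visit).
#' @export
simulate_cohort <- function(design, truths = default_trajectories(),
                            re_spec = random_effect_spec(),
                            covariates = covariate_process(),
                            attrition = attrition_model("none"),
                            seed = 1L,
                            height_model = height_model_default(),
                            decade_effects = NULL, study_effect = NULL) {
  if (!inherits(design, "cohort_design")) stop("invalid design")
  if (design$n_participants == 0L) return(empty_observation_table())
  set.seed(seed)
  ref <- bmi_reference()
  n <- design$n_participants
  if (is.null(study_effect))
    study_effect <- stats::rnorm(1, 0, re_spec$sd_study)
  decades <- seq(floor(design$birth_year_range[1] / 10) * 10,
                 floor(design$birth_year_range[2] / 10) * 10, by = 10)
  if (is.null(decade_effects)) {
    decade_effects <- stats::rnorm(length(decades), 0, re_spec$sd_birth_decade)
    names(decade_effects) <- as.character(decades)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    by <- sample(seq(design$birth_year_range[1], design$birth_year_range[2]), 1)
    dec <- as.character(floor(by / 10) * 10)
    dec_eff <- if (dec %in% names(decade_effects)) decade_effects[[dec]] else 0
    base_ages <- if (is.null(design$entry_age_range)) design$visit_ages
      else stats::runif(1, design$entry_age_range[1],
                        design$entry_age_range[2]) + design$visit_ages
    ages <- base_ages + stats::runif(length(base_ages), -1, 1)
    ages <- pmin(pmax(ages, design$age_window[1]), design$age_window[2])
    ages <- pmin(pmax(ages, 4), 80)
    ages <- sort(ages)
    nv <- length(ages)
    asth <- covariate_chain(ages, covariates$asthma$prev,
                            covariates$asthma$persistence)
    smk_active <- covariate_chain(ages, covariates$smoking$prev,
                                  covariates$smoking$persistence)
    ever_active <- cumsum(smk_active) > 0
    smoking <- ifelse(smk_active, "active",
                      ifelse(ever_active & !smk_active, "former", "never"))
    obese <- covariate_chain(ages, covariates$obesity$prev,
                             covariates$obesity$persistence)
    bmi <- draw_bmi(ages, rep(sex, nv), obese, ref)
    h_ind <- stats::rnorm(1, 0, height_model$sd_individual)
    height <- height_model$mean(ages, sex) + h_ind +
      stats::rnorm(nv, 0, height_model$sd_visit)
    ind_fev1 <- stats::rnorm(1, 0, re_spec$sd_individual)
    ind_fvc <- stats::rnorm(1, 0, re_spec$sd_individual)
    off_fev1 <- covariates$asthma$effect[["FEV1"]] * asth +
      covariates$smoking$effect[["FEV1_active"]] * (smoking == "active") +
      covariates$smoking$effect[["FEV1_former"]] * (smoking == "former") +
      covariates$obesity$effect[["FEV1"]] * obese
    off_fvc <- covariates$asthma$effect[["FVC"]] * asth +
      covariates$smoking$effect[["FVC_active"]] * (smoking == "active") +
      covariates$smoking$effect[["FVC_former"]] * (smoking == "former") +
      covariates$obesity$effect[["FVC"]] * obese
    tr_fev1 <- truths[[paste0("FEV1.", sex)]]
    tr_fvc <- truths[[paste0("FVC.", sex)]]
    fev1 <- eval_true_trajectory(tr_fev1, ages) + ind_fev1 + study_effect +
      dec_eff + off_fev1 + stats::rnorm(nv, 0, re_spec$sd_residual)
    fvc <- if (design$collect_fvc)
      eval_true_trajectory(tr_fvc, ages) + ind_fvc + study_effect +
        dec_eff + off_fvc + stats::rnorm(nv, 0, re_spec$sd_residual)
    else rep(NA_real_, nv)
    keep <- rep(TRUE, nv)
    if (attrition$mode == "MCAR" && nv > 1) {
      keep[-1] <- stats::runif(nv - 1) >= attrition$mcar_rate
    } else if (attrition$mode == "MAR" && nv > 1) {
      b <- attrition$mar_coefficients
      lp <- b[["intercept"]] + b[["age"]] * ages[1] + b[["asthma"]] * asth[1] +
        b[["smoking"]] * (smoking[1] == "active") + b[["obesity"]] * obese[1]
      if (stats::runif(1) >= stats::plogis(lp)) keep[-1] <- FALSE
    }
    rows[[i]] <- data.frame(
      participant_id = sprintf("%s_%05d", design$study_label, i),
      study = design$study_label, sex = sex, birth_year = by,
      visit_index = seq_len(nv), age_years = ages, height_cm = height,
      bmi = bmi, fev1_L = fev1, fvc_L = fvc, asthma = as.integer(asth),
      smoking = smoking, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the pooled accelerated cohort
#'
#' Draws study and birth-decade intercepts once (so the decade factor is
#' crossed, shared across studies), then simulates each design with a
#' deterministic sub-seed and pools the tables. Warns if the designs leave
#' an age gap wider than 5 years anywhere in 4-80.
#'
#' @param config A [synthetic_config()].
#' @return Pooled observation table; the drawn study and decade effects are
#'   attached as attributes `study_effects` and `decade_effects`.
#' @export
simulate_accelerated <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  des <- config$designs
  # coverage check
  wins <- do.call(rbind, lapply(des, function(d) d$age_window))
  grid <- seq(4, 80, by = 0.5)
  covered <- vapply(grid, function(a)
    any(wins[, 1] <= a & wins[, 2] >= a), logical(1))
  if (any(!covered)) {
    runs <- rle(!covered)
    if (max(runs$lengths[runs$values]) * 0.5 > 5)
      warning("designs leave an age gap wider than 5 years in [4, 80]")
  }
  set.seed(config$seed)
  study_effects <- stats::rnorm(length(des), 0, config$re_spec$sd_study)
  names(study_effects) <- vapply(des, `[[`, "", "study_label")
  all_years <- unlist(lapply(des, `[[`, "birth_year_range"))
  decades <- seq(floor(min(all_years) / 10) * 10,
                 floor(max(all_years) / 10) * 10, by = 10)
  decade_effects <- stats::rnorm(length(decades), 0,
                                 config$re_spec$sd_birth_decade)
  names(decade_effects) <- as.character(decades)
  seeds <- design_seeds(config$seed, length(des))
  tabs <- lapply(seq_along(des), function(i)
    simulate_cohort(des[[i]], config$truths, config$re_spec,
                    config$covariates, config$attrition, seeds[i],
                    config$height_model, decade_effects,
                    study_effects[[i]]))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "study_effects") <- study_effects
  attr(out, "decade_effects") <- decade_effects
  out
}

#' Write / read an observation table as CSV
#'
#' UTF-8, header row, '.' decimal separator.
#' @param table Observation table.
#' @param path File path.
#' @export
write_observation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
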