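#' Child BMI-for-age reference (synthetic)
#'
#' Loads the packaged synthetic BMI-for-age reference table (ages 4-18,
#' both sexes). The table is a smooth stand-in with WHO-like medians and
#' SDs, constructed for this package because the official growth reference
#' is not redistributed here; it is labelled synthetic in its filename.
#'
#' @return List with functions `median(age, sex)` and `sd(age, sex)`
#'   (linear interpolation in age, constant beyond 4-18).
#' @export
bmi_reference <- function() {
  path <- system.file("extdata", "bmi_reference_synthetic.csv",
                      package = "lifespiro", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  interp <- function(col) {
    function(age, sex) {
      out <- numeric(length(age))
      for (s in unique(sex)) {
        sub <- tab[tab$sex == s, ]
        i <- sex == s
        out[i] <- stats::approx(sub$age_years, sub[[col]],
                                xout = age[i], rule = 2)$y
      }
      out
    }
  }
  list(median = interp("median_bmi"), sd = interp("sd_bmi"))
}

#' Obesity flag from BMI
#'
#' Adults (age >= 19 years) are flagged at BMI >= 30; children are flagged
#' when the BMI-for-age z-score against the packaged reference is >= +2.
#'
#' @param age,sex,bmi Vectors (recycled to common length).
#' @param reference Reference list from [bmi_reference()].
#' @return Integer vector of 0/1 flags.
#' @export
obesity_flag <- function(age, sex, bmi, reference = bmi_reference()) {
  n <- max(length(age), length(sex), length(bmi))
  age <- rep_len(age, n); sex <- rep_len(sex, n); bmi <- rep_len(bmi, n)
  if (any(age < 4)) stop("age below 4 is outside the supported range")
  if (any(bmi <= 0)) stop("bmi must be positive")
  adult <- age >= 19
  flag <- integer(n)
  flag[adult] <- as.integer(bmi[adult] >= 30)
  if (any(!adult)) {
    z <- (bmi[!adult] - reference$median(age[!adult], sex[!adult])) /
      reference$sd(age[!adult], sex[!adult])
    flag[!adult] <- as.integer(z >= 2)
  }
  flag
}

# add the obesity column if absent (derived from BMI)
ensure_obesity <- function(table) {
  if (!"obesity" %in% names(table))
    table$obesity <- obesity_flag(table$age_years, table$sex, table$bmi)
  table
}

# add birth_decade column
ensure_birth_decade <- function(table) {
  if (!"birth_decade" %in% names(table))
    table$birth_decade <- floor(table$birth_year / 10) * 10
  table
}

#' Apply the inclusion rules
#'
#' Observations outside ages 4-80 are dropped first; then participants
#' with fewer than two complete visits (non-missing lung function, smoking
#' status, BMI and asthma status) are dropped.
#'
#' @param table Observation table.
#' @param parameter Which lung-function column defines completeness:
#'   `"FEV1"`, `"FVC"`, `"FEV1/FVC"` or `NULL` (any of FEV1/FVC present).
#' @param verbose Log row/participant counts.
#' @return Filtered table (attributes `n_dropped_rows`,
#'   `n_dropped_participants` record the losses).
#' @export
apply_inclusion <- function(table, parameter = NULL, verbose = FALSE) {
  n0 <- nrow(table)
  table <- table[table$age_years >= 4 & table$age_years <= 80, , drop = FALSE]
  lf_ok <- switch(if (is.null(parameter)) "any" else parameter,
                  "FEV1" = !is.na(table$fev1_L),
                  "FVC" = !is.na(table$fvc_L),
                  "FEV1/FVC" = !is.na(table$fev1_L) & !is.na(table$fvc_L),
                  "any" = !is.na(table$fev1_L) | !is.na(table$fvc_L))
  complete <- lf_ok & !is.na(table$smoking) & !is.na(table$bmi) &
    !is.na(table$asthma)
  nvis <- tapply(complete, table$participant_id, sum)
  keep_ids <- names(nvis)[nvis >= 2]
  out <- table[complete & table$participant_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0) stop("empty cohort after inclusion rules")
  attr(out, "n_dropped_rows") <- n0 - nrow(out)
  attr(out, "n_dropped_participants") <-
    length(unique(table$participant_id)) - length(unique(out$participant_id))
  if (verbose)
    message(sprintf("inclusion: kept %d rows from %d participants",
                    nrow(out), length(unique(out$participant_id))))
  rownames(out) <- NULL
  out
}

#' Life-course persistence category of a risk factor
#'
#' `persistent` when present at every visit, `never` when absent at every
#' visit, `transient` otherwise. Smoking counts as present when the
#' participant is an active smoker at the visit.
#'
#' @param present Logical vector of per-visit presence (>= 2 visits).
#' @return One of `"never"`, `"transient"`, `"persistent"`.
#' @export
classify_persistence <- function(present) {
  if (any(is.na(present))) stop("missing factor status")
  if (length(present) < 2) stop("need at least two visits")
  if (all(present)) "persistent" else if (!any(present)) "never"
  else "transient"
}

#' Per-participant life-course categories for asthma, smoking and obesity
#'
#' @param table Included observation table (obesity derived from BMI if
#'   absent).
#' @return Data frame with one row per participant and columns
#'   `asthma_cat`, `smoking_cat`, `obesity_cat`.
#' @export
life_course_categories <- function(table) {
  table <- ensure_obesity(table)
  sp <- split(table, table$participant_id)
  out <- data.frame(
    participant_id = names(sp),
    asthma_cat = vapply(sp, function(d) classify_persistence(d$asthma == 1), ""),
    smoking_cat = vapply(sp, function(d)
      classify_persistence(d$smoking == "active"), ""),
    obesity_cat = vapply(sp, function(d) classify_persistence(d$obesity == 1), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# merge undersized (sex, integer-age) strata with the nearest age stratum,
# lower age first on ties, until every stratum reaches min_size
pool_strata <- function(age_int, min_size) {
  groups <- sort(unique(age_int))
  members <- lapply(groups, function(g) which(age_int == g))
  centre <- as.numeric(groups)
  repeat {
    sizes <- lengths(members)
    if (length(sizes) <= 1 || all(sizes >= min_size)) break
    i <- which(sizes < min_size)[1]
    cand <- setdiff(seq_along(members), i)
    d <- abs(centre[cand] - centre[i])
    j <- cand[order(d, centre[cand])][1]
    members[[j]] <- c(members[[j]], members[[i]])
    centre[j] <- min(centre[j], centre[i])  # label by lower age
    members <- members[-i]; centre <- centre[-i]
  }
  lab <- integer(length(age_int))
  for (g in seq_along(members)) lab[members[[g]]] <- g
  lab
}

#' Standardise lung function for height and study within age strata
#'
#' Within each (sex, integer-age) stratum -- pooling adjacent ages until at
#' least `min_stratum` observations are available -- the lung-function
#' value is regressed on height and study indicators, and replaced by its
#' residual re-centred at the stratum mean fitted value. This removes the
#' within-stratum height slope and the between-study mean differences
#' while preserving the stratum mean on the litres scale.
#'
#' @param table Included observation table.
#' @param parameter `"FEV1"`, `"FVC"` or `"FEV1/FVC"`.
#' @param min_stratum Minimum observations per stratum after pooling.
#' @return `table` with the ratio column added when needed and a new
#'   `lf_std` column (litres, or the dimensionless ratio).
#' @export
standardize_lf <- function(table, parameter = "FEV1", min_stratum = 10) {
  lf <- switch(parameter,
               "FEV1" = table$fev1_L,
               "FVC" = table$fvc_L,
               "FEV1/FVC" = table$fev1_L / table$fvc_L,
               stop("unknown parameter"))
  if (any(is.na(lf))) stop("missing lung function; apply inclusion first")
  table$lf_value <- lf
  table$lf_std <- NA_real_
  age_int <- round(table$age_years)
  for (s in unique(table$sex)) {
    idx <- which(table$sex == s)
    if (length(idx) < min_stratum)
      stop(sprintf("sex stratum %s has fewer than %d observations",
                   s, min_stratum))
    lab <- pool_strata(age_int[idx], min_stratum)
    for (g in unique(lab)) {
      rows <- idx[lab == g]
      d <- data.frame(y = table$lf_value[rows],
                      height = table$height_cm[rows],
                      study = table$study[rows])
      terms <- c(if (stats::sd(d$height) > 1e-9) "height",
                 if (length(unique(d$study)) > 1) "study")
      f <- stats::as.formula(paste("y ~",
                                   if (length(terms)) paste(terms, collapse = " + ")
                                   else "1"))
      fit <- stats::lm(f, data = d)
      table$lf_std[rows] <- stats::residuals(fit) + mean(stats::fitted(fit))
    }
  }
  table
}

# 95% Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  cen <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lo = pmax(0, cen - hw), hi = pmin(1, cen + hw))
}

#' Smoothed prevalence curve of a risk factor by year of age
#'
#' Raw per-integer-age proportions (person-visits as the unit) with Wilson
#' 95% intervals, each LOESS-smoothed with the given span.
#'
#' @param table Observation table.
#' @param factor One of `"asthma"`, `"smoking"` (active at visit),
#'   `"obesity"`.
#' @param span LOESS span (default 0.4).
#' @return Data frame `(age, pct, lo, hi)` in percent.
#' @export
prevalence_curves <- function(table, factor, span = 0.4) {
  if (factor == "obesity") table <- ensure_obesity(table)
  present <- switch(factor,
                    asthma = table$asthma == 1,
                    smoking = table$smoking == "active",
                    obesity = table$obesity == 1,
                    stop(sprintf("no such factor column: %s", factor)))
  age <- round(table$age_years)
  agg <- stats::aggregate(present, list(age = age),
                          function(v) c(x = sum(v), n = length(v)))
  ages <- agg$age; x <- agg$x[, "x"]; n <- agg$x[, "n"]
  p <- 100 * x / n
  ci <- 100 * wilson_ci(x, n)
  sm <- function(y) {
    if (length(ages) < 10) return(y)
    fit <- stats::loess(y ~ ages, span = span, degree = 2,
                        family = "gaussian")
    stats::predict(fit, newdata = data.frame(ages = ages))
  }
  data.frame(age = ages, pct = sm(p), lo = sm(ci[, "lo"]),
             hi = sm(ci[, "hi"]))
}
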