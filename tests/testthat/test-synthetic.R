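schema_cols <- c("participant_id", "study", "sex", "birth_year",
                 "visit_index", "age_years", "height_cm", "bmi", "fev1_L",
                 "fvc_L", "asthma", "smoking")

toy_truths <- function() {
  tr <- toy_truth()
  list(FEV1.F = tr, FEV1.M = tr, FVC.F = tr, FVC.M = tr)
}

test_that("zero participants give an empty table with the full schema", {
  d <- cohort_design("X", 0, c(4, 24), c(5, 10), c(1990, 1995))
  out <- simulate_cohort(d, toy_truths())
  expect_identical(names(out), schema_cols)
  expect_equal(nrow(out), 0)
})

test_that("with all noise off every value equals the true trajectory", {
  cov0 <- covariate_process(
    asthma = list(prev = function(a) rep(0.3, length(a)), persistence = 0.5,
                  effect = c(FEV1 = 0, FVC = 0)),
    smoking = list(prev = function(a) rep(0.2, length(a)), persistence = 0.5,
                   effect = c(FEV1_active = 0, FVC_active = 0,
                              FEV1_former = 0, FVC_former = 0)),
    obesity = list(prev = function(a) rep(0.2, length(a)), persistence = 0.5,
                   effect = c(FEV1 = 0, FVC = 0)))
  out <- simulate_cohort(small_design(30), toy_truths(),
                         quiet_spec(), cov0, seed = 5)
  expect_equal(out$fev1_L,
               eval_true_trajectory(toy_truth(), out$age_years),
               tolerance = 1e-12)
  expect_equal(out$fvc_L,
               eval_true_trajectory(toy_truth(), out$age_years),
               tolerance = 1e-12)
})

test_that("Monte-Carlo mean at a scheduled age matches truth plus covariate offset", {
  # all visits at fixed ages, no jitter impossible: use tight window so the
  # first visit age stays near 8; average over participants
  d <- cohort_design("MC", 2000, c(7.9, 24), c(8, 16, 24), c(1985, 1996))
  re <- random_effect_spec(0.1, 0, 0, 0.15)
  prev <- 0.4
  eff <- -0.2
  covc <- covariate_process(
    asthma = list(prev = function(a) rep(prev, length(a)), persistence = 0.5,
                  effect = c(FEV1 = eff, FVC = 0)),
    smoking = list(prev = function(a) rep(0, length(a)), persistence = 0.5,
                   effect = c(FEV1_active = 0, FVC_active = 0,
                              FEV1_former = 0, FVC_former = 0)),
    obesity = list(prev = function(a) rep(0, length(a)), persistence = 0.5,
                   effect = c(FEV1 = 0, FVC = 0)))
  out <- simulate_cohort(d, toy_truths(), re, covc, seed = 11)
  first <- out[out$visit_index == 1, ]
  expected <- mean(eval_true_trajectory(toy_truth(), first$age_years)) +
    prev * eff
  se <- sqrt(0.1^2 + 0.15^2 + prev * (1 - prev) * eff^2) / sqrt(nrow(first))
  expect_lt(abs(mean(first$fev1_L) - expected), 3 * se + 0.01)
  # empirical asthma prevalence tracks the configured rate
  expect_lt(abs(mean(out$asthma) - prev), 3 * sqrt(prev * (1 - prev) /
                                                     nrow(out)) + 0.02)
})

test_that("default accelerated cohort covers every 5-year age bin in 4-80", {
  cfg <- synthetic_config(designs = default_designs(900), seed = 2)
  tab <- simulate_accelerated(cfg)
  bins <- cut(tab$age_years, c(seq(4, 79, by = 5), 80),
              include.lowest = TRUE)
  expect_true(all(table(bins) > 0))
  expect_equal(sort(unique(tab$study)),
               sort(vapply(cfg$designs, `[[`, "", "study_label")))
  # observations per participant stay in the designed 2-8 range
  nv <- table(tab$participant_id)
  expect_true(all(nv >= 2 & nv <= 8))
})

test_that("pooling a single design reduces to simulate_cohort", {
  d <- small_design(40)
  cfg <- synthetic_config(designs = list(d), truths = toy_truths(),
                          seed = 9)
  acc <- suppressWarnings(simulate_accelerated(cfg))
  single <- simulate_cohort(d, toy_truths(), cfg$re_spec, cfg$covariates,
                            cfg$attrition,
                            seed = lifespiro:::design_seeds(9, 1),
                            decade_effects = attr(acc, "decade_effects"),
                            study_effect = attr(acc, "study_effects")[[1]])
  acc2 <- acc
  attributes(acc2) <- attributes(acc2)[c("names", "class", "row.names")]
  expect_equal(acc2, single)
})

test_that("same seed reproduces the table exactly; different seeds differ", {
  cfg <- synthetic_config(designs = list(small_design(30)),
                          truths = toy_truths(), seed = 4)
  a <- suppressWarnings(simulate_accelerated(cfg))
  b <- suppressWarnings(simulate_accelerated(cfg))
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 5L
  c2 <- suppressWarnings(simulate_accelerated(cfg2))
  expect_false(isTRUE(all.equal(a$fev1_L, c2$fev1_L)))
})

test_that("attrition prunes follow-up visits and MAR depends on covariates", {
  d <- small_design(400)
  mcar <- simulate_cohort(d, toy_truths(),
                          attrition = attrition_model("MCAR",
                                                      mcar_rate = 0.5),
                          seed = 3)
  none <- simulate_cohort(d, toy_truths(), seed = 3)
  expect_lt(nrow(mcar), nrow(none))
  expect_true(all(mcar$visit_index[!duplicated(mcar$participant_id)] == 1))
  mar <- simulate_cohort(d, toy_truths(),
                         attrition = attrition_model("MAR"), seed = 3)
  nv <- tapply(mar$visit_index, mar$participant_id, length)
  expect_true(any(nv == 1))  # some participants lost after baseline
})

test_that("designs leaving a wide age gap trigger a warning", {
  d1 <- cohort_design("A", 5, c(4, 10), c(5, 9), c(1990, 1995))
  d2 <- cohort_design("B", 5, c(40, 50), c(41, 49), c(1950, 1960))
  cfg <- synthetic_config(designs = list(d1, d2), truths = toy_truths(),
                          seed = 1)
  expect_warning(simulate_accelerated(cfg), "gap")
})

test_that("CSV round-trip preserves the table", {
  out <- simulate_cohort(small_design(10), toy_truths(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observation_table(out, path)
  back <- read_observation_table(path)
  expect_equal(back$fev1_L, out$fev1_L, tolerance = 1e-12)
  expect_identical(names(back), names(out))
})
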