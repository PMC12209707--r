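test_that("inclusion drops out-of-range observations before visit counting", {
  tab <- manual_table(data.frame(
    participant_id = c("a", "a", "a", "b", "b", "c"),
    age_years = c(63, 79, 82, 30, 40, 50)))
  out <- apply_inclusion(tab)
  # the 82-year observation goes first, but its participant keeps 2 visits
  expect_equal(sort(unique(out$participant_id)), c("a", "b"))
  expect_equal(nrow(out[out$participant_id == "a", ]), 2)
  # participant c has a single visit and is excluded
  expect_false("c" %in% out$participant_id)
})

test_that("participants with missing components are excluded and inclusion is idempotent", {
  tab <- manual_table(data.frame(
    participant_id = c("a", "a", "b", "b", "d", "d"),
    age_years = c(10, 20, 10, 20, 10, 20)))
  tab$bmi[3] <- NA  # b keeps only one complete visit
  out <- apply_inclusion(tab)
  expect_equal(sort(unique(out$participant_id)), c("a", "d"))
  expect_equal(apply_inclusion(out), out, ignore_attr = TRUE)
  # complete table passes unchanged
  ok <- manual_table(data.frame(participant_id = c("x", "x"),
                                age_years = c(5, 9)))
  expect_equal(apply_inclusion(ok), ok, ignore_attr = TRUE)
  expect_error(apply_inclusion(tab[3:4, ]), "empty")
})

test_that("persistence classification follows the all/none/some rule", {
  expect_equal(classify_persistence(c(TRUE, TRUE, TRUE)), "persistent")
  expect_equal(classify_persistence(c(TRUE, FALSE)), "transient")
  expect_equal(classify_persistence(c(FALSE, FALSE)), "never")
  expect_error(classify_persistence(c(TRUE, NA)), "missing")
  expect_error(classify_persistence(TRUE), "two visits")
})

test_that("life-course categories use active smoking as presence and partition participants", {
  tab <- manual_table(data.frame(
    participant_id = rep(c("a", "b", "c"), each = 2),
    age_years = rep(c(30, 40), 3),
    smoking = c("active", "active", "active", "never", "never", "former")))
  cats <- life_course_categories(tab)
  expect_equal(cats$smoking_cat[cats$participant_id == "a"], "persistent")
  expect_equal(cats$smoking_cat[cats$participant_id == "b"], "transient")
  # former-only counts as not currently active -> never "present"
  expect_equal(cats$smoking_cat[cats$participant_id == "c"], "never")
  for (f in c("asthma_cat", "smoking_cat", "obesity_cat"))
    expect_equal(length(cats[[f]]), 3)
})

test_that("obesity flags use BMI 30 for adults and z >= 2 for children", {
  expect_equal(obesity_flag(35, "F", 31), 1L)
  expect_equal(obesity_flag(35, "F", 22), 0L)
  expect_equal(obesity_flag(19, "M", 29.9), 0L)
  expect_error(obesity_flag(3, "F", 20), "range")
  # child flags recomputed against a direct table-lookup z oracle
  ref_tab <- read.csv(system.file("extdata", "bmi_reference_synthetic.csv",
                                  package = "lifespiro"))
  sub <- ref_tab[ref_tab$sex == "F" & ref_tab$age_years == 8, ]
  for (bmi in seq(14, 26, by = 0.5)) {
    z <- (bmi - sub$median_bmi) / sub$sd_bmi
    expect_equal(obesity_flag(8, "F", bmi), as.integer(z >= 2),
                 info = paste("bmi", bmi))
  }
})

test_that("standardisation removes height and study effects but keeps stratum means", {
  set.seed(42)
  n <- 120
  tab <- manual_table(data.frame(
    participant_id = rep(sprintf("p%03d", 1:(n / 2)), each = 2),
    age_years = rep(30, n),
    study = rep(c("S1", "S2"), n / 2),
    height_cm = rnorm(n, 165, 7)))
  tab$fev1_L <- 2 + 0.02 * (tab$height_cm - 165) +
    0.3 * (tab$study == "S2") + rnorm(n, 0, 0.1)
  std <- standardize_lf(tab, "FEV1")
  # brute-force stratum regression oracle on the standardised values
  fit <- lm(lf_std ~ height_cm + study, data = std)
  expect_lt(abs(coef(fit)[["height_cm"]]), 1e-8)
  expect_lt(abs(coef(fit)[["studyS2"]]), 1e-8)
  expect_equal(mean(std$lf_std), mean(std$lf_value), tolerance = 1e-8)
})

test_that("single study with equal heights leaves values untouched", {
  tab <- manual_table(data.frame(
    participant_id = rep(sprintf("p%02d", 1:10), each = 2),
    age_years = rep(50, 20), height_cm = 170,
    fev1_L = rnorm(20, 3, 0.2)))
  std <- standardize_lf(tab, "FEV1")
  expect_equal(std$lf_std, std$lf_value, tolerance = 1e-12)
})

test_that("sparse strata pool towards the nearest age and tiny sex groups error", {
  set.seed(7)
  ages <- c(rep(30, 12), rep(31, 3))  # age-31 stratum below the minimum
  tab <- manual_table(data.frame(
    participant_id = rep(sprintf("q%02d", 1:5), 3),
    age_years = ages, height_cm = rnorm(15, 165, 6)))
  tab$fev1_L <- 2 + 0.01 * tab$height_cm + rnorm(15, 0, 0.05)
  std <- standardize_lf(tab, "FEV1")
  expect_true(all(is.finite(std$lf_std)))
  small <- tab[1:4, ]
  expect_error(standardize_lf(small, "FEV1"), "fewer than")
})

test_that("ratio standardisation works from per-observation ratios", {
  tab <- manual_table(data.frame(
    participant_id = rep(sprintf("r%02d", 1:10), each = 2),
    age_years = rep(40, 20), height_cm = rnorm(20, 170, 5)))
  std <- standardize_lf(tab, "FEV1/FVC")
  expect_equal(std$lf_value, tab$fev1_L / tab$fvc_L)
})

test_that("prevalence curves: degenerate zero factor, constant rate, default span", {
  expect_equal(formals(prevalence_curves)$span, 0.4)
  set.seed(3)
  n_per_age <- 400
  ages <- rep(4:80, each = n_per_age)
  tab <- manual_table(data.frame(
    participant_id = sprintf("s%06d", seq_along(ages)),
    age_years = ages,
    asthma = rbinom(length(ages), 1, 0.3)))
  tab$visit_index <- 1L
  curve <- prevalence_curves(tab, "asthma")
  inner <- curve[curve$age > 10 & curve$age < 74, ]
  # Monte-Carlo oracle: smoothed curve stays within its own CI of 30%
  expect_true(all(inner$lo < 30 & inner$hi > 30))
  expect_lt(max(abs(inner$pct - 30)), 3)
  tab0 <- tab; tab0$asthma <- 0L
  z <- prevalence_curves(tab0, "asthma")
  expect_true(all(abs(z$pct) < 1e-8))
  expect_error(prevalence_curves(tab, "eosinophilia"), "factor")
})
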