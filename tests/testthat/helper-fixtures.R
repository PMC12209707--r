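# small deterministic building blocks shared across tests

toy_truth <- function() true_trajectory(4, 1.0, c(10, 20), c(0.2, 0.1, -0.03))

quiet_spec <- function() random_effect_spec(0, 0, 0, 0)

small_design <- function(n = 50, label = "TOY")
  cohort_design(label, n, c(4, 24), c(4, 8, 16, 24), c(1985, 1996))

# observation table built by hand, bypassing the generator
manual_table <- function(df) {
  defaults <- list(height_cm = 150, bmi = 20, fev1_L = 2, fvc_L = 2.5,
                   asthma = 0L, smoking = "never", birth_year = 1980L,
                   sex = "F", study = "S1")
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$visit_index))
    df$visit_index <- stats::ave(seq_len(nrow(df)), df$participant_id,
                                 FUN = seq_along)
  df
}

balanced_oneway <- function(a = 8, n = 5, mu = 2, sb = 0.5, se = 0.3,
                            seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", 1:a), each = n)
  y <- mu + rep(rnorm(a, 0, sb), each = n) + rnorm(a * n, 0, se)
  tab <- manual_table(data.frame(
    participant_id = g,
    age_years = runif(a * n, 10, 70)))
  tab$lf_std <- y
  tab
}

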