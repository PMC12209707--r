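#' Fit the cross-classified three-level linear mixed model
#'
#' Observations (level 1) are nested in participants (level 2), who are
#' cross-classified by study and 10-year birth cohort (level 3); each
#' grouping enters as a random intercept. Fixed effects are a natural
#' cubic spline in age plus visit-level asthma, smoking (never / former /
#' active) and obesity, each interacted with the spline.
#'
#' @param table Standardised observation table (needs `lf_std`; obesity
#'   and birth decade are derived when absent).
#' @param n_knots Internal spline knots (1-6); 0 drops the age effect
#'   entirely (intercept-only fixed part, useful for degenerate checks).
#' @param method `"ML"` (used for BIC comparison) or `"REML"`.
#' @param weights Optional per-observation weights (scale each
#'   observation's contribution to the likelihood through the residual
#'   precision).
#' @param covariates Include the covariate main effects and interactions.
#' @param re Character subset of `c("participant", "study",
#'   "birth_decade")`; groupings with fewer than two observed levels are
#'   dropped with a warning, and with none left the model reduces to
#'   (weighted) least squares.
#' @return A `ccmm_fit`: fixed effects `beta` with covariance `cov_beta`,
#'   variance components `vc` (litres^2), `logLik`, `BIC` (with all
#'   estimated parameters counted against `n_obs`), the basis spec and
#'   convergence information.
#' @export
fit_ccmm <- function(table, n_knots = 4, method = c("ML", "REML"),
                     weights = NULL, covariates = TRUE,
                     re = c("participant", "study", "birth_decade")) {
  method <- match.arg(method)
  table <- ensure_obesity(ensure_birth_decade(table))
  if (!"lf_std" %in% names(table)) stop("run standardize_lf first")
  if (n_knots == 0) {
    spec <- NULL
    X <- matrix(numeric(0), nrow(table), 0)
  } else {
    B0 <- ncs_basis(table$age_years, n_knots)
    spec <- attr(B0, "basis_spec")
    X <- build_design(table$age_years, table$asthma, table$smoking,
                      table$obesity, spec, covariates)
  }
  # drop aliased columns (sparse covariate-by-spline cells)
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    keep <- sort(setdiff(q$pivot[seq_len(q$rank)], 1L)) - 1L
    X <- X[, keep, drop = FALSE]
  }
  dat <- data.frame(y = table$lf_std, X, check.names = FALSE)
  dat$.pid <- factor(table$participant_id)
  dat$.study <- factor(table$study)
  dat$.bdec <- factor(table$birth_decade)
  gvar <- c(participant = ".pid", study = ".study",
            birth_decade = ".bdec")[re]
  nlev <- vapply(gvar, function(g) nlevels(dat[[g]]), 0L)
  if (any(nlev < 2)) {
    warning(sprintf("dropping random effect(s) with < 2 levels: %s",
                    paste(names(gvar)[nlev < 2], collapse = ", ")))
    gvar <- gvar[nlev >= 2]
  }
  fxt <- if (ncol(X)) paste(sprintf("`%s`", colnames(X)), collapse = " + ")
         else "1"
  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  dat$.w <- w
  n <- nrow(dat)
  if (length(gvar) == 0L) {
    fit <- stats::lm(stats::as.formula(paste("y ~", fxt)), data = dat,
                     weights = .w)
    beta <- stats::coef(fit)
    vc <- c(residual = summary(fit)$sigma^2)
    ll <- as.numeric(stats::logLik(fit))
    p <- length(beta) + 1
    res <- list(beta = beta, cov_beta = stats::vcov(fit), vc = vc,
                logLik = ll, BIC = -2 * ll + p * log(n), n_obs = n, p = p,
                converged = TRUE, fit = fit, engine = "lm")
  } else {
    fml <- stats::as.formula(paste(
      "y ~", fxt, "+",
      paste(sprintf("(1 | %s)", gvar), collapse = " + ")))
    fit <- lme4::lmer(fml, data = dat, REML = (method == "REML"),
                      weights = .w,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(fit)
    vcmat <- as.data.frame(lme4::VarCorr(fit))
    vc <- stats::setNames(vcmat$vcov, vcmat$grp)
    names(vc) <- sub("^\\.pid$", "participant", names(vc))
    names(vc) <- sub("^\\.study$", "study", names(vc))
    names(vc) <- sub("^\\.bdec$", "birth_decade", names(vc))
    names(vc) <- sub("^Residual$", "residual", names(vc))
    ll <- as.numeric(stats::logLik(fit))
    p <- length(beta) + length(vc)  # fixed effects + variances (incl resid)
    conv <- length(fit@optinfo$conv$lme4) == 0
    res <- list(beta = beta, cov_beta = as.matrix(stats::vcov(fit)),
                vc = vc, logLik = ll, BIC = -2 * ll + p * log(n),
                n_obs = n, p = p, converged = conv, fit = fit,
                engine = "lmer")
  }
  res$method <- method
  res$basis_spec <- spec
  res$n_knots <- n_knots
  res$covariates <- covariates
  res$x_cols <- colnames(X)
  class(res) <- "ccmm_fit"
  res
}

#' Elbow selection on a BIC curve
#'
#' The elbow is the knot count maximising the (signed) perpendicular
#' distance below the chord joining the first and last points of the BIC
#' curve; ties resolve to the smallest count, so a monotone non-decreasing
#' or exactly linear curve selects the smallest candidate.
#'
#' @param k Candidate knot counts.
#' @param bic Corresponding BIC values.
#' @return Selected element of `k`.
#' @export
elbow_select <- function(k, bic) {
  stopifnot(length(k) == length(bic), length(k) >= 2)
  dx <- k[length(k)] - k[1]; dy <- bic[length(bic)] - bic[1]
  len <- sqrt(dx^2 + dy^2)
  # positive when the point lies below the chord
  d <- (dy * (k - k[1]) - dx * (bic - bic[1])) / len
  d[d < 1e-9] <- 0
  k[which.max(d)]  # which.max takes the first (smallest k) on ties
}

#' Select the spline knot count by the BIC elbow
#'
#' Fits the cross-classified model by maximum likelihood for each knot
#' count in `kmin..kmax` and picks the elbow of the BIC curve.
#'
#' @inheritParams fit_ccmm
#' @param kmin,kmax Knot-count range (within 1..6).
#' @return List with the selected `k` and the `bic` curve (named by k).
#' @export
select_knots <- function(table, kmin = 1, kmax = 6, weights = NULL,
                         covariates = TRUE,
                         re = c("participant", "study", "birth_decade")) {
  ks <- seq(kmin, kmax)
  bic <- vapply(ks, function(k) {
    f <- tryCatch(fit_ccmm(table, k, "ML", weights, covariates, re),
                  error = function(e)
                    stop(sprintf("fit failed at k = %d: %s", k,
                                 conditionMessage(e))))
    f$BIC
  }, 0)
  k_sel <- if (length(ks) == 1) ks else elbow_select(ks, bic)
  list(k = k_sel, bic = stats::setNames(bic, ks))
}

#' Predict the trajectory at each integer age
#'
#' Fixed-effect predictions (random effects at zero) on the grid of
#' integer ages 4-80. In `marginal` mode the prediction at each age
#' averages over the empirical joint distribution of asthma, smoking and
#' obesity among observations at that (rounded) age, borrowing the nearest
#' observed age when a grid age has no data; `reference` mode uses one
#' fixed covariate profile. The 95% CI comes from the delta method on the
#' fixed-effect covariance; the SD column is the model-implied
#' between-value SD (sum of variance components).
#'
#' @param fit A `ccmm_fit`.
#' @param table The analysis table the model was fitted to (source of the
#'   empirical covariate profiles).
#' @param profile_mode `"marginal"` or `"reference"`.
#' @param ages Prediction grid (default exactly 4..80).
#' @param reference_profile List with `asthma`, `smoking`, `obesity` used
#'   in reference mode.
#' @return Data frame `(age, mean, sd, lo95, hi95)` with attribute
#'   `borrowed_ages` listing grid ages that used a neighbour's profiles.
#' @export
predict_trajectory <- function(fit, table,
                               profile_mode = c("marginal", "reference"),
                               ages = 4:80,
                               reference_profile = list(
                                 asthma = 0, smoking = "never", obesity = 0)) {
  profile_mode <- match.arg(profile_mode)
  stopifnot(inherits(fit, "ccmm_fit"))
  table <- ensure_obesity(table)
  V <- fit$cov_beta
  beta <- fit$beta
  sd_total <- sqrt(sum(fit$vc))
  obs_age <- round(table$age_years)
  borrowed <- numeric(0)
  rows <- lapply(ages, function(a) {
    if (is.null(fit$basis_spec)) {
      xbar <- numeric(0)
    } else if (fit$covariates) {
      if (profile_mode == "marginal") {
        src <- a
        if (!any(obs_age == src)) {
          src <- obs_age[which.min(abs(obs_age - a))]
          borrowed <<- c(borrowed, a)
        }
        i <- obs_age == src
        X <- build_design(rep(a, sum(i)), table$asthma[i],
                          table$smoking[i], table$obesity[i],
                          fit$basis_spec, TRUE)
        xbar <- colMeans(X)
      } else {
        xbar <- drop(build_design(a, reference_profile$asthma,
                                  reference_profile$smoking,
                                  reference_profile$obesity,
                                  fit$basis_spec, TRUE))
      }
    } else {
      xbar <- drop(build_design(a, 0, "never", 0, fit$basis_spec, FALSE))
    }
    x <- c(1, xbar[fit$x_cols])
    m <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    c(mean = m, se = se)
  })
  M <- do.call(rbind, rows)
  z <- stats::qnorm(0.975)
  out <- data.frame(age = ages, mean = M[, "mean"], sd = sd_total,
                    lo95 = M[, "mean"] - z * M[, "se"],
                    hi95 = M[, "mean"] + z * M[, "se"])
  attr(out, "borrowed_ages") <- unique(borrowed)
  out
}
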