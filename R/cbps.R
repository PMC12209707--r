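#' Build a retention problem from an observation table
#'
#' Participant-level baseline covariates (sex, baseline age, baseline
#' asthma / active smoking / obesity, study indicators) and a retained
#' flag; a participant counts as retained when at least two visits
#' survived attrition (the downstream inclusion rule).
#'
#' @param table Observation table (pre-inclusion, so lost participants are
#'   still visible).
#' @return List with covariate matrix `X` (one row per participant),
#'   logical `retained`, and `participant_id`.
#' @export
retention_problem <- function(table) {
  table <- ensure_obesity(table)
  sp <- split(table, table$participant_id)
  base <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$visit_index), ]
    data.frame(participant_id = d$participant_id[1],
               male = as.numeric(d$sex[1] == "M"),
               baseline_age = d$age_years[1],
               asthma = as.numeric(d$asthma[1] == 1),
               smoking = as.numeric(d$smoking[1] == "active"),
               obesity = as.numeric(d$obesity[1] == 1),
               study = d$study[1],
               retained = nrow(d) >= 2, stringsAsFactors = FALSE)
  }))
  studies <- sort(unique(base$study))
  X <- as.matrix(base[, c("male", "baseline_age", "asthma", "smoking",
                          "obesity")])
  if (length(studies) > 1)
    for (s in studies[-1])
      X <- cbind(X, stats::setNames(as.numeric(base$study == s),
                                    paste0("study_", s)))
  colnames(X)[-(1:5)] <- paste0("study_", studies[-1])[seq_len(ncol(X) - 5)]
  list(X = X, retained = base$retained,
       participant_id = base$participant_id)
}

#' Covariate-balancing retention weights
#'
#' Just-identified covariate-balancing propensity scores: inverse
#' probability-of-retention weights from a logistic score whose
#' coefficients solve the moment conditions that the weighted covariate
#' means of the retained participants equal the full-sample means exactly.
#' In `MCAR` mode the weights are uniform.
#'
#' @param problem List from [retention_problem()] (or any list with `X`
#'   and `retained`).
#' @param mode `"MAR"` (balancing weights) or `"MCAR"` (uniform).
#' @param max_iter,tol Newton iteration budget and moment tolerance.
#' @return Data frame `(participant_id, weight)` for retained
#'   participants, weights normalised to mean 1.
#' @export
cbps_weights <- function(problem, mode = c("MAR", "MCAR"), max_iter = 200,
                         tol = 1e-10) {
  mode <- match.arg(mode)
  R <- as.numeric(problem$retained)
  ids <- if (!is.null(problem$participant_id)) problem$participant_id
         else seq_along(R)
  if (!any(R > 0)) stop("no retained participants")
  if (mode == "MCAR" || all(R == 1)) {
    return(data.frame(participant_id = ids[R == 1],
                      weight = rep(1, sum(R)), stringsAsFactors = FALSE))
  }
  X <- as.matrix(problem$X)
  keep <- apply(X, 2, function(v) stats::sd(v) > 1e-12)
  X <- X[, keep, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1)
    stop("covariate matrix not full rank after dropping constants")
  mu <- colMeans(X); sig <- apply(X, 2, stats::sd)
  Z <- cbind(1, sweep(sweep(X, 2, mu), 2, sig, "/"))
  N <- nrow(Z)
  theta <- stats::coef(stats::glm.fit(Z, R,
                                      family = stats::binomial()))
  g <- function(th) {
    p <- stats::plogis(drop(Z %*% th))
    colMeans((R / p - 1) * Z)
  }
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(Z %*% theta))
    gv <- colMeans((R / p - 1) * Z)
    if (max(abs(gv)) < tol) break
    J <- -crossprod(Z * (R * (1 - p) / p), Z) / N
    step <- tryCatch(solve(J, gv), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in CBPS solver")
    # damped Newton: halve until the moment norm decreases
    lam <- 1
    repeat {
      cand <- theta - lam * step
      if (max(abs(g(cand))) < max(abs(gv)) || lam < 1e-6) break
      lam <- lam / 2
    }
    theta <- cand
  }
  gv <- g(theta)
  if (max(abs(gv)) > 1e-6)
    stop(sprintf("CBPS did not balance; worst standardised imbalance %.3g",
                 max(abs(gv))))
  p <- stats::plogis(drop(Z %*% theta))
  w <- (1 / p)[R == 1]
  w <- w / mean(w)
  data.frame(participant_id = ids[R == 1], weight = w,
             stringsAsFactors = FALSE)
}

#' Broadcast participant-level weights to observations
#'
#' @param table Observation table.
#' @param weights Data frame from [cbps_weights()].
#' @return Numeric vector aligned with `table` rows (1 where a participant
#'   has no weight).
#' @export
observation_weights <- function(table, weights) {
  w <- weights$weight[match(table$participant_id, weights$participant_id)]
  w[is.na(w)] <- 1
  w
}
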