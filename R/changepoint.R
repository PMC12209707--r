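#' Trend series for changepoint decomposition
#'
#' @param ages Strictly increasing age grid (years), unit-spaced by
#'   default.
#' @param values Trajectory values (litres or ratio).
#' @param sd Optional per-age SDs (carried along, not used by the default
#'   unknown-noise likelihood).
#' @export
trend_series <- function(ages, values, sd = NULL) {
  stopifnot(length(ages) == length(values), all(diff(ages) > 0),
            all(is.finite(values)))
  structure(list(ages = as.numeric(ages), values = as.numeric(values),
                 sd = sd), class = "trend_series")
}

#' Prior for the piecewise-linear trend model
#'
#' Each segment carries its own intercept, slope and noise variance under
#' a conjugate normal-inverse-gamma prior on the standardised scale; the
#' number of changepoints is uniform on `0..max_changepoints` and, given
#' the number, all admissible positions are equally likely.
#'
#' @param max_changepoints Maximum changepoints (default 10).
#' @param min_segment_length Minimum grid points per segment (>= 2).
#' @param tau Prior SD scale of intercept/slope relative to sigma.
#' @param a0,b0 Inverse-gamma shape/rate for the segment noise variance.
#' @export
cp_prior <- function(max_changepoints = 10, min_segment_length = 2,
                     tau = 10, a0 = 0.01, b0 = 0.01) {
  if (min_segment_length < 2) stop("min_segment_length must be >= 2")
  structure(list(max_changepoints = as.integer(max_changepoints),
                 min_segment_length = as.integer(min_segment_length),
                 tau = tau, a0 = a0, b0 = b0), class = "cp_prior")
}

# log marginal likelihood of segment i..j from prefix sums (standardised y,
# centred time within segment); conjugate NIG linear-regression evidence
make_seg_marginal <- function(t, y, prior) {
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  ct <- c(0, cumsum(t)); ct2 <- c(0, cumsum(t^2))
  cty <- c(0, cumsum(t * y))
  tau2 <- prior$tau^2; a0 <- prior$a0; b0 <- prior$b0
  function(i, j) {
    m <- j - i + 1
    Sy <- cy[j + 1] - cy[i]; Sy2 <- cy2[j + 1] - cy2[i]
    St <- ct[j + 1] - ct[i]; St2 <- ct2[j + 1] - ct2[i]
    Sty <- cty[j + 1] - cty[i]
    tb <- St / m
    Stt <- St2 - m * tb^2          # centred second moment
    Sty_c <- Sty - tb * Sy
    p1 <- 1 / tau2 + m; p2 <- 1 / tau2 + Stt
    mu1 <- Sy / p1; mu2 <- Sty_c / p2
    an <- a0 + m / 2
    bn <- b0 + 0.5 * (Sy2 - mu1^2 * p1 - mu2^2 * p2)
    bn <- max(bn, 1e-300)
    -m / 2 * log(2 * pi) - 0.5 * (log1p(m * tau2) + log1p(Stt * tau2)) +
      a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
  }
}

# posterior draw of the segment line for i..j: intercept (at the segment's
# mean age), slope (z/yr) and the centring age
draw_segment_line <- function(t, y, i, j, prior) {
  ts <- t[i:j]; ys <- y[i:j]
  tb <- mean(ts); tc <- ts - tb
  m <- length(ys)
  tau2 <- prior$tau^2
  p1 <- 1 / tau2 + m; p2 <- 1 / tau2 + sum(tc^2)
  mu1 <- sum(ys) / p1; mu2 <- sum(tc * ys) / p2
  an <- prior$a0 + m / 2
  bn <- prior$b0 + 0.5 * (sum(ys^2) - mu1^2 * p1 - mu2^2 * p2)
  s2 <- 1 / stats::rgamma(1, shape = an, rate = max(bn, 1e-300))
  c(a = stats::rnorm(1, mu1, sqrt(s2 / p1)),
    b = stats::rnorm(1, mu2, sqrt(s2 / p2)), tbar = tb)
}

# known-noise variant: per-age SDs supplied, Gaussian evidence with fixed
# prior scale tau on intercept/slope; returns closures for the segment
# marginal and the posterior line draw (intercept at t = 0)
make_seg_known <- function(t, y, sd_std, tau) {
  w <- 1 / pmax(sd_std, 1e-8)^2
  cw <- c(0, cumsum(w)); cwt <- c(0, cumsum(w * t))
  cwt2 <- c(0, cumsum(w * t^2)); cwy <- c(0, cumsum(w * y))
  cwty <- c(0, cumsum(w * t * y)); cwy2 <- c(0, cumsum(w * y^2))
  cls <- c(0, cumsum(log(2 * pi / w)))
  moments <- function(i, j) {
    Sw <- cw[j + 1] - cw[i]; Swt <- cwt[j + 1] - cwt[i]
    Swt2 <- cwt2[j + 1] - cwt2[i]
    c11 <- 1 / tau^2 + Sw; c12 <- Swt; c22 <- 1 / tau^2 + Swt2
    b1 <- cwy[j + 1] - cwy[i]; b2 <- cwty[j + 1] - cwty[i]
    det <- c11 * c22 - c12^2
    list(c11 = c11, c12 = c12, c22 = c22, det = det, b1 = b1, b2 = b2,
         mu1 = (c22 * b1 - c12 * b2) / det,
         mu2 = (c11 * b2 - c12 * b1) / det)
  }
  list(
    marginal = function(i, j) {
      m <- moments(i, j)
      quad <- (cwy2[j + 1] - cwy2[i]) - (m$mu1 * m$b1 + m$mu2 * m$b2)
      -0.5 * ((cls[j + 1] - cls[i]) + log(tau^4 * m$det) + quad)
    },
    draw = function(i, j) {
      m <- moments(i, j)
      # sample from N(mu, C^-1) via 2x2 Cholesky of the inverse
      iC <- matrix(c(m$c22, -m$c12, -m$c12, m$c11), 2) / m$det
      L <- chol(iC)
      b <- c(m$mu1, m$mu2) + drop(t(L) %*% stats::rnorm(2))
      c(a = b[1], b = b[2], tbar = 0)
    })
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Bayesian piecewise-linear trend decomposition
#'
#' Computes the exact posterior over piecewise-linear segmentations of the
#' series (number and positions of changepoints) by dynamic programming
#' over conjugate per-segment marginal likelihoods, then draws seeded
#' posterior samples of segmentations and segment slopes. The series is
#' internally standardised to zero mean and unit SD; slope samples are in
#' standardised units per year, with the scale constants returned for
#' conversion.
#'
#' @param series A [trend_series()].
#' @param prior A [cp_prior()].
#' @param n_samples Posterior draws.
#' @param seed Seed for the posterior sampling.
#' @return A `cp_posterior`: per-age changepoint probability and mean
#'   trend-change magnitude (dimensionless: slope change of the series
#'   standardised on both axes), per-k posterior mass, slope samples, and
#'   changepoint indicator samples.
#' @export
decompose_trend <- function(series, prior = cp_prior(), n_samples = 2000,
                            seed = 1L) {
  stopifnot(inherits(series, "trend_series"))
  L <- prior$min_segment_length
  n <- length(series$values)
  if (n < 2 * L) stop("series too short for the minimum segment length")
  mu <- mean(series$values); sdv <- stats::sd(series$values)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  y <- (series$values - mu) / sdv
  t <- series$ages
  sd_age <- stats::sd(t)
  known <- !is.null(series$sd)
  if (known) {
    kn <- make_seg_known(t, y, series$sd / sdv, prior$tau)
    segm <- kn$marginal
  } else {
    segm <- make_seg_marginal(t, y, prior)
  }
  smax <- min(prior$max_changepoints + 1L, n %/% L)  # max segments
  logM <- matrix(-Inf, n, n)
  for (i in 1:(n - L + 1)) for (j in (i + L - 1):n) logM[i, j] <- segm(i, j)
  # F[s, j]: log sum of products over partitions of 1..j into s segments
  F <- matrix(-Inf, smax, n)
  F[1, ] <- logM[1, ]
  if (smax > 1) for (s in 2:smax) for (j in (s * L):n) {
    i <- ((s - 1) * L + 1):(j - L + 1)
    F[s, j] <- logsumexp(F[s - 1, i - 1] + logM[i, j])
  }
  # B[s, j]: covering j..n with s segments
  B <- matrix(-Inf, smax, n)
  B[1, ] <- logM[, n]
  if (smax > 1) for (s in 2:smax) for (j in 1:(n - s * L + 1)) {
    e <- (j + L - 1):(n - (s - 1) * L)
    B[s, j] <- logsumexp(logM[j, e] + B[s - 1, e + 1])
  }
  ks <- 0:(smax - 1)
  logNk <- lchoose(n - (ks + 1) * (L - 1) - 1, ks)
  wk <- -log(length(ks)) - logNk
  logpost_k <- F[ks + 1, n] + wk
  logZ <- logsumexp(logpost_k)
  k_mass <- exp(logpost_k - logZ)
  names(k_mass) <- ks
  # per-position changepoint probability (new segment starts at i)
  cp_prob <- numeric(n)
  for (i in 2:n) {
    terms <- -Inf
    for (kk in ks[ks >= 1]) {
      s1 <- seq_len(kk)
      v <- F[s1, i - 1] + B[kk + 1 - s1, i] + wk[kk + 1]
      terms <- c(terms, v)
    }
    cp_prob[i] <- exp(logsumexp(terms) - logZ)
  }
  # seeded posterior sampling of segmentations and slopes
  set.seed(seed)
  slope_samples <- matrix(NA_real_, n_samples, n)
  cp_samples <- matrix(FALSE, n_samples, n)
  cp_age_samples <- matrix(NA_real_, n_samples, n)
  dmag <- matrix(NA_real_, n_samples, n)
  for (r in seq_len(n_samples)) {
    nseg <- sample(seq_len(smax), 1, prob = k_mass)
    bounds <- n  # segment end indices, built backwards
    endj <- n; s <- nseg
    while (s > 1) {
      i_cand <- ((s - 1) * L + 1):(endj - L + 1)
      lw <- F[s - 1, i_cand - 1] + logM[i_cand, endj]
      lw <- lw - max(lw)
      i <- i_cand[sample.int(length(i_cand), 1, prob = exp(lw))]
      cp_samples[r, i] <- TRUE
      bounds <- c(i - 1, bounds)
      endj <- i - 1; s <- s - 1
    }
    starts <- c(1, which(cp_samples[r, ]))
    ends <- bounds
    prev <- NULL
    for (g in seq_along(starts)) {
      ln <- if (known) kn$draw(starts[g], ends[g])
            else draw_segment_line(t, y, starts[g], ends[g], prior)
      slope_samples[r, starts[g]:ends[g]] <- ln[["b"]]
      if (g > 1) {
        i <- starts[g]
        dmag[r, i] <- abs(ln[["b"]] - prev[["b"]])
        # breakpoint age = intersection of the adjacent segment lines,
        # clamped near the sampled boundary
        db <- ln[["b"]] - prev[["b"]]
        x <- if (abs(db) > 1e-8)
          (prev[["a"]] - ln[["a"]] - prev[["b"]] * prev[["tbar"]] +
             ln[["b"]] * ln[["tbar"]]) / db
        else (t[i - 1] + t[i]) / 2
        cp_age_samples[r, i] <- min(max(x, t[i - 1] - 2), t[i] + 2)
      }
      prev <- ln
    }
  }
  magnitude <- numeric(n)
  for (i in 2:n) {
    v <- dmag[cp_samples[, i], i]
    magnitude[i] <- if (length(v)) mean(v) * sd_age else 0
  }
  structure(list(ages = t, values = series$values, mu = mu, sdv = sdv,
                 sd_age = sd_age, k_mass = k_mass, cp_prob = cp_prob,
                 magnitude = magnitude, slope_samples = slope_samples,
                 cp_samples = cp_samples, cp_age_samples = cp_age_samples,
                 prior = prior, seed = seed,
                 n_samples = n_samples),
            class = "cp_posterior")
}

#' Call breakpoints from a changepoint posterior
#'
#' Candidate breakpoints are local maxima of the per-age changepoint
#' probability; the probability attached to each candidate aggregates the
#' posterior mass over its basin (ages nearer to it than to any other
#' maximum), since the posterior for one true breakpoint spreads over
#' neighbouring years. Candidates are kept when that probability exceeds
#' `prob_thresh` and the (dimensionless) trend-change magnitude exceeds
#' `mag_thresh`; each is reported with the posterior-median age and a 95%
#' credible interval from the sampled changepoint positions in its basin.
#'
#' @param post A `cp_posterior`.
#' @param mag_thresh Trend-change magnitude threshold (default 0.1,
#'   standardised units).
#' @param prob_thresh Breakpoint probability threshold (default 0.5).
#' @return Data frame `(age, lo95, hi95, probability, magnitude)`, ordered
#'   by age; zero rows when nothing is called.
#' @export
call_breakpoints <- function(post, mag_thresh = 0.1, prob_thresh = 0.5) {
  p <- post$cp_prob
  n <- length(p)
  empty <- data.frame(age = numeric(), lo95 = numeric(), hi95 = numeric(),
                      probability = numeric(), magnitude = numeric())
  if (all(p <= 0)) return(empty)
  is_max <- logical(n)
  for (i in 2:n) {
    left <- if (i > 2) p[i - 1] else -Inf
    right <- if (i < n) p[i + 1] else -Inf
    is_max[i] <- p[i] > 0 && p[i] >= left && p[i] > right
  }
  maxima <- which(is_max)
  if (!length(maxima)) return(empty)
  idx <- 2:n
  basin_of <- vapply(idx, function(i) maxima[which.min(abs(maxima - i))], 0)
  rows <- lapply(maxima, function(m) {
    b <- idx[basin_of == m]
    prob <- sum(p[b])
    mag <- if (sum(p[b]) > 0) sum(p[b] * post$magnitude[b]) / sum(p[b]) else 0
    cp_ages <- post$cp_age_samples[, b, drop = FALSE]
    cp_ages <- cp_ages[!is.na(cp_ages)]
    if (!length(cp_ages)) cp_ages <- post$ages[m]
    q <- stats::quantile(cp_ages, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(age = q[1], lo95 = q[2], hi95 = q[3],
               probability = min(prob, 1), magnitude = mag)
  })
  out <- do.call(rbind, rows)
  out <- out[out$probability > prob_thresh & out$magnitude > mag_thresh, ,
             drop = FALSE]
  out <- out[order(out$age), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean slope within each inter-breakpoint segment
#'
#' Aggregates the posterior per-age slope samples over the ages of each
#' segment demarcated by the called breakpoints; reported on the original
#' scale per year and in mL/year (x1000).
#'
#' @param series The decomposed [trend_series()].
#' @param post The `cp_posterior`.
#' @param breakpoints Data frame from [call_breakpoints()].
#' @return Data frame with per-segment age range, mean slope and 95% CI.
#' @export
segment_slopes <- function(series, post, breakpoints) {
  ages <- post$ages
  bp <- sort(breakpoints$age)
  seg_id <- findInterval(ages, bp) + 1L  # age >= bp starts the next segment
  rows <- lapply(sort(unique(seg_id)), function(g) {
    cols <- which(seg_id == g)
    if (!length(cols)) stop("empty segment in partition")
    per_draw <- rowMeans(post$slope_samples[, cols, drop = FALSE])
    sl <- per_draw * post$sdv
    q <- stats::quantile(sl, c(0.025, 0.975), names = FALSE)
    data.frame(segment = g, age_start = min(ages[cols]),
               age_end = max(ages[cols]), slope = mean(sl),
               lo95 = q[1], hi95 = q[2],
               slope_mL_yr = 1000 * mean(sl),
               lo95_mL_yr = 1000 * q[1], hi95_mL_yr = 1000 * q[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-age slope-zero probability and plateau intervals
#'
#' A plateau is a maximal run of consecutive ages at which the posterior
#' probability that the slope is zero (within `zero_band`, standardised
#' units per year) exceeds 0.5, sustained for at least `min_years` years.
#'
#' @param post A `cp_posterior`.
#' @param zero_band Half-width of the slope band treated as zero
#'   (standardised units per year).
#' @param min_years Minimum duration (years).
#' @return Data frame `(age_start, age_end, max_prob)`; zero rows if none.
#' @export
plateau_scan <- function(post, zero_band = 0.005, min_years = 1) {
  pp <- colMeans(abs(post$slope_samples) <= zero_band)
  flag <- pp > 0.5
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_years
  if (!any(keep))
    return(data.frame(age_start = numeric(), age_end = numeric(),
                      max_prob = numeric()))
  data.frame(age_start = post$ages[starts[keep]],
             age_end = post$ages[ends[keep]],
             max_prob = vapply(which(keep), function(i)
               max(pp[starts[i]:ends[i]]), 0))
}

#' Per-age probabilities of increase, plateau and decrease
#'
#' Empirical fractions of posterior slope samples above, within and below
#' the zero band; the three probabilities sum to 1 at every age.
#'
#' @inheritParams plateau_scan
#' @return Data frame `(age, p_inc, p_plateau, p_dec)`.
#' @export
sign_probabilities <- function(post, zero_band = 0.005) {
  S <- post$slope_samples
  data.frame(age = post$ages,
             p_inc = colMeans(S > zero_band),
             p_plateau = colMeans(abs(S) <= zero_band),
             p_dec = colMeans(S < -zero_band))
}

#' Peak age from the called breakpoints
#'
#' The peak is interpreted as lying within the 95% credible interval of
#' the called breakpoint with the highest trajectory value. With no called
#' breakpoint the age of the series maximum is returned with a boundary
#' flag.
#'
#' @inheritParams segment_slopes
#' @return List with `age`, `lo95`, `hi95`, `boundary`.
#' @export
peak_estimate <- function(series, post, breakpoints) {
  if (nrow(breakpoints) == 0) {
    i <- which.max(series$values)
    return(list(age = series$ages[i], lo95 = series$ages[i],
                hi95 = series$ages[i], boundary = TRUE))
  }
  v <- stats::approx(series$ages, series$values, xout = breakpoints$age,
                     rule = 2)$y
  b <- breakpoints[which.max(v), ]
  list(age = b$age, lo95 = b$lo95, hi95 = b$hi95, boundary = FALSE)
}
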