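#' Piecewise-linear ground-truth trajectory
#'
#' A `true_trajectory` is the generative mean curve used by the synthetic
#' accelerated-cohort generator: a continuous piecewise-linear function of
#' age anchored at `start_age`, with slope changes at `breakpoint_ages`.
#'
#' @param start_age Age (years) at which the curve is anchored.
#' @param anchor_value Value (litres) at `start_age`.
#' @param breakpoint_ages Strictly increasing ages in `(start_age, 80)` at
#'   which the slope changes. May be empty.
#' @param segment_slopes Slopes (litres/year), one more than the number of
#'   breakpoints.
#' @return An object of class `true_trajectory`.
#' @export
true_trajectory <- function(start_age, anchor_value, breakpoint_ages,
                            segment_slopes) {
  breakpoint_ages <- as.numeric(breakpoint_ages)
  segment_slopes <- as.numeric(segment_slopes)
  stopifnot(is.finite(start_age), is.finite(anchor_value),
            all(is.finite(segment_slopes)))
  if (length(segment_slopes) != length(breakpoint_ages) + 1L)
    stop("need one more slope than breakpoints")
  if (length(breakpoint_ages)) {
    if (any(diff(breakpoint_ages) <= 0))
      stop("breakpoint_ages must be strictly increasing")
    if (any(breakpoint_ages <= start_age | breakpoint_ages >= 80))
      stop("breakpoint_ages must lie inside (start_age, 80)")
  }
  structure(list(start_age = start_age, anchor_value = anchor_value,
                 breakpoint_ages = breakpoint_ages,
                 segment_slopes = segment_slopes),
            class = "true_trajectory")
}

#' Evaluate a ground-truth trajectory at given ages
#'
#' Continuous piecewise-linear evaluation; exact at the breakpoints.
#'
#' @param truth A [true_trajectory()].
#' @param age Numeric vector of ages in `[start_age, 80]`.
#' @return Numeric vector of values (litres).
#' @export
eval_true_trajectory <- function(truth, age) {
  stopifnot(inherits(truth, "true_trajectory"))
  if (any(age < truth$start_age - 1e-9 | age > 80 + 1e-9))
    stop("age outside [start_age, 80]")
  knots <- c(truth$start_age, truth$breakpoint_ages)
  # value at the start of each linear piece
  piece_len <- diff(c(knots, 80))
  v0 <- truth$anchor_value +
    c(0, cumsum(truth$segment_slopes * piece_len))[seq_along(knots)]
  idx <- findInterval(age, knots, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  v0[idx] + truth$segment_slopes[idx] * (age - knots[idx])
}

#' Paper-calibrated default trajectories
#'
#' Loads the packaged fixture file transcribing the published sex-specific
#' FEV1 and FVC breakpoint ages and segment slopes (mL/year converted to
#' L/year); anchor values at age 4 are the package's own choices of
#' plausible childhood volumes.
#'
#' @return Named list of [true_trajectory()] objects, keyed
#'   `"<parameter>.<sex>"`, e.g. `"FEV1.F"`.
#' @export
default_trajectories <- function() {
  path <- system.file("extdata", "trajectory_fixtures.csv",
                      package = "lifespiro", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    br <- as.numeric(strsplit(tab$breakpoints[i], ";")[[1]])
    sl <- as.numeric(strsplit(tab$slopes[i], ";")[[1]])
    out[[paste(tab$parameter[i], tab$sex[i], sep = ".")]] <-
      true_trajectory(tab$start_age[i], tab$anchor_L[i], br, sl)
  }
  out
}
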