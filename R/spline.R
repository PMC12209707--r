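#' Natural cubic spline basis for age
#'
#' Restricted cubic spline basis (linear beyond the boundary knots) with
#' 1-6 internal knots drawn, in a fixed coarse-to-fine order, from six
#' candidate positions log-spaced over ages 5-45. Log-age placement over
#' the growth-to-mid-adult span concentrates knots where lung function
#' changes fastest (the same reason spirometry reference equations model
#' age on the log scale); late-adult decline is close to linear, which
#' the spline's tail handles without dedicated knots. Placement at
#' quantiles of an adult-heavy pooled cohort would instead leave the
#' growth phase without any knot. The coarse-to-fine ordering makes the
#' candidate models nested across knot counts, so the BIC curve used for
#' knot selection decreases smoothly and its elbow is well defined.
#'
#' @param ages Observed ages (years); used to check the basis is
#'   well-defined on the data.
#' @param n_internal_knots Integer in 1..6.
#' @param boundary Boundary knots (years); the basis is linear outside.
#' @param knots Optional explicit internal knot positions (overrides the
#'   default placement).
#' @return Basis matrix with attribute `basis_spec` (list of `knots`,
#'   `boundary`) for re-evaluation at new ages.
#' @export
ncs_basis <- function(ages, n_internal_knots, boundary = c(4, 80),
                      knots = NULL) {
  if (is.null(knots)) {
    if (n_internal_knots < 1 || n_internal_knots > 6)
      stop("n_internal_knots must be between 1 and 6")
    cand <- exp(seq(log(5), log(45), length.out = 6))
    priority <- c(4, 5, 3, 2, 1, 6)  # coarse-to-fine over the grid
    knots <- sort(cand[priority[seq_len(n_internal_knots)]])
    if (any(knots <= boundary[1] | knots >= boundary[2]))
      stop("internal knots must lie inside the boundary knots")
    if (length(unique(round(ages, 6))) < n_internal_knots + 3)
      stop("degenerate age distribution: too few distinct ages")
  }
  B <- splines::ns(ages, knots = knots, Boundary.knots = boundary)
  attr(B, "basis_spec") <- list(knots = knots, boundary = boundary)
  B
}

# evaluate the same basis at new ages
ncs_eval <- function(spec, ages) {
  unclass(splines::ns(ages, knots = spec$knots,
                      Boundary.knots = spec$boundary))
}

# fixed-effect design matrix (no intercept column): spline basis, covariate
# main effects, and covariate-by-spline interactions
build_design <- function(ages, asthma, smoking, obesity, spec,
                         covariates = TRUE) {
  B <- ncs_eval(spec, ages)
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  if (!covariates) return(B)
  covs <- cbind(asthma = as.numeric(asthma),
                smk_former = as.numeric(smoking == "former"),
                smk_active = as.numeric(smoking == "active"),
                obesity = as.numeric(obesity))
  inter <- do.call(cbind, lapply(colnames(covs), function(v) {
    M <- B * covs[, v]
    colnames(M) <- paste(colnames(B), v, sep = "_x_")
    M
  }))
  cbind(B, covs, inter)
}
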