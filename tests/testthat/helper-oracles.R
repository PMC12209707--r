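# independent enumeration oracle for the segmentation posterior: direct
# multivariate-t segment evidence (matrix form) and explicit enumeration
# of all segmentations with up to kmax changepoints
enum_posterior <- function(y, t, prior, kmax = 2) {
  n <- length(y)
  L <- prior$min_segment_length
  y <- (y - mean(y)) / sd(y)
  seg_lml <- function(i, j) {
    ys <- y[i:j]; ts <- t[i:j]; m <- length(ys)
    X <- cbind(1, ts - mean(ts))
    M <- diag(m) + prior$tau^2 * X %*% t(X)
    -m / 2 * log(2 * pi) - 0.5 * determinant(M)$modulus[1] +
      prior$a0 * log(prior$b0) +
      lgamma(prior$a0 + m / 2) - lgamma(prior$a0) -
      (prior$a0 + m / 2) *
        log(prior$b0 + 0.5 * drop(t(ys) %*% solve(M, ys)))
  }
  segs <- list(list(k = 0, cps = integer(0), lml = seg_lml(1, n)))
  if (kmax >= 1) for (i in (1 + L):(n - L + 1))
    segs <- c(segs, list(list(k = 1, cps = i,
                              lml = seg_lml(1, i - 1) + seg_lml(i, n))))
  if (kmax >= 2) for (i in (1 + L):(n - 2 * L + 1))
    for (j in (i + L):(n - L + 1))
      segs <- c(segs, list(list(k = 2, cps = c(i, j),
                                lml = seg_lml(1, i - 1) +
                                  seg_lml(i, j - 1) + seg_lml(j, n))))
  ks <- vapply(segs, `[[`, 0, "k")
  nk <- table(factor(ks, levels = 0:kmax))
  logw <- vapply(segs, `[[`, 0, "lml") - log(as.numeric(nk[ks + 1])) -
    log(kmax + 1)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  k_mass <- vapply(0:kmax, function(k) sum(w[ks == k]), 0)
  cp_prob <- vapply(seq_len(n), function(i)
    sum(w[vapply(segs, function(s) i %in% s$cps, TRUE)]), 0)
  list(k_mass = k_mass, cp_prob = cp_prob)
}

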