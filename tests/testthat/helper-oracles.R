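# Independent oracles used to check the package's implementations by a
# different computational route.

# linear convolution by direct summation (no FFT)
conv_direct <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# zero-insertion upsampling: 2^(j-1)-1 zeros between taps
upsample_direct <- function(v, j) {
  if (j == 1L) return(v)
  step <- 2L^(j - 1L)
  out <- numeric(step * (length(v) - 1L) + 1L)
  out[(seq_along(v) - 1L) * step + 1L] <- v
  out
}

# equivalent level-j filter built from scratch: cascade of upsampled
# stage filters, scaling stages below the target stage
equivalent_filter_direct <- function(g, h, j, kind, rescale = TRUE) {
  target <- if (kind == "wavelet") h else g
  eq <- if (j == 1L) target else {
    acc <- g
    for (k in seq_len(j - 1L)[-1L]) acc <- conv_direct(upsample_direct(g, k), acc)
    conv_direct(upsample_direct(target, j), acc)
  }
  if (rescale) eq / 2^(j / 2) else eq
}

# MODWT coefficients by direct circular filtering with equivalent
# filters (O(N * L_j) summation; independent of the pyramid recursion)
modwt_direct <- function(x, g, h, J0) {
  N <- length(x)
  coef_with <- function(f) {
    vapply(0:(N - 1L), function(t) {
      l <- seq_along(f) - 1L
      sum(f * x[(t - l) %% N + 1L])
    }, numeric(1))
  }
  W <- lapply(seq_len(J0), function(j) {
    coef_with(equivalent_filter_direct(g, h, j, "wavelet"))
  })
  V <- coef_with(equivalent_filter_direct(g, h, J0, "scaling"))
  list(W = W, V = V)
}

# definitional Benjamini-Hochberg step-up: largest k with
# p_(k) <= q k / m; all p up to p_(k) pass
bh_stepup_direct <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= q * i / m) k <- i
  pass <- logical(m)
  if (k > 0) pass[ord[seq_len(k)]] <- TRUE
  pass
}

# brute-force Type-III sums of squares for a balanced 2x2 design
# without covariates: effect SS from cell means, error SS from within-
# cell deviations
anova_2x2_direct <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  stopifnot(nlevels(A) == 2, nlevels(B) == 2)
  cell <- interaction(A, B)
  nc <- table(cell)
  stopifnot(length(unique(nc)) == 1)  # balanced only
  n <- unique(nc)
  cm <- tapply(y, cell, mean)
  am <- tapply(y, A, mean)
  bm <- tapply(y, B, mean)
  gm <- mean(y)
  ss_a <- 2 * n * sum((am - gm)^2)
  ss_b <- 2 * n * sum((bm - gm)^2)
  ss_cells <- n * sum((cm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - cm[cell])^2)
  df_err <- length(y) - 4
  list(
    F = c(A = (ss_a / 1) / (ss_err / df_err),
          B = (ss_b / 1) / (ss_err / df_err),
          AB = (ss_ab / 1) / (ss_err / df_err)),
    ss = c(A = ss_a, B = ss_b, AB = ss_ab, err = ss_err),
    df_err = df_err
  )
}

# textbook pooled-variance two-sample t
pooled_t_direct <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Hardy-Weinberg exact p by Monte-Carlo permutation of the allele pool:
# pair 2n shuffled alleles, tabulate heterozygote counts, p = share of
# tables with probability <= that of the observed table
hwe_mc_direct <- function(n_AA, n_Aa, n_aa, B = 20000) {
  n <- n_AA + n_Aa + n_aa
  pool <- rep(c(0L, 1L), c(2 * n_AA + n_Aa, 2 * n_aa + n_Aa))
  hets <- replicate(B, {
    s <- sample(pool)
    sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)])
  })
  freq <- table(hets) / B
  p_obs <- freq[as.character(n_Aa)]
  if (is.na(p_obs)) p_obs <- 0
  sum(freq[freq <= p_obs + 1e-9])
}

# quadrature of a level filter's squared gain over a frequency band
gain_integral_direct <- function(lf, lo, hi, n = 2048) {
  f <- seq(lo, hi, length.out = n)
  sum(squared_gain(lf, f)) * (hi - lo) / n
}
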