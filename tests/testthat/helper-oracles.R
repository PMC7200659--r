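# Independent oracles, deliberately written by a different route than the
# package implementation.

# Exhaustive Youden sweep: try every candidate threshold with plain loops.
brute_force_cutpoint <- function(hd_control, hd_treatment) {
  cand <- sort(unique(c(hd_control, hd_treatment)))
  best <- list(j = -Inf, cutoff = NA_real_)
  for (cf in cand) {
    sens <- sum(hd_treatment >= cf) / length(hd_treatment)
    spec <- sum(hd_control < cf) / length(hd_control)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, cutoff = cf)
  }
  best
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (with fixed margins) no more probable than
# the observed one.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up from its definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exact two-sample Poisson rate test: conditional on the total, the
# treatment total is binomial.
exact_poisson_p <- function(sum_c, n_c, sum_t, n_t) {
  stats::binom.test(sum_t, sum_t + sum_c,
                    p = n_t / (n_t + n_c))$p.value
}

# Poisson-binomial tail by explicit enumeration over subsets (independent
# of the package's convolution).
pb_tail_enum <- function(p, k_min) {
  n <- length(p)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= k_min) {
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
    }
  }
  total
}

# RMS statistic null by full enumeration of 4-cell tables with a given
# total, weighted by the independence multinomial.
rms_exact_p <- function(cells, stat_fn) {
  tot <- sum(cells)
  prow <- (cells[1] + cells[2]) / tot
  pcol <- (cells[1] + cells[3]) / tot
  p4 <- c(prow * pcol, prow * (1 - pcol), (1 - prow) * pcol,
          (1 - prow) * (1 - pcol))
  obs <- stat_fn(cells)
  p <- 0
  for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
    d <- tot - a - b - cc
    tab <- c(a, b, cc, d)
    if (stat_fn(tab) >= obs - 1e-12) {
      p <- p + stats::dmultinom(tab, prob = p4)
    }
  }
  p
}

# Mantel-Haenszel linear trend statistic from the textbook formula for a
# 2x2 grid with scores (1,2) on both axes.
mh_trend_2x2 <- function(tab) {
  n <- sum(tab)
  u <- c(1, 2)
  v <- c(1, 2)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  mu_u <- sum(u * pu)
  mu_v <- sum(v * pv)
  cov_uv <- sum(outer(u - mu_u, v - mu_v) * tab) / n
  r <- cov_uv / sqrt(sum((u - mu_u)^2 * pu) * sum((v - mu_v)^2 * pv))
  (n - 1) * r^2
}
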