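# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the library shortcuts it calls) so that agreement is a
# two-route check.

# Benjamini-Hochberg step-up by definition: q_i = min over ranks j >= rank(i)
# of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    q_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# hypergeometric upper tail P(X >= k) by direct pmf summation with choose()
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# OLS by explicit normal equations through solve(), for cross-checking
ols_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
  list(beta = drop(beta), se = se, df = df)
}

# inverse-variance combination re-derived as intercept-only weighted least
# squares via the normal equations
wls_intercept_oracle <- function(y, v) {
  X <- matrix(1, length(y), 1)
  W <- diag(1 / v, length(y))
  XtWX <- t(X) %*% W %*% X
  est <- solve(XtWX, t(X) %*% W %*% y)
  list(est = drop(est), se = sqrt(1 / XtWX[1, 1]))
}

# naive O(S*G) interval containment scan
map_oracle <- function(snps, models) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(models))) {
      if (snps$chrom[i] == models$chrom[j] &&
          snps$pos[i] >= models$start[j] && snps$pos[i] <= models$end[j]) {
        hits[[length(hits) + 1L]] <- data.frame(
          pos = snps$pos[i], gene = models$name[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(pos = integer(), gene = character()))
  do.call(rbind, hits)
}
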