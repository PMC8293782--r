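# Independent oracles used to validate the package's estimators.
# Deliberately implemented from first principles (raw sums, explicit
# projection matrices, sort-and-average), never via lm()/car/emmeans.

# OLS from the normal equations on raw sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r2 <- (n * sxy - sx * sy)^2 / ((n * sxx - sx^2) * (n * syy - sy^2))
  se_slope <- {
    res <- y - intercept - slope * x
    sqrt(sum(res^2) / (n - 2) / (sxx - sx^2 / n))
  }
  t_stat <- slope / se_slope
  p <- 2 * stats::pt(-abs(t_stat), n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       se_slope = se_slope, t = t_stat, p = p)
}

# Lowest-fraction mean by explicit sort-and-average.
smr_oracle <- function(values, fraction = 0.10) {
  k <- max(1, floor(fraction * length(values)))
  mean(sort(values)[seq_len(k)])
}

# Partial (Type III) F tests for y ~ group + covariate via explicit
# projection matrices: full design (intercept, sum-to-zero factor columns,
# covariate) vs the design with the tested term removed.
rss_proj <- function(X, y) {
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  sum(((diag(nrow(X)) - P) %*% y)^2)
}

ancova_oracle <- function(y, g, x) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(y)
  # sum-to-zero coding by hand
  G <- matrix(0, n, k - 1)
  for (j in seq_len(k - 1)) {
    G[g == levels(g)[j], j] <- 1
    G[g == levels(g)[k], j] <- -1
  }
  X_full <- cbind(1, G, x)
  rss_full <- rss_proj(X_full, y)
  df_res <- n - ncol(X_full)
  rss_nog <- rss_proj(cbind(1, x), y)
  rss_nox <- rss_proj(cbind(1, G), y)
  F_g <- ((rss_nog - rss_full) / (k - 1)) / (rss_full / df_res)
  F_x <- ((rss_nox - rss_full) / 1) / (rss_full / df_res)
  list(factor_F = F_g, factor_df = c(k - 1, df_res),
       factor_p = stats::pf(F_g, k - 1, df_res, lower.tail = FALSE),
       covariate_F = F_x,
       covariate_p = stats::pf(F_x, 1, df_res, lower.tail = FALSE))
}

# Welch statistic and Satterthwaite df from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}
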