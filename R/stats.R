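# Statistical layer: ANCOVA (Type III, sum-to-zero contrasts) with
# Bonferroni pairwise comparisons on adjusted means, simple TDF-on-SMR
# regressions, and the Welch t-test.

#' ANCOVA of a response on a group factor with a covariate
#'
#' Fits `response ~ group + covariate` by least squares with sum-to-zero
#' contrasts and reports Type III (partial) F tests for the factor and the
#' covariate, adjusted (marginal) group means evaluated at the grand-mean
#' covariate, and residual assumption diagnostics (Shapiro-Wilk normality,
#' Levene variance homogeneity). Diagnostics are reported, never used to
#' gate the fit. The sum-of-squares type is switchable for benchmarking
#' against analyses run with other conventions.
#'
#' @param data data.frame containing the variables.
#' @param response,group_factor,covariate Column names (strings).
#' @param ss_type Sum-of-squares type for the F tests: 3 (default), 2 or 1.
#' @return An object of class `ancova_result` with elements `response`,
#'   `factor_F`, `factor_df` (numerator, denominator), `factor_p`,
#'   `covariate_F`, `covariate_df`, `covariate_p`, `adjusted_means`
#'   (data.frame level/emmean/se), `diagnostics`, `model` and `emmeans`.
#' @export
fit_ancova <- function(data, response, group_factor, covariate, ss_type = 3) {
  stopifnot(all(c(response, group_factor, covariate) %in% names(data)))
  counts <- table(data[[group_factor]])
  empty <- names(counts)[counts == 0]
  if (length(empty)) stop("empty group level(s): ", paste(empty, collapse = ", "))
  data[[group_factor]] <- factor(data[[group_factor]])
  lev <- levels(data[[group_factor]])
  if (length(lev) < 2L) stop("need at least 2 group levels")
  form <- stats::reformulate(c(group_factor, covariate), response)
  contr <- stats::setNames(list("contr.sum"), group_factor)
  mod <- stats::lm(form, data = data, contrasts = contr)
  if (stats::df.residual(mod) < 1) stop("no residual degrees of freedom")
  df_den <- stats::df.residual(mod)
  k <- length(lev)
  rss_full <- stats::deviance(mod)
  tot_ss <- sum((data[[response]] - mean(data[[response]]))^2)

  partial_f <- function(rss_reduced, q) {
    # guarded partial F: a (near-)perfect fit still has a defined answer
    num <- max(0, rss_reduced - rss_full)
    if (rss_full <= 1e-12 * max(1, tot_ss)) {
      if (num <= 1e-12 * max(1, tot_ss)) list(F = 0, p = 1)
      else list(F = Inf, p = 0)
    } else {
      f <- (num / q) / (rss_full / df_den)
      list(F = f, p = stats::pf(f, q, df_den, lower.tail = FALSE))
    }
  }

  degenerate <- rss_full <= 1e-12 * max(1, tot_ss)
  if (degenerate) {
    # drop-term RSS comparison (equals Type III for this additive model);
    # car::Anova refuses models with zero residual sum of squares
    rss_nog <- stats::deviance(stats::lm(stats::reformulate(covariate, response),
                                         data = data))
    rss_nox <- stats::deviance(stats::lm(stats::reformulate(group_factor, response),
                                         data = data))
    pf_g <- partial_f(rss_nog, k - 1)
    pf_x <- partial_f(rss_nox, 1)
    fac <- list(F = pf_g$F, df = k - 1, p = pf_g$p)
    cov <- list(F = pf_x$F, df = 1, p = pf_x$p)
  } else {
    tab <- if (ss_type == 1) stats::anova(mod) else car::Anova(mod, type = ss_type)
    get_row <- function(term) {
      i <- match(term, rownames(tab))
      fcol <- grep("^F", colnames(tab), value = TRUE)[1]
      pcol <- grep("^Pr", colnames(tab), value = TRUE)[1]
      list(F = tab[i, fcol], df = tab[i, "Df"], p = tab[i, pcol])
    }
    fac <- get_row(group_factor)
    cov <- get_row(covariate)
  }

  emm <- muffle_perfect_fit(emmeans::emmeans(mod, specs = group_factor))
  emm_df <- as.data.frame(emm)
  adjusted_means <- data.frame(level = as.character(emm_df[[1]]),
                               emmean = emm_df$emmean, se = emm_df$SE,
                               stringsAsFactors = FALSE)

  res <- stats::resid(mod)
  diagnostics <- tryCatch({
    sw <- stats::shapiro.test(res)
    lev_test <- car::leveneTest(res ~ data[[group_factor]])
    list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
         levene_f = lev_test[1, "F value"], levene_p = lev_test[1, "Pr(>F)"])
  }, error = function(e) {
    # degenerate residuals (e.g. all identical) have no testable distribution
    list(shapiro_w = NA_real_, shapiro_p = NA_real_,
         levene_f = NA_real_, levene_p = NA_real_)
  })

  structure(list(response = response, group_factor = group_factor,
                 covariate = covariate, ss_type = ss_type,
                 factor_F = fac$F, factor_df = c(fac$df, df_den),
                 factor_p = fac$p,
                 covariate_F = cov$F, covariate_df = c(cov$df, df_den),
                 covariate_p = cov$p,
                 adjusted_means = adjusted_means,
                 diagnostics = diagnostics,
                 model = mod, emmeans = emm),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ %s + %s (type %s SS)\n", x$response,
              x$group_factor, x$covariate, x$ss_type))
  cat(sprintf("  %s: F(%g, %g) = %.3f, p = %.4g\n", x$group_factor,
              x$factor_df[1], x$factor_df[2], x$factor_F, x$factor_p))
  cat(sprintf("  %s: F(%g, %g) = %.3f, p = %.4g\n", x$covariate,
              x$covariate_df[1], x$covariate_df[2], x$covariate_F, x$covariate_p))
  invisible(x)
}

# Compact letter display: split-and-absorb. Start from one group holding all
# levels; for every significantly different pair, split any group containing
# both; drop groups that are subsets of others. Levels sharing a letter are
# not significantly different.
letter_display <- function(levels, sig_pairs) {
  groups <- list(levels)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$level_a[k]; b <- sig_pairs$level_b[k]
    new_groups <- list()
    for (gset in groups) {
      if (a %in% gset && b %in% gset) {
        new_groups <- c(new_groups, list(setdiff(gset, a)), list(setdiff(gset, b)))
      } else {
        new_groups <- c(new_groups, list(gset))
      }
    }
    # drop groups that are (proper or duplicate) subsets of another group
    keep <- rep(TRUE, length(new_groups))
    for (i in seq_along(new_groups)) {
      for (j in seq_along(new_groups)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_groups[[i]] %in% new_groups[[j]])) {
          same <- length(new_groups[[i]]) == length(new_groups[[j]])
          if (!same || i > j) keep[i] <- FALSE
        }
      }
    }
    groups <- new_groups[keep]
  }
  # a level distinct from everything still needs its own letter
  orphan <- setdiff(levels, unlist(groups))
  for (lv in orphan) groups <- c(groups, list(lv))
  letters_out <- stats::setNames(rep("", length(levels)), levels)
  for (i in seq_along(groups)) {
    for (lv in groups[[i]]) {
      letters_out[lv] <- paste0(letters_out[lv], letters[i])
    }
  }
  letters_out
}

#' Bonferroni-adjusted pairwise comparisons of ANCOVA adjusted means
#'
#' All unordered pairs of factor levels are compared via t-tests on the
#' adjusted-mean contrasts; raw p-values are multiplied by the number of
#' pairs (capped at 1). A compact letter display is attached: levels that
#' share a letter do not differ at `alpha` after adjustment.
#'
#' @param ancova An [fit_ancova()] result.
#' @param alpha Significance level for the letter display.
#' @return An object of class `pairwise_result`: `comparisons` (data.frame
#'   `level_a`, `level_b`, `estimate`, `se`, `t`, `df`, `p_raw`, `p_adj`)
#'   and `letters` (named character vector per level).
#' @export
bonferroni_pairwise <- function(ancova, alpha = 0.05) {
  stopifnot(inherits(ancova, "ancova_result"))
  ctr <- muffle_perfect_fit(
    summary(emmeans::contrast(ancova$emmeans, method = "pairwise",
                              adjust = "none")))
  pair_names <- strsplit(as.character(ctr$contrast), " - ", fixed = TRUE)
  # emmeans may wrap levels containing spaces/hyphens in parentheses
  strip <- function(x) gsub("^\\(|\\)$", "", x)
  m <- nrow(ctr)
  p_raw <- ctr$p.value
  # zero-SE contrasts (perfect fits) have no finite t; the decision is exact
  bad <- !is.finite(p_raw)
  p_raw[bad] <- ifelse(abs(ctr$estimate[bad]) > 1e-12, 0, 1)
  comparisons <- data.frame(
    level_a = strip(vapply(pair_names, `[`, "", 1)),
    level_b = strip(vapply(pair_names, `[`, "", 2)),
    estimate = ctr$estimate, se = ctr$SE, t = ctr$t.ratio, df = ctr$df,
    p_raw = p_raw,
    p_adj = pmin(1, p_raw * m),
    stringsAsFactors = FALSE
  )
  sig <- comparisons[comparisons$p_adj < alpha, c("level_a", "level_b")]
  lets <- letter_display(ancova$adjusted_means$level, sig)
  structure(list(comparisons = comparisons, letters = lets,
                 n_comparisons = m, alpha = alpha),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("Bonferroni pairwise comparisons (%d pairs, alpha = %g)\n",
              x$n_comparisons, x$alpha))
  print(x$comparisons, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Simple linear regression with slope test
#'
#' OLS of `y` on `x` with a two-sided t-test of the slope on n - 2 df.
#'
#' @param y Response vector.
#' @param x Predictor vector (must have positive variance).
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `se_slope`, `t`, `df`, `p`, `r_squared`, `n`.
#' @export
fit_regression <- function(y, x) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  # slope inference from the residuals directly (summary.lm warns on exact fits)
  res <- stats::resid(fit)
  df <- fit$df.residual
  se_slope <- sqrt(sum(res^2) / df / sum((x - mean(x))^2))
  t_stat <- if (se_slope > 0) slope / se_slope else sign(slope) * Inf
  p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), df) else as.numeric(slope == 0)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  structure(list(slope = slope, intercept = intercept,
                 se_slope = se_slope, t = t_stat, df = df, p = p,
                 r_squared = r2, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope = %.4g (t[%d] = %.3f, p = %.4g), R^2 = %.3f, n = %d\n",
              x$slope, x$df, x$t, x$p, x$r_squared, x$n))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (fractional)
#' degrees of freedom.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return An object of class `welch_t_result`: `t`, `df`, `p`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  stderr_w <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (stderr_w < 10 * .Machine$double.eps * max(abs(mean(a)), abs(mean(b)))) {
    # degenerate (constant) samples: the comparison is exact
    d <- mean(a) - mean(b)
    return(structure(list(t = if (d == 0) 0 else sign(d) * Inf,
                          df = length(a) + length(b) - 2,
                          p = as.numeric(d == 0),
                          mean_a = mean(a), mean_b = mean(b),
                          n_a = length(a), n_b = length(b)),
                     class = "welch_t_result"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "welch_t_result")
}

#' @export
print.welch_t_result <- function(x, ...) {
  cat(sprintf("Welch t-test: t[%.3f] = %.3f, p = %.4g (means %.3f vs %.3f)\n",
              x$df, x$t, x$p, x$mean_a, x$mean_b))
  invisible(x)
}
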