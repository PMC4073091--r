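#' One-sample and paired t tests
#'
#' Thin wrappers around [stats::t.test()] returning a flat result row
#' (`t`, `df`, `p`, `mean`, `n`); two-sided, `df = n - 1`.
#'
#' @param x numeric vector (differences, or the single sample).
#' @param mu null value for the one-sample test.
#' @param y optional second vector for a paired test.
#' @return A list with `t`, `df`, `p`, `mean`, `n`.
#' @export
t_test_one <- function(x, mu = 0, y = NULL) {
  if (!is.null(y)) {
    if (length(x) != length(y)) stop_stat("paired vectors must match in length")
    x <- x - y
  }
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop_stat("need at least 2 finite observations")
  if (stats::sd(x) == 0) {
    if (mean(x) == mu) {
      return(list(t = 0, df = length(x) - 1L, p = 1, mean = mean(x),
                  n = length(x)))
    }
    stop_stat("zero variance with nonzero effect: t undefined")
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(x), n = length(x))
}

#' Two-sample (Welch or pooled) t test
#'
#' @param x,y the two groups.
#' @param var_equal pool the variance (classic two-sample t with
#'   `df = n1 + n2 - 2`).
#' @export
t_test_two <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop_stat("need >= 2 per group")
  if (stats::sd(c(x, y)) == 0) {
    return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                mean_diff = 0, n = c(length(x), length(y))))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(x) - mean(y), n = c(length(x), length(y)))
}

#' Pearson or Spearman correlation
#'
#' Wrapper around [stats::cor.test()] returning `r` and `p`.
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_stat("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_stat("zero variance: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Partial correlation by residualization
#'
#' Correlates the residuals of `x` and `y` after regressing each on the
#' covariate. For the Spearman variant all three vectors are rank-transformed
#' first, then residualized, then correlated (Pearson on rank residuals).
#' The p-value uses the t approximation with `df = n - 3`.
#'
#' @param x,y numeric vectors.
#' @param covar covariate to partial out.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covar,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y) & is.finite(covar)
  x <- x[ok]; y <- y[ok]; covar <- covar[ok]
  n <- length(x)
  if (n < 4L) stop_stat("need at least 4 complete triples")
  if (stats::sd(covar) == 0) stop_stat("covariate has zero variance")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); covar <- rank(covar)
  }
  rx <- stats::residuals(stats::lm(x ~ covar))
  ry <- stats::residuals(stats::lm(y ~ covar))
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) || stats::sd(ry) < 1e-12 * max(1, stats::sd(y))) {
    stop_stat("residual variance vanishes: variable collinear with covariate")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n,
       method = method)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic within-subject F for a subjects x levels score matrix, with the
#' Greenhouse-Geisser epsilon computed from the sample covariance of the
#' level scores. Corrected degrees of freedom are `eps * (L - 1)` and
#' `eps * (L - 1) * (n - 1)`; with two levels epsilon is exactly 1.
#'
#' @param mat numeric matrix, one row per subject, one column per level;
#'   complete cases required.
#' @return A list: `F`, `df1`, `df2` (uncorrected), `epsilon`, `df1_gg`,
#'   `df2_gg`, `p` (uncorrected), `p_gg`.
#' @export
rm_anova_gg <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop_input("missing cells: complete cases required")
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2L || L < 2L) stop_input("need >= 2 subjects and >= 2 levels")
  grand <- mean(mat)
  subj_m <- rowMeans(mat)
  lev_m <- colMeans(mat)
  ss_lev <- n * sum((lev_m - grand)^2)
  ss_err <- sum((mat - outer(subj_m, rep(1, L)) -
                   outer(rep(1, n), lev_m) + grand)^2)
  df1 <- L - 1L
  df2 <- (L - 1L) * (n - 1L)
  if (ss_err == 0) {
    Fval <- if (ss_lev == 0) 0 else Inf
  } else {
    Fval <- (ss_lev / df1) / (ss_err / df2)
  }
  # Greenhouse-Geisser epsilon from the sample covariance of level scores
  S <- stats::cov(mat)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (L * (dbar - sbar))^2
  den <- (L - 1) * (sum(S^2) - 2 * L * sum(rowMeans(S)^2) + L^2 * sbar^2)
  eps <- if (den <= 0) 1 else min(1, max(1 / (L - 1), num / den))
  if (L == 2L) eps <- 1
  p_unc <- if (is.finite(Fval)) stats::pf(Fval, df1, df2, lower.tail = FALSE) else 0
  p_gg <- if (is.finite(Fval)) {
    stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  } else 0
  list(F = Fval, df1 = df1, df2 = df2, epsilon = eps,
       df1_gg = eps * df1, df2_gg = eps * df2, p = p_unc, p_gg = p_gg)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m size of the test family (>= number of p-values).
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop_config("m must be >= number of p-values")
  pmin(1, m * p_values)
}

#' Are priors accurate? Self vs agent deviation from performance
#'
#' For each participant computes the absolute deviation of the fitted prior
#' SD from the performance SD, separately for the self and agent priors, and
#' contrasts them with a paired t test (participants with flat agent priors
#' excluded). Also runs the one-sample contrast of the signed self
#' difference `self_prior_sd - performance_sd` against zero — negative means
#' the self prior is narrower ("optimistic") than true performance.
#'
#' @param group_table one row per participant with `performance_sd_px`,
#'   `self_prior_sd_px`, `agent_prior_sd_px`, `agent_prior_flat`.
#' @return A list with the two contrasts and the per-participant deviations.
#' @export
prior_accuracy_contrast <- function(group_table) {
  g <- group_table
  need <- c("performance_sd_px", "self_prior_sd_px", "agent_prior_sd_px",
            "agent_prior_flat")
  if (!all(need %in% names(g))) {
    stop_input("group table must contain: ", paste(need, collapse = ", "))
  }
  self_dev <- abs(g$self_prior_sd_px - g$performance_sd_px)
  agent_dev <- abs(g$agent_prior_sd_px - g$performance_sd_px)
  keep <- !g$agent_prior_flat
  self_diff <- g$self_prior_sd_px - g$performance_sd_px
  self_vs_perf <- t_test_one(self_diff, mu = 0)
  paired <- if (sum(keep) >= 2L) {
    t_test_one(self_dev[keep], y = agent_dev[keep])
  } else {
    NULL  # all agent priors flat: paired contrast skipped
  }
  list(
    self_vs_performance = self_vs_perf,
    self_vs_agent_deviation = paired,
    n_flat_excluded = sum(!keep),
    deviations = data.frame(
      participant_id = g$participant_id,
      self_dev = self_dev, agent_dev = agent_dev,
      agent_prior_flat = g$agent_prior_flat
    ),
    note = if (is.null(paired)) "all agent priors flat: paired contrast skipped" else NULL
  )
}

#' Median-split analysis of learning by prior width
#'
#' Splits participants into two equal groups at the median self prior SD
#' (participants at the median join the lower group; with odd n the median
#' participant joins the lower group) and contrasts the learning score —
#' performance SD (during feedback) minus performance SD (before) — between
#' groups with a two-sample t test. Also reports the continuous correlation
#' between prior SD and learning score.
#'
#' @param group_table one row per participant with `self_prior_sd_px` and
#'   either a `learning_score` column or `performance_sd_during` /
#'   `performance_sd_before`.
#' @return A list with the group test, group sizes, and the correlation.
#' @export
median_split_learning <- function(group_table) {
  g <- group_table
  if (!"learning_score" %in% names(g)) {
    if (!all(c("performance_sd_during", "performance_sd_before") %in% names(g))) {
      stop_input("need learning_score or performance_sd_during/before")
    }
    g$learning_score <- g$performance_sd_during - g$performance_sd_before
  }
  n <- nrow(g)
  if (n < 4L) stop_stat("median split needs at least 4 participants")
  ord <- order(g$self_prior_sd_px, seq_len(n))  # stable tie-break
  n_low <- ceiling(n / 2)
  low <- ord[seq_len(n_low)]
  high <- ord[(n_low + 1L):n]
  test <- t_test_two(g$learning_score[low], g$learning_score[high])
  corr <- tryCatch(correlations(g$self_prior_sd_px, g$learning_score),
                   selfpriors_stat_error = function(e) NULL)
  list(group_test = test, n_low = length(low), n_high = length(high),
       split_value = stats::median(g$self_prior_sd_px),
       correlation = corr)
}
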