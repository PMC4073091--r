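#' Reliability weighting of the prior
#'
#' The weight the optimal observer gives the prior when combining it with
#' sensory evidence: `w = evidence_sd^2 / (prior_sd^2 + evidence_sd^2)`.
#' A narrow (reliable) prior or noisy evidence pushes `w` toward 1.
#'
#' @param prior_sd prior SD (> 0), px.
#' @param evidence_sd evidence SD (> 0), px.
#' @return `w` in (0, 1). Vectorized.
#' @export
posterior_weight <- function(prior_sd, evidence_sd) {
  if (any(!is.finite(prior_sd)) || any(prior_sd <= 0) ||
      any(!is.finite(evidence_sd)) || any(evidence_sd <= 0)) {
    stop_config("posterior_weight requires strictly positive, finite SDs")
  }
  # computed via the ratio so that huge (flat) prior SDs do not overflow
  r2 <- (evidence_sd / prior_sd)^2
  r2 / (1 + r2)
}

#' Predicted report distribution for a trial
#'
#' Under the Gaussian prior x Gaussian likelihood observer, the report is
#' `w * (prior_mean + prior_shift) + (1 - w) * (true_stop + direction *
#' evidence_shift)` plus evidence noise scaled by `(1 - w)`, i.e. the report
#' is Normal with that mean and SD `(1 - w) * evidence_sd`. The mean equals
#' the maximum of the posterior over final positions.
#'
#' @param params an [observer_params()]; `prior_mean_px = NA` means "use the
#'   target" (pass it via `prior_mean`).
#' @param true_stop true final position(s), px.
#' @param direction motion direction(s), +1 or -1.
#' @param prior_mean fallback prior mean when `params$prior_mean_px` is `NA`.
#' @return A list with vectors `mean` and `sd`.
#' @export
predict_estimate <- function(params, true_stop, direction = 1,
                             prior_mean = NULL) {
  stopifnot(inherits(params, "observer_params"))
  mu_p <- if (is.finite(params$prior_mean_px)) params$prior_mean_px else prior_mean
  if (is.null(mu_p)) stop_config("prior mean unspecified: set prior_mean_px or prior_mean")
  w <- posterior_weight(params$prior_sd_px, params$evidence_sd_px[[1]])
  mean <- w * (mu_p + params$prior_shift_px) +
    (1 - w) * (true_stop + direction * params$evidence_shift_px)
  list(mean = mean, sd = rep_len((1 - w) * params$evidence_sd_px[[1]],
                                 length(mean)))
}

# ---- parameter layout -----------------------------------------------------

# Maps a model spec + trial table onto a flat parameter vector:
# log prior SD per prior cell, log evidence SD per evidence cell, and (for
# shift models) one prior shift and one evidence shift per condition.
build_layout <- function(spec, trials) {
  lv <- data_levels(trials)
  prior_cells <- if ("condition" %in% spec$tie_prior_across) "all" else lv$condition
  ev_parts <- list()
  if (!("condition" %in% spec$tie_evidence_across)) {
    ev_parts$condition <- as.character(trials$condition)
  }
  if (!("direction" %in% spec$tie_evidence_across) &&
      length(lv$direction) > 1L) {
    ev_parts$direction <- ifelse(trials$direction > 0, "R", "L")
  }
  if (!("feedback_level" %in% spec$tie_evidence_across) &&
      length(lv$feedback_level) > 1L) {
    ev_parts$feedback_level <- as.character(trials$feedback_level)
  }
  ev_label <- if (length(ev_parts) == 0L) {
    rep("all", nrow(trials))
  } else {
    do.call(paste, c(ev_parts, sep = "."))
  }
  ev_cells <- sort(unique(ev_label))
  prior_label <- if (identical(prior_cells, "all")) {
    rep("all", nrow(trials))
  } else {
    as.character(trials$condition)
  }
  par_names <- c(paste0("prior_sd.", prior_cells),
                 paste0("evidence_sd.", ev_cells))
  if (spec$include_shifts) {
    par_names <- c(par_names,
                   paste0("prior_shift.", lv$condition),
                   paste0("evidence_shift.", lv$condition))
  }
  list(
    spec = spec, levels = lv,
    prior_cells = prior_cells, ev_cells = ev_cells,
    prior_idx = match(prior_label, prior_cells),
    ev_idx = match(ev_label, ev_cells),
    cond_idx = match(as.character(trials$condition), lv$condition),
    par_names = par_names,
    n_prior = length(prior_cells), n_ev = length(ev_cells),
    k = length(par_names)
  )
}

# theta: log SDs for the SD entries, raw px for shift entries
layout_nll <- function(theta, layout, target, true_stop, estimate, direction) {
  np <- layout$n_prior; ne <- layout$n_ev
  prior_sd <- exp(theta[seq_len(np)])[layout$prior_idx]
  ev_sd <- exp(theta[np + seq_len(ne)])[layout$ev_idx]
  if (layout$spec$include_shifts) {
    nc <- length(layout$levels$condition)
    sp <- theta[np + ne + seq_len(nc)][layout$cond_idx]
    se <- theta[np + ne + nc + seq_len(nc)][layout$cond_idx]
  } else {
    sp <- 0; se <- 0
  }
  dirfac <- if (layout$spec$evidence_shift_direction_coupled) direction else 1
  w <- posterior_weight(prior_sd, ev_sd)
  mu <- w * (target + sp) + (1 - w) * (true_stop + dirfac * se)
  sd <- (1 - w) * ev_sd
  ll <- stats::dnorm(estimate, mu, sd, log = TRUE)
  nll <- -sum(ll)
  if (!is.finite(nll)) nll <- 1e12  # penalty keeps the optimizer in-bounds
  nll
}

# analytic gradient of layout_nll in the same coordinates
# (log SDs; raw shifts). Derivatives use w' = -2w(1-w) wrt log prior SD and
# +2w(1-w) wrt log evidence SD.
layout_nll_grad <- function(theta, layout, target, true_stop, estimate,
                            direction) {
  np <- layout$n_prior; ne <- layout$n_ev
  prior_sd <- exp(theta[seq_len(np)])[layout$prior_idx]
  ev_sd <- exp(theta[np + seq_len(ne)])[layout$ev_idx]
  if (layout$spec$include_shifts) {
    nc <- length(layout$levels$condition)
    sp <- theta[np + ne + seq_len(nc)][layout$cond_idx]
    se <- theta[np + ne + nc + seq_len(nc)][layout$cond_idx]
  } else {
    nc <- 0L; sp <- 0; se <- 0
  }
  dirfac <- if (layout$spec$evidence_shift_direction_coupled) direction else 1
  w <- posterior_weight(prior_sd, ev_sd)
  P <- target + sp
  E <- true_stop + dirfac * se
  mu <- w * P + (1 - w) * E
  s <- (1 - w) * ev_sd
  r <- estimate - mu
  inv_s2 <- 1 / (s * s)
  # d/d(log prior sd) and d/d(log evidence sd) through w and s
  dw_da <- -2 * w * (1 - w)
  dmu_da <- (P - E) * dw_da
  ds_da <- -ev_sd * dw_da
  dmu_db <- -dmu_da
  ds_db <- (1 - w) * ev_sd * (1 - 2 * w)
  common_s <- (1 / s) - r * r / (s^3)
  g_a <- ds_da * common_s - dmu_da * r * inv_s2
  g_b <- ds_db * common_s - dmu_db * r * inv_s2
  grad <- c(
    as.numeric(rowsum(g_a, layout$prior_idx, reorder = TRUE)),
    as.numeric(rowsum(g_b, layout$ev_idx, reorder = TRUE))
  )
  if (layout$spec$include_shifts) {
    g_sp <- -w * r * inv_s2
    g_se <- -(1 - w) * dirfac * r * inv_s2
    grad <- c(grad,
              as.numeric(rowsum(g_sp, layout$cond_idx, reorder = TRUE)),
              as.numeric(rowsum(g_se, layout$cond_idx, reorder = TRUE)))
  }
  grad[!is.finite(grad)] <- 0
  grad
}

#' Negative log-likelihood of a trial set under the observer model
#'
#' Sums, over non-excluded trials, the negative log density of each report
#' under its predicted Normal distribution (see [predict_estimate()]), with
#' parameters resolved per factor cell according to the model spec.
#'
#' @param params named numeric vector on the natural scale: `prior_sd.<cell>`,
#'   `evidence_sd.<cell>`, and for shift models `prior_shift.<condition>` /
#'   `evidence_shift.<condition>`. Cell names as produced by [fit_model()].
#' @param spec a [model_spec()].
#' @param trials trial data frame (rows flagged `excluded` are dropped).
#' @return Total negative log-likelihood in nats (a non-finite likelihood is
#'   reported as a large finite penalty, flagged by attribute `degenerate`).
#' @export
neg_log_likelihood <- function(params, spec, trials) {
  use <- trials[!trials$excluded, , drop = FALSE]
  if (nrow(use) == 0L) stop_input("no usable trials")
  layout <- build_layout(spec, use)
  if (!all(layout$par_names %in% names(params))) {
    stop_config("params must name: ", paste(layout$par_names, collapse = ", "))
  }
  theta <- params[layout$par_names]
  sd_part <- seq_len(layout$n_prior + layout$n_ev)
  theta[sd_part] <- log(theta[sd_part])
  val <- layout_nll(unname(theta), layout, use$target_x_px,
                    use$true_stop_x_px, use$estimate_x_px, use$direction)
  structure(val, degenerate = (val >= 1e12))
}

#' Bayesian Information Criterion
#'
#' `bic = k * log(n) + 2 * neg_log_lik` (nats scale); lower is better.
#'
#' @param neg_log_lik total negative log-likelihood.
#' @param k number of free parameters.
#' @param n number of trials entering the fit.
#' @export
compute_bic <- function(neg_log_lik, k, n) {
  if (!is.finite(n) || n < 1) stop_config("BIC requires n >= 1")
  if (!is.finite(k) || k < 0) stop_config("BIC requires k >= 0")
  k * log(n) + 2 * neg_log_lik
}

#' Maximum-likelihood fit of an observer model
#'
#' Minimizes the negative log-likelihood over log-SD (and raw shift)
#' coordinates with multi-start L-BFGS-B: one moment-based start from the
#' error regression plus `n_restarts - 1` random restarts with log-uniform
#' SDs. Boundary-hugging prior SDs are returned as-is and left to
#' [classify_flat()] rather than treated as failures.
#'
#' @param trials trial data frame (excluded rows are dropped; rows without a
#'   finite target are dropped).
#' @param spec a [model_spec()].
#' @param n_restarts number of optimizer starts (>= 1).
#' @param seed seed for the random restarts.
#' @param sd_bounds log-scale box for the SDs, px.
#' @param shift_bounds box for shifts, px.
#' @return A `fit_result` list: `model`, `params` (named, natural scale),
#'   `weight_by_condition`, `neg_log_lik`, `n_trials`, `k`, `bic`,
#'   `converged`, `n_restarts_used`, `layout`.
#' @export
fit_model <- function(trials, spec, n_restarts = 8, seed = 1L,
                      sd_bounds = c(0.1, 1e9), shift_bounds = c(-1000, 1000)) {
  stopifnot(inherits(spec, "model_spec"))
  use <- trials[!trials$excluded & is.finite(trials$target_x_px), , drop = FALSE]
  layout <- build_layout(spec, use)
  if (nrow(use) < layout$k + 2L) {
    stop_fit(sprintf("need at least k + 2 = %d usable trials, got %d",
                     layout$k + 2L, nrow(use)))
  }
  perf_err <- use$true_stop_x_px - use$target_x_px
  est_err <- use$estimate_x_px - use$true_stop_x_px
  if (stats::sd(perf_err) == 0 && stats::sd(est_err) == 0) {
    stop_fit("degenerate input: zero variance in both errors")
  }

  # moment-based start from the pooled error regression
  w0 <- 0.5
  sd_e0 <- max(stats::sd(est_err), 1)
  if (stats::sd(perf_err) > 0) {
    b <- stats::coef(stats::lm(est_err ~ perf_err))[["perf_err"]]
    w0 <- min(max(-b, 0.02), 0.98)
    res <- stats::sd(stats::residuals(stats::lm(est_err ~ perf_err)))
    sd_e0 <- max(res / (1 - w0), 1)
  }
  sd_p0 <- sd_e0 * sqrt((1 - w0) / w0)
  smart <- c(rep(log(sd_p0), layout$n_prior), rep(log(sd_e0), layout$n_ev))
  if (spec$include_shifts) {
    smart <- c(smart, rep(0, 2L * length(layout$levels$condition)))
  }

  n_sd <- layout$n_prior + layout$n_ev
  lower <- c(rep(log(sd_bounds[1]), n_sd),
             rep(shift_bounds[1], layout$k - n_sd))
  upper <- c(rep(log(sd_bounds[2]), n_sd),
             rep(shift_bounds[2], layout$k - n_sd))

  nll_fn <- function(th) layout_nll(th, layout, use$target_x_px,
                                    use$true_stop_x_px, use$estimate_x_px,
                                    use$direction)
  grad_fn <- function(th) layout_nll_grad(th, layout, use$target_x_px,
                                          use$true_stop_x_px,
                                          use$estimate_x_px, use$direction)
  starts <- list(smart)
  if (n_restarts > 1L) {
    with_seed(derive_seed(seed, paste0("fit/", spec$name)), {
      for (r in seq_len(n_restarts - 1L)) {
        th <- c(stats::runif(n_sd, log(1), log(1e4)),
                if (layout$k > n_sd) stats::runif(layout$k - n_sd, -50, 50))
        starts[[r + 1L]] <- th
      }
    })
  }
  best <- NULL
  any_conv <- FALSE
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, nll_fn, gr = grad_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop_fit("all optimizer restarts failed",
                              diagnostics = list(n_restarts = n_restarts))
  theta <- best$par
  # A prior SD that the likelihood cannot distinguish from an arbitrarily
  # wide one is reported at the upper bound, where classify_flat() picks it
  # up, instead of at whatever large value the optimizer happened to stop at.
  for (j in seq_len(layout$n_prior)) {
    th_try <- theta
    th_try[j] <- log(sd_bounds[2])
    if (nll_fn(th_try) - best$value <= 1e-6) theta <- th_try
  }
  best_val <- nll_fn(theta)
  params <- theta
  params[seq_len(n_sd)] <- exp(theta[seq_len(n_sd)])
  names(params) <- layout$par_names

  prior_sd_t <- params[seq_len(layout$n_prior)][layout$prior_idx]
  ev_sd_t <- params[layout$n_prior + seq_len(layout$n_ev)][layout$ev_idx]
  w_t <- posterior_weight(prior_sd_t, ev_sd_t)
  w_by_cond <- tapply(w_t, use$condition, mean)

  n <- nrow(use)
  structure(list(
    model = spec$name,
    spec = spec,
    params = params,
    weight_by_condition = w_by_cond,
    neg_log_lik = best_val,
    n_trials = n,
    k = layout$k,
    bic = compute_bic(best_val, layout$k, n),
    converged = any_conv,
    n_restarts_used = length(starts),
    layout = layout
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s  NLL=%.3f  k=%d  n=%d  BIC=%.2f%s\n",
              x$model, x$neg_log_lik, x$k, x$n_trials, x$bic,
              if (x$converged) "" else "  [not converged]"))
  print(round(x$params, 3))
  invisible(x)
}

#' Classify fitted priors as flat
#'
#' A fitted prior is "flat" when its SD exceeds `threshold` (strictly): the
#' prior is so wide it contributes no bias and the weighting is effectively
#' zero. Flat priors are excluded from SD-based parametric contrasts but
#' retained for rank-based statistics.
#'
#' @param fit a `fit_result` (or a numeric vector of prior SDs).
#' @param threshold flatness threshold in px.
#' @return Named logical, one entry per prior cell.
#' @export
classify_flat <- function(fit, threshold = 1e7) {
  sds <- if (inherits(fit, "fit_result")) {
    fit$params[grep("^prior_sd\\.", names(fit$params))]
  } else fit
  out <- sds > threshold
  if (inherits(fit, "fit_result")) {
    names(out) <- sub("^prior_sd\\.", "", names(out))
  }
  out
}
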