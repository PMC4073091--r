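#' BIC model selection across participants
#'
#' Given, for each participant, a fit under every candidate model spec,
#' reports the per-participant winner (lowest BIC), and for every pair of
#' models the group mean BIC difference, the counts of participants favoring
#' each, and a strong-evidence verdict (inclusive at a mean |BIC difference|
#' of 6).
#'
#' @param fits named list: one entry per participant, each a named list of
#'   `fit_result`s keyed by model name. Every participant must carry the
#'   same model set.
#' @param strong_threshold BIC difference treated as strong evidence.
#' @return A list with `bic_table` (participant x model BICs), `winners`,
#'   `win_counts`, and `pairs` (per-pair mean difference, counts, verdict).
#' @export
compare_models <- function(fits, strong_threshold = 6) {
  if (length(fits) == 0L) stop_input("no fits supplied")
  model_names <- names(fits[[1]])
  for (p in names(fits)) {
    if (!identical(sort(names(fits[[p]])), sort(model_names))) {
      stop_input("ragged input: participant ", p,
                 " does not carry the same model set")
    }
  }
  bic <- t(vapply(fits, function(f) {
    vapply(model_names, function(m) f[[m]]$bic, numeric(1))
  }, numeric(length(model_names))))
  colnames(bic) <- model_names
  winners <- model_names[apply(bic, 1L, which.min)]
  names(winners) <- rownames(bic)

  pairs <- list()
  if (length(model_names) > 1L) {
    cmb <- utils::combn(model_names, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      d <- bic[, a] - bic[, b]  # positive favors b
      mean_diff <- mean(d)
      verdict <- if (abs(mean_diff) >= strong_threshold) {
        "strong"
      } else if (mean_diff == 0) "indistinguishable" else "weak"
      pairs[[paste(a, "vs", b)]] <- list(
        model_a = a, model_b = b,
        mean_bic_diff = mean_diff,
        favors = if (mean_diff < 0) a else if (mean_diff > 0) b else "neither",
        n_favor_a = sum(d < 0), n_favor_b = sum(d > 0), n_tied = sum(d == 0),
        strong_evidence = abs(mean_diff) >= strong_threshold,
        verdict = verdict
      )
    }
  }
  list(
    bic_table = bic,
    winners = winners,
    win_counts = table(factor(winners, levels = model_names)),
    pairs = pairs
  )
}

#' Percentile bootstrap confidence intervals for fitted parameters
#'
#' Resamples trials with replacement within participant x condition cells
#' (preserving the design), refits the model on each replicate (warm-started
#' at the original estimate), and returns per-parameter percentile intervals.
#'
#' @param trials trial data frame the original fit used.
#' @param spec a [model_spec()].
#' @param B number of bootstrap replicates (>= 2); the conventional default
#'   is 5000.
#' @param alpha 1 - confidence level (default 0.05 for 95% intervals).
#' @param seed integer seed; replicate r uses a substream derived from it.
#' @param n_restarts restarts per replicate refit (the warm start counts).
#' @param cells grouping columns defining the resampling unit.
#' @return A list with `ci` (data frame: `param`, `estimate`, `lower`,
#'   `upper`), `B`, `n_failed`, and the original `fit`.
#' @export
bootstrap_cis <- function(trials, spec, B = 5000, alpha = 0.05, seed = 1L,
                          n_restarts = 2,
                          cells = c("participant_id", "condition")) {
  if (B < 2) stop_config("B must be >= 2")
  fit <- fit_model(trials, spec, seed = seed)
  use <- trials[!trials$excluded & is.finite(trials$target_x_px), , drop = FALSE]
  cells <- intersect(cells, names(use))
  cell_id <- interaction(use[cells], drop = TRUE)
  idx_by_cell <- split(seq_len(nrow(use)), cell_id)

  n_sd <- fit$layout$n_prior + fit$layout$n_ev
  warm <- fit$params
  warm[seq_len(n_sd)] <- log(warm[seq_len(n_sd)])

  draws <- matrix(NA_real_, nrow = B, ncol = fit$k,
                  dimnames = list(NULL, names(fit$params)))
  n_failed <- 0L
  for (r in seq_len(B)) {
    idx <- unlist(lapply(idx_by_cell, function(ii) {
      with_seed(derive_seed(seed, sprintf("boot/%d/%s", r, ii[1])),
                sample(ii, length(ii), replace = TRUE))
    }), use.names = FALSE)
    rep_fit <- tryCatch(
      fit_model_from_start(use[idx, , drop = FALSE], spec, warm,
                           n_restarts = n_restarts,
                           seed = derive_seed(seed, paste0("bootfit/", r))),
      error = function(e) NULL)
    if (is.null(rep_fit)) {
      n_failed <- n_failed + 1L
    } else {
      draws[r, ] <- rep_fit$params[colnames(draws)]
    }
  }
  if (n_failed > B / 2) {
    stop_fit(sprintf("bootstrap failed: %d of %d replicate fits errored",
                     n_failed, B),
             diagnostics = list(n_failed = n_failed, B = B))
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci <- data.frame(
    param = names(fit$params),
    estimate = unname(fit$params),
    lower = apply(draws, 2L, stats::quantile, probs[1], na.rm = TRUE),
    upper = apply(draws, 2L, stats::quantile, probs[2], na.rm = TRUE),
    row.names = NULL
  )
  list(ci = ci, B = B, n_failed = n_failed, fit = fit)
}

# fit_model with an explicit extra start (used for warm-started refits)
fit_model_from_start <- function(trials, spec, start_theta, n_restarts = 2,
                                 seed = 1L) {
  # delegate to fit_model for the random restarts, then polish from the warm
  # start and keep the better optimum
  base <- if (n_restarts > 1L) {
    tryCatch(fit_model(trials, spec, n_restarts = n_restarts - 1L,
                       seed = seed),
             error = function(e) NULL)
  } else NULL
  use <- trials[!trials$excluded & is.finite(trials$target_x_px), , drop = FALSE]
  layout <- build_layout(spec, use)
  if (length(start_theta) != layout$k) {
    if (is.null(base)) stop_fit("warm start incompatible with data layout")
    return(base)
  }
  n_sd <- layout$n_prior + layout$n_ev
  lower <- c(rep(log(0.1), n_sd), rep(-1000, layout$k - n_sd))
  upper <- c(rep(log(1e9), n_sd), rep(1000, layout$k - n_sd))
  nll_fn <- function(th) layout_nll(th, layout, use$target_x_px,
                                    use$true_stop_x_px, use$estimate_x_px,
                                    use$direction)
  grad_fn <- function(th) layout_nll_grad(th, layout, use$target_x_px,
                                          use$true_stop_x_px,
                                          use$estimate_x_px, use$direction)
  opt <- tryCatch(
    stats::optim(unname(start_theta), nll_fn, gr = grad_fn,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e7)),
    error = function(e) NULL)
  if (is.null(opt) && is.null(base)) stop_fit("warm-start refit failed")
  if (!is.null(base) && (is.null(opt) || base$neg_log_lik <= opt$value)) {
    return(base)
  }
  params <- opt$par
  params[seq_len(n_sd)] <- exp(params[seq_len(n_sd)])
  names(params) <- layout$par_names
  n <- nrow(use)
  structure(list(
    model = spec$name, spec = spec, params = params,
    neg_log_lik = opt$value, n_trials = n, k = layout$k,
    bic = compute_bic(opt$value, layout$k, n),
    converged = opt$convergence == 0, n_restarts_used = n_restarts,
    layout = layout
  ), class = "fit_result")
}
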