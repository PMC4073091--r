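#' Flag trials excluded by the timing rules
#'
#' Two rules, each computed within participant x condition cells (and task,
#' if a `task` column is present): trials whose estimation time lies more
#' than 2 SD from the cell mean are flagged `est_time`; agent trials whose
#' reaction time to the computer's stop lies more than 2 SD from the cell
#' mean are flagged `agent_rt` (an attention control — the rule never touches
#' self trials). The rule is two-sided (`|t - mean| > 2 SD`), cells with zero
#' SD exclude nothing, and the cell statistics always include every trial, so
#' re-applying the function is a no-op. Rows are only flagged, never dropped.
#'
#' @param trials a trial data frame with `estimation_time_s` and (for agent
#'   rows) `reaction_time_s`.
#' @return The same data frame with `excluded` / `excluded_reason` set.
#' @export
apply_exclusions <- function(trials) {
  need <- c("participant_id", "condition", "estimation_time_s",
            "reaction_time_s")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0) {
    stop_input("missing timing columns: ", paste(missing_cols, collapse = ", "))
  }
  keys <- c("participant_id", "condition",
            if ("task" %in% names(trials)) "task")
  cell <- interaction(trials[keys], drop = TRUE)

  flag_2sd <- function(x) {
    ok <- is.finite(x)
    if (sum(ok) < 2L) return(rep(FALSE, length(x)))
    m <- mean(x[ok])
    s <- stats::sd(x[ok])
    out <- rep(FALSE, length(x))
    if (s > 0) out[ok] <- abs(x[ok] - m) > 2 * s
    out
  }

  est_flag <- stats::ave(trials$estimation_time_s, cell, FUN = flag_2sd) > 0
  rt_flag <- rep(FALSE, nrow(trials))
  is_agent <- trials$condition == "agent"
  if (any(is_agent)) {
    rt_raw <- stats::ave(trials$reaction_time_s, cell, FUN = flag_2sd) > 0
    rt_flag[is_agent] <- rt_raw[is_agent] & is.finite(trials$reaction_time_s[is_agent])
  }

  reason <- character(nrow(trials))
  reason[est_flag] <- "est_time"
  reason[rt_flag & !est_flag] <- "agent_rt"
  reason[rt_flag & est_flag] <- "est_time;agent_rt"
  trials$excluded <- est_flag | rt_flag
  trials$excluded_reason <- reason
  trials
}

#' Regress estimation error on performance error
#'
#' Ordinary least squares of the estimation error (report minus true final
#' position) on the performance error (true final position minus target),
#' over non-excluded trials. Under the reliability-weighted observer the
#' population slope is exactly `-w`, so the empirical prior weighting is the
#' negated slope; the residual SD estimates `(1 - w) * evidence_sd`.
#'
#' @param trials a trial data frame with targets (excluded rows are ignored).
#' @return A list of class `error_regression`: `slope`, `intercept`,
#'   `slope_se`, `residual_sd_px`, `n_used`, `weighting` (== `-slope`).
#' @export
fit_error_regression <- function(trials) {
  use <- trials[!trials$excluded & is.finite(trials$target_x_px), , drop = FALSE]
  if (nrow(use) < 3L) {
    stop_stat("need at least 3 usable trials with a target for the regression")
  }
  perf_err <- use$true_stop_x_px - use$target_x_px
  est_err <- use$estimate_x_px - use$true_stop_x_px
  if (stats::sd(perf_err) == 0) {
    stop_stat("performance error has zero variance; slope undefined")
  }
  fit <- stats::lm(est_err ~ perf_err)
  # exact fits (e.g. a veridical reporter) are legitimate; silence lm's
  # perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  res_ms <- sum(stats::residuals(fit)^2) / fit$df.residual
  structure(list(
    slope = unname(cf["perf_err", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope_se = unname(cf["perf_err", "Std. Error"]),
    residual_sd_px = sqrt(res_ms),
    n_used = nrow(use),
    weighting = -unname(cf["perf_err", "Estimate"])
  ), class = "error_regression")
}

#' Per-cell error regressions over a trial table
#'
#' Convenience wrapper running [fit_error_regression()] within participant x
#' condition (x extra grouping columns) cells.
#'
#' @param trials trial data frame.
#' @param by grouping columns.
#' @return A data frame with one row per cell and the regression fields.
#' @export
regress_by_cell <- function(trials, by = c("participant_id", "condition")) {
  cells <- unique(trials[by])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(trials))
    for (k in by) sel <- sel & trials[[k]] == cells[[k]][i]
    r <- fit_error_regression(trials[sel, , drop = FALSE])
    cbind(cells[i, , drop = FALSE],
          data.frame(slope = r$slope, intercept = r$intercept,
                     slope_se = r$slope_se, residual_sd_px = r$residual_sd_px,
                     n_used = r$n_used, weighting = r$weighting))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
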