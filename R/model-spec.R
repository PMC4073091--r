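#' Define a parameter-tying scheme for the observer model
#'
#' A model spec says which factor cells share which parameters. Evidence SDs
#' can be tied across any of condition, direction and feedback level; prior
#' SDs can be tied across condition. Shift models add, per condition, a prior
#' shift (offset of the prior mean from the target) and an evidence shift
#' whose sign follows the ball's direction of motion.
#'
#' @param name identifier.
#' @param tie_evidence_across factors across which the evidence SD is shared,
#'   subset of `c("condition", "direction", "feedback_level")`.
#' @param tie_prior_across factors across which the prior SD is shared,
#'   subset of `c("condition")`.
#' @param include_shifts add per-condition prior and evidence shifts.
#' @param fix_prior_mean_at_target prior mean fixed at the trial's target
#'   (always `TRUE` here; shift models displace it via the prior shift).
#' @param evidence_shift_direction_coupled the evidence shift enters with the
#'   sign of the motion direction.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name,
                       tie_evidence_across = character(),
                       tie_prior_across = character(),
                       include_shifts = FALSE,
                       fix_prior_mean_at_target = TRUE,
                       evidence_shift_direction_coupled = include_shifts) {
  ok_ev <- c("condition", "direction", "feedback_level")
  if (!all(tie_evidence_across %in% ok_ev)) {
    stop_config("tie_evidence_across must be a subset of ",
                paste(ok_ev, collapse = "/"))
  }
  if (!all(tie_prior_across %in% "condition")) {
    stop_config("tie_prior_across may only contain 'condition'")
  }
  structure(list(
    name = name,
    tie_evidence_across = tie_evidence_across,
    tie_prior_across = tie_prior_across,
    include_shifts = include_shifts,
    fix_prior_mean_at_target = fix_prior_mean_at_target,
    evidence_shift_direction_coupled = evidence_shift_direction_coupled
  ), class = "model_spec")
}

#' Preset model specs
#'
#' The single-direction family: `exp1_full` (separate prior and evidence SD
#' per condition, 4 parameters with two conditions), `exp1_shared_evidence`
#' (evidence SD tied across conditions, 3), `exp1_shared_prior` (prior SD
#' tied, 3). The bidirectional shift family: `exp2_full_shift` (per
#' condition: prior SD, prior shift, direction-coupled evidence shift;
#' evidence SD per condition x direction; 10) and `exp2_shared_direction`
#' (evidence SD tied across direction; 8).
#'
#' @param name preset name.
#' @return A [model_spec()].
#' @export
model_preset <- function(name = c("exp1_full", "exp1_shared_evidence",
                                  "exp1_shared_prior", "exp2_full_shift",
                                  "exp2_shared_direction")) {
  name <- match.arg(name)
  switch(name,
    exp1_full = model_spec("exp1_full"),
    exp1_shared_evidence = model_spec("exp1_shared_evidence",
                                      tie_evidence_across = "condition"),
    exp1_shared_prior = model_spec("exp1_shared_prior",
                                   tie_prior_across = "condition"),
    exp2_full_shift = model_spec("exp2_full_shift", include_shifts = TRUE),
    exp2_shared_direction = model_spec("exp2_shared_direction",
                                       tie_evidence_across = "direction",
                                       include_shifts = TRUE)
  )
}

# factor levels actually present in a trial table
data_levels <- function(trials) {
  list(
    condition = sort(unique(as.character(trials$condition))),
    direction = sort(unique(as.integer(trials$direction))),
    feedback_level = sort(unique(as.character(trials$feedback_level)))
  )
}

#' Number of free parameters implied by a model spec
#'
#' A pure function of the spec and the factor levels present in the data:
#' one prior SD per untied condition, one evidence SD per combination of
#' untied factors, plus (for shift models) one prior shift and one evidence
#' shift per condition. With two conditions and one direction the
#' single-direction presets give 4 (full) and 3 (either SD tied); with two
#' conditions and two directions the shift presets give 10 and 8.
#'
#' @param spec a [model_spec()].
#' @param levels factor levels, as from `data_levels()` or a list with
#'   entries `condition`, `direction`, `feedback_level`.
#' @return Integer parameter count.
#' @export
count_free_params <- function(spec, levels) {
  stopifnot(inherits(spec, "model_spec"))
  n_cond <- length(levels$condition)
  n_dir <- max(1L, length(levels$direction))
  n_fb <- max(1L, length(levels$feedback_level))
  if (n_cond < 1L) stop_config("levels$condition must be non-empty")
  n_prior <- if ("condition" %in% spec$tie_prior_across) 1L else n_cond
  n_ev <- prod(
    if ("condition" %in% spec$tie_evidence_across) 1L else n_cond,
    if ("direction" %in% spec$tie_evidence_across) 1L else n_dir,
    if ("feedback_level" %in% spec$tie_evidence_across) 1L else n_fb
  )
  n_shift <- if (spec$include_shifts) 2L * n_cond else 0L
  as.integer(n_prior + n_ev + n_shift)
}
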