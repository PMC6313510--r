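#' Perceived safety-specific social support
#'
#' The ratio of management interventions received by the crew (safety
#' improvements plus safety feedback) to coworker safety violations, scaled
#' and capped at 1. With no violations in the window the support ratio is
#' vacuously satisfied and support is full (1).
#'
#' @param n_impr,n_fb,n_viol Window counts of safety improvements, safety
#'   feedback and coworker violations.
#' @param scaling Scaling parameter (default 100).
#' @return Support in `[0, 1]`. Vectorized.
#' @export
perceived_social_support <- function(n_impr, n_fb, n_viol, scaling = 100) {
  ifelse(n_viol == 0, 1,
         pmin(1, (n_impr + n_fb) / pmax(n_viol, 1e-300) * scaling))
}

#' Perceived production pressure
#'
#' Zero for crews at or above the average productivity; otherwise the crew's
#' relative shortfall times the scaling parameter, capped at 1.
#'
#' @param crew_prod Crew productivity over the trailing window.
#' @param avg_prod Average productivity of all crews over the same window.
#' @param scaling Scaling parameter (default 100).
#' @return Pressure in `[0, 1]`. Vectorized over `crew_prod`.
#' @export
perceived_production_pressure <- function(crew_prod, avg_prod,
                                          scaling = 100) {
  if (avg_prod <= 0) return(rep(0, length(crew_prod)))
  ifelse(crew_prod >= avg_prod, 0,
         pmin(1, (avg_prod - crew_prod) / avg_prod * scaling))
}

#' Attitudinal ambivalence toward safety compliance
#'
#' Empirical path-coefficient combination of the two perceptions:
#' `w = min(1, max(0, 0.68 * PP - 0.13 * SS))`.
#'
#' @param pp Perceived production pressure in `[0, 1]`.
#' @param ss Perceived safety-specific social support in `[0, 1]`.
#' @return Ambivalence weight in `[0, 1]`. Vectorized.
#' @export
attitudinal_ambivalence <- function(pp, ss) {
  pmin(1, pmax(0, 0.68 * pp - 0.13 * ss))
}

#' Safety performance gap and safety control pressure
#'
#' The weighted incident count of the trailing week (near-misses plus ten
#' times accidents) is compared against the weekly tolerable count
#' `safe_goal`; the relative excess is the safety performance gap, clamped to
#' `[0, 1]` as the safety control pressure.
#'
#' @param near_7d,acc_7d Near-miss and accident counts over the trailing 7
#'   days.
#' @param safe_goal Weekly tolerable weighted incident count (> 0).
#' @return List: `gap` and `scp`.
#' @export
safety_control_pressure <- function(near_7d, acc_7d, safe_goal) {
  if (safe_goal <= 0) stop("safe_goal must be positive")
  gap <- (near_7d + 10 * acc_7d - safe_goal) / safe_goal
  list(gap = gap, scp = min(1, max(0, gap)))
}

#' Daily management outputs
#'
#' Translates the proactive-management intensity and the reactive safety
#' control pressure into the four management parameters: intervention rates
#' `max(1 - proacMan, SCP)`, inspection distance (the same quantity scaled by
#' `distance_scale`), and the tolerable hazard level
#' `min(100 * proacMan, 100 * (1 - SCP))`. A lower `proac_man` is the
#' "highly intensive" direction: higher rates, larger reach, lower
#' tolerance.
#'
#' @param proac_man Proactive management intensity in `[0, 1]`.
#' @param scp Safety control pressure in `[0, 1]`.
#' @param distance_scale Cells of inspection reach at full intensity. The
#'   default 10 makes the baseline (`proac_man = 0.5`, `scp = 0`) distance 5.
#' @param hazard_scale Hazard units per unit tolerance (default 100).
#' @return List: `feedback_rate`, `improvement_rate`, `distance`,
#'   `tolerable_hazard`.
#' @export
management_outputs <- function(proac_man, scp, distance_scale = 10,
                               hazard_scale = 100) {
  if (proac_man < 0 || proac_man > 1 || scp < 0 || scp > 1)
    stop("proac_man and scp must lie in [0, 1]")
  intensity <- max(1 - proac_man, scp)
  list(feedback_rate = intensity,
       improvement_rate = intensity,
       distance = distance_scale * intensity,
       tolerable_hazard = min(hazard_scale * proac_man,
                              hazard_scale * (1 - scp)))
}
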