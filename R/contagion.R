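#' Coworker hazard index
#'
#' The per-task violation-hazard load of a coworker over the observation
#' window: the sum of the hazard levels at each of the coworker's violations
#' divided by the total number of tasks the coworker completed. A coworker
#' with no completed tasks exposes no observable behaviour and contributes 0.
#'
#' The engine's default contagion index instead feeds this quotient with the
#' hazards of *all* completed tasks (mean exposure during task
#' implementation); see the `contagion_index` field of
#' [simulation_config()] and the methods vignette for why both readings are
#' provided.
#'
#' @param violation_hazards Hazard levels at the coworker's violations within
#'   the window (vector, possibly empty), or a precomputed sum.
#' @param n_tasks Total tasks the coworker completed within the window.
#' @return The index, hazard units.
#' @export
coworker_hazard_index <- function(violation_hazards, n_tasks) {
  if (n_tasks == 0) return(0)
  sum(violation_hazards) / n_tasks
}

#' Update the perceived crew hazard tolerance
#'
#' Memory-weighted recursion: the new crew tolerance is a convex combination
#' of the previous value (weight `1 - 1/m`) and the mean of the coworkers'
#' current hazard indices (weight `1/m`).
#'
#' @param tc_prev Previous crew tolerance, hazard units.
#' @param coworker_indices Hazard indices of the crew clique (excluding the
#'   focal worker); nonempty.
#' @param m Memory capacity in days (`m >= 1`).
#' @return Updated crew tolerance.
#' @export
update_crew_tolerance <- function(tc_prev, coworker_indices, m) {
  if (m < 1) stop("memory capacity m must be >= 1")
  if (length(coworker_indices) == 0) stop("coworker clique must be nonempty")
  (1 - 1 / m) * tc_prev + mean(coworker_indices) / m
}

#' Blend crew and management tolerance by attitudinal ambivalence
#'
#' The final perceived hazard tolerance is the ambivalence-weighted convex
#' combination of the crew norm and the management tolerance: workers with
#' high ambivalence weight the crew norm, workers with low ambivalence weight
#' the formal rule.
#'
#' @param tc Crew hazard tolerance.
#' @param tm Management tolerable hazard level.
#' @param w Attitudinal ambivalence weight in `[0, 1]`.
#' @return Perceived tolerance, hazard units. Vectorized.
#' @export
perceived_tolerance <- function(tc, tm, w) {
  if (any(w < 0 | w > 1)) stop("ambivalence weight must lie in [0, 1]")
  w * tc + (1 - w) * tm
}

#' Adapt a worker's acceptable hazard level
#'
#' Risk-homeostasis set point adaptation: the acceptable hazard moves toward
#' the perceived tolerance at the worker's contagion probability, then is
#' clamped to the admissible range. A contagion probability of 0 leaves the
#' worker unchanged; 1 makes the worker fully determined by external
#' influence.
#'
#' @param ar_prev Previous acceptable hazard.
#' @param tr Perceived tolerance (see [perceived_tolerance()]).
#' @param cp Contagion probability in `[0, 1]`.
#' @param clamp Bounds for the result.
#' @return Updated acceptable hazard. Vectorized.
#' @export
adapt_acceptable_hazard <- function(ar_prev, tr, cp, clamp = c(0, 200)) {
  if (any(cp < 0 | cp > 1)) stop("contagion probability must lie in [0, 1]")
  pmin(pmax((1 - cp) * ar_prev + cp * tr, clamp[1]), clamp[2])
}
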