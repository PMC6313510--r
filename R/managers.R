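#' Relocate managers by patrol-by-sampling
#'
#' Each tick every manager moves to the cell of a uniformly chosen non-stopped
#' member of their crew; if the whole crew is stopped the manager stays put.
#'
#' @param manager_pos Integer vector of manager cell indices (one per crew).
#' @param worker_pos Worker cell indices.
#' @param crew Crew id per worker.
#' @param active Logical: is the worker available (not stopped)?
#' @return Updated manager positions.
#' @export
position_managers <- function(manager_pos, worker_pos, crew, active) {
  for (k in seq_along(manager_pos)) {
    cand <- worker_pos[crew == k & active]
    if (length(cand) > 0)
      manager_pos[k] <- cand[sample.int(length(cand), 1L)]
  }
  manager_pos
}

#' Chebyshev distance between two cells
#'
#' Grid-native inspection metric: a worker "within d metres" occupies the
#' `(2d+1) x (2d+1)` square centred on the manager.
#'
#' @param a,b Cell indices.
#' @param W Grid width.
#' @return Integer distance.
#' @export
chebyshev_distance <- function(a, b, W) {
  ax <- (a - 1L) %% W; ay <- (a - 1L) %/% W
  bx <- (b - 1L) %% W; by <- (b - 1L) %/% W
  pmax(abs(ax - bx), abs(ay - by))
}

#' Inspect a worker starting a task
#'
#' Management intervenes only when the worker is within the inspection
#' distance and the cell's effective hazard exceeds the management tolerance.
#' A present situational constraint is then removed with probability
#' `improvement_rate` (safety improvement; the worker proceeds to safety
#' checking). Otherwise, a pending routine violation is averted with
#' probability `feedback_rate` (safety feedback; the warned task is performed
#' compliantly and the averted violation is not counted).
#'
#' @param manager_pos,worker_pos Cell indices.
#' @param W Grid width.
#' @param hazard Effective hazard of the task cell.
#' @param tm Management tolerable hazard level.
#' @param distance Inspection distance (cells).
#' @param constraint_present Situational constraint on the cell?
#' @param pending_routine Would the worker commit a routine violation absent
#'   feedback?
#' @param feedback_rate,improvement_rate Intervention probabilities.
#' @return List: `result` (`"FEEDBACK_GIVEN"`, `"IMPROVEMENT_MADE"` or
#'   `"NONE"`) and `constraint_present` after any improvement.
#' @export
inspect_worker <- function(manager_pos, worker_pos, W, hazard, tm, distance,
                           constraint_present, pending_routine,
                           feedback_rate, improvement_rate) {
  res <- "NONE"
  in_range <- chebyshev_distance(manager_pos, worker_pos, W) <= distance
  if (in_range && hazard > tm) {
    if (constraint_present) {
      if (stats::runif(1) < improvement_rate) {
        constraint_present <- FALSE
        res <- "IMPROVEMENT_MADE"
      }
    } else if (pending_routine) {
      if (stats::runif(1) < feedback_rate) res <- "FEEDBACK_GIVEN"
    }
  }
  list(result = res, constraint_present = constraint_present)
}
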