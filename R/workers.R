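#' Worker behavioural parameters
#'
#' Parameters governing worker agents: initial acceptable-hazard and contagion
#' probability ranges (uniform heterogeneity across the crew), production
#' speed, the safety-productivity tradeoff, contagion memory, and the
#' experiential decrements applied after near-misses and accidents.
#'
#' @param acceptable_hazard_range Uniform range for each worker's initial
#'   acceptable hazard level (hazard units); extremes of absolute risk
#'   aversion/seeking are excluded.
#' @param contagion_pro_range Uniform range of the contagion probability.
#' @param production_speed Compliant production speed, workload units per day.
#' @param production_incr Fractional speed gain while violating (the
#'   safety-productivity tradeoff), applied per violating task only.
#' @param memory_days Memory capacity `m` for coworker behaviour, days.
#' @param nearmiss_ar_decrement,accident_ar_decrement Drop in acceptable
#'   hazard after a near-miss / an accident.
#' @param accident_stop_days Work stoppage after an accident, days.
#' @param ar_clamp Bounds that the acceptable hazard is clamped to.
#' @return A `worker_params` list.
#' @export
worker_params <- function(acceptable_hazard_range = c(20, 180),
                          contagion_pro_range = c(0.1, 0.9),
                          production_speed = 20,
                          production_incr = 0.2,
                          memory_days = 28,
                          nearmiss_ar_decrement = 5,
                          accident_ar_decrement = 50,
                          accident_stop_days = 3,
                          ar_clamp = c(0, 200)) {
  if (production_speed <= 0) stop("production_speed must be positive")
  if (memory_days < 1) stop("memory_days must be >= 1")
  structure(as.list(environment()), class = "worker_params")
}

#' Violation outcome probabilities
#'
#' Calibration constants for the three possible outcomes of a violating task:
#' no incident (with the temporary speed bonus), a near-miss, or an accident.
#' The law is linear in hazard: at effective hazard `h` a violation ends in
#' an accident with probability `alpha * h / 200` and in a near-miss with
#' probability `r * alpha * h / 200`; a hazard of 0 can never produce an
#' incident. Defaults were calibrated (jointly with the situational
#' constraint coefficient in [site_config()]) so that the modest-hazard
#' baseline reproduces empirical benchmarks: roughly one violation per three
#' worker-days, ~11% situational share, ~3.2 accidents per 100 full-time
#' worker-years, and a Heinrich-like near-miss:accident ratio near 8.
#'
#' @param p_accident_at_max Probability `alpha` of an accident per violation
#'   at the maximum hazard 200.
#' @param nearmiss_multiplier Ratio `r` of near-miss to accident probability.
#' @return An `outcome_params` list.
#' @export
outcome_params <- function(p_accident_at_max = 0.00165,
                           nearmiss_multiplier = 8.18) {
  if (p_accident_at_max * (1 + nearmiss_multiplier) > 1)
    stop("outcome probabilities exceed 1 at maximum hazard")
  structure(list(p_accident_at_max = p_accident_at_max,
                 nearmiss_multiplier = nearmiss_multiplier),
            class = "outcome_params")
}

#' Initialize a heterogeneous worker population
#'
#' Draws each worker's initial acceptable hazard and contagion probability
#' from their uniform ranges and assigns workers to equally sized crews.
#' Under factorial manipulation of the median contagion probability `M`, each
#' worker's draw is shifted by `M - 0.5` and clamped to `[0.1, 0.99]`,
#' preserving the baseline spread (and the baseline's exclusion of
#' effectively frozen extreme cases) while moving the median.
#'
#' @param n_workers Number of workers.
#' @param n_crews Number of crews (`n_workers` must be divisible).
#' @param params A [worker_params()].
#' @param median_contagion Target median contagion probability (0.5 leaves
#'   the baseline U(0.1, 0.9) untouched).
#' @return List of vectors: `crew`, `ar` (acceptable hazard), `cp` (contagion
#'   probability).
#' @export
init_workers <- function(n_workers = 100L, n_crews = 5L,
                         params = worker_params(),
                         median_contagion = 0.5) {
  if (n_workers %% n_crews != 0)
    stop("n_workers must be a multiple of n_crews")
  ar <- stats::runif(n_workers, params$acceptable_hazard_range[1],
                     params$acceptable_hazard_range[2])
  u <- stats::runif(n_workers, params$contagion_pro_range[1],
                    params$contagion_pro_range[2])
  cp <- pmin(0.99, pmax(0.1, u + (median_contagion - 0.5)))
  crew <- rep(seq_len(n_crews), each = n_workers / n_crews)
  list(crew = crew, ar = ar, cp = cp)
}

#' Decide how a task will be implemented
#'
#' The decision chain at task start: a situational constraint that management
#' has not removed forces a situational violation; otherwise the worker
#' performs safety checking by risk homeostasis - if the cell's effective
#' hazard is below the worker's acceptable hazard the worker commits a
#' routine violation (unless suppressed by management feedback, in which case
#' the task is performed normally); otherwise the task is compliant.
#'
#' @param hazard Effective hazard of the cell.
#' @param acceptable_hazard The worker's acceptable hazard level.
#' @param constraint_present Is an (unremoved) situational constraint
#'   present?
#' @param feedback_given Has management feedback suppressed a pending routine
#'   violation?
#' @return One of `"NORMAL"`, `"ROUTINE_VIOLATION"`,
#'   `"SITUATIONAL_VIOLATION"`.
#' @export
decide_task_mode <- function(hazard, acceptable_hazard,
                             constraint_present = FALSE,
                             feedback_given = FALSE) {
  if (constraint_present) return("SITUATIONAL_VIOLATION")
  if (hazard < acceptable_hazard) {
    if (feedback_given) return("NORMAL")
    return("ROUTINE_VIOLATION")
  }
  "NORMAL"
}

#' Task duration in days
#'
#' Duration is workload over production speed; violating tasks run at the
#' temporarily increased speed `production_speed * (1 + production_incr)`.
#'
#' @param workload Cell workload, units.
#' @param production_speed Compliant speed, units/day.
#' @param mode Task mode (see [decide_task_mode()]).
#' @param production_incr Fractional violation speed bonus.
#' @return Duration in days.
#' @export
task_duration <- function(workload, production_speed, mode = "NORMAL",
                          production_incr = 0.2) {
  if (any(production_speed <= 0)) stop("production_speed must be positive")
  speed <- production_speed *
    ifelse(mode == "NORMAL", 1, 1 + production_incr)
  workload / speed
}

#' Roll the outcome of a violating task
#'
#' Drawn once per violating task at completion: accident with probability
#' `alpha * h / 200`, near-miss with probability `r * alpha * h / 200`,
#' otherwise no incident. Vectorized over `hazard`.
#'
#' @param hazard Effective hazard at the task (0..200).
#' @param params An [outcome_params()].
#' @return Character vector in `"NONE"`, `"NEAR_MISS"`, `"ACCIDENT"`.
#' @export
roll_violation_outcome <- function(hazard, params = outcome_params()) {
  p_acc <- params$p_accident_at_max * hazard / 200
  p_nm <- params$nearmiss_multiplier * p_acc
  if (any(p_acc + p_nm > 1)) stop("outcome probabilities exceed 1")
  u <- stats::runif(length(hazard))
  out <- rep("NONE", length(hazard))
  out[u < p_acc + p_nm] <- "NEAR_MISS"
  out[u < p_acc] <- "ACCIDENT"
  out
}

#' Apply a violation outcome to a worker
#'
#' A near-miss lowers the acceptable hazard by the near-miss decrement; an
#' accident lowers it by the accident decrement and stops the worker for the
#' configured number of days. The acceptable hazard is clamped to its bounds.
#'
#' @param ar The worker's acceptable hazard before the outcome.
#' @param outcome One of `"NONE"`, `"NEAR_MISS"`, `"ACCIDENT"`.
#' @param params A [worker_params()].
#' @return List with updated `ar` and `stop_days` (0 unless an accident).
#' @export
apply_outcome <- function(ar, outcome, params = worker_params()) {
  stop_days <- 0
  if (outcome == "NEAR_MISS") {
    ar <- ar - params$nearmiss_ar_decrement
  } else if (outcome == "ACCIDENT") {
    ar <- ar - params$accident_ar_decrement
    stop_days <- params$accident_stop_days
  }
  ar <- min(max(ar, params$ar_clamp[1]), params$ar_clamp[2])
  list(ar = ar, stop_days = stop_days)
}

#' Choose the next cell for an approaching worker
#'
#' One step to a uniformly chosen 8-neighbour building cell with positive
#' workload; if none is available, a uniform random-walk step over all
#' in-grid neighbours (the worker stays in the approaching state).
#'
#' @param pos Current cell index.
#' @param grid A `site_grid`.
#' @return List: `pos` (new cell index) and `has_work` (logical).
#' @export
choose_next_cell <- function(pos, grid) {
  nb <- .cell_neighbours(pos, grid$W, grid$H)
  work <- nb[grid$is_building[nb] & grid$workload[nb] > 0]
  if (length(work) > 0) {
    list(pos = work[sample.int(length(work), 1L)], has_work = TRUE)
  } else {
    list(pos = nb[sample.int(length(nb), 1L)], has_work = FALSE)
  }
}

.cell_neighbours <- function(pos, W, H) {
  x <- ((pos - 1L) %% W) + 1L
  y <- ((pos - 1L) %/% W) + 1L
  xs <- x + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  ys <- y + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  ok <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
  xs[ok] + (ys[ok] - 1L) * W
}
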