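#' Full simulation configuration
#'
#' Bundles the site, worker, outcome and system-dynamics settings for one
#' run. Defaults are the modest-hazard baseline: 100 workers in 5 crews of
#' 20 with one manager each, a 250 work-day horizon (one full-time work
#' year) at 10 ticks per day, `safeGoal = 1.25`, `proacMan = 0.5`,
#' production increase 0.2, contagion probability U(0.1, 0.9) and a 28-day
#' memory.
#'
#' @param n_workers,n_crews Workforce size and crew count (one manager per
#'   crew).
#' @param horizon_days Simulated work days.
#' @param ticks_per_day Sub-day agent ticks (tasks shorter than a day
#'   resolve at tick granularity; contagion and system dynamics update
#'   daily).
#' @param site A [site_config()].
#' @param worker A [worker_params()].
#' @param outcome An [outcome_params()].
#' @param safe_goal Weekly tolerable weighted incident count.
#' @param proac_man Proactive management intensity in `[0, 1]`.
#' @param median_contagion Target median contagion probability.
#' @param support_scaling,pressure_scaling Scaling parameters of the social
#'   support and production pressure auxiliaries.
#' @param distance_scale Inspection reach at full management intensity,
#'   cells.
#' @param sd_window_days Trailing window for the system-dynamics stocks
#'   (incident counts against the weekly `safe_goal`, crew intervention and
#'   violation counts behind social support).
#' @param pp_window_days Trailing window for the crew productivity
#'   comparison behind production pressure. The default 1 compares the
#'   previous day's crew outputs: with homogeneous workers a longer window
#'   averages crew differences below the pressure auxiliary's saturation
#'   threshold and collapses ambivalence (see the methods vignette).
#' @param contagion_index `"exposure"`: the crew tolerance index averages
#'   the hazard a coworker is exposed to over all completed tasks;
#'   `"violation_load"`: only violation hazards enter the numerator (still
#'   divided by total tasks). See the methods vignette.
#' @param contagion_enabled Disable to freeze acceptable hazards at their
#'   initial values (used by compliant-productivity checks).
#' @param log_events Record a per-task event log (slower, more memory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_workers = 100L, n_crews = 5L,
                              horizon_days = 250L, ticks_per_day = 10L,
                              site = site_config(),
                              worker = worker_params(),
                              outcome = outcome_params(),
                              safe_goal = 1.25, proac_man = 0.5,
                              median_contagion = 0.5,
                              support_scaling = 100, pressure_scaling = 100,
                              distance_scale = 10,
                              sd_window_days = 7L,
                              pp_window_days = 1L,
                              contagion_index = c("exposure",
                                                  "violation_load"),
                              contagion_enabled = TRUE,
                              log_events = FALSE) {
  if (n_workers %% n_crews != 0)
    stop("n_workers must be a multiple of n_crews")
  if (horizon_days < 1) stop("horizon_days must be >= 1")
  if (proac_man < 0 || proac_man > 1) stop("proac_man must lie in [0, 1]")
  contagion_index <- match.arg(contagion_index)
  structure(list(
    n_workers = as.integer(n_workers), n_crews = as.integer(n_crews),
    horizon_days = as.integer(horizon_days),
    ticks_per_day = as.integer(ticks_per_day),
    site = site, worker = worker, outcome = outcome,
    safe_goal = safe_goal, proac_man = proac_man,
    median_contagion = median_contagion,
    support_scaling = support_scaling,
    pressure_scaling = pressure_scaling,
    distance_scale = distance_scale,
    sd_window_days = as.integer(sd_window_days),
    pp_window_days = as.integer(pp_window_days),
    contagion_index = contagion_index,
    contagion_enabled = isTRUE(contagion_enabled),
    log_events = isTRUE(log_events)
  ), class = "simulation_config")
}

# 8-neighbour index list for every cell, computed once per run.
.neighbour_list <- function(W, H) {
  nc <- W * H
  out <- vector("list", nc)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      xs <- x + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      ys <- y + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      ok <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
      out[[x + (y - 1L) * W]] <- xs[ok] + (ys[ok] - 1L) * W
    }
  }
  out
}

#' Run one simulation
#'
#' Executes the daily loop - system-dynamics update from the previous day's
#' stocks, contagion update of every worker's acceptable hazard, then
#' tick-level agent simulation (crane rotation, manager patrol, task
#' decisions with inspection, continuous task execution, outcome rolls at
#' completion). Movement between tasks is instantaneous at task boundaries;
#' the fraction of a tick left after completing a task carries into the next
#' one, so a fully compliant worker produces exactly
#' `production_speed` units per day.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `crewsim_run` list: `totals`, `daily` data frame, per-crew
#'   daily matrices (`crew_daily`), per-worker summaries (`workers`), the
#'   optional event log, and the echoed `config` and `seed`.
#' @export
run_simulation <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  N <- config$n_workers; K <- config$n_crews
  H <- config$horizon_days; tpd <- config$ticks_per_day
  tick_days <- 1 / tpd
  wp <- config$worker; op <- config$outcome
  speed0 <- wp$production_speed
  incr <- wp$production_incr
  m_days <- wp$memory_days
  alpha <- op$p_accident_at_max; rmul <- op$nearmiss_multiplier
  kappa <- config$site$constraint_coeff
  wl_max <- config$site$workload_max
  swin <- config$sd_window_days
  use_exposure <- config$contagion_index == "exposure"
  crew_size <- N %/% K

  grid <- generate_site(config$site)
  W <- grid$W
  workload <- grid$workload
  base_h <- grid$base_hazard
  crane_h <- grid$crane_hazard
  constraint <- grid$constraint
  hz_mode <- config$site$hazard_mode
  crane_lo <- config$site$crane_hazard_range[1]
  crane_hi <- config$site$crane_hazard_range[2]
  cranes <- grid$cranes
  n_hsteps <- grid$n_heading_steps
  nbrs <- .neighbour_list(W, grid$H)

  wk <- init_workers(N, K, wp, config$median_contagion)
  crew <- wk$crew; ar <- wk$ar; cp <- wk$cp
  ar0 <- ar
  building_work <- which(grid$is_building)
  pos <- building_work[sample.int(length(building_work), N, replace = TRUE)]
  state <- integer(N)            # 0 approaching, 1 implementing, 2 stopped
  stop_ticks <- integer(N)
  rem <- numeric(N)              # remaining task duration, days
  task_speed <- numeric(N)
  task_mode <- integer(N)        # 0 normal, 1 routine, 2 situational
  task_h <- numeric(N)
  task_cell <- integer(N)

  tc <- as.vector(rowsum(ar, crew)) / crew_size
  tc <- tc[crew]                 # crew mean of initial AR, per worker

  # daily tallies
  tasks_dw <- matrix(0, H, N); thaz_dw <- matrix(0, H, N)
  vhaz_dw <- matrix(0, H, N)
  viol_crew <- matrix(0, H, K); impr_crew <- matrix(0, H, K)
  fb_crew <- matrix(0, H, K); prod_crew <- matrix(0, H, K)
  routine_d <- numeric(H); situ_d <- numeric(H)
  nm_d <- numeric(H); acc_d <- numeric(H)
  w_kd <- matrix(0, H, K); pp_kd <- matrix(0, H, K); ss_kd <- matrix(0, H, K)
  scp_d <- numeric(H); gap_d <- numeric(H); tm_d <- numeric(H)
  dist_d <- numeric(H); rate_d <- numeric(H)
  ar_sum <- numeric(N)           # worker running AR sum (daily snapshots)
  viol_worker <- numeric(N)
  averted <- 0
  stopped_ticks_total <- 0

  log_ev <- config$log_events
  if (log_ev) {
    ev_cap <- 4096L; ev_n <- 0L
    ev_log <- matrix(NA_real_, ev_cap, 10)
    colnames(ev_log) <- c("day", "tick", "worker", "crew", "cell", "hazard",
                          "mode", "outcome", "ar_before", "ar_after")
  }

  mgr_pos <- integer(K)
  for (k in seq_len(K)) {
    cand <- pos[crew == k]
    mgr_pos[k] <- cand[sample.int(length(cand), 1L)]
  }

  for (d in seq_len(H)) {
    ## --- system dynamics (stocks from the trailing window, outputs today)
    if (d > 1) {
      win <- max(1L, d - swin):(d - 1L)
      pwin <- max(1L, d - config$pp_window_days):(d - 1L)
      n_impr <- colSums(impr_crew[win, , drop = FALSE])
      n_fb <- colSums(fb_crew[win, , drop = FALSE])
      n_viol <- colSums(viol_crew[win, , drop = FALSE])
      cprod <- colSums(prod_crew[pwin, , drop = FALSE])
      near7 <- sum(nm_d[win]); acc7 <- sum(acc_d[win])
    } else {
      n_impr <- n_fb <- n_viol <- cprod <- numeric(K)
      near7 <- acc7 <- 0
    }
    ss <- perceived_social_support(n_impr, n_fb, n_viol,
                                   config$support_scaling)
    pp <- perceived_production_pressure(cprod, mean(cprod),
                                        config$pressure_scaling)
    w_k <- attitudinal_ambivalence(pp, ss)
    sc <- safety_control_pressure(near7, acc7, config$safe_goal)
    mo <- management_outputs(config$proac_man, sc$scp,
                             config$distance_scale)
    ss_kd[d, ] <- ss; pp_kd[d, ] <- pp; w_kd[d, ] <- w_k
    gap_d[d] <- sc$gap; scp_d[d] <- sc$scp
    tm_d[d] <- mo$tolerable_hazard; dist_d[d] <- mo$distance
    rate_d[d] <- mo$feedback_rate
    tm_now <- mo$tolerable_hazard; dist_now <- mo$distance
    fb_rate <- mo$feedback_rate; impr_rate <- mo$improvement_rate

    ## --- social contagion (daily, before event-driven decrements)
    if (config$contagion_enabled) {
      cwin <- max(1L, d - m_days):(d - 1L)
      if (d > 1) {
        tw <- colSums(tasks_dw[cwin, , drop = FALSE])
        num <- if (use_exposure) colSums(thaz_dw[cwin, , drop = FALSE])
               else colSums(vhaz_dw[cwin, , drop = FALSE])
        ha <- ifelse(tw > 0, num / tw, 0)
      } else ha <- numeric(N)
      crewsum <- as.vector(rowsum(ha, crew))
      cw_mean <- (crewsum[crew] - ha) / (crew_size - 1)
      tc <- (1 - 1 / m_days) * tc + cw_mean / m_days
      w_i <- w_k[crew]
      tr <- w_i * tc + (1 - w_i) * tm_now
      ar <- pmin(pmax((1 - cp) * ar + cp * tr, wp$ar_clamp[1]),
                 wp$ar_clamp[2])
    }
    ar_sum <- ar_sum + ar

    ## --- agent ticks
    for (tk in seq_len(tpd)) {
      # crane rotation with fresh dynamic hazards
      for (cr in seq_along(cranes)) {
        cs <- cranes[[cr]]
        crane_h[cs$sectors[[cs$heading + 1L]]] <- 0
        cs$heading <- (cs$heading + 1L) %% n_hsteps
        nw <- cs$sectors[[cs$heading + 1L]]
        crane_h[nw] <- stats::runif(length(nw), crane_lo, crane_hi)
        cranes[[cr]] <- cs
      }
      # manager patrol-by-sampling
      active <- state != 2L
      for (k in seq_len(K)) {
        cand <- pos[crew == k & active]
        if (length(cand) > 0)
          mgr_pos[k] <- cand[sample.int(length(cand), 1L)]
      }
      mgx <- (mgr_pos - 1L) %% W; mgy <- (mgr_pos - 1L) %/% W
      # stoppage countdown: idle for exactly stop_ticks full ticks
      st <- which(state == 2L)
      if (length(st) > 0) {
        state[st[stop_ticks[st] <= 0L]] <- 0L
        st <- st[stop_ticks[st] > 0L]
        stopped_ticks_total <- stopped_ticks_total + length(st)
        stop_ticks[st] <- stop_ticks[st] - 1L
      }
      consumed <- numeric(N)
      # fast path: mid-task workers
      imp <- which(state == 1L)
      finishing <- rem[imp] <= tick_days + 1e-12
      easy <- imp[!finishing]
      if (length(easy) > 0) {
        rem[easy] <- rem[easy] - tick_days
        consumed[easy] <- tick_days * task_speed[easy]
      }
      # event path: completions and task starts
      ev <- c(imp[finishing], which(state == 0L))
      for (w in ev) {
        b <- tick_days
        kw <- crew[w]
        repeat {
          if (state[w] == 1L) {
            if (rem[w] > b + 1e-12) {
              rem[w] <- rem[w] - b
              consumed[w] <- consumed[w] + b * task_speed[w]
              break
            }
            # task completes
            consumed[w] <- consumed[w] + rem[w] * task_speed[w]
            b <- b - rem[w]
            rem[w] <- 0
            h <- task_h[w]
            tasks_dw[d, w] <- tasks_dw[d, w] + 1
            thaz_dw[d, w] <- thaz_dw[d, w] + h
            outc <- 0L
            ar_before <- ar[w]
            if (task_mode[w] > 0L) {
              if (task_mode[w] == 1L) routine_d[d] <- routine_d[d] + 1
              else situ_d[d] <- situ_d[d] + 1
              viol_crew[d, kw] <- viol_crew[d, kw] + 1
              vhaz_dw[d, w] <- vhaz_dw[d, w] + h
              viol_worker[w] <- viol_worker[w] + 1
              p_acc <- alpha * h / 200
              u <- stats::runif(1)
              if (u < p_acc) {
                outc <- 2L
                acc_d[d] <- acc_d[d] + 1
                ar[w] <- max(wp$ar_clamp[1], ar[w] - wp$accident_ar_decrement)
                state[w] <- 2L
                stop_ticks[w] <- as.integer(wp$accident_stop_days * tpd)
                b <- 0
              } else if (u < p_acc * (1 + rmul)) {
                outc <- 1L
                nm_d[d] <- nm_d[d] + 1
                ar[w] <- max(wp$ar_clamp[1], ar[w] - wp$nearmiss_ar_decrement)
              }
            }
            if (log_ev) {
              ev_n <- ev_n + 1L
              if (ev_n > ev_cap) {
                ev_log <- rbind(ev_log, matrix(NA_real_, ev_cap, 10))
                ev_cap <- 2L * ev_cap
              }
              ev_log[ev_n, ] <- c(d, tk, w, kw, task_cell[w], h,
                                  task_mode[w], outc, ar_before, ar[w])
            }
            # replenish the claimed cell (steady-state project)
            cell <- task_cell[w]
            if (config$site$replenish) {
              nwl <- sample.int(wl_max, 1L)
              workload[cell] <- nwl
              base_h[cell] <- rtri(1, 0, hz_mode, 200)
              constraint[cell] <- stats::runif(1) < kappa * nwl / wl_max
            }
            if (state[w] == 2L) break
            state[w] <- 0L
            next
          }
          # approaching: one step to a workable neighbour, instantaneous
          if (b <= 1e-12) break
          nb <- nbrs[[pos[w]]]
          wn <- nb[workload[nb] > 0]
          nn <- length(wn)
          if (nn == 0L) {
            pos[w] <- nb[1L + as.integer(stats::runif(1) * length(nb))]
            break                 # random-walk step consumes the remainder
          }
          cell <- wn[1L + as.integer(stats::runif(1) * nn)]
          pos[w] <- cell
          wl <- workload[cell]
          h <- base_h[cell]
          if (crane_h[cell] > h) h <- crane_h[cell]
          constr <- constraint[cell]
          pending <- h < ar[w]
          mode <- 0L
          # inspection gate at task start
          dx <- abs(((cell - 1L) %% W) - mgx[kw])
          dy <- abs(((cell - 1L) %/% W) - mgy[kw])
          if (h > tm_now && max(dx, dy) <= dist_now) {
            if (constr) {
              if (stats::runif(1) < impr_rate) {
                constr <- FALSE
                constraint[cell] <- FALSE
                impr_crew[d, kw] <- impr_crew[d, kw] + 1
                if (pending) mode <- 1L
              } else mode <- 2L
            } else if (pending) {
              if (stats::runif(1) < fb_rate) {
                fb_crew[d, kw] <- fb_crew[d, kw] + 1
                averted <- averted + 1
              } else mode <- 1L
            }
          } else {
            if (constr) mode <- 2L else if (pending) mode <- 1L
          }
          task_mode[w] <- mode
          task_speed[w] <- if (mode > 0L) speed0 * (1 + incr) else speed0
          rem[w] <- wl / task_speed[w]
          task_h[w] <- h
          task_cell[w] <- cell
          workload[cell] <- 0     # claimed
          state[w] <- 1L
        }
      }
      prod_crew[d, ] <- prod_crew[d, ] +
        colSums(matrix(consumed, nrow = crew_size))
    }
  }

  workload_total <- sum(prod_crew)
  daily <- data.frame(
    day = seq_len(H), routine = routine_d, situational = situ_d,
    near_miss = nm_d, accident = acc_d, gap = gap_d, scp = scp_d,
    tolerable_hazard = tm_d, distance = dist_d, intervention_rate = rate_d
  )
  crew_viol <- colSums(viol_crew)
  workers <- data.frame(
    id = seq_len(N), crew = crew, cp = cp, ar_init = ar0,
    ar_mean = ar_sum / H, ar_final = ar,
    violations = viol_worker,
    coworker_violations = crew_viol[crew] - viol_worker,
    ambivalence_mean = colMeans(w_kd)[crew],
    pressure_mean = colMeans(pp_kd)[crew]
  )
  res <- list(
    totals = list(
      routine = sum(routine_d), situational = sum(situ_d),
      violations = sum(routine_d) + sum(situ_d),
      near_misses = sum(nm_d), accidents = sum(acc_d),
      tasks = sum(tasks_dw), averted = averted,
      workload_done = workload_total,
      worker_days = N * H,
      active_worker_days = N * H - stopped_ticks_total * tick_days
    ),
    daily = daily,
    crew_daily = list(ambivalence = w_kd, pressure = pp_kd, support = ss_kd,
                      violations = viol_crew, improvements = impr_crew,
                      feedback = fb_crew, productivity = prod_crew),
    workers = workers,
    events = if (log_ev) as.data.frame(ev_log[seq_len(ev_n), , drop = FALSE])
             else NULL,
    config = config, seed = seed
  )
  class(res) <- "crewsim_run"
  res
}

#' Summary metrics of a run
#'
#' The headline indicators: violations per worker per day, the situational
#' share of violations, near-misses and accidents per 100 full-time workers
#' over the horizon, the near-miss:accident ratio, and completed workload
#' per active worker-day.
#'
#' @param result A `crewsim_run`.
#' @return A `crewsim_metrics` list of scalars (ratios `NA` when the
#'   denominator is zero).
#' @export
compute_metrics <- function(result) {
  t <- result$totals
  cfg <- result$config
  per100 <- 100 / cfg$n_workers
  structure(list(
    ratio_violations = t$violations / t$worker_days,
    prop_situational = if (t$violations > 0) t$situational / t$violations
                       else NA_real_,
    rate_accidents = t$accidents * per100,
    rate_near_misses = t$near_misses * per100,
    nm_per_accident = if (t$accidents > 0) t$near_misses / t$accidents
                      else NA_real_,
    rate_productivity = t$workload_done / t$active_worker_days
  ), class = "crewsim_metrics")
}

#' Aggregate metrics across replicate runs
#'
#' @param reports List of [compute_metrics()] results (>= 2).
#' @return Data frame with per-metric mean, across-run standard deviation
#'   and standard error of the mean (ratios aggregated over non-missing
#'   runs).
#' @export
aggregate_metrics <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 replicate reports")
  nm <- names(reports[[1]])
  vals <- sapply(reports, function(r) unlist(r))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(nm))
  data.frame(
    metric = nm,
    mean = apply(vals, 1, mean, na.rm = TRUE),
    sd = apply(vals, 1, stats::sd, na.rm = TRUE),
    se = apply(vals, 1, function(x) {
      x <- x[!is.na(x)]
      stats::sd(x) / sqrt(length(x))
    }),
    row.names = NULL
  )
}

#' Run replicates and collect metrics
#'
#' Convenience wrapper running `n_runs` independent replicates with distinct
#' seeds derived from `seed`.
#'
#' @param config A [simulation_config()].
#' @param n_runs Number of replicates.
#' @param seed Base seed.
#' @param keep_runs Also return the full run objects.
#' @return List: `metrics` (list of per-run [compute_metrics()]),
#'   `summary` (from [aggregate_metrics()]), `totals` (pooled counts),
#'   optionally `runs`.
#' @export
run_replicates <- function(config = simulation_config(), n_runs = 10,
                           seed = 1L, keep_runs = FALSE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_runs)
  runs <- vector("list", n_runs)
  mets <- vector("list", n_runs)
  pooled <- NULL
  for (i in seq_len(n_runs)) {
    r <- run_simulation(config, seeds[i])
    mets[[i]] <- compute_metrics(r)
    tt <- unlist(r$totals)
    pooled <- if (is.null(pooled)) tt else pooled + tt
    runs[[i]] <- if (keep_runs) r else r["workers"]
  }
  list(metrics = mets,
       summary = aggregate_metrics(mets),
       totals = as.list(pooled),
       runs = runs,
       seeds = seeds)
}

#' Export a run as delimited text files
#'
#' Writes the daily system trace (`sd_trace.csv`), the per-crew daily panel
#' (`crew_daily.csv`), per-worker summaries (`workers.csv`) and, when the
#' run logged events, the per-task event log (`events.csv`).
#'
#' @param result A `crewsim_run`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "sd_trace.csv")
  utils::write.csv(result$daily, p, row.names = FALSE)
  paths <- c(paths, p)
  cd <- result$crew_daily
  K <- ncol(cd$ambivalence)
  long <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(day = seq_len(nrow(cd$ambivalence)), crew = k,
               ambivalence = cd$ambivalence[, k],
               pressure = cd$pressure[, k], support = cd$support[, k],
               violations = cd$violations[, k],
               improvements = cd$improvements[, k],
               feedback = cd$feedback[, k],
               productivity = cd$productivity[, k])
  }))
  p <- file.path(dir, "crew_daily.csv")
  utils::write.csv(long, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "workers.csv")
  utils::write.csv(result$workers, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$events)) {
    p <- file.path(dir, "events.csv")
    utils::write.csv(result$events, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read or write a flat configuration file
#'
#' The configuration file is a flat YAML mapping of [simulation_config()]
#' arguments plus dotted site/worker/outcome overrides
#' (e.g. `site.hazard_mode: 50`).
#'
#' @param path File path.
#' @param config For writing, a [simulation_config()].
#' @return `read_config()` a `simulation_config`; `write_config()`
#'   invisibly the path.
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  site_args <- v[startsWith(names(v), "site.")]
  names(site_args) <- sub("^site\\.", "", names(site_args))
  worker_args <- v[startsWith(names(v), "worker.")]
  names(worker_args) <- sub("^worker\\.", "", names(worker_args))
  outcome_args <- v[startsWith(names(v), "outcome.")]
  names(outcome_args) <- sub("^outcome\\.", "", names(outcome_args))
  top <- v[!grepl("\\.", names(v))]
  top$site <- do.call(site_config, site_args)
  top$worker <- do.call(worker_params, worker_args)
  top$outcome <- do.call(outcome_params, outcome_args)
  do.call(simulation_config, top)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  flat <- config[!names(config) %in% c("site", "worker", "outcome")]
  s <- config$site
  flat <- c(flat,
            stats::setNames(
              list(s$hazard_mode, s$constraint_coeff, s$replenish),
              c("site.hazard_mode", "site.constraint_coeff",
                "site.replenish")),
            stats::setNames(
              list(config$worker$production_incr,
                   config$worker$memory_days),
              c("worker.production_incr", "worker.memory_days")),
            stats::setNames(
              list(config$outcome$p_accident_at_max,
                   config$outcome$nearmiss_multiplier),
              c("outcome.p_accident_at_max",
                "outcome.nearmiss_multiplier")))
  yaml::write_yaml(flat, path)
  invisible(path)
}
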