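test_that("runs are bit-reproducible from the seed", {
  a <- run_simulation(small_config(), seed = 11)
  b <- run_simulation(small_config(), seed = 11)
  expect_identical(a$totals, b$totals)
  expect_identical(a$daily, b$daily)
  expect_identical(a$workers, b$workers)
  c <- run_simulation(small_config(), seed = 12)
  expect_false(identical(a$totals, c$totals))
})

test_that("with violations disabled productivity is exactly the speed", {
  r <- run_simulation(compliant_config(), seed = 5)
  expect_equal(r$totals$violations, 0)
  expect_equal(r$totals$accidents, 0)
  expect_equal(r$totals$near_misses, 0)
  expect_equal(r$totals$workload_done / r$totals$worker_days, 20)
})

test_that("totals equal the event-level aggregations", {
  cfg <- small_config(log_events = TRUE)
  r <- run_simulation(cfg, seed = 21)
  expect_equal(sum(r$daily$routine), r$totals$routine)
  expect_equal(sum(r$daily$situational), r$totals$situational)
  expect_equal(sum(r$daily$near_miss), r$totals$near_misses)
  expect_equal(sum(r$daily$accident), r$totals$accidents)
  expect_equal(sum(r$crew_daily$violations), r$totals$violations)
  expect_equal(sum(r$crew_daily$productivity), r$totals$workload_done)
  expect_equal(sum(r$workers$violations), r$totals$violations)
  # event log agrees with the counters
  ev <- r$events
  expect_equal(nrow(ev), r$totals$tasks)
  expect_equal(sum(ev$mode == 1), r$totals$routine)
  expect_equal(sum(ev$mode == 2), r$totals$situational)
  expect_equal(sum(ev$outcome == 1), r$totals$near_misses)
  expect_equal(sum(ev$outcome == 2), r$totals$accidents)
  expect_true(all(ev$hazard >= 0 & ev$hazard <= 200))
  # incidents only arise from violating tasks
  expect_true(all(ev$mode[ev$outcome > 0] > 0))
  expect_lte(r$totals$accidents + r$totals$near_misses,
             r$totals$violations)
})

test_that("accidents stop workers and reduce active worker-days", {
  # inflated outcome probabilities so that accidents are plentiful
  cfg <- small_config(outcome = outcome_params(0.2, 2))
  r <- run_simulation(cfg, seed = 8)
  expect_gt(r$totals$accidents, 0)
  expect_lt(r$totals$active_worker_days, r$totals$worker_days)
  # each accident removes at most 3 worker-days (less near the horizon)
  expect_gte(r$totals$active_worker_days,
             r$totals$worker_days - 3 * r$totals$accidents)
  # production never exceeds the violating speed on active time
  expect_lte(r$totals$workload_done / r$totals$active_worker_days,
             20 * 1.2 + 1e-9)
})

test_that("summary metrics are the documented ratios", {
  fake <- structure(list(
    totals = list(routine = 7120, situational = 880, violations = 8000,
                  near_misses = 26, accidents = 3, tasks = 5e4, averted = 0,
                  workload_done = 5e5, worker_days = 25000,
                  active_worker_days = 25000),
    config = simulation_config()), class = "crewsim_run")
  m <- compute_metrics(fake)
  expect_equal(m$ratio_violations, 0.32)
  expect_equal(m$prop_situational, 0.11)
  expect_equal(m$nm_per_accident, 26 / 3)
  expect_equal(m$rate_accidents, 3)
  expect_equal(m$rate_productivity, 20)
  fake$totals$accidents <- 0
  expect_true(is.na(compute_metrics(fake)$nm_per_accident))
})

test_that("aggregation reports replicate means and standard errors", {
  m1 <- structure(list(a = 0.3, b = 1), class = "crewsim_metrics")
  m2 <- structure(list(a = 0.34, b = 1), class = "crewsim_metrics")
  s <- aggregate_metrics(list(m1, m2))
  expect_equal(s$mean[s$metric == "a"], 0.32)
  expect_equal(s$se[s$metric == "b"], 0)
  s2 <- aggregate_metrics(list(m1, m1, m1))
  expect_equal(s2$sd, c(0, 0))
  expect_error(aggregate_metrics(list(m1)), "at least 2")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_workers = 101, n_crews = 5), "multiple")
  expect_error(simulation_config(horizon_days = 0), "horizon")
  expect_error(simulation_config(proac_man = 2), "proac_man")
})

test_that("run export and config round-trip through text files", {
  r <- run_simulation(small_config(horizon_days = 10L, log_events = TRUE),
                      seed = 2)
  d <- withr::local_tempdir()
  paths <- write_run_csv(r, d)
  expect_true(all(file.exists(paths)))
  tr <- utils::read.csv(file.path(d, "sd_trace.csv"))
  expect_equal(nrow(tr), 10)
  expect_equal(sum(tr$routine), r$totals$routine)

  cfg <- simulation_config(safe_goal = 2,
                           site = site_config(hazard_mode = 150),
                           outcome = outcome_params(0.001, 5))
  p <- file.path(d, "config.yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back$safe_goal, 2)
  expect_equal(back$site$hazard_mode, 150)
  expect_equal(back$outcome$p_accident_at_max, 0.001)
})
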