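test_that("the factorial design matrix is the standard 2^4 layout", {
  d <- fed_design()
  expect_equal(dim(d), c(16L, 4L))
  expect_equal(unname(d[1, ]), rep(-1L, 4))
  expect_equal(unname(d[16, ]), rep(1L, 4))
  expect_equal(unname(d[2, ]), c(1L, -1L, -1L, -1L))
  # orthogonal, balanced columns
  expect_equal(unname(crossprod(d)), diag(16, 4))
  expect_equal(unname(colSums(d)), rep(0L, 4))
  expect_equal(nrow(unique(d)), 16L)
})

test_that("standardized effects match the brute-force contrast oracle", {
  des <- fed_design()
  n <- 5
  point <- rep(1:16, each = n)
  set.seed(123)
  y <- rnorm(16 * n, mean = 10, sd = 1)
  eff <- standardized_effects(y, point)
  ybar <- tapply(y, point, mean)
  for (f in 1:4) {
    bf <- mean(ybar[des[, f] == 1]) - mean(ybar[des[, f] == -1])
    expect_equal(eff$effect[eff$term == c("A", "B", "C", "D")[f]], bf)
  }
  # two-way interaction contrast, brute force
  ab <- des[, 1] * des[, 2]
  expect_equal(eff$effect[eff$term == "A:B"],
               mean(ybar[ab == 1]) - mean(ybar[ab == -1]))
})

test_that("standardized effects agree with the linear-model route", {
  des <- fed_design()
  n <- 4
  point <- rep(1:16, each = n)
  set.seed(99)
  y <- rnorm(64, 5 + 1.5 * des[point, 2], 0.8)
  eff <- standardized_effects(y, point)
  df <- data.frame(y = y, A = des[point, 1], B = des[point, 2],
                   C = des[point, 3], D = des[point, 4])
  fit <- summary(stats::lm(y ~ A * B * C * D, data = df))$coefficients
  for (i in seq_len(nrow(eff))) {
    lm_term <- gsub(":", ":", eff$term[i])
    expect_equal(eff$standardized[i], unname(fit[lm_term, "t value"]),
                 tolerance = 1e-10)
    expect_equal(eff$effect[i], 2 * unname(fit[lm_term, "Estimate"]),
                 tolerance = 1e-10)
  }
})

test_that("a planted effect is recovered as the only significant term", {
  des <- fed_design()
  n <- 3
  point <- rep(1:16, each = n)
  set.seed(7)
  y <- 2 * des[point, 2] + rnorm(48, sd = 0.05)
  eff <- standardized_effects(y, point)
  # planted coefficient 2 on B = contrast effect 4 (mean(+) - mean(-))
  expect_equal(eff$term[1], "B")
  expect_gt(eff$effect[1], 0)
  expect_equal(eff$effect[1], 4, tolerance = 0.05)
  expect_true(eff$significant[1])
  # the planted term towers over everything noise-generated
  expect_gt(abs(eff$standardized[1]), 10 * abs(eff$standardized[2]))
  expect_error(standardized_effects(y[point != 16], point[point != 16]),
               "replicates")
})

test_that("the factorial runner produces point means and raw replicates", {
  cfg <- simulation_config(n_workers = 20L, n_crews = 4L,
                           horizon_days = 12L)
  fed <- run_fed(hazard_mode = 100, n_runs = 2, seed = 3, config = cfg)
  expect_equal(nrow(fed$responses), 16)
  expect_equal(nrow(fed$raw), 32)
  expect_true(all(fed$raw$rate_productivity > 0))
  expect_equal(fed$responses$rate_accidents,
               as.vector(tapply(fed$raw$rate_accidents, fed$raw$point,
                                mean)))
  # routine + situational ratios recompose the violation ratio
  m <- fed$raw$ratio_routine + fed$raw$ratio_situational
  expect_true(all(m >= 0))
})

test_that("sensitivity and validation runners return the documented shapes", {
  cfg <- simulation_config(n_workers = 20L, n_crews = 4L,
                           horizon_days = 15L)
  sens <- run_sensitivity(cfg, n_runs = 2, seed = 5)
  expect_equal(colnames(sens$pct_change),
               c("safe_goal", "proac_man", "median_contagion",
                 "production_incr"))
  expect_true("ratio_violations" %in% rownames(sens$pct_change))

  val <- run_baseline_validation(cfg, n_runs = 3, seed = 5)
  expect_named(val$regressions,
               c("coworker_violations", "ambivalence", "pressure"))
  expect_true(all(is.finite(vapply(val$regressions,
                                   function(r) r$slope, numeric(1)))))
  expect_equal(nrow(val$panel), 3 * 20)
})
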