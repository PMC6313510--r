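#' Baseline validation study
#'
#' Runs the baseline configuration for `n_runs` replicates, aggregates the
#' headline metrics, and fits three pooled per-worker least-squares
#' regressions of the mean acceptable hazard on (i) the count of coworker
#' violations, (ii) the crew's mean attitudinal ambivalence and (iii) the
#' crew's mean perceived production pressure. A positive slope in each
#' reproduces the qualitative contagion signature: workers embedded in more
#' violation-prone, more ambivalent, more pressured crews tolerate more
#' hazard.
#'
#' @param config Baseline [simulation_config()].
#' @param n_runs Replicates.
#' @param seed Base seed.
#' @return List: `summary` (metric means/SDs/SEs), `pooled_totals`,
#'   `regressions` (per predictor: slope, r.squared, p.value), `metrics`.
#' @export
run_baseline_validation <- function(config = simulation_config(),
                                    n_runs = 50, seed = 1L) {
  rr <- run_replicates(config, n_runs, seed)
  panel <- do.call(rbind, lapply(seq_along(rr$runs), function(i) {
    w <- rr$runs[[i]]$workers
    w$run <- i
    w
  }))
  regs <- lapply(
    c(coworker_violations = "coworker_violations",
      ambivalence = "ambivalence_mean",
      pressure = "pressure_mean"),
    function(v) {
      fit <- stats::lm(stats::reformulate(v, "ar_mean"), data = panel)
      sm <- summary(fit)
      list(slope = unname(stats::coef(fit)[2]),
           r.squared = sm$r.squared,
           p.value = unname(sm$coefficients[2, 4]))
    })
  list(summary = rr$summary, pooled_totals = rr$totals,
       regressions = regs, metrics = rr$metrics, panel = panel)
}

#' One-at-a-time sensitivity analysis
#'
#' Increases each of `safe_goal`, `proac_man`, `median_contagion` and
#' `production_incr` by `pct` (default +50%) over its base value, one at a
#' time, runs `n_runs` replicates per variant with seeds common to the base
#' runs (variance reduction by common random numbers), and reports the
#' percent change of each mean metric relative to base.
#'
#' @param config Baseline [simulation_config()].
#' @param n_runs Replicates per variant.
#' @param seed Base seed (shared across variants).
#' @param pct Fractional increase applied to each parameter.
#' @return List: `base` (metric means), `pct_change` (matrix metrics x
#'   parameters).
#' @export
run_sensitivity <- function(config = simulation_config(), n_runs = 50,
                            seed = 1L, pct = 0.5) {
  base <- run_replicates(config, n_runs, seed)
  bm <- stats::setNames(base$summary$mean, base$summary$metric)
  variants <- list(
    safe_goal = function(cfg) { cfg$safe_goal <- cfg$safe_goal * (1 + pct); cfg },
    proac_man = function(cfg) {
      cfg$proac_man <- min(1, cfg$proac_man * (1 + pct)); cfg },
    median_contagion = function(cfg) {
      cfg$median_contagion <- cfg$median_contagion * (1 + pct); cfg },
    production_incr = function(cfg) {
      cfg$worker$production_incr <- cfg$worker$production_incr * (1 + pct)
      cfg }
  )
  chg <- sapply(variants, function(f) {
    vs <- run_replicates(f(config), n_runs, seed)
    vm <- stats::setNames(vs$summary$mean, vs$summary$metric)
    100 * (vm - bm) / bm
  })
  list(base = bm, pct_change = chg, n_runs = n_runs)
}

#' Factor levels of the 2^4 experiment
#'
#' The negative and positive levels of the four manipulated factors.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
fed_levels <- function() {
  list(safe_goal = c(0.5, 2),
       proac_man = c(0.2, 0.8),
       median_contagion = c(0.2, 0.8),
       production_incr = c(0.08, 0.32))
}

#' Full-factorial design matrix
#'
#' The 16-run +/-1 coded design over the four factors, in standard order:
#' the safety goal alternates fastest and the production increase switches
#' after run 8, so design point 1 is all-low and point 16 all-high.
#'
#' @return 16 x 4 integer matrix with columns `safe_goal`, `proac_man`,
#'   `median_contagion`, `production_incr`.
#' @export
fed_design <- function() {
  g <- expand.grid(safe_goal = c(-1L, 1L), proac_man = c(-1L, 1L),
                   median_contagion = c(-1L, 1L),
                   production_incr = c(-1L, 1L))
  as.matrix(g)
}

#' Run the replicated 2^4 factorial experiment
#'
#' For each of the 16 design points, applies the factor levels to the
#' configuration and runs `n_runs` replicates; returns per-point response
#' means (accident rate, routine and situational violation ratios,
#' productivity) and the per-replicate raw responses for effects analysis.
#'
#' @param hazard_mode Site hazard mode: 50 (low), 100 (modest) or 150
#'   (high).
#' @param n_runs Replicates per design point.
#' @param seed Base seed.
#' @param config Template [simulation_config()] (factor fields are
#'   overwritten).
#' @return List: `design`, `responses` (16-row data frame of means), `raw`
#'   (long data frame: point, replicate, the four responses).
#' @export
run_fed <- function(hazard_mode = 100, n_runs = 50, seed = 1L,
                    config = simulation_config()) {
  des <- fed_design()
  lev <- fed_levels()
  config$site <- site_config(
    hazard_mode = hazard_mode,
    constraint_coeff = config$site$constraint_coeff,
    replenish = config$site$replenish)
  raw <- vector("list", nrow(des))
  for (p in seq_len(nrow(des))) {
    cfg <- config
    cfg$safe_goal <- lev$safe_goal[(des[p, "safe_goal"] + 3L) / 2L]
    cfg$proac_man <- lev$proac_man[(des[p, "proac_man"] + 3L) / 2L]
    cfg$median_contagion <-
      lev$median_contagion[(des[p, "median_contagion"] + 3L) / 2L]
    cfg$worker$production_incr <-
      lev$production_incr[(des[p, "production_incr"] + 3L) / 2L]
    rr <- run_replicates(cfg, n_runs, seed)
    raw[[p]] <- do.call(rbind, lapply(seq_len(n_runs), function(i) {
      m <- rr$metrics[[i]]
      data.frame(point = p, replicate = i,
                 rate_accidents = m$rate_accidents,
                 ratio_routine = m$ratio_violations *
                   (1 - ifelse(is.na(m$prop_situational), 0,
                               m$prop_situational)),
                 ratio_situational = m$ratio_violations *
                   ifelse(is.na(m$prop_situational), 0,
                          m$prop_situational),
                 rate_productivity = m$rate_productivity)
    }))
  }
  raw <- do.call(rbind, raw)
  responses <- do.call(rbind, lapply(split(raw, raw$point), function(d) {
    data.frame(point = d$point[1],
               rate_accidents = mean(d$rate_accidents),
               ratio_routine = mean(d$ratio_routine),
               ratio_situational = mean(d$ratio_situational),
               rate_productivity = mean(d$rate_productivity))
  }))
  rownames(responses) <- NULL
  list(design = des, responses = responses, raw = raw,
       hazard_mode = hazard_mode, n_runs = n_runs)
}

#' Standardized-effect (Pareto) analysis of a replicated 2^4 experiment
#'
#' Estimates all 15 main and interaction effects by orthogonal contrasts on
#' the per-replicate responses; the error variance is pooled from
#' within-point replicates (df = 16 (n - 1)), the standardized effect is the
#' estimate over its standard error, and two-sided p-values come from the t
#' distribution. The table is sorted by absolute standardized effect
#' (Pareto order).
#'
#' @param y Response values, one per replicate run.
#' @param point Design point index (1..16, matching [fed_design()] rows)
#'   for each element of `y`; at least 2 replicates per point.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame: term, effect, se, standardized (t), p.value,
#'   significant; attribute `t_critical` holds the significance threshold.
#' @export
standardized_effects <- function(y, point, alpha = 0.05) {
  des <- fed_design()
  if (!all(point %in% seq_len(16))) stop("point must index the 16-run design")
  n_rep <- as.vector(table(factor(point, levels = seq_len(16))))
  if (any(n_rep < 2)) stop("need >= 2 replicates per design point for an error estimate")
  if (length(unique(n_rep)) > 1) stop("replicates must be balanced across design points")
  n <- n_rep[1]
  # model matrix of all 15 factorial terms, +/-1 coded
  terms <- list()
  cn <- colnames(des)
  short <- c(safe_goal = "A", proac_man = "B", median_contagion = "C",
             production_incr = "D")
  for (k in 1:4) {
    for (cmb in utils::combn(4, k, simplify = FALSE)) {
      col <- apply(des[, cmb, drop = FALSE], 1, prod)
      terms[[paste(short[cn[cmb]], collapse = ":")]] <- col
    }
  }
  X <- do.call(cbind, terms)          # 16 x 15
  ybar <- as.vector(tapply(y, factor(point, levels = seq_len(16)), mean))
  effects <- as.vector(crossprod(X, ybar)) / 8   # mean(+1) - mean(-1)
  s2 <- sum(tapply(y, point, function(v) sum((v - mean(v))^2))) / (16 * (n - 1))
  se <- sqrt(s2 / (4 * n))            # Var(effect) = s2 * (1/8n + 1/8n)
  tval <- effects / se
  df <- 16 * (n - 1)
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(term = colnames(X), effect = effects, se = se,
                    standardized = tval, p.value = p,
                    significant = p <= alpha)
  out <- out[order(-abs(out$standardized)), ]
  rownames(out) <- NULL
  attr(out, "t_critical") <- stats::qt(1 - alpha / 2, df)
  attr(out, "df") <- df
  out
}
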