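#' Site configuration
#'
#' Builds the configuration for the cell-based virtual construction site:
#' a 92 x 84 grid of 1 m^2 cells with 3600 building cells arranged as four
#' rectangular blocks separated by two road corridors, three tower cranes,
#' and a triangular static hazard field.
#'
#' @param hazard_mode Mode of the triangular hazard distribution
#'   `Triangular(0, hazard_mode, 200)`; one of 50 (low), 100 (modest) or
#'   150 (high).
#' @param grid_width,grid_height Grid dimensions in cells.
#' @param workload_max Maximum cell workload (integer units); building cells
#'   draw workload uniformly from `1:workload_max`.
#' @param n_cranes Number of tower cranes (pivots placed at the centroids of
#'   the first `n_cranes` building blocks).
#' @param jib_length Crane jib length in cells.
#' @param crane_step_deg Angular advance of each jib per tick, degrees.
#' @param crane_hazard_range Hazard range (uniform) for cells under a jib.
#' @param replenish Should a depleted building cell be redrawn immediately
#'   (steady-state project)?
#' @param constraint_coeff Situational-constraint coefficient kappa: a cell
#'   generated with workload `w` carries a situational constraint with
#'   probability `kappa * w / workload_max`.
#' @return A `site_config` list.
#' @export
site_config <- function(hazard_mode = 100,
                        grid_width = 92L, grid_height = 84L,
                        workload_max = 20L,
                        n_cranes = 3L, jib_length = 20,
                        crane_step_deg = 15,
                        crane_hazard_range = c(160, 200),
                        replenish = TRUE,
                        constraint_coeff = 0.0345) {
  if (!hazard_mode %in% c(50, 100, 150))
    stop("hazard_mode must be one of 50, 100, 150")
  if (grid_width <= 0 || grid_height <= 0)
    stop("grid dimensions must be positive")
  if (constraint_coeff < 0 || constraint_coeff > 1)
    stop("constraint_coeff must lie in [0, 1]")
  structure(list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    n_building_cells = 3600L,
    workload_max = as.integer(workload_max),
    hazard_mode = hazard_mode,
    hazard_bounds = c(0, 200),
    n_cranes = as.integer(n_cranes),
    jib_length = jib_length,
    crane_step_deg = crane_step_deg,
    crane_hazard_range = crane_hazard_range,
    replenish = isTRUE(replenish),
    constraint_coeff = constraint_coeff
  ), class = "site_config")
}

#' Triangular distribution sampler and CDF
#'
#' Hazard levels are drawn from `Triangular(a, c, b)` via inverse-CDF
#' sampling; `ptri()` is the matching distribution function used by
#' distributional tests.
#'
#' @param n Number of draws.
#' @param a,b Lower and upper bounds.
#' @param c Mode.
#' @return `rtri()` a numeric vector of draws; `ptri()` probabilities.
#' @export
rtri <- function(n, a = 0, c = 100, b = 200) {
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' @rdname rtri
#' @param q Quantiles.
#' @export
ptri <- function(q, a = 0, c = 100, b = 200) {
  p <- numeric(length(q))
  p[q <= a] <- 0
  p[q >= b] <- 1
  i <- q > a & q <= c
  p[i] <- (q[i] - a)^2 / ((b - a) * (c - a))
  i <- q > c & q < b
  p[i] <- 1 - (b - q[i])^2 / ((b - a) * (b - c))
  p
}

# Four 30x30 building blocks separated by a vertical and a horizontal road
# corridor. Returns list(blocks = 4x4 matrix [x0 x1 y0 y1], road cells).
.site_layout <- function(W, H) {
  blocks <- rbind(
    c(8, 37, 7, 36),
    c(55, 84, 7, 36),
    c(8, 37, 48, 77),
    c(55, 84, 48, 77)
  )
  road_x <- 44:48   # vertical corridor
  road_y <- 40:44   # horizontal corridor
  list(blocks = blocks, road_x = road_x, road_y = road_y)
}

#' Generate the virtual construction site
#'
#' Builds the site grid: 3600 building cells in four rectangular blocks, two
#' road corridors, per-cell integer workload drawn uniformly on
#' `1:workload_max`, static hazard drawn `Triangular(0, hazard_mode, 200)`,
#' situational-constraint flags drawn with probability
#' `kappa * workload / workload_max`, and cranes at block centroids with
#' uniformly random initial headings.
#'
#' Uses the current R random stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param config A [site_config()].
#' @return A `site_grid` list with per-cell vectors (column-major,
#'   `idx = x + (y-1)*W`): `workload`, `base_hazard`, `crane_hazard`,
#'   `is_building`, `is_road`, `constraint`, plus crane state and
#'   precomputed jib sectors.
#' @export
generate_site <- function(config = site_config()) {
  W <- config$grid_width; H <- config$grid_height
  nc <- W * H
  lay <- .site_layout(W, H)
  is_building <- logical(nc)
  block_id <- integer(nc)
  for (b in seq_len(nrow(lay$blocks))) {
    bl <- lay$blocks[b, ]
    for (y in bl[3]:bl[4]) {
      i <- bl[1]:bl[2] + (y - 1L) * W
      is_building[i] <- TRUE
      block_id[i] <- b
    }
  }
  stopifnot(sum(is_building) == config$n_building_cells)
  is_road <- logical(nc)
  for (x in lay$road_x) is_road[x + (seq_len(H) - 1L) * W] <- TRUE
  for (y in lay$road_y) is_road[seq_len(W) + (y - 1L) * W] <- TRUE
  is_road <- is_road & !is_building

  nb <- sum(is_building)
  workload <- integer(nc)
  workload[is_building] <- sample.int(config$workload_max, nb, replace = TRUE)
  base_hazard <- numeric(nc)
  base_hazard[is_building] <- rtri(nb, 0, config$hazard_mode, 200)
  constraint <- logical(nc)
  constraint[is_building] <- stats::runif(nb) <
    config$constraint_coeff * workload[is_building] / config$workload_max

  n_steps <- as.integer(round(360 / config$crane_step_deg))
  cranes <- vector("list", config$n_cranes)
  for (cr in seq_len(config$n_cranes)) {
    bl <- lay$blocks[cr, ]
    px <- round(mean(bl[1]:bl[2])); py <- round(mean(bl[3]:bl[4]))
    sectors <- .crane_sectors(px, py, config$jib_length,
                              config$crane_step_deg, W, H, is_building)
    cranes[[cr]] <- list(pivot = c(px, py),
                         heading = sample.int(n_steps, 1L) - 1L,
                         sectors = sectors)
  }

  structure(list(
    config = config, W = W, H = H,
    workload = workload, base_hazard = base_hazard,
    crane_hazard = numeric(nc),
    is_building = is_building, is_road = is_road,
    block_id = block_id, constraint = constraint,
    cranes = cranes, n_heading_steps = n_steps
  ), class = "site_grid")
}

# Precompute, for each discrete heading, the building cells under the jib:
# within jib_length of the pivot and within +/- step/2 degrees of the heading.
.crane_sectors <- function(px, py, jib, step_deg, W, H, is_building) {
  xr <- max(1, px - ceiling(jib)):min(W, px + ceiling(jib))
  yr <- max(1, py - ceiling(jib)):min(H, py + ceiling(jib))
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - px; dy <- g$y - py
  r <- sqrt(dx^2 + dy^2)
  keep <- r > 0 & r <= jib
  g <- g[keep, ]; dx <- dx[keep]; dy <- dy[keep]
  idx <- g$x + (g$y - 1L) * W
  keep2 <- is_building[idx]
  idx <- idx[keep2]
  ang <- (atan2(dy[keep2], dx[keep2]) * 180 / pi) %% 360
  n_steps <- as.integer(round(360 / step_deg))
  lapply(seq_len(n_steps) - 1L, function(s) {
    h <- s * step_deg
    d <- abs(((ang - h + 180) %% 360) - 180)
    idx[d <= step_deg / 2]
  })
}

#' Advance the crane danger zones by one tick
#'
#' Each jib rotates by the configured angular step; building cells under the
#' new jib sector receive a fresh dynamic hazard drawn uniformly from the
#' crane hazard range, and cells leaving a sector are reset to 0.
#'
#' @param grid A `site_grid`.
#' @return The updated grid.
#' @export
update_crane_zones <- function(grid) {
  lo <- grid$config$crane_hazard_range[1]
  hi <- grid$config$crane_hazard_range[2]
  for (cr in seq_along(grid$cranes)) {
    cs <- grid$cranes[[cr]]
    old <- cs$sectors[[cs$heading + 1L]]
    grid$crane_hazard[old] <- 0
    cs$heading <- (cs$heading + 1L) %% grid$n_heading_steps
    new <- cs$sectors[[cs$heading + 1L]]
    grid$crane_hazard[new] <- stats::runif(length(new), lo, hi)
    grid$cranes[[cr]] <- cs
  }
  grid
}

#' Effective hazard of each cell
#'
#' The pointwise maximum of the static hazard field and the dynamic crane
#' overlay, bounded in `[0, 200]`.
#'
#' @param grid A `site_grid`.
#' @param idx Optional cell indices (defaults to all cells).
#' @return Numeric vector of hazard levels.
#' @export
effective_hazard <- function(grid, idx = NULL) {
  if (is.null(idx)) pmax(grid$base_hazard, grid$crane_hazard)
  else pmax(grid$base_hazard[idx], grid$crane_hazard[idx])
}

#' Consume workload from a cell, replenishing on depletion
#'
#' Decrements a cell's workload; when a building cell reaches 0 and the site
#' is configured to replenish, the cell is immediately redrawn (fresh uniform
#' workload, fresh triangular static hazard, fresh situational-constraint
#' flag), modelling a continuing project at steady state.
#'
#' @param grid A `site_grid`.
#' @param cell Cell index (`x + (y-1)*W`).
#' @param amount Workload units to consume; must not exceed the cell's
#'   workload.
#' @return The updated grid.
#' @export
site_consume <- function(grid, cell, amount) {
  if (amount > grid$workload[cell] + 1e-9)
    stop("cannot consume more workload than the cell holds")
  grid$workload[cell] <- grid$workload[cell] - amount
  if (grid$workload[cell] <= 1e-9) {
    grid$workload[cell] <- 0
    if (grid$config$replenish && grid$is_building[cell])
      grid <- .replenish_cell(grid, cell)
  }
  grid
}

.replenish_cell <- function(grid, cell) {
  cfg <- grid$config
  wl <- sample.int(cfg$workload_max, 1L)
  grid$workload[cell] <- wl
  grid$base_hazard[cell] <- rtri(1, 0, cfg$hazard_mode, 200)
  grid$constraint[cell] <-
    stats::runif(1) < cfg$constraint_coeff * wl / cfg$workload_max
  grid
}

#' Export site layers as delimited text
#'
#' Writes one whitespace-delimited file per layer (workload, base hazard,
#' effective hazard), row-major with a `width height` header line.
#'
#' @param grid A `site_grid`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_site_layers <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- list(workload = grid$workload,
                 base_hazard = grid$base_hazard,
                 effective_hazard = effective_hazard(grid))
  paths <- character(0)
  for (nm in names(layers)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    con <- file(p, "w")
    writeLines(paste(grid$W, grid$H), con)
    m <- matrix(layers[[nm]], nrow = grid$W)  # column y, row x
    for (y in seq_len(grid$H))
      writeLines(paste(signif(m[, y], 6), collapse = " "), con)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
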