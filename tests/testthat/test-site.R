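test_that("generated site has the prescribed structure", {
  set.seed(1)
  g <- generate_site(site_config())
  expect_equal(sum(g$is_building), 3600)
  expect_false(any(g$is_building & g$is_road))
  expect_true(all(g$workload[g$is_building] >= 1 &
                    g$workload[g$is_building] <= 20))
  expect_true(all(g$workload[!g$is_building] == 0))
  expect_true(all(g$base_hazard >= 0 & g$base_hazard <= 200))
  expect_length(g$cranes, 3)
})

test_that("site generation is reproducible from the seed", {
  set.seed(99); a <- generate_site(site_config())
  set.seed(99); b <- generate_site(site_config())
  expect_identical(a$workload, b$workload)
  expect_identical(a$base_hazard, b$base_hazard)
  expect_identical(a$constraint, b$constraint)
  expect_identical(vapply(a$cranes, function(x) x$heading, integer(1)),
                   vapply(b$cranes, function(x) x$heading, integer(1)))
})

test_that("static hazards follow the configured triangular law", {
  for (mode in c(50, 100, 150)) {
    set.seed(mode)
    g <- generate_site(site_config(hazard_mode = mode))
    h <- g$base_hazard[g$is_building]
    # triangular mean is (a+b+c)/3; MC tolerance ~3 SE at n=3600
    expect_equal(mean(h), (0 + mode + 200) / 3, tolerance = 0.04)
    ks <- stats::ks.test(h, function(q) ptri(q, 0, mode, 200))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("invalid site configurations are rejected", {
  expect_error(site_config(hazard_mode = 75), "hazard_mode")
  expect_error(site_config(grid_width = -1), "positive")
  expect_error(site_config(constraint_coeff = 2), "constraint_coeff")
})

test_that("cells under a jib carry dynamic hazard in [160, 200]", {
  set.seed(5)
  g <- generate_site(site_config())
  for (i in 1:10) {
    g <- update_crane_zones(g)
    under <- g$crane_hazard > 0
    expect_true(all(g$crane_hazard[under] >= 160 &
                      g$crane_hazard[under] <= 200))
    expect_true(all(effective_hazard(g)[under] >= 160))
    expect_true(all(g$is_building[under]))
  }
})

test_that("a full jib sweep covers exactly the building disk around the pivot", {
  set.seed(7)
  g <- generate_site(site_config())
  cr <- g$cranes[[1]]
  swept <- integer(0)
  for (i in seq_len(g$n_heading_steps)) {
    g <- update_crane_zones(g)
    swept <- union(swept, which(g$crane_hazard > 0 &
                                  g$block_id == g$block_id[
                                    cr$pivot[1] + (cr$pivot[2] - 1) * g$W]))
  }
  # independent geometric oracle: building cells within the jib radius
  xy <- expand.grid(x = seq_len(g$W), y = seq_len(g$H))
  d <- sqrt((xy$x - cr$pivot[1])^2 + (xy$y - cr$pivot[2])^2)
  disk <- which(d > 0 & d <= g$config$jib_length & g$is_building)
  # restrict both sides to crane 1's own block to avoid overlap with others
  blk <- g$block_id[cr$pivot[1] + (cr$pivot[2] - 1) * g$W]
  disk <- disk[g$block_id[disk] == blk]
  expect_setequal(swept, disk)
})

test_that("cells never under a jib keep zero crane hazard", {
  set.seed(8)
  g <- generate_site(site_config())
  pivots <- t(vapply(g$cranes, function(x) x$pivot, numeric(2)))
  xy <- expand.grid(x = seq_len(g$W), y = seq_len(g$H))
  near <- rep(FALSE, g$W * g$H)
  for (k in seq_len(nrow(pivots)))
    near <- near | sqrt((xy$x - pivots[k, 1])^2 +
                          (xy$y - pivots[k, 2])^2) <= g$config$jib_length
  for (i in 1:30) {
    g <- update_crane_zones(g)
    expect_true(all(g$crane_hazard[!near] == 0))
  }
})

test_that("workload consumption depletes and optionally replenishes", {
  set.seed(11)
  g <- generate_site(site_config(replenish = FALSE))
  cell <- which(g$is_building & g$workload == 5)[1]
  g <- site_consume(g, cell, 5)
  expect_equal(g$workload[cell], 0)
  expect_error(site_consume(g, cell, 1), "consume")

  g2 <- generate_site(site_config(replenish = TRUE))
  cell <- which(g2$is_building)[1]
  draws <- replicate(200, {
    gg <- site_consume(g2, cell, g2$workload[cell])
    gg$workload[cell]
  })
  expect_true(all(draws >= 1 & draws <= 20))
  # replenished workloads are uniform on 1..20 (mean 10.5)
  expect_equal(mean(draws), 10.5, tolerance = 0.15)
})

test_that("site layer export writes readable grids", {
  set.seed(3)
  g <- generate_site(site_config())
  d <- withr::local_tempdir()
  paths <- write_site_layers(g, d)
  expect_length(paths, 3)
  lines <- readLines(paths[1])
  expect_equal(lines[1], paste(g$W, g$H))
  expect_length(lines, 1 + g$H)
  row1 <- scan(text = lines[2], quiet = TRUE)
  expect_equal(row1, g$workload[seq_len(g$W)])
})
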