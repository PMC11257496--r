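# Cellular Potts engine: energy bookkeeping, Metropolis dynamics, division,
# unit calibration.

test_that("unit calibration reproduces the 27 s/MCS conversion", {
  cal <- unit_calibration()
  expect_equal(cal$seconds_per_mcs, 27)
  expect_equal(mcs_to_seconds(1), 27)
  expect_equal(mcs_to_seconds(0), 0)
  expect_equal(days_to_mcs(1), 86400 / 27)  # 3200 MCS per day
  expect_equal(mcs_to_days(days_to_mcs(2.5)), 2.5)
  expect_error(mcs_to_seconds(-1), "non-negative")
  ## invariant tying the calibration quantities together
  expect_equal(cal$seconds_per_mcs,
               cal$reference_cell_speed * cal$microns_per_pixel * 3600 /
                 cal$reference_migration_speed)
})

test_that("acceptance probability follows the Boltzmann factor", {
  expect_equal(accept_probability(-5, 10), 1)
  expect_equal(accept_probability(0, 10), 1)
  expect_equal(accept_probability(10, 10), exp(-1))
  expect_equal(accept_probability(23, 10), exp(-2.3))
  expect_error(accept_probability(1, 0), "Tm")
  ## empirical acceptance frequency matches the law within binomial error
  set.seed(42)
  for (dH in c(0.5, 1, 2)) {
    p <- accept_probability(dH, 1)
    n <- 1e5
    hits <- mean(stats::runif(n) < p)
    expect_lt(abs(hits - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("delta_energy matches the volume-term closed form on a toy cell", {
  p <- default_params()
  p$energy$J[] <- 0
  p$energy$lambda_surface[] <- 0
  sim <- empty_state(5, 5, p)
  id <- woundcpm:::new_cell_record(sim, cell_types()[["Fibroblast"]], tvol = 4)
  sim$lamv[id] <- 1; sim$lams[id] <- 0
  sim$grid[2:3, 2:3] <- id
  woundcpm:::resync_bookkeeping(sim)
  ## medium copy removing a corner pixel: dH = (3-4)^2 - (4-4)^2 = 1
  expect_equal(delta_energy(sim, c(2, 2), 0L), 1)
  ## null attempt is an error
  expect_error(delta_energy(sim, c(2, 2), id), "null attempt")
  expect_error(delta_energy(sim, c(9, 1), 0L), "bounds")
})

test_that("incremental delta H equals brute-force H difference for every flip", {
  ct <- cell_types()
  set.seed(7)
  for (rep in 1:6) {
    W <- sample(5:6, 1)
    p <- default_params()
    sim <- empty_state(W, W, p)
    for (k in 1:3)
      woundcpm:::new_cell_record(sim, sample(ct[-1], 1))
    sim$grid[] <- sample(0:3, W * W, replace = TRUE)
    woundcpm:::resync_bookkeeping(sim)
    H0 <- oracle_H_state(sim)
    for (x in seq_len(W)) for (y in seq_len(W)) {
      occ <- sim$grid[x, y]
      for (src in 0:3) {
        if (src == occ) next
        if (src > 0 && sim$volume[src] == 0) next
        dH <- delta_energy(sim, c(x, y), src)
        grid2 <- sim$grid; grid2[x, y] <- src
        n <- sim$n_ids
        H1 <- oracle_H(grid2, sim$type[1:n], sim$tvol[1:n], sim$lamv[1:n],
                       sim$tsurf[1:n], sim$lams[1:n], p$energy$J)
        expect_equal(dH, H1 - H0, tolerance = 1e-10)
      }
    }
  }
})

test_that("empty lattice is a fixed point of the Monte Carlo step", {
  sim <- empty_state(10, 10)
  monte_carlo_step(sim, 5)
  expect_true(all(sim$grid == 0L))
  expect_equal(sim$time_mcs, 5)
})

test_that("incremental bookkeeping matches a full recount after 1000 MCS", {
  set.seed(3)
  p <- default_params()
  sim <- empty_state(20, 20, p)
  a <- add_rect_cell(sim, "Fibroblast", 3:10, 3:10)
  b <- add_rect_cell(sim, "Macrophage", 12:19, 12:19)
  monte_carlo_step(sim, 1000, diffuse = FALSE)
  rc <- woundcpm:::.cpm_recount_cpp(sim$grid, sim$n_ids)
  n <- sim$n_ids
  expect_equal(sim$volume[1:n], rc$volume)
  expect_equal(sim$surface[1:n], rc$surface)
  expect_equal(sim$msurface[1:n], rc$msurface)
  expect_equal(sim$sumx[1:n], rc$sumx)
  expect_equal(sim$sumy[1:n], rc$sumy)
  ## total occupied pixels equal summed volumes
  expect_equal(sum(sim$grid != 0L), sum(rc$volume))
})

test_that("over-volume cell shrinks monotonically to target at low temperature", {
  p <- default_params()
  p$energy$Tm <- 1e-4
  p$energy$J[] <- 0
  sim <- empty_state(16, 16, p)
  id <- woundcpm:::new_cell_record(sim, cell_types()[["Fibroblast"]], tvol = 36)
  sim$lams[id] <- 0
  sim$grid[4:13, 4:13] <- id  # volume 100, target 36
  woundcpm:::resync_bookkeeping(sim)
  set.seed(5)
  prev <- sim$volume[id]
  for (k in 1:60) {
    monte_carlo_step(sim, 5, diffuse = FALSE)
    expect_lte(sim$volume[id], prev)
    prev <- sim$volume[id]
  }
  expect_equal(sim$volume[id], 36)
})

test_that("free-cell speed increases with the fluctuation amplitude", {
  speed_at <- function(Tm, n_mcs = 1500) {
    p <- default_params(); p$energy$Tm <- Tm
    sim <- empty_state(40, 40, p)
    id <- add_rect_cell(sim, "Fibroblast", 17:24, 17:24)
    set.seed(11)
    prev <- c(sim$sumx[id], sim$sumy[id]) / sim$volume[id]
    d <- numeric(n_mcs)
    for (i in seq_len(n_mcs)) {
      monte_carlo_step(sim, 1, diffuse = FALSE)
      cur <- c(sim$sumx[id], sim$sumy[id]) / sim$volume[id]
      d[i] <- sqrt(sum((cur - prev)^2)); prev <- cur
    }
    mean(d)
  }
  speeds <- vapply(c(4, 8.5, 16), speed_at, numeric(1))
  expect_true(all(diff(speeds) > 0))
})

test_that("division splits at doubling volume into equal-target daughters", {
  p <- default_params()
  sim <- empty_state(24, 24, p)
  id <- woundcpm:::new_cell_record(sim, cell_types()[["Fibroblast"]])
  sim$grid[5:20, 5:12] <- id  # 16 x 8 = 128 pixels = doubling volume
  woundcpm:::resync_bookkeeping(sim)
  set.seed(2)
  did <- maybe_divide(sim, id)
  expect_false(is.na(did))
  expect_equal(sim$volume[id] + sim$volume[did], 128)
  expect_equal(sim$tvol[id], 64)
  expect_equal(sim$tvol[did], 64)
  expect_equal(sim$type[did], sim$type[id])
  ## below the doubling volume nothing happens
  sim2 <- empty_state(24, 24, p)
  id2 <- woundcpm:::new_cell_record(sim2, cell_types()[["Fibroblast"]])
  sim2$grid[5:14, 5:14] <- id2  # 100 < 128
  woundcpm:::resync_bookkeeping(sim2)
  expect_true(is.na(maybe_divide(sim2, id2)))
  ## non-growing types never divide
  sim3 <- empty_state(24, 24, p)
  id3 <- woundcpm:::new_cell_record(sim3, cell_types()[["ECM"]], tvol = 4)
  sim3$grid[5:20, 5:12] <- id3
  woundcpm:::resync_bookkeeping(sim3)
  expect_true(is.na(maybe_divide(sim3, id3)))
})

test_that("random division axes give daughter volume ratios centred on one", {
  p <- default_params()
  set.seed(9)
  ratios <- replicate(300, {
    sim <- empty_state(20, 20, p)
    id <- woundcpm:::new_cell_record(sim, cell_types()[["Macrophage"]])
    sim$grid[3:18, 5:12] <- id  # 128-pixel rectangle
    woundcpm:::resync_bookkeeping(sim)
    did <- maybe_divide(sim, id)
    sim$volume[did] / sim$volume[id]
  })
  ## a line through the centre of a centrally symmetric cell bisects it, so
  ## the ratio distribution is tightly centred on 1
  expect_lt(abs(mean(log(ratios))), 0.15)
  expect_true(all(is.finite(ratios) & ratios > 0))
})

test_that("free-surface fraction Rs covers its boundary cases", {
  p <- default_params()
  sim <- empty_state(12, 12, p)
  lone <- add_rect_cell(sim, "Fibroblast", 2:5, 2:5)
  expect_equal(compute_rs(sim, lone), 1)  # fully surrounded by medium
  ## enclosed cell: Rs = 0
  sim2 <- empty_state(12, 12, p)
  inner <- woundcpm:::new_cell_record(sim2, cell_types()[["Fibroblast"]])
  outer <- woundcpm:::new_cell_record(sim2, cell_types()[["Macrophage"]])
  sim2$grid[4:9, 4:9] <- outer
  sim2$grid[6:7, 6:7] <- inner
  woundcpm:::resync_bookkeeping(sim2)
  expect_equal(compute_rs(sim2, inner), 0)
  ## half the boundary faces touch medium on a constructed configuration:
  ## 2x2 cell with cells covering its left and bottom sides
  sim3 <- empty_state(12, 12, p)
  c1 <- woundcpm:::new_cell_record(sim3, cell_types()[["Fibroblast"]])
  c2 <- woundcpm:::new_cell_record(sim3, cell_types()[["Macrophage"]])
  sim3$grid[5:6, 5:6] <- c1
  sim3$grid[4, 5:6] <- c2   # covers left side (2 faces)
  sim3$grid[5:6, 4] <- c2   # covers bottom side (2 faces)
  woundcpm:::resync_bookkeeping(sim3)
  expect_equal(compute_rs(sim3, c1), 0.5)
})
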