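test_that("initial populations pack the disc with duration-weighted phases", {
  cells <- create_initial_population(440, disc_radius_um = 200, seed = 3)
  expect_equal(length(cells$id), 440L)
  expect_true(all(sqrt((cells$x)^2 + (cells$y)^2) < 210))
  # determinism
  cells2 <- create_initial_population(440, disc_radius_um = 200, seed = 3)
  expect_identical(cells$x, cells2$x)
  expect_identical(cells$phase, cells2$phase)
  # disc too small
  expect_error(create_initial_population(440, disc_radius_um = 40, seed = 1),
               "too small")
  # phase histogram tracks duration weights within 1% over a large sample
  big <- create_initial_population(30000, disc_radius_um = 1800, seed = 5)
  cyc <- cycle_params()
  dur <- c(cyc$g1_h, cyc$s_h, cyc$g2_h, cyc$m_h)
  frac <- tabulate(big$phase, 4) / 30000
  expect_true(all(abs(frac - dur / sum(dur)) < 0.01))
})

test_that("cycle checkpoints gate G1, stretch under hypoxia, double volume
           and signal division", {
  mk <- function() create_initial_population(1, disc_radius_um = 20,
                                             seed = 1)
  cyc <- cycle_params()
  # baseline: ample ATP, low density, reference oxygen -> G1 completes at 5 h
  cells <- mk(); cells$phase[1] <- 1L; cells$phase_clock[1] <- 0
  t <- 0
  repeat {
    r <- advance_cycle(cells, 0.1, density = 0, o2_mmHg = 38, atp_mM = 2,
                       cycle = cyc)
    cells <- r$cells; t <- t + 0.1
    if (cells$phase[1] != 1L) break
  }
  expect_equal(t, 5, tolerance = 0.05)
  expect_equal(cells$phase[1], 2L)  # S

  # high density at checkpoint 1 -> G0, and stays until density drops
  cells <- mk(); cells$phase[1] <- 1L; cells$phase_clock[1] <- 0
  r <- advance_cycle(cells, 0.1, density = 1.2, o2_mmHg = 38, atp_mM = 2,
                     cycle = cyc)
  expect_equal(r$cells$phase[1], 5L)
  for (k in 1:50) r <- advance_cycle(r$cells, 0.1, density = 1.2,
                                     o2_mmHg = 38, atp_mM = 2, cycle = cyc)
  expect_equal(r$cells$phase[1], 5L)
  r <- advance_cycle(r$cells, 0.1, density = 0.2, o2_mmHg = 38, atp_mM = 2,
                     cycle = cyc)
  expect_equal(r$cells$phase[1], 1L)

  # oxygen at half reference (above the floor): G1 target doubles to 10 h
  cells <- mk(); cells$phase[1] <- 1L; cells$phase_clock[1] <- 0
  t <- 0
  repeat {
    r <- advance_cycle(cells, 0.1, density = 0, o2_mmHg = 19, atp_mM = 2,
                       cycle = cyc)
    cells <- r$cells; t <- t + 0.1
    if (cells$phase[1] != 1L) break
  }
  expect_equal(t, 5 * 38 / 19, tolerance = 0.05)

  # S phase doubles the volume linearly; M completion emits the signal
  cells <- mk(); cells$phase[1] <- 2L; cells$phase_clock[1] <- 0
  for (k in 1:80) {
    r <- advance_cycle(cells, 0.1, density = 0, o2_mmHg = 38, atp_mM = 2,
                       cycle = cyc)
    cells <- r$cells
  }
  expect_equal(cells$volume[1], 2 * cells$basal_volume, tolerance = 1e-6)
  # run through G2 and M
  div <- FALSE
  for (k in 1:60) {
    r <- advance_cycle(cells, 0.1, density = 0, o2_mmHg = 38, atp_mM = 2,
                       cycle = cyc)
    cells <- r$cells
    if (any(r$divide)) { div <- TRUE; break }
  }
  expect_true(div)
})

test_that("division halves volume, copies state and perturbs gamma", {
  cells <- create_initial_population(1, disc_radius_um = 20, seed = 2)
  cells$volume[1] <- 2 * cells$basal_volume
  cells$gamma[1] <- 1.07
  parent_state <- cells$state[, 1]
  v0 <- cells$volume[1]
  out <- divide_cells(cells, divide = TRUE, seed = 9, tick = 4,
                      gamma_sigma = 0)
  expect_equal(length(out$id), 2L)
  expect_equal(out$volume, rep(v0 / 2, 2))
  expect_identical(out$state[, 1], parent_state)
  expect_identical(out$state[, 2], parent_state)
  # degenerate distribution: daughters keep the parent's gamma
  expect_equal(out$gamma, rep(1.07, 2))
  # with sigma > 0, gammas differ between daughters but hover near parent
  out2 <- divide_cells(cells, divide = TRUE, seed = 9, tick = 4,
                       gamma_sigma = 0.05)
  expect_false(out2$gamma[1] == out2$gamma[2])
  expect_true(all(abs(log(out2$gamma / 1.07)) < 0.5))
  # daughters sit one half-radius on either side of the parent position
  expect_false(out2$x[1] == out2$x[2] && out2$y[1] == out2$y[2])
})

test_that("necrosis needs 3 h of persistent ATP deficit and scales with
           depth", {
  mk <- function() create_initial_population(1, disc_radius_um = 20,
                                             seed = 1)
  dp <- death_params(p_max = 1)
  # 2 h at 0.1 mM: alive, clock accumulated
  cells <- mk()
  for (k in 1:20) cells <- update_death(cells, 0.1, atp_mM = 0.1, seed = 1,
                                        tick = k, death = dp)
  expect_true(cells$alive[1])
  expect_equal(cells$atp_clock[1], 2, tolerance = 1e-9)
  # recovery resets the clock
  cells <- update_death(cells, 0.1, atp_mM = 0.5, seed = 1, tick = 99,
                        death = dp)
  expect_equal(cells$atp_clock[1], 0)
  # 0.5 mM forever: never necrotic
  cells <- mk()
  for (k in 1:500) cells <- update_death(cells, 0.1, atp_mM = 0.5, seed = 1,
                                         tick = k, death = dp)
  expect_true(cells$alive[1])
  # zero ATP with the clock beyond persistence and p_max = 1: certain death
  cells <- mk()
  cells$atp_clock[1] <- 3
  cells <- update_death(cells, 0.1, atp_mM = 0, seed = 1, tick = 1,
                        death = dp)
  expect_false(cells$alive[1])
  expect_equal(cell_phases(cells)[1], "NECROTIC_SWELLING")
})

test_that("necrosis swells, lyses into the voxel and terminates as debris", {
  cells <- create_initial_population(1, disc_radius_um = 20, seed = 1)
  dp <- death_params()
  cells$alive[1] <- FALSE
  cells$phase[1] <- 6L
  cells$phase_clock[1] <- 0
  cells$necro_v0[1] <- cells$volume[1]
  cells$state["lactate_i", 1] <- 4
  vols <- numeric(0)
  lys <- NULL
  for (k in 1:70) {
    r <- progress_necrosis(cells, 0.1, dp)
    cells <- r$cells
    vols <- c(vols, cells$volume[1])
    if (!is.null(r$lysis)) lys <- r$lysis
  }
  # volume strictly increasing during swelling
  expect_true(all(diff(vols[1:59]) > 0))
  expect_false(is.null(lys))
  # lysis reports concentration and volume; voxel conversion oracle
  voxvol <- 20^3
  deposit <- lys$lactate[1] * lys$volume[1] / voxvol
  expect_equal(deposit, 4 * dp$swell_factor * cells$basal_volume / voxvol)
  # shrink to debris, metabolism off
  for (k in 1:260) cells <- progress_necrosis(cells, 0.1, dp)$cells
  expect_equal(cell_phases(cells)[1], "DEBRIS")
  expect_false(cells$alive[1])
})

test_that("mechanics: equilibrium separation, repulsion of overlaps,
           isolated cells stationary", {
  mech <- mechanics_params()
  r0 <- (3 * 2494 / (4 * pi))^(1 / 3)
  # rest separation: solve for the distance where the pair force vanishes
  d_star <- uniroot(function(d) pair_force(d, r0, r0, mech),
                    c(1.2 * r0, 2 * r0), tol = 1e-12)$root
  expect_equal(pair_force(d_star, r0, r0, mech), 0, tolerance = 1e-8)
  cells <- create_initial_population(2, disc_radius_um = 30, seed = 1,
                                     center_um = c(200, 200))
  cells$x <- c(200, 200 + d_star); cells$y <- c(200, 200)
  moved <- mechanics_step(cells, dt_s = 6, mech = mech, extent_um = 400)
  expect_equal(moved$x, cells$x, tolerance = 1e-7)
  # overlapping cells separate monotonically
  cells$x <- c(200, 200 + r0)
  seps <- numeric(0)
  for (k in 1:20) {
    cells <- mechanics_step(cells, dt_s = 6, mech = mech, extent_um = 400)
    seps <- c(seps, abs(diff(cells$x)))
  }
  expect_true(all(diff(seps) > -1e-12))
  expect_gt(seps[20], r0 * 1.2)
  # isolated cell does not move
  one <- create_initial_population(1, disc_radius_um = 20, seed = 1,
                                   center_um = c(200, 200))
  m1 <- mechanics_step(one, dt_s = 6, mech = mech, extent_um = 400)
  expect_equal(m1$x, one$x)
  expect_equal(m1$y, one$y)
})

test_that("local density is the analytic neighbour cross-section fraction", {
  cells <- create_initial_population(1, disc_radius_um = 20, seed = 1,
                                     center_um = c(100, 100))
  expect_equal(local_density(cells), 0)
  # constructed ring of 6 neighbours at 20 um
  n <- 7
  ring <- create_initial_population(n, disc_radius_um = 40, seed = 1,
                                    center_um = c(100, 100))
  ring$x <- c(100, 100 + 20 * cos(2 * pi * (0:5) / 6))
  ring$y <- c(100, 100 + 20 * sin(2 * pi * (0:5) / 6))
  r0 <- (3 * 2494 / (4 * pi))^(1 / 3)
  dens <- local_density(ring, neigh_radius_um = 26)
  expect_equal(dens[1], 6 * r0^2 / 26^2, tolerance = 1e-6)
  # monotone: adding a neighbour never decreases occupancy
  more <- ring
  more$x <- c(more$x, 110); more$y <- c(more$y, 100)
  more$volume <- c(more$volume, 2494)
  more$id <- c(more$id, 99L)
  dens2 <- local_density(more, neigh_radius_um = 26)
  expect_gte(dens2[1], dens[1])
})
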