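test_that("scheduler maintains the printed step ratios", {
  sc <- schedule_counts(schedule())
  # per 6-min phenotype interval: 600 diffusion, 300 metabolism,
  # 60 mechanics steps, i.e. 10:5:1 per 6 simulated seconds
  expect_equal(unname(sc), c(600L, 300L, 60L))
  expect_equal(unname(sc / (schedule()$dt_phenotype_s / 6)), c(10, 5, 1))
  expect_warning(schedule(dt_metabolism_s = 0.6), "ratios")
})

test_that("one kernel tick of 6 s performs 10 diffusion, 5 metabolism and
           1 mechanics invocations", {
  cfg <- tiny_sim_config()
  grid <- make_grid(cfg)
  cells <- create_initial_population(3, disc_radius_um = 30, seed = 1,
                                     center_um = c(200, 200))
  p <- metabolic_parameters()
  res <- metaspheroid:::msx_tick(
    unname(grid$fields), p, unname(grid$D), c(0L, 0L, 0L, 0L),
    unname(grid$bc_value), rep(NA_real_, 4), 20, 0.6, 10L, 2L, 10L,
    cells$state, cells$x, cells$y, cells$volume, rep(1L, 3), cells$gamma,
    as.numeric(cells$id), 0, 1, 0, c(30, 3, 1.25, 2), 400)
  expect_equal(unname(res$counts), c(10L, 5L, 1L))
})

test_that("identical config and seed give identical outputs", {
  cfg <- tiny_sim_config(t_end_h = 1)
  s1 <- run_simulation(cfg, seed = 4)
  s2 <- run_simulation(cfg, seed = 4)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$final$cells$state, s2$final$cells$state)
  expect_identical(s1$final$grid$fields, s2$final$grid$fields)
  s3 <- run_simulation(cfg, seed = 5)
  expect_false(identical(s1$final$cells$state, s3$final$cells$state))
})

test_that("cell iteration order does not change the tick outcome", {
  cfg <- tiny_sim_config()
  grid <- make_grid(cfg)
  cells <- create_initial_population(6, disc_radius_um = 40, seed = 2,
                                     center_um = c(200, 200))
  p <- metabolic_parameters()
  run_tick <- function(ord) {
    metaspheroid:::msx_tick(
      unname(grid$fields), p, unname(grid$D), c(0L, 0L, 0L, 0L),
      unname(grid$bc_value), rep(NA_real_, 4), 20, 0.6, 100L, 2L, 10L,
      cells$state[, ord], cells$x[ord], cells$y[ord], cells$volume[ord],
      rep(1L, 6), cells$gamma[ord], as.numeric(cells$id[ord]), 0.02, 9, 0,
      c(30, 3, 1.25, 2), 400)
  }
  a <- run_tick(1:6)
  b <- run_tick(6:1)
  expect_equal(a$fields, b$fields, tolerance = 1e-12)
  expect_equal(a$state, b$state[, 6:1], tolerance = 1e-12)
})

test_that("an empty population leaves pure diffusion dynamics", {
  cfg <- tiny_sim_config()
  grid <- make_grid(cfg)
  p <- metabolic_parameters()
  grid$fields$glucose[10, 10] <- 20
  res <- metaspheroid:::msx_tick(
    unname(grid$fields), p, unname(grid$D), c(0L, 0L, 0L, 0L),
    unname(grid$bc_value), rep(NA_real_, 4), 20, 0.6, 50L, 2L, 10L,
    matrix(numeric(0), 53, 0), numeric(0), numeric(0), numeric(0),
    integer(0), numeric(0), numeric(0), 0, 1, 0, c(30, 3, 1.25, 2), 400)
  ref <- grid$fields$glucose
  for (k in 1:50) {
    out <- metaspheroid:::msx_adi_step(ref, grid$D[["glucose"]], 0.01, 20,
                                       0L, 6, NULL)
    ref <- out$field
  }
  expect_equal(res$fields[[2]], ref, tolerance = 1e-12)
})

test_that("perturbation entries drive boundaries and clamps", {
  bc0 <- c(oxygen = o2_mmHg_to_mM(38), glucose = 6, lactate = 0.1,
           proton = proton_from_ph(7.4))
  sw <- list(kind = "square_wave", species = "oxygen", high = 70, low = 15,
             period_h = 18, from_h = 10, units = "mmHg")
  r1 <- resolve_perturbations(list(sw), 10, bc0)
  expect_equal(unname(r1$bc_value["oxygen"]), o2_mmHg_to_mM(70))
  r2 <- resolve_perturbations(list(sw), 10 + 9, bc0)
  expect_equal(unname(r2$bc_value["oxygen"]), o2_mmHg_to_mM(15))
  # a clamp scheduled for 60 h is a no-op at 59 h
  fc <- list(kind = "field_clamp", species = "glucose", value = 0.01,
             from_h = 60, units = "mM")
  r3 <- resolve_perturbations(list(fc), 59, bc0)
  expect_true(is.na(r3$clamp[["glucose"]]))
  r4 <- resolve_perturbations(list(fc), 60, bc0)
  expect_equal(r4$clamp[["glucose"]], 0.01)
  # pH clamp translates to the free-proton field value
  pc <- list(kind = "field_clamp", species = "proton", value = 6.0,
             from_h = 50, units = "pH")
  r5 <- resolve_perturbations(list(pc), 80, bc0)
  expect_equal(r5$clamp[["proton"]], 1e-3)
  # apply_perturbation overwrites the field for clamps
  g <- make_grid(tiny_grid_config())
  g2 <- apply_perturbation(g, pc, 80)
  expect_true(all(g2$fields$proton == 1e-3))
})

test_that("population growth doubles near the configured cycle time under
           abundant nutrients", {
  # no density cap, uniform rich medium: doubling time within 10% of the
  # 18 h total cycle
  cfg <- tiny_sim_config(t_end_h = 20, n = 40, extent = 600)
  cfg$cells$disc_radius_um <- 200
  cfg$cells$cycle <- list(density_threshold = 1.5)
  cfg$cells$noise_amp <- 0
  sim <- run_simulation(cfg, seed = 2)
  s <- sim$series
  n0 <- s$n_total[s$time_h == 1]
  n18 <- s$n_total[s$time_h == 18]
  expect_gt(n18 / n0, 2 / 1.15)
  expect_lt(n18 / n0, 2 * 1.15)
})
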