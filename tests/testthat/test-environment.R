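test_that("oxygen pressure and pH unit conversions are exact", {
  expect_identical(o2_mmHg_to_mM(0), 0)
  expect_equal(o2_mmHg_to_mM(38), 0.0494)
  expect_equal(o2_mmHg_to_mM(160), 0.208)
  expect_equal(o2_mM_to_mmHg(o2_mmHg_to_mM(73.2)), 73.2)
  expect_error(o2_mmHg_to_mM(-1), "non-negative")

  expect_equal(proton_from_ph(7.0), 1e-4)
  expect_equal(proton_from_ph(6.0), 1e-3)
  expect_equal(proton_from_ph(7.4), 10^(-7.4) * 1e3, tolerance = 1e-12)
  expect_equal(ph_from_proton(proton_from_ph(7.123)), 7.123,
               tolerance = 1e-12)
  expect_error(ph_from_proton(0), "positive")
})

test_that("make_grid initializes fields at scenario concentrations", {
  g <- make_grid(tiny_grid_config())
  expect_equal(g$nx, 5L)
  expect_equal(dim(g$fields$oxygen), c(5, 5))
  expect_true(all(g$fields$oxygen == o2_mmHg_to_mM(38)))
  expect_true(all(g$fields$glucose == 6))
  expect_true(all(g$fields$lactate == 0.1))
  expect_equal(ph_from_proton(g$fields$proton[1, 1]), 7.4)
  expect_error(make_grid(tiny_grid_config(extent = 95)), "divisible")
  bad <- tiny_grid_config()
  names(bad$species)[1] <- "ozone"
  expect_error(make_grid(bad), "unknown species")
})

test_that("uniform field with matching dirichlet value is an equilibrium", {
  g <- make_grid(tiny_grid_config(extent = 200))
  before <- g$fields$proton
  for (k in 1:20) g <- step_diffusion(g, 0.6)
  expect_equal(g$fields$proton, before, tolerance = 1e-13)
})

test_that("zero-flux boundaries conserve mass to 1e-9 relative", {
  g <- make_grid(tiny_grid_config(extent = 200, boundary = "neumann"))
  # break uniformity (smoothly) so diffusion actually acts
  xc <- (1:10 - 0.5) * 20
  bump <- exp(-(outer((xc - 60)^2, (xc - 90)^2, "+")) / (2 * 50^2))
  g$fields$glucose <- g$fields$glucose + 4 * bump
  g$fields$proton <- g$fields$proton + 2e-5 * bump
  m0 <- vapply(g$fields, sum, numeric(1))
  for (k in 1:2000) g <- step_diffusion(g, 0.6)
  m1 <- vapply(g$fields, sum, numeric(1))
  expect_true(all(abs(m1 - m0) / m0 < 1e-9))
})

test_that("dirichlet boundary voxels equal the boundary value exactly", {
  g <- make_grid(tiny_grid_config(extent = 200))
  g$fields$oxygen[4, 4] <- 0  # interior perturbation
  for (k in 1:5) g <- step_diffusion(g, 0.6)
  f <- g$fields$oxygen
  edge <- c(f[1, ], f[nrow(f), ], f[, 1], f[, ncol(f)])
  expect_identical(unique(edge), o2_mmHg_to_mM(38))
})

test_that("steady diffusion-uptake matches the analytic parabola within 1%", {
  # 1D strip (dirichlet x-ends, zero-flux y-sides): uniform volumetric
  # uptake k against the stationary solution of D c'' = k with both ends
  # at c0: c(x) = c0 - (k/2D)(x - x0)(x1 - x), ends at the boundary-voxel
  # centers x0, x1.
  D <- 30000   # um^2/min
  h <- 20
  nx <- 20; ny <- 5
  c0 <- 6
  k_up <- 2.0  # mM/min
  f <- matrix(c0, nx, ny)
  src <- matrix(-k_up, nx, ny)
  for (it in 1:1500) {
    res <- metaspheroid:::msx_adi_step(f, D, 0.6 / 60, h, 2L, c0, src)
    f <- res$field
  }
  x <- (seq_len(nx) - 0.5) * h
  x0 <- x[1]; x1 <- x[nx]
  analytic <- c0 - (k_up / (2 * D)) * (x - x0) * (x1 - x)
  expect_lt(max(abs(f[, 3] - analytic)) / c0, 0.01)
  # the strip is uniform across y
  expect_lt(max(abs(f[, 1] - f[, 5])), 1e-9)
})

test_that("production solver agrees with a tiny-dt explicit reference", {
  cfg <- tiny_grid_config(extent = 180, voxel = 20, boundary = "dirichlet")
  g <- make_grid(cfg)
  set.seed(42)
  g$fields$proton <- matrix(10^runif(81, -5, -3.5), 9, 9)
  ref <- ftcs_reference(g$fields$proton, g$D[["proton"]],
                        t_total_min = 50 * 0.6 / 60, dt_min = 1e-5,
                        h = 20, bc_kind = "dirichlet",
                        bc_value = g$bc_value[["proton"]])
  for (k in 1:50) g <- step_diffusion(g, 0.6)
  err <- max(abs(g$fields$proton - ref)) / max(ref)
  expect_lt(err, 0.005)
})

test_that("exchange deposits are additive and floor at zero with logging", {
  g <- make_grid(tiny_grid_config())
  g <- deposit_exchange(g, c(3, 3), c(lactate = 1))
  g <- deposit_exchange(g, c(3, 3), c(lactate = 1))
  expect_equal(g$exchange$lactate[3, 3], 2)
  g <- deposit_exchange(g, c(3, 3), c(glucose = 0))
  expect_equal(g$exchange$glucose[3, 3], 0)
  expect_error(deposit_exchange(g, c(9, 1), c(lactate = 1)), "outside")

  # uptake far exceeding the voxel content: concentration floors at 0 and
  # the shortfall is logged as clipped mass
  g2 <- make_grid(tiny_grid_config(lac = 0.05))
  g2 <- deposit_exchange(g2, c(3, 3), c(lactate = -1e4))
  g2 <- step_diffusion(g2, 0.6)
  expect_true(all(g2$fields$lactate >= 0))
  expect_gt(g2$clipped[["lactate"]], 0)
})

test_that("radial profiles average voxels per distance bin", {
  g <- make_grid(tiny_grid_config(extent = 400))
  p <- radial_profile(g, "glucose", bin_width = 20)
  expect_true(all(abs(p$mean[!p$empty] - 6) < 1e-12))

  # constructed radially symmetric field c(r) = r, against a brute-force
  # average over enumerated voxels
  nx <- g$nx
  h <- g$voxel_um
  ctr <- c(200, 200)
  xc <- (seq_len(nx) - 0.5) * h
  d <- sqrt(outer((xc - ctr[1])^2, (xc - ctr[2])^2, "+"))
  f <- d
  p2 <- radial_profile(f, center = ctr, bin_width = 25, voxel_um = h)
  brute <- tapply(as.vector(d), floor(as.vector(d) / 25), mean)
  got <- p2$mean[!p2$empty]
  expect_equal(unname(got), unname(as.numeric(brute)), tolerance = 1e-12)
  # bin means track the bin-center radius within half a voxel diagonal
  expect_true(all(abs(got - p2$bin_center[!p2$empty]) <= h * sqrt(2) / 2))

  # locality: perturbing one voxel changes only its own bin
  f2 <- matrix(1, nx, nx)
  f2[14, 10] <- 5
  pa <- radial_profile(matrix(1, nx, nx), center = ctr, bin_width = 20,
                       voxel_um = h)
  pb <- radial_profile(f2, center = ctr, bin_width = 20, voxel_um = h)
  diffbins <- which(abs(pa$mean - pb$mean) > 1e-12)
  r_star <- sqrt((xc[14] - 200)^2 + (xc[10] - 200)^2)
  expect_equal(length(diffbins), 1L)
  expect_equal(floor(r_star / 20) + 1, diffbins)
})
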