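# Shared fixtures: tiny grids, environments and configs built in code.

tiny_grid_config <- function(extent = 100, voxel = 20,
                             o2_mmHg = 38, glc = 6, lac = 0.1, pH = 7.4,
                             boundary = "dirichlet") {
  list(grid = list(extent_um = extent, voxel_um = voxel),
       species = list(
         oxygen = list(initial_mmHg = o2_mmHg, boundary = boundary,
                       boundary_mmHg = o2_mmHg),
         glucose = list(initial_mM = glc, boundary = boundary,
                        boundary_mM = glc),
         lactate = list(initial_mM = lac, boundary = boundary,
                        boundary_mM = lac),
         proton = list(initial_pH = pH, boundary = boundary,
                       boundary_pH = pH)))
}

basal_env <- function() {
  local_environment(oxygen_mmHg = 38, glucose_mM = 6, lactate_mM = 0.1,
                    pH = 7.4)
}

hypoxic_lactate_env <- function() {
  # the mapped low-oxygen study level (2 mmHg), with ample glucose + lactate
  local_environment(oxygen_mmHg = 2, glucose_mM = 6, lactate_mM = 5,
                    pH = 7.4)
}

# tiny full-engine config for determinism/scheduler tests
tiny_sim_config <- function(t_end_h = 1, n = 12, extent = 400) {
  cfg <- build_reference(scaled = TRUE)
  cfg$grid$extent_um <- extent
  cfg$cells$n_initial <- n
  cfg$cells$disc_radius_um <- 50
  cfg$schedule$t_end_h <- t_end_h
  cfg
}

# independent explicit FTCS reference integrator (tiny dt), used as the
# oracle for the production ADI solver
ftcs_reference <- function(field, D, t_total_min, dt_min, h, bc_kind,
                           bc_value) {
  nx <- nrow(field); ny <- ncol(field)
  steps <- round(t_total_min / dt_min)
  f <- field
  for (s in seq_len(steps)) {
    if (bc_kind == "dirichlet") {
      f[1, ] <- bc_value; f[nx, ] <- bc_value
      f[, 1] <- bc_value; f[, ny] <- bc_value
    }
    up <- rbind(f[-1, ], f[nx, ]); dn <- rbind(f[1, ], f[-nx, ])
    rt <- cbind(f[, -1], f[, ny]); lf <- cbind(f[, 1], f[, -ny])
    lap <- (up + dn + rt + lf - 4 * f) / h^2
    f <- f + D * dt_min * lap
    if (bc_kind == "dirichlet") {
      f[1, ] <- bc_value; f[nx, ] <- bc_value
      f[, 1] <- bc_value; f[, ny] <- bc_value
    }
  }
  f
}
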