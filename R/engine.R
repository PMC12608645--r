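#' @title Multirate simulation engine
#' @description The scheduler binding environment, metabolism, cells and
#'   phenotyping: diffusion every 0.6 s, metabolism every second diffusion
#'   step, mechanics every tenth, and phenotype/cycle/death evaluation every
#'   6 minutes, exactly the 10:5:1(:600) ratio structure of the framework.
#' @name engine-module
NULL

#' Multirate schedule
#'
#' @param dt_diffusion_s Diffusion step (s).
#' @param dt_metabolism_s Metabolism step; must be 2x diffusion for default
#'   configs (overriding is allowed but flagged with a warning).
#' @param dt_mechanics_s Mechanics step (10x diffusion).
#' @param dt_phenotype_s Phenotype evaluation interval (600x diffusion).
#' @param t_end_h Simulated end time (h).
#' @param snapshot_h Output cadence (h).
#' @return Validated schedule list.
#' @export
schedule <- function(dt_diffusion_s = 0.6, dt_metabolism_s = 1.2,
                     dt_mechanics_s = 6, dt_phenotype_s = 360,
                     t_end_h = 120, snapshot_h = 1) {
  s <- list(dt_diffusion_s = dt_diffusion_s,
            dt_metabolism_s = dt_metabolism_s,
            dt_mechanics_s = dt_mechanics_s,
            dt_phenotype_s = dt_phenotype_s,
            t_end_h = t_end_h, snapshot_h = snapshot_h)
  ratios <- c(s$dt_metabolism_s / s$dt_diffusion_s,
              s$dt_mechanics_s / s$dt_diffusion_s,
              s$dt_phenotype_s / s$dt_diffusion_s)
  if (!isTRUE(all.equal(ratios, c(2, 10, 600))))
    warning("schedule overrides the default 2/10/600 step ratios")
  s
}

#' Counts of sub-process invocations per phenotype tick
#'
#' @param sched A [schedule()].
#' @return Named integer vector: diffusion, metabolism, mechanics steps per
#'   phenotype evaluation interval.
#' @export
schedule_counts <- function(sched = schedule()) {
  n_diff <- round(sched$dt_phenotype_s / sched$dt_diffusion_s)
  met_every <- round(sched$dt_metabolism_s / sched$dt_diffusion_s)
  mech_every <- round(sched$dt_mechanics_s / sched$dt_diffusion_s)
  c(diffusion = n_diff,
    metabolism = length(seq(0, n_diff - 1, by = met_every)),
    mechanics = length(seq(0, n_diff - 1, by = mech_every)))
}

#' Resolve the active perturbations at a time point
#'
#' Perturbation entries are data, not code: `boundary_set` changes a
#' species' Dirichlet boundary value, `field_clamp` overwrites the whole
#' field every diffusion step from a start time, and `square_wave`
#' alternates the boundary value between a high and a low level with
#' half-period phases. Values are given in natural units (mmHg for oxygen,
#' pH for protons, mM otherwise).
#'
#' @param entries List of perturbation entries (see shipped scenarios).
#' @param t_h Current time (h).
#' @param bc_value Baseline boundary values (mM, named per species).
#' @return List with updated `bc_value` and `clamp` (mM per species, NA =
#'   no clamp).
#' @export
resolve_perturbations <- function(entries, t_h, bc_value) {
  clamp <- stats::setNames(rep(NA_real_, 4), MSX_SPECIES)
  for (e in entries) {
    from <- e$from_h %||% 0
    until <- e$until_h %||% Inf
    if (t_h < from || t_h >= until) next
    sp <- e$species
    if (e$kind == "square_wave") {
      half <- e$period_h / 2
      phase <- floor((t_h - from) / half) %% 2
      val <- if (phase == 0) e$high else e$low
      bc_value[sp] <- pert_value_mM(sp, val, e$units %||% NULL)
    } else if (e$kind == "boundary_set") {
      bc_value[sp] <- pert_value_mM(sp, e$value, e$units %||% NULL)
    } else if (e$kind == "field_clamp") {
      v <- pert_value_mM(sp, e$value, e$units %||% NULL)
      clamp[sp] <- v
      bc_value[sp] <- v
    } else stop("unknown perturbation kind: ", e$kind)
  }
  list(bc_value = bc_value, clamp = clamp)
}

pert_value_mM <- function(species, value, units = NULL) {
  if (is.null(units)) {
    units <- switch(species, oxygen = "mmHg", proton = "pH", "mM")
  }
  switch(units,
         mmHg = o2_mmHg_to_mM(value),
         pH = proton_from_ph(value),
         mM = value,
         stop("unknown units: ", units))
}

#' Apply a single perturbation entry to a grid (diagnostic surface)
#'
#' @param grid An `msx_grid`.
#' @param entry One perturbation entry.
#' @param t_h Current time (h).
#' @return The grid with boundary values updated and, for field clamps,
#'   the field overwritten.
#' @export
apply_perturbation <- function(grid, entry, t_h) {
  res <- resolve_perturbations(list(entry), t_h, grid$bc_value)
  grid$bc_value <- res$bc_value
  for (s in MSX_SPECIES) {
    if (is.finite(res$clamp[[s]])) grid$fields[[s]][] <- res$clamp[[s]]
  }
  grid
}

#' Run a scenario simulation
#'
#' The single entry point: builds the grid and population from the
#' configuration and advances the multirate loop to `t_end_h`. Within each
#' 6-minute tick the compiled kernel performs 600 diffusion steps with
#' metabolism every 2nd and mechanics every 10th step (cell exchange is
#' accumulated per voxel and consumed by the following diffusion step, so
#' results are independent of cell iteration order); the tick boundary then
#' applies phenotype classification, cycle checkpoints, necrosis, division
#' and snapshot hooks. Identical (config, seed) pairs give identical
#' outputs.
#'
#' @param config Scenario configuration (see [build_reference()] etc.).
#' @param seed Integer seed driving every source of randomness.
#' @param progress Print a progress line every simulated 12 h.
#' @param resume A previous `msx_sim` to continue from (warm start): the
#'   grid, cells and RNG stream counters are taken from its final state and
#'   the loop continues at the next tick. Used to branch perturbation arms
#'   off a shared history (the seed must match). The returned series covers
#'   only the resumed interval.
#' @return An object of class `msx_sim`: `series` (per-snapshot population
#'   counts, phenotype and Warburg-status fractions), `snapshots` (cell
#'   tables and radial profiles at the configured cadence), `landscape`
#'   (per-frame and time-integrated LDH-PDH histograms), `final` (grid and
#'   cells), and `manifest`.
#' @export
run_simulation <- function(config, seed = 1, progress = FALSE,
                           resume = NULL) {
  sched <- do.call(schedule, config$schedule %||% list())
  params <- if (!is.null(config$parameter_file))
    metabolic_parameters(config$parameter_file) else metabolic_parameters()
  cc <- config$cells
  cycle <- do.call(cycle_params, cc$cycle %||% list())
  death <- do.call(death_params, cc$death %||% list())
  mech <- do.call(mechanics_params, cc$mechanics %||% list())
  if (is.null(resume)) {
    grid <- make_grid(config)
    cells <- create_initial_population(
      n = cc$n_initial, disc_radius_um = cc$disc_radius_um, seed = seed,
      cycle = cycle, volume_um3 = cc$volume_um3 %||% 2494,
      gamma = cc$gamma %||% 1,
      center_um = c(grid$extent_um / 2, grid$extent_um / 2))
  } else {
    if (!identical(resume$manifest$seed, seed))
      stop("resume seed does not match")
    grid <- resume$final$grid
    cells <- resume$final$cells
  }
  noise_amp <- cc$noise_amp %||% 0.01
  gamma_sigma <- cc$gamma_sigma %||% 0.05

  dt_tick_h <- sched$dt_phenotype_s / 3600
  n_ticks <- round(sched$t_end_h / dt_tick_h)
  n_diff <- round(sched$dt_phenotype_s / sched$dt_diffusion_s)
  met_every <- round(sched$dt_metabolism_s / sched$dt_diffusion_s)
  mech_every <- round(sched$dt_mechanics_s / sched$dt_diffusion_s)
  snap_every <- max(1, round(sched$snapshot_h / dt_tick_h))
  bc_kind_code <- vapply(MSX_SPECIES, function(s) bc_code(grid$bc_kind[[s]]),
                         integer(1))
  mech_vec <- c(mech$c_rep, mech$c_adh, mech$adh_scale, mech$max_disp_um)
  perts <- config$perturbations %||% list()
  record_tables <- config$outputs$cell_tables %||% "last"
  land_bins <- config$outputs$landscape_bins %||% 60

  series <- list()
  snapshots <- list()
  land_frames <- list()
  land_total <- NULL
  step0 <- if (is.null(resume)) 0 else resume$final$step0
  tick_start <- if (is.null(resume)) 0L else resume$final$tick
  voxvol <- grid$voxel_um^3

  if (tick_start >= n_ticks)
    stop("resume state is already at or beyond the configured end time")
  for (tick in (tick_start + 1L):n_ticks) {
    t_h <- tick * dt_tick_h
    pert <- resolve_perturbations(perts, t_h - dt_tick_h, grid$bc_value)
    active <- as.integer(cells$alive)
    res <- msx_tick(unname(grid$fields), params,
                    unname(grid$D[MSX_SPECIES]),
                    unname(bc_kind_code), unname(pert$bc_value[MSX_SPECIES]),
                    unname(pert$clamp[MSX_SPECIES]),
                    grid$voxel_um, sched$dt_diffusion_s, n_diff, met_every,
                    mech_every, cells$state, cells$x, cells$y, cells$volume,
                    active, cells$gamma, as.numeric(cells$id), noise_amp,
                    seed, step0, mech_vec, grid$extent_um)
    for (k in seq_along(MSX_SPECIES)) grid$fields[[MSX_SPECIES[k]]] <- res$fields[[k]]
    grid$clipped <- grid$clipped + stats::setNames(res$clipped, MSX_SPECIES)
    cells$state <- res$state
    cells$x <- res$x
    cells$y <- res$y
    step0 <- res$step_next
    flux <- res$flux_avg

    # phenotype evaluation over living cells (interval-average fluxes)
    live <- cells$alive
    r12 <- flux[12, ]; r18 <- flux[18, ]; r21 <- flux[21, ]
    labels <- classify_phenotype(r12[live], r18[live])
    eps <- warburg_eps(r21[live])
    statuses <- classify_lactate_status(r21[live], labels, eps)
    snap_due <- (tick %% snap_every == 0 || tick == n_ticks)
    tab <- if (snap_due && (record_tables == "all" ||
                            (record_tables == "last" && tick == n_ticks)))
      cell_table(cells, r12, r18, r21, labels, statuses) else NULL
    land_live <- cells$state[c("LDH", "PDH"), live, drop = FALSE]

    # death, necrosis, lysis
    atp <- cells$state["atp", ]
    cells <- update_death(cells, dt_tick_h, atp, seed, tick, death)
    nec <- progress_necrosis(cells, dt_tick_h, death)
    cells <- nec$cells
    if (!is.null(nec$lysis)) {
      for (k in seq_len(nrow(nec$lysis))) {
        vi <- pmin(grid$nx, pmax(1, floor(nec$lysis$x[k] / grid$voxel_um) + 1))
        vj <- pmin(grid$ny, pmax(1, floor(nec$lysis$y[k] / grid$voxel_um) + 1))
        sc <- nec$lysis$volume[k] / voxvol
        grid$fields$glucose[vi, vj] <- grid$fields$glucose[vi, vj] +
          nec$lysis$glucose[k] * sc
        grid$fields$lactate[vi, vj] <- grid$fields$lactate[vi, vj] +
          nec$lysis$lactate[k] * sc
        grid$fields$proton[vi, vj] <- grid$fields$proton[vi, vj] +
          nec$lysis$proton[k] * sc
      }
    }
    cells <- drop_cells(cells, nec$remove)

    # cycle and division
    live_idx <- cells$alive
    if (any(live_idx)) {
      dens <- local_density(cells, mech$neigh_radius_um)
      vi <- pmin(grid$nx, pmax(1, floor(cells$x / grid$voxel_um) + 1))
      vj <- pmin(grid$ny, pmax(1, floor(cells$y / grid$voxel_um) + 1))
      o2 <- o2_mM_to_mmHg(grid$fields$oxygen[cbind(vi, vj)])
      cyc <- advance_cycle(cells, dt_tick_h, dens, o2,
                           cells$state["atp", ], cycle)
      cells <- divide_cells(cyc$cells, cyc$divide, seed, tick, gamma_sigma)
    }

    if (snap_due) {
      pf <- population_fractions(labels, statuses, cell_phases(cells))
      row <- c(list(time_h = t_h, n_total = n_cells(cells),
                    n_living = sum(cells$alive)),
               as.list(pf$counts), as.list(pf$label_fractions),
               as.list(pf$status_fractions),
               list(mean_atp = if (any(cells$alive))
                      mean(cells$state["atp", cells$alive]) else NA_real_,
                    clipped_mass = sum(grid$clipped)))
      series[[length(series) + 1]] <- as.data.frame(row)
      lf <- landscape_density(land_live["LDH", ], land_live["PDH", ],
                              bins = land_bins)
      land_frames[[length(land_frames) + 1]] <- lf
      land_total <- if (is.null(land_total)) lf
                    else landscape_accumulate(land_total, lf)
      snap <- list(time_h = t_h,
                   profiles = lapply(stats::setNames(MSX_SPECIES, MSX_SPECIES),
                                     function(s) radial_profile(grid, s)))
      if (!is.null(tab)) snap$cells <- tab
      snapshots[[length(snapshots) + 1]] <- snap
      if (progress && (t_h %% 12 < dt_tick_h)) {
        message(sprintf("t=%.0f h: %d cells (%d living)", t_h,
                        n_cells(cells), sum(cells$alive)))
      }
    }
  }

  series <- do.call(rbind, series)
  structure(list(
    series = series, snapshots = snapshots,
    landscape = list(frames = land_frames, integrated = land_total),
    final = list(grid = grid, cells = cells, step0 = step0,
                 tick = n_ticks),
    manifest = list(config = config, seed = seed,
                    package_version = as.character(
                      utils::packageVersion("metaspheroid")))),
    class = "msx_sim")
}

# per-cell output table for one snapshot (taken at classification time)
cell_table <- function(cells, r12, r18, r21, labels, statuses) {
  live <- cells$alive
  lab <- rep("DEAD", n_cells(cells))
  st <- rep("DEAD", n_cells(cells))
  lab[live] <- as.character(labels)
  st[live] <- as.character(statuses)
  data.frame(
    id = cells$id, x = cells$x, y = cells$y, volume = cells$volume,
    phase = cell_phases(cells),
    LDH = cells$state["LDH", ], PDH = cells$state["PDH", ],
    ATP = cells$state["atp", ], r12 = r12, r18 = r18, r21 = r21,
    phenotype = lab, lactate_status = st, gamma = cells$gamma)
}

#' @export
print.msx_sim <- function(x, ...) {
  s <- x$series
  cat("metaspheroid simulation:", nrow(s), "snapshots to t =",
      max(s$time_h), "h\n")
  cat("final population:", s$n_total[nrow(s)], "agents (",
      s$n_living[nrow(s)], "living )\n")
  invisible(x)
}
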