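#' @title Cell agents: cycle, death, mechanics
#' @description Agent state and behavior: asynchronous cell cycle with
#'   checkpoints (ATP, density, oxygen-stretched G1), quiescence, volume
#'   doubling and division with gamma reassignment, two-stage necrosis with
#'   lysis release, and overdamped adhesion/repulsion mechanics.
#' @name cells-module
NULL

MSX_PHASES <- c("G1", "S", "G2", "M", "G0",
                "NECROTIC_SWELLING", "NECROTIC_SHRINKING", "DEBRIS")

#' Default cell-cycle parameters
#'
#' G1 has a 5 h baseline; S, G2 and M are 8, 4 and 1 h so the total cycle
#' sits in the 18-24 h band typical of glioblastoma lines. The density
#' threshold is the occupancy above which checkpoint 1 sends the cell to
#' G0; G1 is stretched in low oxygen between the hypoxia floor and the
#' reference tension.
#'
#' @param g1_h,s_h,g2_h,m_h Phase durations (h).
#' @param density_threshold Occupancy threshold for quiescence.
#' @param atp_checkpoint_mM ATP needed to pass checkpoint 1 (mM).
#' @param hypoxia_floor_mmHg,o2_reference_mmHg G1-stretching range (mmHg).
#' @return List of cycle parameters.
#' @export
cycle_params <- function(g1_h = 5, s_h = 8, g2_h = 4, m_h = 1,
                         density_threshold = 1.0, atp_checkpoint_mM = 0.8,
                         hypoxia_floor_mmHg = 15, o2_reference_mmHg = 38) {
  stopifnot(g1_h > 0, s_h > 0, g2_h > 0, m_h > 0,
            density_threshold > 0, density_threshold <= 1.5)
  list(g1_h = g1_h, s_h = s_h, g2_h = g2_h, m_h = m_h,
       density_threshold = density_threshold,
       atp_checkpoint_mM = atp_checkpoint_mM,
       hypoxia_floor_mmHg = hypoxia_floor_mmHg,
       o2_reference_mmHg = o2_reference_mmHg)
}

#' Default necrosis parameters
#'
#' Necrosis triggers when ATP stays below 0.3 mM for at least 3 h; the
#' per-evaluation probability then grows with the depth of depletion,
#' `p = clamp(1 - atp/0.3, 0, 1) * p_max`. Necrosis swells the cell to
#' `swell_factor` times its basal volume over `swell_h`, lyses (releasing
#' glucose, lactate and protons), shrinks to debris over `shrink_h`, and
#' debris is cleared after `debris_clear_h`.
#'
#' @param atp_threshold_mM,persistence_h,p_max Death-trigger parameters.
#' @param swell_factor,swell_h,shrink_h,debris_clear_h Necrosis staging.
#' @return List of death parameters.
#' @export
death_params <- function(atp_threshold_mM = 0.3, persistence_h = 3,
                         p_max = 0.3, swell_factor = 1.5, swell_h = 6,
                         shrink_h = 24, debris_clear_h = 100) {
  list(atp_threshold_mM = atp_threshold_mM, persistence_h = persistence_h,
       p_max = p_max, swell_factor = swell_factor, swell_h = swell_h,
       shrink_h = shrink_h, debris_clear_h = debris_clear_h)
}

#' Default mechanics parameters
#'
#' Overdamped polynomial adhesion/repulsion: repulsion acts within the sum
#' of radii, adhesion within `adh_scale` times that; per-step displacement
#' is capped for stability. Mechanics provides plausible packing, not a
#' calibration target.
#'
#' @param c_rep,c_adh Force coefficients (um/min).
#' @param adh_scale Adhesion range relative to the repulsion range.
#' @param max_disp_um Displacement cap per mechanics step (um).
#' @param neigh_radius_um Neighbourhood radius used for local density (um).
#' @return List of mechanics parameters.
#' @export
mechanics_params <- function(c_rep = 30, c_adh = 1.5, adh_scale = 1.25,
                             max_disp_um = 2, neigh_radius_um = 26) {
  list(c_rep = c_rep, c_adh = c_adh, adh_scale = adh_scale,
       max_disp_um = max_disp_um, neigh_radius_um = neigh_radius_um)
}

cell_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Create the initial cell population
#'
#' Packs `n` cells on a jittered hexagonal lattice inside a disc, assigns
#' each cell a cycle phase with probability proportional to phase duration
#' (asynchronous population) and a uniform clock within the phase, and
#' starts every cell at the basal metabolic state. Deterministic per seed.
#'
#' @param n Number of cells (>= 1).
#' @param disc_radius_um Packing disc radius (um).
#' @param seed Integer seed.
#' @param cycle Cycle parameters ([cycle_params()]).
#' @param volume_um3 Basal cell volume (um^3).
#' @param gamma Initial gene-regulation modulation for every cell.
#' @param center_um Disc center; default `c(0, 0)` (relative coordinates).
#' @return An object of class `msx_cells`.
#' @export
create_initial_population <- function(n, disc_radius_um, seed = 1,
                                      cycle = cycle_params(),
                                      volume_um3 = 2494, gamma = 1,
                                      center_um = c(0, 0)) {
  stopifnot(n >= 1, disc_radius_um > 0)
  r0 <- cell_radius(volume_um3)
  spacing <- 1.95 * r0
  # hex lattice covering the disc
  k <- ceiling(disc_radius_um / spacing) + 1
  pts <- list()
  for (row in -k:k) {
    y <- row * spacing * sqrt(3) / 2
    off <- if (row %% 2 == 0) 0 else spacing / 2
    xs <- seq(-k, k) * spacing + off
    pts[[length(pts) + 1]] <- cbind(xs, y)
  }
  pts <- do.call(rbind, pts)
  d <- sqrt(rowSums(pts^2))
  pts <- pts[d <= disc_radius_um, , drop = FALSE]
  if (nrow(pts) < n)
    stop("disc too small to pack ", n, " cells at radius ", disc_radius_um)
  # deterministic ordering: closest to center first
  pts <- pts[order(sqrt(rowSums(pts^2))), , drop = FALSE][seq_len(n), ,
                                                          drop = FALSE]
  # seeded jitter and phase assignment via the package's counter RNG
  jit <- matrix(msx_cell_runif(seed, 0, 1, 2 * n), ncol = 2)
  pts <- pts + (jit - 0.5) * 0.3 * spacing
  dur <- c(cycle$g1_h, cycle$s_h, cycle$g2_h, cycle$m_h)
  u_phase <- msx_cell_runif(seed, 0, 2, n)
  u_clock <- msx_cell_runif(seed, 0, 3, n)
  cum <- cumsum(dur) / sum(dur)
  phase <- findInterval(u_phase, cum) + 1L  # 1..4
  clock <- u_clock * dur[phase]
  st <- basal_state_table()
  cells <- structure(list(
    id = seq_len(n),
    x = as.numeric(pts[, 1] + center_um[1]),
    y = as.numeric(pts[, 2] + center_um[2]),
    volume = rep(volume_um3, n),
    basal_volume = volume_um3,
    phase = phase,
    phase_clock = clock,
    atp_clock = rep(0, n),
    necro_v0 = rep(NA_real_, n),
    gamma = rep(gamma, n),
    alive = rep(TRUE, n),
    state = matrix(rep(as.numeric(st), n), nrow = 53,
                   dimnames = list(names(st), NULL)),
    next_id = n + 1L
  ), class = "msx_cells")
  cells
}

n_cells <- function(cells) length(cells$id)

#' Phase names of a population
#' @param cells An `msx_cells` object.
#' @return Character vector of phase names.
#' @export
cell_phases <- function(cells) MSX_PHASES[cells$phase]

#' Local density (occupancy) around each cell
#'
#' Fraction of a reference neighbourhood disc covered by the
#' cross-sections of neighbouring cells (centres within the neighbourhood
#' radius; the cell itself excluded). Can transiently exceed 1 under
#' overlap.
#'
#' @param cells An `msx_cells` object.
#' @param neigh_radius_um Neighbourhood radius (um).
#' @return Numeric occupancy per cell.
#' @export
local_density <- function(cells, neigh_radius_um = 26) {
  msx_local_density(cells$x, cells$y, cell_radius(cells$volume),
                    neigh_radius_um)
}

#' Advance the cell cycle
#'
#' Applies the cycle checkpoints per cell over `dt_h` hours:
#' checkpoint 1 in G1 (sufficient ATP and sub-threshold density, else G0);
#' checkpoint 2 releases G0 cells when both conditions clear; checkpoint 3
#' stretches the G1 target duration by `o2_reference / o2` between the
#' hypoxia floor and the reference tension; checkpoint 4 doubles the
#' volume linearly across S. M completion raises a division signal.
#'
#' @param cells An `msx_cells` object.
#' @param dt_h Time step (h).
#' @param density Occupancy per cell (see [local_density()]).
#' @param o2_mmHg Local oxygen per cell (mmHg).
#' @param atp_mM ATP per cell (mM); default read from the metabolic state.
#' @param cycle Cycle parameters.
#' @return List with updated `cells` and logical `divide` signals.
#' @export
advance_cycle <- function(cells, dt_h, density, o2_mmHg,
                          atp_mM = cells$state["atp", ], cycle = cycle_params()) {
  ph <- cells$phase
  ok_atp <- atp_mM >= cycle$atp_checkpoint_mM
  ok_den <- density <= cycle$density_threshold
  # checkpoint 1: G1 cells failing either condition enter G0
  to_g0 <- cells$alive & ph == 1L & !(ok_atp & ok_den)
  cells$phase[to_g0] <- 5L
  cells$phase_clock[to_g0] <- 0
  # checkpoint 2: G0 cells re-enter G1 when both conditions clear
  to_g1 <- cells$alive & ph == 5L & ok_atp & ok_den
  cells$phase[to_g1] <- 1L
  cells$phase_clock[to_g1] <- 0

  ph <- cells$phase
  adv <- cells$alive & ph %in% 1:4 & !to_g1
  cells$phase_clock[adv] <- cells$phase_clock[adv] + dt_h

  # checkpoint 3: oxygen-stretched G1 target duration
  o2c <- pmin(pmax(o2_mmHg, cycle$hypoxia_floor_mmHg),
              cycle$o2_reference_mmHg)
  g1_target <- cycle$g1_h * cycle$o2_reference_mmHg / o2c
  g1_done <- cells$alive & cells$phase == 1L & cells$phase_clock >= g1_target
  cells$phase[g1_done] <- 2L
  cells$phase_clock[g1_done] <- 0

  # checkpoint 4: linear volume doubling across S
  in_s <- cells$alive & cells$phase == 2L
  cells$volume[in_s] <- cells$basal_volume *
    pmin(2, 1 + cells$phase_clock[in_s] / cycle$s_h)
  s_done <- in_s & cells$phase_clock >= cycle$s_h
  cells$phase[s_done] <- 3L
  cells$phase_clock[s_done] <- 0

  g2_done <- cells$alive & cells$phase == 3L & cells$phase_clock >= cycle$g2_h
  cells$phase[g2_done] <- 4L
  cells$phase_clock[g2_done] <- 0

  divide <- cells$alive & cells$phase == 4L & cells$phase_clock >= cycle$m_h
  list(cells = cells, divide = divide)
}

#' Divide flagged cells
#'
#' Each dividing parent is replaced by two daughters of exactly half the
#' parent volume, metabolic state copied element-wise, positions offset by
#' one cell radius in a random direction, and gamma independently redrawn
#' for each daughter as `gamma * exp(rnorm(0, sigma))` (multiplicative
#' log-normal epimutation). Daughters receive fresh RNG streams through
#' their new ids.
#'
#' @param cells An `msx_cells` object.
#' @param divide Logical vector of division signals.
#' @param seed Global seed (stream coordinate).
#' @param tick Integer tick counter (stream coordinate).
#' @param gamma_sigma Log-scale sd of the gamma reassignment.
#' @return Updated `msx_cells` with daughters appended.
#' @export
divide_cells <- function(cells, divide, seed = 0, tick = 0,
                         gamma_sigma = 0.05) {
  idx <- which(divide)
  if (!length(idx)) return(cells)
  k <- length(idx)
  pid <- cells$id[idx]
  ang <- 2 * pi * vapply(pid, function(id)
    msx_cell_runif(seed, id, 4e6 + tick, 1), numeric(1))
  vol <- cells$volume[idx] / 2
  r <- cell_radius(vol)
  dx <- r * cos(ang); dy <- r * sin(ang)
  if (gamma_sigma > 0) {
    z <- t(vapply(pid, function(id)
      msx_cell_rnorm(seed, id, 5e6 + tick, 2), numeric(2)))
    g1 <- cells$gamma[idx] * exp(gamma_sigma * z[, 1])
    g2 <- cells$gamma[idx] * exp(gamma_sigma * z[, 2])
  } else {
    g1 <- g2 <- cells$gamma[idx]
  }
  nid <- cells$next_id + seq_len(k) - 1L
  # parent rows become daughter 1; daughter 2 appended with a fresh id
  newx <- cells$x[idx] + dx; newy <- cells$y[idx] + dy
  cells$volume[idx] <- vol
  cells$phase[idx] <- 1L
  cells$phase_clock[idx] <- 0
  cells$x[idx] <- cells$x[idx] - dx
  cells$y[idx] <- cells$y[idx] - dy
  cells$gamma[idx] <- g1
  cells$id <- c(cells$id, nid)
  cells$x <- c(cells$x, newx)
  cells$y <- c(cells$y, newy)
  cells$volume <- c(cells$volume, vol)
  cells$phase <- c(cells$phase, rep(1L, k))
  cells$phase_clock <- c(cells$phase_clock, rep(0, k))
  cells$atp_clock <- c(cells$atp_clock, rep(0, k))
  cells$necro_v0 <- c(cells$necro_v0, rep(NA_real_, k))
  cells$gamma <- c(cells$gamma, g2)
  cells$alive <- c(cells$alive, rep(TRUE, k))
  cells$state <- cbind(cells$state, cells$state[, idx, drop = FALSE])
  cells$next_id <- cells$next_id + k
  cells
}

#' Update the necrosis trigger
#'
#' Accumulates the ATP-deficit clock while ATP is below the threshold
#' (reset on recovery); once the deficit has persisted 3 h, applies the
#' depth-dependent death probability per evaluation. Dying cells enter
#' necrotic swelling and stop metabolizing.
#'
#' @param cells An `msx_cells` object.
#' @param dt_h Evaluation interval (h).
#' @param atp_mM ATP per cell (mM).
#' @param seed,tick RNG stream coordinates.
#' @param death Death parameters ([death_params()]).
#' @return Updated cells.
#' @export
update_death <- function(cells, dt_h, atp_mM = cells$state["atp", ],
                         seed = 0, tick = 0, death = death_params()) {
  live <- cells$alive
  low <- live & atp_mM < death$atp_threshold_mM
  cells$atp_clock[low] <- cells$atp_clock[low] + dt_h
  cells$atp_clock[live & !low] <- 0
  eligible <- which(low & cells$atp_clock >= death$persistence_h)
  if (length(eligible) && death$p_max > 0) {
    p <- pmin(pmax(1 - atp_mM[eligible] / death$atp_threshold_mM, 0), 1) *
      death$p_max
    u <- vapply(eligible, function(i)
      msx_cell_runif(seed, cells$id[i], 6e6 + tick, 1), numeric(1))
    dies <- eligible[u < p]
    if (length(dies)) {
      cells$alive[dies] <- FALSE
      cells$phase[dies] <- 6L
      cells$phase_clock[dies] <- 0
      cells$necro_v0[dies] <- cells$volume[dies]
    }
  }
  cells
}

#' Progress necrotic cells and collect lysis releases
#'
#' Swelling grows the volume linearly to `swell_factor` times basal over
#' `swell_h`; at the swelling-to-shrinking transition the cell lyses,
#' releasing its intracellular glucose, lactate and protons (amounts =
#' concentration x cell volume; the oxygen term is zero since oxygen
#' equilibrates passively and carries no intracellular store). Shrinking
#' reduces the volume to 10% over `shrink_h`, after which the cell is
#' DEBRIS; debris older than `debris_clear_h` is flagged for removal.
#'
#' @param cells An `msx_cells` object.
#' @param dt_h Time step (h).
#' @param death Death parameters.
#' @return List with `cells`, `lysis` (data.frame id/x/y/glucose/lactate/
#'   proton/volume of cells lysing this step) and `remove` (logical).
#' @export
progress_necrosis <- function(cells, dt_h, death = death_params()) {
  sw <- which(cells$phase == 6L)
  lysis <- NULL
  if (length(sw)) {
    cells$phase_clock[sw] <- cells$phase_clock[sw] + dt_h
    target <- death$swell_factor * cells$basal_volume
    frac <- pmin(1, cells$phase_clock[sw] / death$swell_h)
    cells$volume[sw] <- cells$necro_v0[sw] +
      (target - cells$necro_v0[sw]) * frac
    done <- sw[cells$phase_clock[sw] >= death$swell_h]
    if (length(done)) {
      lysis <- data.frame(
        id = cells$id[done], x = cells$x[done], y = cells$y[done],
        glucose = cells$state["glucose_i", done],
        lactate = cells$state["lactate_i", done],
        proton = cells$state["proton_i", done],
        volume = cells$volume[done])
      cells$phase[done] <- 7L
      cells$phase_clock[done] <- 0
      cells$necro_v0[done] <- cells$volume[done]
      cells$state[, done] <- 0
    }
  }
  sh <- which(cells$phase == 7L)
  if (length(sh)) {
    cells$phase_clock[sh] <- cells$phase_clock[sh] + dt_h
    frac <- pmin(1, cells$phase_clock[sh] / death$shrink_h)
    cells$volume[sh] <- cells$necro_v0[sh] * (1 - 0.9 * frac)
    done <- sh[cells$phase_clock[sh] >= death$shrink_h]
    cells$phase[done] <- 8L
    cells$phase_clock[done] <- 0
  }
  db <- which(cells$phase == 8L)
  remove <- rep(FALSE, n_cells(cells))
  if (length(db)) {
    cells$phase_clock[db] <- cells$phase_clock[db] + dt_h
    remove[db[cells$phase_clock[db] >= death$debris_clear_h]] <- TRUE
  }
  list(cells = cells, lysis = lysis, remove = remove)
}

drop_cells <- function(cells, drop) {
  if (!any(drop)) return(cells)
  keep <- !drop
  for (f in c("id", "x", "y", "volume", "phase", "phase_clock", "atp_clock",
              "necro_v0", "gamma", "alive")) {
    cells[[f]] <- cells[[f]][keep]
  }
  cells$state <- cells$state[, keep, drop = FALSE]
  cells
}

#' One mechanics step
#'
#' Overdamped position update from pairwise adhesion-repulsion forces
#' (polynomial potentials), with repelling domain walls when an extent is
#' given.
#'
#' @param cells An `msx_cells` object.
#' @param dt_s Mechanics time step in seconds (default 6).
#' @param mech Mechanics parameters.
#' @param extent_um Domain extent; positions are confined to
#'   `[0, extent_um]` in both axes.
#' @return Updated cells.
#' @export
mechanics_step <- function(cells, dt_s = 6, mech = mechanics_params(),
                           extent_um = 1e6) {
  res <- msx_mechanics_step(cells$x, cells$y, cell_radius(cells$volume),
                            dt_s / 60, mech$c_rep, mech$c_adh,
                            mech$adh_scale, mech$max_disp_um, extent_um)
  cells$x <- res$x
  cells$y <- res$y
  cells
}

#' Pairwise mechanics force (diagnostic)
#'
#' Signed force magnitude between two cells along their separation axis
#' (positive = repulsive, negative = attractive).
#'
#' @param d Center distance (um).
#' @param ri,rj Cell radii (um).
#' @param mech Mechanics parameters.
#' @return Numeric force value.
#' @export
pair_force <- function(d, ri, rj, mech = mechanics_params()) {
  msx_pair_force(d, ri, rj, mech$c_rep, mech$c_adh, mech$adh_scale)
}
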