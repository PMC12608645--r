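#' @title Shipped scenarios and the outcome-matrix protocol
#' @description Ready-made scenario configurations - reference spheroid
#'   growth, cyclic hypoxia, acid shock, glucose depletion, glycolytic
#'   challenge - plus desk-scale overrides, single-cell fixtures, and the
#'   eight-row environment outcome matrix.
#' @name scenarios-module
NULL

base_config <- function() {
  list(
    grid = list(extent_um = 3000, voxel_um = 20),
    species = list(
      oxygen = list(initial_mmHg = 38, boundary = "dirichlet",
                    boundary_mmHg = 38),
      glucose = list(initial_mM = 6, boundary = "dirichlet",
                     boundary_mM = 6),
      lactate = list(initial_mM = 0.1, boundary = "dirichlet",
                     boundary_mM = 0.1),
      proton = list(initial_pH = 7.4, boundary = "dirichlet",
                    boundary_pH = 7.4)),
    cells = list(n_initial = 440, disc_radius_um = 200,
                 cycle = list(), death = list(), mechanics = list(),
                 noise_amp = 0.01, gamma_sigma = 0.05),
    schedule = list(t_end_h = 443, snapshot_h = 1),
    perturbations = list(),
    outputs = list(cell_tables = "last", landscape_bins = 60))
}

apply_scaled <- function(cfg, scaled) {
  if (!scaled) return(cfg)
  # desk-scale overrides touch only geometry, population size and t_end
  cfg$grid$extent_um <- 800
  cfg$cells$n_initial <- 200
  cfg$cells$disc_radius_um <- 140
  cfg$schedule$t_end_h <- min(cfg$schedule$t_end_h, 120)
  cfg
}

#' Reference spheroid-growth scenario
#'
#' Initial and boundary conditions of a spheroid culture with continuously
#' renewed medium: oxygen 38 mmHg, glucose 6 mM, lactate 0.1 mM, pH 7.4,
#' all Dirichlet; 440 initial cells, 443 h. The desk-scale override uses
#' an 800 um domain, 200 cells and 120 h.
#'
#' @param scaled Apply the desk-scale overrides.
#' @return Scenario configuration list (class `msx_config`).
#' @export
build_reference <- function(scaled = FALSE) {
  cfg <- apply_scaled(base_config(), scaled)
  cfg$name <- if (scaled) "reference_scaled" else "reference"
  structure(cfg, class = c("msx_config", "list"))
}

#' Cyclic-hypoxia scenario
#'
#' Reference configuration with the boundary oxygen alternating between
#' 70 mmHg and 15 mmHg as a square wave; each phase lasts half the cycle
#' period. 300 h total.
#'
#' @param period_h Cycle period in hours; 18, 36 and 72 are the standard
#'   protocols (other values are allowed with a warning).
#' @param scaled Apply the desk-scale overrides.
#' @return Scenario configuration.
#' @export
build_cyclic_hypoxia <- function(period_h = 18, scaled = FALSE) {
  if (!period_h %in% c(18, 36, 72))
    warning("non-standard hypoxia cycle period: ", period_h, " h")
  cfg <- base_config()
  cfg$schedule$t_end_h <- 300
  cfg$perturbations <- list(list(
    kind = "square_wave", species = "oxygen", high = 70, low = 15,
    period_h = period_h, from_h = 0, units = "mmHg"))
  cfg <- apply_scaled(cfg, scaled)
  cfg$name <- paste0("hypoxia", period_h, if (scaled) "_scaled" else "")
  structure(cfg, class = c("msx_config", "list"))
}

#' Acid-shock scenario
#'
#' The entire environment (not only the boundaries) is held at pH 7.4 for
#' the first 50 h, then clamped at the target pH. Landscape snapshots are
#' taken at 50 h and 130 h.
#'
#' @param ph_target Target pH, one of 7.4, 6.7, 6.0, 5.3 (values above
#'   7.4 are rejected).
#' @param scaled Apply the desk-scale overrides.
#' @param shift_h Time of the pH shift (h).
#' @param t_end_h End time (h).
#' @return Scenario configuration.
#' @export
build_acid_shock <- function(ph_target = 6.0, scaled = FALSE,
                             shift_h = 50, t_end_h = 130) {
  if (ph_target > 7.4) stop("acid-shock target must be <= 7.4")
  cfg <- base_config()
  cfg$schedule$t_end_h <- t_end_h
  cfg$perturbations <- list(
    list(kind = "field_clamp", species = "proton", value = 7.4,
         from_h = 0, until_h = shift_h, units = "pH"),
    list(kind = "field_clamp", species = "proton", value = ph_target,
         from_h = shift_h, units = "pH"))
  cfg <- apply_scaled(cfg, scaled)
  cfg$schedule$t_end_h <- t_end_h
  cfg$name <- sprintf("acid_shock_pH%.1f%s", ph_target,
                      if (scaled) "_scaled" else "")
  cfg$report_times_h <- c(shift_h, t_end_h)
  structure(cfg, class = c("msx_config", "list"))
}

#' Glucose-depletion scenario
#'
#' Glucose is held uniformly at 6 mM until 60 h, then abruptly reduced to
#' 0.01 mM throughout the environment and held constant; 300 h total.
#'
#' @param scaled Apply the desk-scale overrides.
#' @return Scenario configuration.
#' @export
build_glucose_depletion <- function(scaled = FALSE) {
  cfg <- base_config()
  cfg$schedule$t_end_h <- 300
  cfg$perturbations <- list(
    list(kind = "field_clamp", species = "glucose", value = 6.0,
         from_h = 0, until_h = 60, units = "mM"),
    list(kind = "field_clamp", species = "glucose", value = 0.01,
         from_h = 60, units = "mM"))
  cfg <- apply_scaled(cfg, scaled)
  if (scaled) cfg$schedule$t_end_h <- 300
  cfg$name <- paste0("glucose_depletion", if (scaled) "_scaled" else "")
  structure(cfg, class = c("msx_config", "list"))
}

#' Glycolytic-challenge scenario
#'
#' Oxygen fixed at atmospheric pressure (160 mmHg, strong excess), glucose
#' limited to 1 mM, no initial lactate, acidic initial pH (6.7), and
#' zero-flux (Neumann) boundaries for lactate and protons so both can
#' accumulate. Runs to 420 h at full scale.
#'
#' @param scaled Apply the desk-scale overrides (also shortens the run).
#' @return Scenario configuration.
#' @export
build_glycolytic_challenge <- function(scaled = FALSE) {
  cfg <- base_config()
  cfg$species$oxygen <- list(initial_mmHg = 160, boundary = "dirichlet",
                             boundary_mmHg = 160)
  cfg$species$glucose <- list(initial_mM = 1, boundary = "dirichlet",
                              boundary_mM = 1)
  cfg$species$lactate <- list(initial_mM = 0, boundary = "neumann")
  cfg$species$proton <- list(initial_pH = 6.7, boundary = "neumann")
  cfg$schedule$t_end_h <- 420
  cfg <- apply_scaled(cfg, scaled)
  if (scaled) cfg$schedule$t_end_h <- 120
  cfg$name <- paste0("glycolytic_challenge", if (scaled) "_scaled" else "")
  structure(cfg, class = c("msx_config", "list"))
}

#' Qualitative environment levels for the outcome matrix
#'
#' Maps the qualitative low/high/very-high levels to concentrations:
#' oxygen 2 / 38 mmHg, glucose 0.1 / 6 mM, lactate 0.1 / 3 / 10 mM.
#'
#' @return Nested list of levels in mM.
#' @export
table1_levels <- function() {
  list(oxygen = c("-" = o2_mmHg_to_mM(2), "+" = o2_mmHg_to_mM(38)),
       glucose = c("-" = 0.1, "+" = 6),
       lactate = c("-" = 0.1, "+" = 3, "++" = 10))
}

#' Single-cell fixture environment
#'
#' One cell at the basal state in a clamped uniform environment built from
#' the qualitative level mapping - the fixture for the outcome-matrix
#' protocol.
#'
#' @param o2_level,glc_level One of "-", "+".
#' @param lac_level One of "-", "+", "++".
#' @param pH Environment pH (default 7.4).
#' @return List with `state` (basal [init_state()]) and `env`.
#' @export
fixture_single_cell_env <- function(o2_level = "+", glc_level = "+",
                                    lac_level = "-", pH = 7.4) {
  lv <- table1_levels()
  stopifnot(o2_level %in% names(lv$oxygen),
            glc_level %in% names(lv$glucose),
            lac_level %in% names(lv$lactate))
  env <- local_environment(oxygen_mM = unname(lv$oxygen[o2_level]),
                           glucose_mM = unname(lv$glucose[glc_level]),
                           lactate_mM = unname(lv$lactate[lac_level]),
                           pH = pH)
  list(state = init_state(), env = env)
}

#' The eight-row environment outcome matrix
#'
#' @return data.frame of the eight (oxygen, glucose, lactate) level rows
#'   and their expected qualitative outcomes.
#' @export
table1_rows <- function() {
  data.frame(
    oxygen = c("+", "+", "+", "+", "+", "-", "-", "-"),
    glucose = c("+", "+", "+", "-", "-", "+", "-", "-"),
    lactate = c("++", "+", "-", "+", "-", "+", "+", "-"),
    outcome = c("import", "excretion", "low excretion", "import", "death",
                "excretion", "death", "death"),
    stringsAsFactors = FALSE)
}

#' Run the outcome-matrix protocol
#'
#' Simulates `replicates` independent cells per row for `hours` in the
#' clamped environment (gene noise on, necrosis checkpoint active) and
#' classifies each row: `death` when at least 90% of replicates die within
#' the run, otherwise `import`/`excretion` by the replicate-mean net MCT
#' flux averaged over the final hours.
#'
#' @param replicates Cells per row (default 20).
#' @param hours Simulated hours per cell (default 48; flux rows use the
#'   steady tail).
#' @param seed Integer seed.
#' @param noise_amp Gene-noise amplitude.
#' @return data.frame: the matrix rows with observed mean flux, death
#'   fraction, observed outcome and agreement flag.
#' @export
run_table1 <- function(replicates = 20, hours = 48, seed = 1,
                       noise_amp = 0.01) {
  rows <- table1_rows()
  p <- metabolic_parameters()
  out <- rows
  out$mean_r21 <- NA_real_
  out$death_fraction <- NA_real_
  out$observed <- NA_character_
  for (k in seq_len(nrow(rows))) {
    fx <- fixture_single_cell_env(rows$oxygen[k], rows$glucose[k],
                                  rows$lactate[k])
    died <- 0
    fluxes <- numeric(0)
    for (rep in seq_len(replicates)) {
      res <- msx_single_cell(unname(as.numeric(fx$state)), env_vec(fx$env),
                             p, 1, hours, 1.2, 360, noise_amp, seed,
                             k * 1000 + rep, 0.3, 3, 0.3, hours)
      if (!is.na(res$death_time_h)) {
        died <- died + 1
      } else {
        n <- length(res$r21)
        fluxes <- c(fluxes, res$r21[n])
      }
    }
    out$death_fraction[k] <- died / replicates
    out$mean_r21[k] <- if (length(fluxes)) mean(fluxes) else NA_real_
    out$observed[k] <-
      if (died / replicates >= 0.9) "death"
      else if (mean(fluxes) < 0) "import"
      else "excretion"
  }
  expected_dir <- ifelse(out$outcome == "low excretion", "excretion",
                         out$outcome)
  out$agrees <- out$observed == expected_dir
  out
}

#' Write simulation outputs as plain-text files
#'
#' Writes the time series, radial profiles, final cell table and the
#' integrated landscape histogram as CSV files under `dir`, plus a JSON
#' manifest.
#'
#' @param sim An `msx_sim` from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  prof <- do.call(rbind, lapply(sim$snapshots, function(sn) {
    do.call(rbind, lapply(names(sn$profiles), function(s) {
      p <- sn$profiles[[s]]
      data.frame(time_h = sn$time_h, radius_um = p$bin_center, species = s,
                 mean_value = p$mean)
    }))
  }))
  utils::write.csv(prof, file.path(dir, "radial_profiles.csv"),
                   row.names = FALSE)
  last <- sim$snapshots[[length(sim$snapshots)]]
  if (!is.null(last$cells))
    utils::write.csv(last$cells, file.path(dir, "cells_final.csv"),
                     row.names = FALSE)
  li <- sim$landscape$integrated
  land <- data.frame(ldh = rep(li$ldh_mid, times = length(li$pdh_mid)),
                     pdh = rep(li$pdh_mid, each = length(li$ldh_mid)),
                     count = as.vector(li$counts))
  utils::write.csv(land[land$count > 0, ],
                   file.path(dir, "landscape_integrated.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
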