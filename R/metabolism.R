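#' @title Per-cell gene-metabolism network
#' @description The 53-variable coupled gene-regulation and metabolism
#'   network integrated inside every cell: glycolysis, glycogen buffering,
#'   TCA cycle and oxidative phosphorylation, cytosolic/mitochondrial redox
#'   pools, reversible MCT lactate-proton symport, pH-modulated glycolysis,
#'   and ten regulated genes (including LDH, PDH and HIF-1a) with their
#'   protein products.
#' @name metabolism-module
NULL

#' Construct a local environment for one cell
#'
#' @param oxygen_mM Oxygen concentration (mM); alternatively `oxygen_mmHg`.
#' @param glucose_mM Extracellular glucose (mM).
#' @param lactate_mM Extracellular lactate (mM).
#' @param proton_mM Free proton concentration (mM); alternatively `pH`.
#' @param oxygen_mmHg Oxygen partial pressure (converted internally).
#' @param pH Extracellular pH (converted internally).
#' @return Numeric vector of class `msx_env` in the order
#'   oxygen, glucose, lactate, proton (all mM).
#' @export
local_environment <- function(oxygen_mM = NULL, glucose_mM = 6,
                              lactate_mM = 0.1, proton_mM = NULL,
                              oxygen_mmHg = NULL, pH = NULL) {
  if (is.null(oxygen_mM)) {
    if (is.null(oxygen_mmHg)) stop("provide oxygen_mM or oxygen_mmHg")
    oxygen_mM <- o2_mmHg_to_mM(oxygen_mmHg)
  }
  if (is.null(proton_mM)) {
    proton_mM <- proton_from_ph(if (is.null(pH)) 7.4 else pH)
  }
  env <- c(oxygen = oxygen_mM, glucose = glucose_mM, lactate = lactate_mM,
           proton = proton_mM)
  if (any(env < 0)) stop("environment concentrations must be non-negative")
  class(env) <- c("msx_env", "numeric")
  env
}

env_vec <- function(env) {
  if (inherits(env, "msx_env") || (is.numeric(env) && length(env) == 4))
    return(unname(as.numeric(env)))
  stop("environment must be an msx_env or a numeric vector of length 4")
}

state_vec <- function(state) {
  s <- unname(as.numeric(state))
  if (length(s) != 53) stop("metabolic state must have 53 variables")
  s
}

#' Evaluate all reaction and transport rates for one cell
#'
#' Computes the 30 instantaneous network rates (mM/min, cell-volume
#' referenced) without mutating the state. Named entries `r1`..`r30`;
#' `r12` is LDH (pyruvate to lactate positive), `r18` PDH (non-negative),
#' `r21` MCT lactate-proton symport (positive = export), `r1` glucose
#' uptake.
#'
#' @param state A 53-variable metabolic state (see [init_state()]).
#' @param env A local environment (see [local_environment()]).
#' @param params Parameter vector from [metabolic_parameters()].
#' @return Named numeric vector of 30 rates plus `glucose_uptake`.
#' @export
reaction_rates <- function(state, env, params = metabolic_parameters()) {
  r <- msx_reaction_rates(state_vec(state), env_vec(env), params)
  c(r, glucose_uptake = unname(r["r1"]))
}

#' MCT lactate-proton symport flux
#'
#' Reversible saturating flux on the lactate-proton product gradient:
#' zero exactly when `lactate_i * proton_i == lactate_e * proton_e`,
#' positive (export) when the intracellular product is larger.
#'
#' @param lactate_i,proton_i Intracellular lactate and free protons (mM).
#' @param lactate_e,proton_e Extracellular lactate and free protons (mM).
#' @param mct_capacity Transport capacity (mM/min), >= 0.
#' @param km Half-saturation of the concentration product (mM^2).
#' @return Signed rate in mM/min (positive = export).
#' @export
mct_flux <- function(lactate_i, proton_i, lactate_e, proton_e,
                     mct_capacity = NULL, km = NULL) {
  p <- metabolic_parameters()
  if (is.null(mct_capacity)) mct_capacity <- unname(p["vmax_mct"])
  if (is.null(km)) km <- unname(p["km_mct"])
  msx_mct_flux(lactate_i, proton_i, lactate_e, proton_e, mct_capacity, km)
}

#' pH modulation of glycolysis
#'
#' Multiplicative inhibition factor applied to the glycolytic limiting step
#' (phosphofructokinase): a sigmoid in pH, anchored at 1 for physiological
#' pH >= 7.4 and monotonically non-decreasing in pH. Intra- and
#' extracellular acidity both contribute.
#'
#' @param base_rate Unmodulated rate (mM/min).
#' @param ph_i Intracellular pH, in (3, 9).
#' @param ph_e Extracellular pH, in (3, 9).
#' @param params Parameter vector.
#' @return Modulated rate `base_rate * factor`, factor in `[0, 1]`.
#' @export
glycolysis_ph_modulation <- function(base_rate, ph_i, ph_e = 7.4,
                                     params = metabolic_parameters()) {
  if (ph_i <= 3 || ph_i >= 9 || ph_e <= 3 || ph_e >= 9)
    stop("pH outside the admissible range (3, 9)")
  base_rate * msx_ph_factor(ph_i, params) * msx_ph_factor(ph_e, params)
}

#' @rdname glycolysis_ph_modulation
#' @param ph A single pH value.
#' @return `ph_inhibition_factor`: the bare factor in `[0, 1]`.
#' @export
ph_inhibition_factor <- function(ph, params = metabolic_parameters()) {
  msx_ph_factor(ph, params)
}

#' Advance one cell's metabolism over one step
#'
#' Integrates the full 53-variable network over `dt_s` seconds (RK4 with
#' automatic halving on positivity breaches), with the pH modulation applied
#' and seeded additive Gaussian noise on the gene-expression equations.
#' Reported fluxes are the interval average (RK4-stage quadrature), exactly
#' consistent with the integrated mass balance.
#'
#' @param state 53-variable metabolic state.
#' @param env Local environment.
#' @param dt_s Step in seconds (default 1.2, twice the diffusion step).
#' @param params Parameter vector.
#' @param gamma Gene-regulation modulation factor (per cell).
#' @param noise_amp Gene-expression noise amplitude (fraction of unit
#'   expression scale; 0 disables noise).
#' @param seed,cell_id,step_index Stream coordinates of the counter-based
#'   RNG: identical arguments give identical trajectories, independent of
#'   cell iteration order.
#' @return List with `state` (advanced), `fluxes` (interval-average rates,
#'   named r1..r30 plus `glucose_uptake`), and `exchange` (net release to
#'   the environment, mM/min cell-volume referenced, named per species).
#' @export
step_metabolism <- function(state, env, dt_s = 1.2,
                            params = metabolic_parameters(),
                            gamma = attr(state, "gamma") %||% 1,
                            noise_amp = 0, seed = 0, cell_id = 0,
                            step_index = 0) {
  if (dt_s <= 0) stop("dt must be positive")
  res <- msx_step_metabolism(state_vec(state), env_vec(env), params, gamma,
                             dt_s, noise_amp, seed, cell_id, step_index)
  st <- res$state
  attr(st, "gamma") <- gamma
  class(st) <- c("msx_state", "numeric")
  fl <- res$rates
  list(state = st,
       fluxes = c(fl, glucose_uptake = unname(fl["r1"])),
       exchange = res$exchange)
}

#' Advance the gene-regulation layer
#'
#' The ten gene-expression ODEs are integrated as part of the coupled
#' network (their inputs - intracellular lactate, the HIF-1a protein, the
#' energy state - are themselves dynamic), scaled by the per-cell `gamma`
#' and perturbed by seeded Gaussian noise. This is [step_metabolism()]
#' exposed under the regulation surface; the returned state carries the
#' advanced gene expressions.
#'
#' @inheritParams step_metabolism
#' @return The advanced 53-variable state.
#' @export
gene_regulation_step <- function(state, env, gamma = 1, dt_s = 1.2,
                                 params = metabolic_parameters(),
                                 noise_amp = 0, seed = 0, cell_id = 0,
                                 step_index = 0) {
  step_metabolism(state, env, dt_s, params, gamma, noise_amp, seed, cell_id,
                  step_index)$state
}

#' Relax a cell to steady state in a fixed environment
#'
#' Convenience wrapper around the single-cell driver: integrates metabolism
#' (and optionally the 6-minute necrosis checkpoint) for `hours` in a
#' clamped uniform environment.
#'
#' @inheritParams step_metabolism
#' @param hours Simulated hours.
#' @param death If `TRUE`, apply the ATP-threshold necrosis checkpoint
#'   (0.3 mM, 3 h persistence) every 6 minutes.
#' @param p_max Maximal per-evaluation death probability.
#' @param record_every_h Recording cadence for the returned trajectory.
#' @return List with trajectory vectors (`time_h`, `atp`, `lactate_i`,
#'   `r12`, `r18`, `r21`, `LDH`, `PDH`, `HIF1A`, ...), `death_time_h`
#'   (NA if alive) and the final `state`.
#' @export
simulate_cell <- function(state, env, hours, params = metabolic_parameters(),
                          gamma = 1, noise_amp = 0, seed = 0, cell_id = 0,
                          death = FALSE, p_max = 0.2, record_every_h = 1) {
  msx_single_cell(state_vec(state), env_vec(env), params, gamma, hours,
                  1.2, 360, noise_amp, seed, cell_id,
                  0.3, 3, if (death) p_max else 0, record_every_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
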