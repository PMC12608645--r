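#' @title Extracellular environment: reaction-diffusion grid
#' @description Voxelized 2D medium carrying the four diffusible species
#'   (oxygen, glucose, lactate, protons), with per-species diffusion
#'   coefficients, boundary conditions, cell exchange accumulators and
#'   radial profiling.
#' @name environment-module
NULL

MSX_SPECIES <- c("oxygen", "glucose", "lactate", "proton")

# diffusion coefficients, um^2/min
MSX_DIFFUSION <- c(oxygen = 87600, glucose = 30000, lactate = 12600,
                   proton = 270000)

#' Convert oxygen partial pressure to concentration
#'
#' Henry-law conversion of oxygen partial pressure (mmHg) to dissolved
#' concentration (mM) with the solubility coefficient 1.30e-3 mM/mmHg.
#'
#' @param p Partial pressure in mmHg (non-negative).
#' @return Concentration in mM.
#' @export
o2_mmHg_to_mM <- function(p) {
  if (any(p < 0)) stop("oxygen partial pressure must be non-negative")
  1.30e-3 * p
}

#' @rdname o2_mmHg_to_mM
#' @param c Concentration in mM (non-negative).
#' @export
o2_mM_to_mmHg <- function(c) {
  if (any(c < 0)) stop("oxygen concentration must be non-negative")
  c / 1.30e-3
}

#' Convert between pH and free-proton concentration
#'
#' Protons are stored and diffused as free-proton concentration (mM);
#' pH is computed for reporting and for the glycolytic pH modulation.
#'
#' @param c Free proton concentration in mM (positive).
#' @return pH (dimensionless).
#' @export
ph_from_proton <- function(c) {
  if (any(c <= 0)) stop("proton concentration must be positive")
  -log10(c * 1e-3)
}

#' @rdname ph_from_proton
#' @param ph pH value (finite).
#' @export
proton_from_ph <- function(ph) {
  if (any(!is.finite(ph))) stop("pH must be finite")
  10^(-ph) * 1e3
}

#' Build the reaction-diffusion grid for a scenario
#'
#' Creates the four species fields at the scenario's initial concentrations,
#' attaches boundary conditions and zeroed exchange accumulators.
#'
#' @param config A scenario configuration (see [build_reference()]) or any
#'   list with `grid$extent_um`, `grid$voxel_um` and a `species` section.
#' @return An object of class `msx_grid`.
#' @export
make_grid <- function(config) {
  g <- config$grid
  if (is.null(g$extent_um) || is.null(g$voxel_um))
    stop("config$grid must provide extent_um and voxel_um")
  if (g$voxel_um <= 0) stop("voxel size must be positive")
  if (g$extent_um %% g$voxel_um != 0)
    stop("extent must be divisible by voxel size")
  n <- as.integer(g$extent_um / g$voxel_um)
  sp <- config$species
  extra <- setdiff(names(sp), MSX_SPECIES)
  if (length(extra)) stop("unknown species: ", paste(extra, collapse = ", "))
  fields <- list()
  bc_kind <- bc_value <- init <- stats::setNames(numeric(4), MSX_SPECIES)
  kinds <- stats::setNames(character(4), MSX_SPECIES)
  for (s in MSX_SPECIES) {
    cs <- sp[[s]]
    if (is.null(cs)) stop("missing species config: ", s)
    iv <- species_value_mM(s, cs, "initial")
    if (iv < 0) stop("initial concentration must be non-negative: ", s)
    fields[[s]] <- matrix(iv, n, n)
    kinds[s] <- match.arg(cs$boundary, c("dirichlet", "neumann"))
    bc_value[s] <- if (kinds[s] == "dirichlet")
      species_value_mM(s, cs, "boundary") else 0
    init[s] <- iv
  }
  structure(list(
    nx = n, ny = n, voxel_um = g$voxel_um, extent_um = g$extent_um,
    fields = fields, D = MSX_DIFFUSION, bc_kind = kinds, bc_value = bc_value,
    exchange = lapply(stats::setNames(MSX_SPECIES, MSX_SPECIES),
                      function(s) matrix(0, n, n)),
    clipped = stats::setNames(numeric(4), MSX_SPECIES)
  ), class = "msx_grid")
}

# read "initial"/"boundary" value of a species config in mM, accepting the
# natural units (mmHg for oxygen, pH for protons, mM otherwise)
species_value_mM <- function(species, cs, what) {
  keys <- paste0(what, c("_mM", "_mmHg", "_pH"))
  for (k in keys) {
    if (!is.null(cs[[k]])) {
      if (endsWith(k, "mmHg")) {
        if (species != "oxygen") stop("mmHg only valid for oxygen")
        return(o2_mmHg_to_mM(cs[[k]]))
      }
      if (endsWith(k, "pH")) {
        if (species != "proton") stop("pH only valid for protons")
        return(proton_from_ph(cs[[k]]))
      }
      return(cs[[k]])
    }
  }
  stop("species ", species, " lacks an ", what, " value")
}

bc_code <- function(kind) ifelse(kind == "dirichlet", 0L, 1L)

#' Advance the grid one diffusion step
#'
#' One operator-split (alternating-direction implicit) diffusion step for
#' every species, consuming the exchange accumulator as a volumetric
#' source/sink. Dirichlet boundaries are re-imposed exactly; negative
#' concentrations produced by sinks are floored at zero and the clipped
#' mass is logged in `grid$clipped`.
#'
#' @param grid An `msx_grid`.
#' @param dt_s Time step in seconds (default 0.6).
#' @return The advanced grid; the exchange accumulator is zeroed.
#' @export
step_diffusion <- function(grid, dt_s = 0.6) {
  stopifnot(inherits(grid, "msx_grid"), dt_s > 0)
  for (s in MSX_SPECIES) {
    res <- msx_adi_step(grid$fields[[s]], grid$D[[s]], dt_s / 60,
                        grid$voxel_um, bc_code(grid$bc_kind[[s]]),
                        grid$bc_value[[s]], grid$exchange[[s]])
    grid$fields[[s]] <- res$field
    grid$clipped[[s]] <- grid$clipped[[s]] + res$clipped
    grid$exchange[[s]][] <- 0
  }
  grid
}

#' Deposit cell exchange rates into a voxel
#'
#' Adds per-species net source/sink rates (mM/min, voxel-volume referenced)
#' to the exchange accumulator. Deposits from multiple cells in the same
#' voxel are additive; the accumulator is consumed (and zeroed) by the next
#' [step_diffusion()].
#'
#' @param grid An `msx_grid`.
#' @param voxel_index Integer pair (i, j), 1-based.
#' @param rates Named numeric vector (any subset of
#'   oxygen/glucose/lactate/proton), mM/min.
#' @return The updated grid.
#' @export
deposit_exchange <- function(grid, voxel_index, rates) {
  stopifnot(inherits(grid, "msx_grid"))
  i <- voxel_index[1]; j <- voxel_index[2]
  if (i < 1 || i > grid$nx || j < 1 || j > grid$ny)
    stop("voxel index outside the domain")
  for (s in names(rates)) {
    if (!s %in% MSX_SPECIES) stop("unknown species: ", s)
    grid$exchange[[s]][i, j] <- grid$exchange[[s]][i, j] + rates[[s]]
  }
  grid
}

#' Radial concentration profile
#'
#' Bins voxels by the distance of their centers from a reference point and
#' averages the species concentration per bin (the spheroid-profile view of
#' the fields). Empty bins are reported with `NA` means and flagged.
#'
#' @param grid An `msx_grid` (or a bare matrix plus `voxel_um`).
#' @param species One of oxygen/glucose/lactate/proton (ignored for a bare
#'   matrix).
#' @param center Point (x, y) in micrometers; default domain center.
#' @param bin_width Bin width in micrometers.
#' @param voxel_um Voxel size when `grid` is a bare matrix.
#' @return A data.frame with `bin_center`, `mean`, `n_voxels`, `empty`.
#' @export
radial_profile <- function(grid, species = "oxygen", center = NULL,
                           bin_width = 20, voxel_um = NULL) {
  if (inherits(grid, "msx_grid")) {
    f <- grid$fields[[species]]
    h <- grid$voxel_um
  } else {
    f <- grid
    h <- voxel_um
    if (is.null(h)) stop("voxel_um required for a bare matrix")
  }
  if (bin_width <= 0) stop("bin width must be positive")
  nx <- nrow(f); ny <- ncol(f)
  if (is.null(center)) center <- c(nx * h / 2, ny * h / 2)
  if (center[1] < 0 || center[1] > nx * h || center[2] < 0 ||
      center[2] > ny * h)
    stop("center outside the domain")
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  d <- sqrt(outer((xc - center[1])^2, (yc - center[2])^2, "+"))
  bin <- floor(d / bin_width)
  nb <- max(bin) + 1
  sums <- tapply(as.vector(f), as.vector(bin), sum)
  cnts <- tapply(as.vector(f), as.vector(bin), length)
  idx <- as.integer(names(sums))
  out <- data.frame(bin_center = (seq_len(nb) - 0.5) * bin_width,
                    mean = NA_real_, n_voxels = 0L)
  out$mean[idx + 1] <- sums / cnts
  out$n_voxels[idx + 1] <- as.integer(cnts)
  out$empty <- out$n_voxels == 0L
  out
}
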