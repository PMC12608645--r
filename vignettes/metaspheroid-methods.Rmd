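---
title: "Modeling tumor spheroid metabolism with metaspheroid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor spheroid metabolism with metaspheroid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaspheroid)
```

## The model

`metaspheroid` simulates a two-dimensional multicellular tumor spheroid in
which metabolic phenotypes are emergent, not prescribed. Three coupled
levels are integrated with different time steps:

* **Environment** — four diffusible species (oxygen, glucose, lactate,
  free protons) on a voxel lattice, advanced by a reaction–diffusion
  solver every 0.6 s. Diffusion coefficients are fixed per species
  (87,600 / 30,000 / 12,600 / 270,000 µm²/min). Boundaries are either
  Dirichlet (continuously renewed medium) or zero-flux.
* **Cells** — discrete agents with a cycle (G1–S–G2–M plus quiescent G0),
  two-stage necrosis, division with heritable perturbation of a
  regulation parameter γ, and overdamped adhesion–repulsion mechanics
  (every 6 s).
* **Intracellular metabolism** — every cell integrates a 53-variable
  gene–metabolism network every 1.2 s: full glycolysis with a glycogen
  buffer, lumped TCA cycle and oxidative phosphorylation with explicit
  cytosolic/mitochondrial NAD pools and an adenine pool, reversible
  lactate–proton symport (MCT), and ten regulated genes — HIF-1α, LDH,
  PDH, PDK, GLUT, MCT, HK, PFK, MYC, AMPK — with their protein products
  scaling the corresponding capacities.

Phenotypes are evaluated every 6 min (600 diffusion steps) from
interval-averaged fluxes: a cell is fermentative when its LDH flux `r12`
exceeds its PDH flux `r18` (pronounced when more than tenfold), and
expresses the Warburg effect when its net MCT flux `r21` is outward
(reverse Warburg when inward). The metabolic landscape is the density of
cells in (LDH, PDH) expression space; its local maxima are the oxidative,
glycolytic and intermediate attractors.

## The metabolic network

The network couples mass-action/Michaelis–Menten metabolite kinetics to a
gene layer that relaxes toward environment-dependent drives. The
mechanistically load-bearing elements are:

* **Redox partitioning decides the fate of pyruvate.** LDH is modeled as
  a reversible near-equilibrium enzyme; the cytosolic NADH/NAD⁺ ratio —
  set by the glycolytic flux against the (oxygen-dependent) shuttle —
  determines whether pyruvate is reduced to lactate or lactate is
  oxidized back to pyruvate. Under anoxia the shuttle stalls, NADH
  accumulates and fermentation is the only way to regenerate NAD⁺; with
  oxygen and scarce glucose, an oxidized cytosol drives lactate
  consumption that feeds respiration.
* **MCT transport follows the lactate·proton product.** The symport rate
  is a saturating odd function of the difference of the intra- and
  extracellular lactate·H⁺ products, so transport direction responds to
  both the lactate gradient and acidity, and is exactly zero at symport
  equilibrium.
* **pH inhibits glycolysis.** A sigmoid factor (midpoint pH 6.6,
  steepness 3 per pH unit, anchored at 1 for pH ≥ 7.4) multiplies the
  PFK rate, with intra- and extracellular pH both contributing. Acidic
  environments therefore throttle fermentation and favor the oxidative,
  lactate-consuming state.
* **Lactate sensing through HIF-1α.** Intracellular lactate raises the
  HIF-1α drive (half-activation 10 mM); HIF-1α induces LDH, PDK, GLUT
  and MCT and represses the PDH gene. Together with hypoxic
  stabilization this closes the positive loop that creates the
  glycolytic attractor, while PFK control by ATP, AMP and citrate closes
  the loops that keep the oxidative state stable. Pyruvate inhibition of
  PDK (feed-forward PDH activation) lets abundant imported lactate tip
  the carbon balance toward net import.
* **Energy.** ATP is produced by glycolysis and by ADP-limited oxidative
  phosphorylation (P/O 2.5 and 1.5 for the NADH and FADH₂ branches) and
  consumed by a saturating maintenance demand. The basal state holds
  ≈1.9 mM ATP; the necrosis threshold of 0.3 mM is then roughly 15% of
  basal.

The full parameter table ships as an editable CSV
(`system.file("extdata", "metabolic_parameters.csv", package =
"metaspheroid")`); the basal steady state (the initial condition of every
cell) ships alongside it. Rate constants were chosen for physiological
flux magnitudes (glycolysis ~0.1–0.2 mM/min and oxygen consumption
~0.6 mM/min per cell volume at the well-fed state, a severalfold
fermentative surge under hypoxia) and for numerical stability of the
explicit integrator at the 1.2 s metabolism step; equilibrium constants
follow the standard directionality of each reaction. Protons are carried
as free concentration with a lumped buffering ratio (2×10⁴ total-to-free,
both compartments), the minimal closure that keeps realistic lactic-acid
fluxes from producing absurd pH excursions while carbonate chemistry
stays out of scope.

## Numerical choices

* **Diffusion** uses a Peaceman–Rachford alternating-direction implicit
  scheme (tridiagonal solves per axis, second order in time,
  unconditionally stable). This matters because the printed 0.6 s step
  is far beyond the explicit stability bound for protons at 20 µm voxels
  (≈0.02 s). Dirichlet boundaries are re-imposed exactly after every
  half sweep; zero-flux boundaries use reflecting ends and conserve mass
  to machine precision. Sinks that would drive a voxel negative are
  floored at zero and the clipped mass is logged.
* **Metabolism** uses RK4 at the 1.2 s step with automatic step halving
  (up to 2⁸) on positivity breaches or suspiciously large single-step
  jumps. Interval-average fluxes are accumulated with the RK4 quadrature
  weights, so reported fluxes are exactly consistent with the mass
  balance the integrator realized — endpoint sampling would alias the
  fastest redox modes.
* **Stochasticity** enters as additive Gaussian noise on the gene ODEs
  (default amplitude 1% of the unit expression scale), generated by a
  counter-based RNG keyed by (seed, cell id, step); trajectories are
  reproducible and independent of cell iteration order. Division draws
  fresh streams for daughters through their new ids.
* **Coupling.** Cells read the concentrations of the voxel containing
  their center; exchange is accumulated per voxel (cell-to-voxel volume
  scaled) and consumed by the following diffusion steps. Uptake is
  Michaelis–Menten limited, so voxel overdraw is negligible by
  construction; any residual negativity is clipped and logged.

## Cell decisions

Cycle: G1 5 h, S 8 h, G2 4 h, M 1 h (18 h total, in the 18–24 h band of
glioblastoma lines). Checkpoint 1 (in G1) requires ATP ≥ 0.8 mM and
local occupancy below the threshold; failing either sends the cell to G0,
which it leaves when both clear. The occupancy threshold (default 1.0,
in units of the neighbourhood cross-section fraction) was set so that
crowding arrest engages only after the first couple of division rounds
compress the spheroid interior — producing a quiescent ring on the
reference timeline — and reflects the elevated density tolerance of
tumor cells. G1 stretches by `o2_ref / o2` between 15 and 38 mmHg.
Volume doubles linearly across S; division yields equal-volume daughters
with copied state and γ redrawn multiplicatively (log-normal, σ = 0.05).

Necrosis: ATP < 0.3 mM persisting 3 h arms the trigger; the
per-evaluation probability is `clamp(1 − ATP/0.3, 0, 1) × p_max`
(default p_max 0.3 per 6-min evaluation; the exact law beyond
"probability increases with depth of depletion" is a modeling choice).
Swelling to 1.5× basal volume over 6 h, lysis releasing intracellular
glucose, lactate and protons into the voxel (no oxygen term — oxygen
equilibrates passively and has no intracellular store), shrinkage over
24 h, debris cleared after 100 h.

## Scenarios

All five protocols are data, not code (`build_reference()`,
`build_cyclic_hypoxia(18/36/72)`, `build_acid_shock(7.4/6.7/6.0/5.3)`,
`build_glucose_depletion()`, `build_glycolytic_challenge()`), with
perturbations expressed as timed boundary changes, square waves, or
whole-field clamps. The qualitative outcome matrix maps low/high/very
high levels to 2/38 mmHg oxygen, 0.1/6 mM glucose and 0.1/3/10 mM
lactate; a "death" outcome means at least 90% of 20 replicate cells
necrotic within the protocol window.

## Scale

The full-scale reference domain is 3,000 µm (20 µm voxels, a convention
adopted from lattice-based cell frameworks; the domain size itself is a
design choice) with 440 initial cells and 443 h of growth. Development
and testing use a desk-scale profile — 800 µm, 200 cells, 120 h for the
reference; smaller domains and shorter horizons for perturbation arms —
chosen so the full suite runs on a laptop-class single core. Desk-scale
overrides change only geometry, population size and end time, never
kinetic parameters.

## What the generator does and does not emulate

The synthetic spheroid reproduces: radially structured oxygen/glucose
depletion and lactate/acid accumulation; the proliferative → quiescent →
necrotic ring ordering; coexistence of oxidative and glycolytic
attractors and their occupation shifting with oxygen, acidity and
lactate; Warburg and reverse-Warburg transport states, including their
partial decoupling from the fermentative/respiratory phenotype. It does
not attempt: 3D geometry (2D only, so "spheroid" diameters grow faster
than in 3D), vascularization, cell migration or ECM interaction,
apoptosis signaling, carbonate buffering, or glutamine/fatty-acid
metabolism. Quantitative agreement with any particular cell line is not
claimed; tests of this package establish internal consistency and the
qualitative phenomenology above, not predictions for real spheroids.

## Known limitations

* The gene-regulation layer is a phenomenological relaxation-to-drive
  model; time constants (45–120 min) set the adaptation speed and were
  not fit to data.
* The glycogen store is a small, hours-scale carbon buffer; real
  starvation responses (autophagy, protein catabolism) are absent, so
  glucose-deprivation kinetics are compressed relative to experiments.
* Proton handling uses a constant buffering ratio; pH extremes outside
  roughly 5–8 are not mechanistically meaningful.
* At strictly zero oxygen an isolated cell eventually collapses even with
  glucose: the glycolytic surge needs ATP investment at hexokinase and
  PFK, and with no residual oxidative phosphorylation it cannot bootstrap
  out of a deep ATP crash. Hypoxic behavior is therefore characterized at
  the low-oxygen study level (2 mmHg), where fermentation sustains the
  cell; the strict-anoxia limit is a known model boundary.
* With one cell exchanging with one voxel, sub-voxel concentration
  heterogeneity is unresolved; at 20 µm voxels this is within the usual
  tolerance of lattice-based multicellular models.
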