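---
title: "The scafflow model: coupled flow, transport and growth on a fibrous scaffold unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scafflow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scafflow)
```

scafflow simulates chondrocyte culture on one repeating unit of a fibrous
scaffold perfused by culture medium, and screens candidate unit geometries
by their culture efficiency. This vignette is the package's own account of
the model, its parameters, the numerical choices, and what the
implementation does and does not capture.

## The scaffold unit and its parameterization

The unit is a cube of edge `2r` (default 200 um) representing the junction
volume between two pairs of orthogonal fibers. Each pair is encoded by one
indicator-point displacement: the fiber surface passes through the two
edges of its face and bulges a depth `delta` into the unit, so the fiber
cross-section inside the cube is a circular segment with chord `2r` and
sagitta `delta`, giving the diameter

    D = (r^2 + delta^2) / delta.

`D` is minimal (`2r`, fibers of neighbouring layers touching) at
`delta = r` and grows without bound as the cap flattens; `delta = 0` is a
flat-wall sentinel (no fiber on that pair of faces). Flow is along +x; the
primary pair (from `deltaY`) occupies the bottom/top faces with fiber axes
along y, the secondary pair (from `deltaZ`) the front/back faces with axes
along z.

Two published design points deserve note. The reference design
(`D1 = D2 = 200 um`, `delta = 100` on all faces) has all four caps mutually
tangent at the unit centre: the analytic free cross-section pinches to zero
there. The geometry was originally meshed with a commercial octree
mesher, which regularizes the contact; we obtain the same effect by
labelling a voxel solid only when it lies *entirely* inside a cap, which
keeps the tangency cusps open as O(h) channels that vanish under
refinement. The voxelized solid volume converges first-order to the
analytic segment volume (verified in the tests). Secondly, the published
secondary diameters of the improved designs (182-185 um for
`deltaZ = 90 um`) are inconsistent with the sagitta relation, which gives
201 um; the package follows the relation and treats diameters below `2r`
as errors. Printed sub-micrometre diameter fractions are truncated (1435.57
prints as 1435), and the package reports them the same way.

The attachment area of a cultured fiber is the cap arc times the axial
span, `D asin(2r/D) * 2r`; the attachment angle `asin(2r/D)` (degrees) is
reported as a descriptive metric only.

## Voxel domain and phases

`voxelize()` discretizes the unit on a uniform Cartesian grid (default
32^3; a convergence test in the suite documents the first-order behaviour).
Every voxel is exactly one of: solid (inside a fiber cap), biomass (the
monolayer shell of thickness `dc = 13 um`, one cell diameter, over the
cultured surfaces), or fluid. At 32^3 the shell is 2-3 voxels thick; below
`dc ~ h` the shell degenerates to the single surface-adjacent layer, which
is why resolutions under 16 are only used for smoke tests.

Within the biomass shell the cell volume fraction `epsC` and the fluid
fraction `epsF = 1 - epsC` always sum to one. Cell counts convert to
volume fractions through the volume of one cell, taken as a sphere of
diameter `dc` (`epsC = N pi/6 dc^3`); the published work never states this
conversion, so it is exposed as a parameter. The default seeding density
5e7 cells/cm^3 gives `epsC = 0.058`.

## Flow

The medium is Newtonian (water-like) and the Reynolds number at the
default operating point (200 um, 3 mm/s) is about 0.6, so the solver
implements steady Stokes (creeping) flow; the convective term is
negligible at these scales and quasi-steady re-solves per growth step
capture the slow geometry change. The biomass is not excluded from the
flow: it is a single-field penalized medium whose viscosity rises linearly
with the cell fraction from 0.001 Pa s (no cells) to 1 Pa s (fully packed),
which throttles medium penetration as the culture densifies.

Discretization is a staggered (MAC) finite-volume scheme with:

* plug inflow on the fluid part of the inlet plane — biomass voxels
  touching the inlet are not force-fed, since their upstream continuation
  is more cell layer rather than free stream;
* a natural zero-stress, zero-gauge-pressure outlet;
* no-slip on solid voxels and domain walls (half-cell wall treatment at
  domain boundaries, first-order at interior voxelized walls);
* harmonic-mean edge viscosities in the tangential couplings. This matters:
  arithmetic averaging overestimates the interface shear at the 1000-fold
  biomass/fluid viscosity contrast and drags a packed cell layer at a
  third of the free-stream speed, where the harmonic form reproduces the
  analytic near-rigid behaviour (velocity reduction > 99% in the packed
  limit).

The saddle-point system is solved by conjugate gradients on the pressure
Schur complement, preconditioned by a multigrid V-cycle of the pressure
Poisson approximation `D diag(A)^-1 D'`; the inner momentum solves use the
package's geometric-multigrid-preconditioned CG (C++ core). Convergence is
declared at a relative divergence residual of 1e-8, so cross-plane flux is
conserved far below the 1e-6 documented bound. One 32^3 solve takes a few
seconds; per-step re-solves warm-start from the previous pressure.

Shear stress is reported as `tau = sqrt(0.5 sigma':sigma')` (equal to
`mu |du/dy|` in simple shear). Off-diagonal stress components are evaluated
at staggered edge positions with the same harmonic-mean viscosities as the
momentum operator, then averaged to cell centres. Evaluating `mu_cell`
times a central-difference gradient would overestimate the stress in
interface cells by roughly the viscosity ratio (about 30-fold at seeding
density) — the edge-based form keeps the stress continuous across the
biomass surface, which is essential because the growth law reads `tau`
exactly there.

Validation: the fully developed reductions (`solveChannelFlow`,
`solveDuctFlow`) match the plane-Poiseuille wall shear `6 mu U / H` and the
rectangular-duct series solution within 2% at 64 cells; the 3-D solver's
outflow profile matches the duct series within 2% at 20^3 and conserves
flux to 1e-6.

## Transport

Glucose lives in both phases, with the cell-phase concentration tied to
the fluid phase by a linear interfacial equilibrium `cgc = Keq cgf`
(`Keq = 0.1`) inside the shell. One implicit Euler step (a two-step BDF2
variant is available as `scheme = "bdf2"`) updates the phase-weighted
content `(epsF + Keq epsC) cgf` with:

* diffusion in both phases (`Dgf + Keq Dgc` in the shell, harmonic-mean
  face conductances, zero flux into solid);
* conservative first-order upwind advection by the staggered velocities
  (the penalized local velocity inside biomass), chosen for positivity at
  the coarse-grid cell Peclet numbers (~60) of the desk scale;
* the Michaelis-Menten sink `Rg = Vm epsC cgc / (Km + epsC cgc)`,
  Picard-linearized in the denominator and iterated to convergence. The
  cell fraction in the uptake law is identified with `epsC` (the published
  formulation interchanges the two symbols).

The old content enters the time term with the capacity it was stored at,
so the capacity change caused by growth between steps conserves glucose
mass exactly; closed domains conserve scalar mass to 1e-10 per step, and
negative concentrations (iterative-solver noise) are clipped with the run
aborting if clipped mass ever exceeds 0.1% of throughput.

Lactate is a single-phase scalar with source `Rl = 2 Rg` (evaluated at the
same time level as the glucose step, so the stoichiometric link between
the cumulative budgets is maintained by construction and verified from the
fields in the tests), diffusivity `Dlf`, zero inlet concentration and
outflow at the outlet. Local pH follows the affine relation
`pH = 7.4 - 0.0406 cl`.

## Growth and viability

The proliferation rate is

    rg = Kg(tau) * cgc / (kc rhoCell epsC + cgc)

with the piecewise shear modulation `Kg(tau)`: stimulation
`Kg0 (alpha + beta tau)` below 0.1 Pa, plateau `11.326 Kg0` on [0.1, 0.6),
inhibition `2.5 (1 - tau) 11.326 Kg0` on [0.6, 1), and zero at or above
1 Pa. With the published `alpha = 0.8761` and `beta = 104.5` 1/Pa the
factor is continuous at the branch points (to about 1e-4 at 0.1 Pa).

Two closures have no published value:

* `kc` (with units such that `kc rhoCell epsC` is a concentration): the
  default 0.01236 makes half-saturation occur at half the default inlet
  concentration for a fully packed monolayer. It is flagged non-published
  and config-exposed.
* `rd` (death rate): default 0; cells are lost only through the pH gate.
  Cell migration (`Dc`) defaults to 0 as quantitatively negligible.

Viability: voxels whose pH falls below 6.8 (inclusive boundary: alive at
exactly 6.8) are gated. The default mode removes the biomass instantly
(`epsC <- epsC * S{pH}`, the published formulation); a "freeze" mode that
retains but stops the biomass is available. Lethal shear (>= 1 Pa) stops
growth but does not by itself remove cells.

Each biomass voxel then grows exponentially with an exponential-Heun
update (predictor at the start-of-step rate, corrector at the predicted
cell fraction): exact for constant rates, second-order in the
self-limitation, and the reason a time-step halving at the default
operating point moves the final density by only ~0.2%. Two monolayer caps
bound the result: `epsC <= 1` per voxel, and per attachment column
(voxels of one shell footprint) the integrated `epsC` thickness may not
exceed `dc` — the cells-per-attachment-area bound applied per column
rather than per voxel.

## Culture efficiency, desk scales and the design search

A culture run couples the pieces once per time step (default 1 h): flow
re-solve with the viscosity of the current cell fraction, glucose step,
lactate step, pH gate, growth. Culture efficiency is

    CE = (mean final cell density - mean initial) / mean initial

averaged over the biomass shell volume (the monolayer's habitat). A
zero-duration run has CE exactly 0, and runs are bit-deterministic.

Desk scales: the package's default grid is 32^3 with 1 h steps; test and
campaign horizons are 2-120 h rather than the 30-day horizon of the source
study, and campaign candidates are evaluated on coarser grids (10-16^3).
These are the package's chosen working points — the logic is identical at
any resolution, and the suite's refinement tests document the
discretization behaviour.

The generate-and-test search draws candidate displacement pairs uniformly
from (0, 100] um (indicator points on the same face share one value),
evaluates each candidate's CE with the full simulator, and ranks them; ties
break by larger attachment area, then lower index. Failed candidates are
logged and excluded. A seeded campaign is bit-reproducible, and the
sampling never disturbs the caller's RNG stream. `ratioReport()` bins CE
against `|deltaY/deltaZ|`, flagging the favourable band [0, 1] and the
risk band above 5.5.

## What the desk-scale model does not show

* The shear magnitudes in the strongly constricted published geometries are
  qualitative. Under the sagitta relation, `deltaZ = 90 um` leaves a 20 um
  slot that carries the full plug influx, and the reference design pinches
  to cusp channels; local stresses there are far above the published means
  (which were obtained on a geometry whose secondary diameters do not
  satisfy the sagitta relation). Ordering comparisons between designs are
  meaningful; absolute stress values are not reproduced.
* Oxygen metabolism, scaffold degradation, ECM synthesis and
  fluid-structure interaction are out of scope; the scaffold is rigid and
  impermeable.
* A single unit with plug inflow stands in for the scaffold: bypass flow
  around constricted units in a real multi-unit lattice is not modelled,
  so constricted designs see artificially high local velocities.
* The biomass occupies a fixed shell whose cell fraction evolves; the
  shell geometry itself does not move.

## Numerical settings

| Setting | Default | Notes |
|---|---|---|
| grid | 32^3 | `resolution` argument, >= 8 |
| time step | 1 h | halving changes the outcome < 1% |
| scheme | implicit Euler | `"bdf2"` optional |
| flow tolerance | 1e-8 relative divergence | config `flow_tol` |
| momentum/transport solves | 1e-11 / 1e-12 relative residual | multigrid-CG / BiCGSTAB |
| Picard iterations | up to 6, tol 1e-10 | uptake linearization |
| viability mode | instant removal | `"freeze"` optional |
| clip guard | 0.1% of throughput | aborts the run beyond it |

Configurations are YAML with the customary bioreactor units (um, mm/s,
g/cm^3, cells/cm^3, h) converted to SI once at load; every artifact embeds
the MD5 hash of its canonical configuration. Fields export to legacy-ASCII
VTK structured points and CSV voxel tables; trajectories and campaign
reports to CSV/JSON (plain-text outputs only, by design).
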