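---
title: "From fiber-bundle microstructure to Darcy permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fiber-bundle microstructure to Darcy permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blood oxygenators pass blood across bundles of thousands of microporous
hollow fibers; gas flows inside the fibers and exchange happens through the
fiber walls. Whole-device CFD treats the bundle as a homogeneous porous
medium, which requires two effective parameters of the microstructure: the
porosity $\varepsilon$ (fluid volume fraction, counting fiber walls *and*
lumens as solid, since blood never enters the fibers) and the directional
Darcy permeability $K$,

$$K \;=\; \mu \,\frac{Q}{A}\,\frac{L}{\Delta P},$$

where $Q/A$ is the superficial velocity through total cross-section $A$,
$L$ the sample length along the flow, $\Delta P$ the pressure drop and
$\mu$ the dynamic viscosity. During device assembly the bundle is
press-fitted into its rigid housing — compressed by 5–15% of its height —
which compacts the microstructure and can more than halve the permeability.
`fiberperm` quantifies this chain: parametric unit-cell geometry →
press-fit deformation → porosity → periodic creeping-flow solve → $K$ and
$K/K_0$.

## The repetitive unit

Idealized bundles are periodic: mats of parallel fibers (outer diameter
$d$, wall thickness $t$, in-layer pitch $p$) stacked along $Z$ with
alternating orientation. Two layups are covered:

* **orthogonal** — layers along $X$ and $Y$ alternately; the minimal
  periodic box is $p \times p \times 2d$;
* **angled** — layers at $\pm\alpha$ from the $Y$ (axial) axis; the minimal
  *rectangular* periodic box is $p/\cos\alpha \times p/\sin\alpha \times 2d$.

Layer centre planes sit at $z = d/2$ and $3d/2$, so adjacent layers touch.
Fibers are registered with zero lateral offset between the two families
(both base lines pass through the in-plane origin). For the angled layup no
in-plane cell dimensions are forced by the physics alone; the minimal
lattice above is the smallest rectangle on which both $\pm\alpha$ families
are simultaneously periodic, and its correctness is checked through the
porosity invariant (the undeformed porosity must equal
$1 - \pi d / 4p$ regardless of configuration) and through periodicity
property tests on the solid indicator.

An internal detail that matters for boundary conditions: with this
registration the $x=0$ and $y=0$ box faces contain fiber axes and are
mirror planes of the microstructure, but the $z=0$ face lies *between*
layers and is **not** a mirror plane. Free-slip "symmetry" boundaries are
therefore only ever applied on lateral $X$/$Y$ faces; lateral $Z$ faces
stay periodic.

## Press-fit models

Press-fit of degree $f$ compresses the stack along $Z$: box height
$2d(1-f)$, layer spacing $d(1-f)$, in-plane pitch unchanged (the housing
constrains only $Z$). Two models of what happens at the fiber crossings:

* **interpenetrated** — fibers move rigidly and their circular sections
  overlap where layers cross. This is exact bookkeeping for the rigid-motion
  idealization and reproduces the reference porosity table to 2 decimal
  places.
* **flattened** — a parametric stand-in for the structurally deformed
  contact: near every crossing the circular section is replaced by an
  area-preserving ellipse with minor semi-axis $b = (d/2)(1-f)$ along $Z$
  and major semi-axis $a = (d/2)^2/b$ in-plane, blended into the circle
  with a raised-cosine weight over one diameter of axial distance from the
  contact. Area preservation mimics the bending of a nearly incompressible
  thin wall, and $b$ is chosen so the flattened sections of adjacent layers
  touch exactly — no interpenetration remains. This is an explicit
  approximation of the contact-mechanics solution, not a replacement for
  it: porosities land within 0.02 of the structural (finite-element)
  reference values, and permeability comparisons against it are qualitative
  only.

Degrees are restricted to $[0, 0.2]$; at degree 0 both models return the
undeformed cell bit-for-bit. Flattening refuses degrees
$f \ge 1 - 2t/d$, where the ellipse would invert the fiber wall.

## Voxelization and the 1 µm gap rule

The fluid domain is the box minus the fibers and their lumens. It is
discretized on a regular grid: a voxel is solid iff its **centre** lies
inside a fiber outer surface, with periodic wrap. Per axis the voxel count
is `round(L / spacing)`, so effective spacings differ from the nominal one
by up to half a voxel per axis; the flow solver consumes the effective
per-axis spacings, and the grid always tiles the exact cell box. Default
spacings are $d/64$ for porosity counting and $d/32$ for flow, chosen by
the grid-sensitivity procedure below.

Where fibers touch, the fluid volume around the contact line becomes
arbitrarily thin. Instead of artificially spacing fibers apart, the contact
area is slightly *extended*: during voxelization the local fiber-to-fiber
gap (the sum of the two layer families' surface distances) is recorded per
voxel, and any fluid voxel whose gap is below 1 µm is converted to solid.
Every remaining fluid passage is then at least 1 µm thick; the porosity
change is well below 0.005 and no percolating direction is ever closed by
the rule (both are asserted in tests). For the flattened geometry the
surface distance is approximated by the first-order normalization
$\phi/|\nabla \phi|$ of the implicit ellipse function, exact in the
circular limit.

## The flow solve

Steady incompressible creeping flow is solved directly on the voxel
lattice: staggered (MAC) finite differences, face-normal velocities and
cell pressures, no-slip imposed at solid voxel faces (tangential wall
neighbours use mirror ghosts, so the wall sits on the cell boundary).
Driving is a uniform body force along the flow axis with fully periodic
pressure; in the Darcy regime this is equivalent to prescribing a mass-flow
pair of periodic faces with zero outlet pressure. The force is rescaled
after the (linear) solve so the superficial velocity corresponds to
Re = 1 — the oxygenator operating point — with Re defined on the
superficial velocity and fiber outer diameter (the defining convention for
the characteristic scales is a package choice; it shifts the operating flow
rate, never $K$). Water properties ($\mu = 10^{-3}$ kg/(m s),
$\rho = 998$ kg/m³) only enter this rescaling: $K$ is geometric, and
doubling $\mu$ leaves it unchanged to solver precision (tested).

Two interchangeable linear solvers operate on the identical discrete
system:

* **MINRES** (default) — preconditioned MINRES on the full
  velocity–pressure saddle-point system, Jacobi on the velocity block and
  identity on the pressure block (the MAC Schur complement is spectrally
  close to the identity in the scaled units used);
* **Schur-CG** — conjugate gradients on the pressure Schur complement with
  Jacobi-preconditioned inner velocity solves.

Both are iterated until the normalized momentum *and* continuity residuals
fall below $10^{-5}$ (momentum: $\|f - Au - Gp\|_2/\|f\|_2$; continuity:
RMS cell flux imbalance relative to the RMS velocity over the mean
spacing). The two routes agree to ~$10^{-10}$ relative in $K$ and the
slice-wise flow rate is constant to well below 0.1%, which is the discrete
mass-conservation check.

By default the advection term is dropped (Stokes): at Re = 1 inertial
corrections are far inside every tolerance used here, and Stokes makes
$\Delta P \propto Q$ exact. A `navier_stokes` option adds the advective
term by explicit Picard iteration (central differences on the staggered
faces, periodic boundaries only) and is used to demonstrate that
$\Delta P$ versus $Q$ stays linear to well under 2% over a decade of flow
rates at Re ≤ 1.

### Verification fixtures

The synthetic-data module generates voxel geometries with closed-form
answers, emulating exactly the structure the analysis assumes (periodic
fibrous solids with known $\varepsilon$ and $K$):

* **plane channel**, half-width $h$: $K = h^2/3$ on the channel
  cross-section and max/mean velocity $3/2$ — recovered within 2% at 64
  voxels across;
* **square array of parallel cylinders**: transverse flow against the
  Gebart lubrication closed form and axial flow against the Drummond–Tahir
  series, each within 10% *inside the validity range of the respective
  formula*. The Gebart form is a near-packing asymptote: against the exact
  Sangani–Acrivos dilute expansion at $c = 0.05$ the solver is within 1%,
  and against Gebart at $V_f = 0.65$–$0.7$ within a few %, while at
  $V_f = 0.4$ the formula itself overestimates $K$ by roughly 15% — a
  documented model limitation of the closed form, not a solver error. The
  suite therefore checks Gebart in its asymptotic range and the dilute
  expansion elsewhere.

### Grid sensitivity

Following the usual mesh-independence procedure, `grid_convergence()`
re-solves a problem over a ladder of spacings and reports the pressure drop
per level; the optimal level is the coarsest whose pressure drop is within
1% of the finest. On smooth geometries (the channel) the rule selects a
coarse level immediately. On voxelized bundles the staircase
re-discretization between $d/16 \to d/24 \to d/32$ moves $\Delta P$ by a
few %, so the rule typically selects the finest level of the ladder — the
report is honest about this, and the packaged flow default ($d/32$) is the
finest level used in the study runs. Voxel porosity converges to the
analytic/Monte-Carlo membership values with observed order ≥ 1 in the
spacing.

## Darcy extraction and normalization

For a cell at press-fit degree $f$, $A$ and $L$ come from the nominal
(compressed) box: for $Z$ flow $L = 2d(1-f)$ and $A = L_x L_y$; for in-plane
flow $L$ is the box length along the flow and $A$ includes the compressed
height. `normalize_permeability()` divides each $K$ by the $K_0$ of the
same bundle and direction at 0% press-fit (one normalized curve per
bundle, direction and method; 0% entries are exactly 1).

## The study pipeline

`study_plan()`/`run_study()` reproduce the full study design: the
six-preset bundle matrix (`O_380_50_500`, `A_380_50_500`, `O_380_50_450`,
`O_380_50_550`, `O_200_25_263`, `O_300_25_395`), degrees 0/5/10/15%,
anisotropy directions for the two reference bundles and main-direction
($Z$) flow for the others. Output tables mirror the reference layout (rows
= bundle/method, columns = degree) for eyeball diffing. Runs are
deterministic — fixed iteration order, no randomness — and repeated runs
write byte-identical CSVs (tested). Per-cell failures are collected as
structured errors while the rest of the matrix completes.

Default problem sizes keep a full single-bundle sweep at a few minutes on
one core: porosity at $d/64$ (~1–3 M voxels) and flow at $d/32$ (~0.1–0.4 M
voxels, 400–800 MINRES iterations). These defaults are the study
conditions; tests that only need qualitative behaviour use coarser grids
explicitly.

## The fiber material model

The only structural content that survives without a contact
finite-element solver is the calibrated constitutive model of the fiber
wall: a Neo-Hookean potential

$$U = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}(J_{el} - 1)^2$$

with $C_{10} = 17.308$ MPa and $D_1 = 0.027$ MPa$^{-1}$, calibrated against
transverse compression of commercial polypropylene oxygenator fibers
(380 µm outer diameter, 50 µm wall). The package ships it as
`oxyphan_pp_material()` together with its small-strain limits
($\mu_0 = 2C_{10} = 34.6$ MPa, $K = 2/D_1 = 74.1$ MPa, $\nu \approx 0.30$).
Re-running the calibration loop would require the original
force–displacement measurements and a hyperelastic contact solver; both
are out of scope, so the constants are shipped as data, and the
structural press-fit deformation itself is represented by the two
geometric models above.

## What the tests do and do not show

The fixtures and property tests validate the *solver* (closed forms,
linearity, symmetry equivalences, mass conservation) and the *geometry
engine* (analytic porosity, exact overlap integrals, periodicity). The
bundle-level results inherit two idealizations that real bundles violate:
perfect fiber alignment and uniformity (no positional randomness — real
bundles have irregular pitch, which shifts $K$), and rigid or
parametrically flattened fibers instead of the true contact mechanics.
Consequently press-fitted permeabilities from the interpenetrated model
overestimate the structurally correct values increasingly with degree (the
open lateral gaps it leaves at contacts are exactly what real flattening
closes), and flattened-model permeabilities are qualitative. Undeformed
$K_0$ values carry the voxel staircase bias of roughly −10% at $d/32$
against a body-fitted reference; this is inside the ±15% band used for
comparisons and shrinks with resolution.

## Numerical choices at a glance

| choice | value | why |
|---|---|---|
| internal length unit | µm | geometry magnitudes O(100); $K$ converted to m² at the Darcy boundary |
| porosity spacing | $d/64$ | porosity error ≤ 0.002 vs analytic |
| flow spacing | $d/32$ | $K$ within the ±15% comparison band at minutes-per-solve cost |
| residual tolerance | $10^{-5}$ | continuity and momentum, both normalized |
| membership rule | voxel-centre | simplicity; accuracy governed by the sensitivity ladder |
| min gap | 1 µm | thinnest fluid passage kept meshable at contacts |
| tie-breaks | surface points count as solid | measure-zero, fixed for determinism |
| degenerate inputs | pitch ≤ d, α ∈ {0°, 90°} for angled, degree ≥ 1−2t/d | rejected with specific errors |
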