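---
title: "Methods: virtual pressure-flow studies of the renal pelvis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual pressure-flow studies of the renal pelvis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelviflow)
```

`pelviflow` emulates the Whitaker antegrade pressure-flow study in silico:
given a luminal geometry of the renal pelvis, ureteropelvic junction (UPJ)
and proximal ureter, it computes the pressure difference between the pelvis
and the ureteral outlet at imposed physiological urine production rates and
classifies the collecting system by whether that difference rises with
flow. This vignette documents the model, its assumptions, the numerical
choices, and what the synthetic test geometries can and cannot tell you
about real anatomy.

## Governing equations and boundary conditions

Urine is treated as an incompressible Newtonian fluid with density
$\rho = 1050\ \mathrm{kg\,m^{-3}}$ and dynamic viscosity
$\mu = 0.001\ \mathrm{Pa\,s}$ (essentially water at body temperature,
marginally densified by solutes). The flow field satisfies

$$\nabla\cdot\mathbf{U} = 0, \qquad
\rho(\mathbf{U}\cdot\nabla)\mathbf{U} = -\nabla P + \mu\nabla^2\mathbf{U},$$

with the Stokes mode dropping the convective term entirely. Boundary
conditions mirror the urodynamic set-up:

* **Inlet** (papillary patch on the pelvic dome): uniform plug velocity
  normal to the patch, scaled so the *discrete* boundary integral of
  $\mathbf{U}\cdot\mathbf{n}$ equals the prescribed flow rate $Q$ exactly.
  Multiple patches split $Q$ area-weighted (configurable shares). Plug
  inflow is the least-assumptive profile; the pelvic chamber dissipates
  profile details long before the UPJ, which the uniformity check below
  verifies a posteriori.
* **Walls**: homogeneous no-slip on a rigid wall. Peristalsis and wall
  compliance are out of scope.
* **Outlet** (ureter end): zero-traction (do-nothing) condition with
  reference pressure 0 Pa, so all reported pressures are static gauge
  pressures relative to the ureteral outlet. A nonzero
  `outlet_pressure` only shifts the datum.
* **No body force**: gravity is omitted; posture effects are not
  modelled.

Urine output is swept over 360–1440 mL/day (0.25–1.0 mL/min), the
physiological range from infancy to adolescence; the band is a plain
argument (`flow_rates_ml_day`) so it can be personalised per patient. At
these rates the throat Reynolds number of even a 1 mm stenosis stays below
$\sim 25$, so the flow is firmly steady-laminar, and in wide sections it is
genuinely creeping flow. This has two practical consequences the test
suite exploits: Stokes solutions are *exactly* proportional to $Q$ (a sweep
needs one linear solve), and the Navier–Stokes answer approaches the Stokes
answer as $\mathrm{Re}\to 0$ (verified to 1% below Re 0.1).

## Discretisation and linear algebra

The mixed finite-element discretisation uses Taylor–Hood elements on
tetrahedra: continuous piecewise-quadratic velocity (vertex + edge-midpoint
dofs) and continuous piecewise-linear pressure. The pair is inf-sup (LBB)
stable, so no pressure stabilisation terms are needed and no checkerboard
pressure modes appear (asserted on the benchmark duct). Element integrals
use a degree-5 Grundmann–Möller rule (exactness is unit-tested against the
closed-form monomial integrals on the simplex), which integrates every
operator here — viscous, divergence and convective — exactly.

With velocity Dirichlet data eliminated, the Stokes system is solved via
the pressure Schur complement: the scalar velocity stiffness block is
factorised once per mesh (sparse supernodal Cholesky, shared by all three
velocity components), and conjugate gradients run on
$S = B (\mu A)^{-1} B^{\mathsf T}$ preconditioned with the lumped pressure
mass matrix scaled by $\mu$ — spectrally equivalent to $S$ for Stokes, so
iteration counts are mesh-independent (a few dozen). The CG tolerance
($10^{-13}$ relative) is chosen so that two independent solves at $Q$ and
$2Q$ agree to better than $10^{-8}$ at the field level.

Navier–Stokes uses Picard (fixed-point) iteration on the convective term,
initialised from the Stokes solution: each iteration assembles
$C(\mathbf{w})$ at the current iterate, factorises the scalar
convection-diffusion block with a sparse LU (again shared across
components), and solves the now mildly nonsymmetric Schur complement with
BiCGSTAB. Two standard economies keep this cheap without affecting the
converged answer: the pressure solve is warm-started from the previous
iterate, and its tolerance tracks the nonlinear residual (inexact Picard),
tightening to $10^{-13}$ near convergence. The iteration stops when the
relative momentum residual drops below $10^{-8}$; after 50 iterations it
errors out, reporting the last residual and the throat Reynolds number,
since failure to converge is itself evidence against the steady-laminar
assumption. At physiological rates the solver needs 7–15 iterations.

## The synthetic phantom

Real CT-segmented anatomy is not distributable with the package, so the
generator builds the geometry class the clinical question depends on: a
dilated chamber draining through a localized narrowing into a tube. The
phantom is a watertight surface of revolution composed of a flat papillary
inlet cap, an elliptical dome, a cylindrical pelvic body, a cosine funnel
converging to the throat, a cylindrical UPJ throat, a cosine expansion, and
a straight ureter with a flat outlet cap; all joins except the end caps are
$C^1$, which avoids spurious pressure singularities at re-entrant corners.

Defaults describe a paediatric hydronephrotic system and are fixed package
choices, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `pelvis_ap_diameter` | 30 mm | severely dilated pelvis (grade 3–4 range) |
| `pelvis_length` | 40 mm | dome + chamber + funnel extent |
| `upj_throat_diameter` | 1 mm | severe UPJ stenosis; set equal to the ureter diameter for an open (non-obstructed) phantom |
| `upj_length` | 3 mm | short congenital segment |
| `ureter_diameter` | 7 mm | mildly dilated proximal ureter |
| `ureter_length` | 25 mm | modelled segment down to the outlet |
| `inlet_patch_fraction` | 0.2 | papillary inflow area as a fraction of the dome; the patch is realised as the polar cap of the dome, flattened, with rim radius from the spherical-cap area formula |
| `jitter` | 0 | optional smooth, seeded radial perturbation for irregular-lumen testing |

The papillary inflow of a real kidney is distributed over several calyces;
the single-patch default is a modelling choice (multiple `INLET_k` patches
with area-weighted flux shares are supported). Everything is SI metres
internally; millimetre-scale files are handled by `unit_scale` on input.

What the phantom does *not* emulate: calyceal branching, non-circular and
tortuous cross-sections, wall compliance, peristaltic transport, and the
patient-specific UPJ morphology that determines the absolute pressure
numbers. Passing tests on phantoms therefore demonstrate that the
*pipeline* is correct (conservation, oracle agreement, scaling laws,
classification logic) — not that any particular clinical threshold
generalises. The one irreducibly clinical default, the 0.015 Pa
classification threshold, is the lower edge of the pressure band that
accompanied impaired renal function in a single index case; it is exposed
as `threshold_pa` and flagged in every report as a configurable default,
not a validated cutoff.

```{r phantom, eval = FALSE}
spec <- phantom_spec()                       # stenotic defaults above
surf <- make_phantom(spec)                   # INLET / OUTLET / WALL tags
summary(surf)
```

## Meshing

No general-purpose tetrahedral mesher is bundled; instead the mesher is
specialised to the geometry class at hand — tube-like lumens with a single
principal axis and star-shaped cross-sections — which covers phantoms,
benchmark ducts and voxelised tubular masks alike:

1. The principal axis is found from the area-weighted surface PCA.
2. The cross-section area profile $A(t)$ is recovered by slicing the
   triangulated surface with planes along the axis; the oriented
   intersection segments make the enclosed area a single shoelace sum, with
   no polygon chaining.
3. Axial stations are marched with spacing tied to the local radius, the
   edge target and the profile slope, then adaptively bisected until each
   interval's frustum volume matches the sliced-area integral to 0.3% — so
   the tetrahedral volume tracks the surface volume well inside the 2%
   contract.
4. A structured triangulated disk (`nr` rings, ring $i$ carrying $6i$
   vertices; optional radial grading towards the wall via
   `near_wall_refine`) is scaled per station and extruded; prisms are split
   into tetrahedra with the minimum-global-vertex diagonal rule, which
   guarantees conforming diagonals.
5. Disk radii are scaled so each discrete polygonal cross-section
   reproduces the sliced area *exactly*. This removes the leading
   inscribed-polygon bias — for Poiseuille flow the resistance error of an
   inscribed 18-gon would otherwise be $\sim 4\%$ by itself.
6. Boundary facets inherit surface tags by nearest-facet matching with a
   30° normal tolerance, tie-breaking to `WALL`.

Tetrahedra with graded sizing replace the prism/polyhedral boundary layers
a commercial solver would extrude: in the Stokes regime the boundary-layer
resolution requirement is mild, and the grid-convergence study
(`grid_convergence()`, three levels, final gap below 2% on the stenotic
phantom) guards the accuracy of the desk-scale defaults. Default meshes run
at 14–45k cells — deliberately far coarser than industrial practice on
clinical geometries — because the convergence study shows the clinical
readout is already mesh-converged there.

Voxel masks (e.g. from a segmentation) are converted by extracting the
boundary faces of the foreground component (6-connectivity enforced, with
errors naming empty or disconnected masks); the blocky surface encloses
exactly the voxel volume, and optional volume-preserving Laplacian
smoothing is available.

## The clinical readout

Three pressure probes are placed automatically on the luminal axis at the
25/50/75% stations of the pelvis region — the half of the domain along the
principal axis containing the largest cross-section — and snapped to the
nearest interior cell centroid. For geometries with no enlarged region (a
straight duct) the probes fall back to whole-domain stations and the
result carries a `fallback` flag. Manual probe coordinates are accepted
wherever probes are.

$\Delta P(Q)$ is the mean of the three probe pressures relative to the
outlet datum. The mean is insensitive to probe choice because the pelvic
chamber is nearly isobaric: the maximum pairwise probe spread is reported
as `uniformity_pa` and bounded at 5% of $\Delta P$ in the acceptance suite
(on phantoms it is orders of magnitude smaller). The classifier then
implements the Whitaker dichotomy: `FLOW_DEPENDENT_OBSTRUCTIVE` iff
$\Delta P$ at the maximum physiological rate reaches `threshold_pa` *and*
$\Delta P$ increases strictly across the sweep; otherwise
`FLOW_INDEPENDENT`. The reported slope is a least-squares fit of
$\Delta P$ against flow in mL/min. Classification is invariant to adding
intermediate flow rates (tested).

```{r sweep, eval = FALSE}
mesh <- generate_volume_mesh(surf)
sweep <- pressure_sweep(mesh, fluid_properties(), model = "STOKES")
classify_obstruction(sweep)                  # threshold_pa = 0.015 default
```

## Verification strategy

* **Closed-form oracle**: on a straight duct the solver's axial pressure
  gradient — measured as 5-point section averages at the 10% and 90%
  stations, excluding entrance and exit effects the closed form ignores —
  must match $8\mu L Q/(\pi R^4)$ within 5% at the default mesh and 2%
  after one refinement, with observed convergence order above 1.
* **Structure of the equations**: exact mass conservation (inlet/outlet
  flux balance within 0.5% of $Q$; in practice machine precision, because
  the P1 pressure space contains constants), exact linearity of Stokes
  solutions in $Q$, Navier–Stokes → Stokes agreement within 1% below
  Re 0.1, and superlinear $\Delta P(Q)$ once inertia matters.
* **Physics of stenosis**: across throat diameters 2.0/1.5/1.0/0.5 mm,
  $\Delta P$ at 1 mL/min increases strictly, and for a long (10 mm) throat
  halving the diameter multiplies $\Delta P$ by $2^4$ within 25% — the
  Poiseuille $R^{-4}$ law with entrance/taper corrections.
* **Grid convergence**: three-level refinement on the stenotic phantom with
  the two finest levels within 2%.

## Degenerate inputs and numerical edge cases

Meshes without an `OUTLET` patch are rejected before solving (the pressure
datum would be undetermined); missing inlets, zero/negative flow rates,
non-watertight surfaces (after a vertex-merge repair attempt, with open
edges listed), empty or multi-component masks, overlapping tag rules, and
inverted cells all raise errors naming the condition. Slicing planes are
nudged off vertex planes; the inlet rim inherits no-slip (wall wins over
plug), and the plug magnitude is rescaled after rim clipping so the imposed
flux is exact. Surface generation, meshing, probe placement and the whole
pipeline are deterministic given the configuration and seed; the optional
jitter draws from a locally seeded generator and restores the global RNG
state.

## Known limitations

Absolute pressures are estimates, not measurements: rigid walls, steady
flow, plug inflow and the idealised phantom geometry all bias the absolute
$\Delta P$, and the method's clinical content lies in the *flow-dependence
pattern*, not the numbers. Peristalsis, compliant walls, unsteady or
pulsatile flow, gravity/posture, CT segmentation itself and renographic
function estimates are out of scope. The mesher handles tube-like lumens
only; strongly branched (caliceal) trees would need a general constrained
mesher upstream, after which every downstream stage applies unchanged.
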