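---
title: "Mechanobiology-driven design of spherical-pore bone scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanobiology-driven design of spherical-pore bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffopt)
```

## The problem

Regular bone-tissue-engineering scaffolds are built by tiling a unit cell.
The family treated here is a cube of edge $L_{uc}$ from which a centered
sphere of diameter $D_s$ and three orthogonal centered cylinders of diameter
$D_c$ are Boolean-subtracted: the sphere is the pore, the cylinders are the
interconnections that let cells, nutrients and fluid move between pores.
After implantation the pore space is assumed filled with soft granulation
tissue. The design question is: for a given in-vivo load, which $(D_s, D_c)$
maximizes the fraction of the scaffold volume whose mechanical
micro-environment drives mesenchymal stem cells toward *mature bone*?

`scaffopt` answers it with four cooperating layers:

1. **geometry** — implicit CSG membership of the unit cell, voxelized on a
   regular grid and tiled into the full scaffold (default $L = 2.548$ mm,
   $4^3 = 64$ cells);
2. **fem** — a quasi-static Biot poroelastic finite-element solver on the
   voxel mesh (both materials biphasic);
3. **mechanoreg** — the Prendergast stimulus
   $S = \gamma/a + v/b$ and its phenotype bands, yielding the objective
   $BO\%$;
4. **optimizer** — constrained maximization of $BO\%$ over $(D_s, D_c)$.

## Geometry and the coherence constraints

Two topologies exist: **S** ("small", $0 < D_s \le L_{uc}$, the sphere stays
inside the cell) and **L** ("large", $L_{uc} < D_s \le 2L_{uc}$, the sphere
pierces the faces). For the motif to stay coherent the cylinder diameter is
bounded: from below in topology L by the chord
$C = \sqrt{D_s^2 - L_{uc}^2}$ cut by the sphere on the cell face (the
cylinder must cover the sphere's face opening), and from above by the
requirement that a single connected spherical surface survives inside the
cell.

The package implements the upper bound in two selectable dialects, because
the literature this model family comes from is internally inconsistent on
it: the printed constraint table states $D_c \le D_s/2$, yet the worked
geometries used for the published stimulus maps ($D_s = 0.425$,
$D_c = 0.275$ mm) satisfy only the weaker bound $D_c \le D_s/\sqrt{2}$,
which is also what the inscribed-square construction used to justify the
constraint actually yields: the square traced by the cylinder edges in a
mid-plane section has side $D_c$ and half-diagonal $D_c/\sqrt{2}$, and its
vertices touch the spherical edge of radius $D_s/2$ exactly when
$D_c = D_s/\sqrt{2}$, not $D_s/2$. We do not guess the intent: `as_printed` (default) enforces the table verbatim,
`derived` replaces $D_s/2$ with $D_s/\sqrt 2$. The three validation
geometries $(0.85, 0.55)$, $(0.75, 0.5)$, $(0.65, 0.45)$ mm marginally
violate even the chord bound ($0.55 < 0.5628$); they are reproducible with
`enforce_constraints = FALSE` and are treated as deliberately
constraint-exempt benchmark models, not as feasible designs.

Voxelization samples the implicit membership at voxel centers. This
converges to the analytic volume at first order or better (the suite checks
the $D_c \to 0$, $D_s = L_{uc}$ sphere case against $1 - \pi/6$ with error
halving per resolution doubling), and it meshes directly into hexahedral
finite elements. The published average element size of 50 µm corresponds to
roughly 13 voxels per 0.637 mm cell edge; tests use 6–16 voxels per edge to
stay inside desk-scale budgets, and scale-sensitive conclusions are flagged
as such below.

```{r geometry}
spec <- scaffold_spec(Ds = 0.5, Dc = 0.25, L = 0.637, cells_per_side = 1L)
validate_cell(spec)
grid <- assemble_scaffold(spec, resolution = 8L)
volume_fraction(grid)
```

## The poroelastic model

Scaffold and granulation tissue are linear biphasic poroelastic (Biot)
materials:

| property | granulation | scaffold |
|---|---:|---:|
| $E$ (MPa) | 0.2 | 1000 |
| $\nu$ | 0.167 | 0.3 |
| $k$ (m$^4$/N·s) | $10^{-14}$ | $10^{-14}$ |
| porosity $n$ | 0.8 | 0.5 |
| $K_{grain}$ (MPa) | 2300 | 13,920 |
| $K_{fluid}$ (MPa) | 2300 | 2300 |

The Biot coefficient and modulus are derived with the standard relations
$\alpha = 1 - K_d/K_{grain}$ and
$1/M = n/K_{fluid} + (\alpha - n)/K_{grain}$, so every tabulated constant
is used. Internally the unit system is mm–N–s–MPa; permeabilities are
converted once at model build ($10^{-14}$ m$^4$/N·s $= 10^{-2}$
mm$^4$/N·s), and fluid velocities are reported in µm/s.

Discretization: trilinear hexahedra for displacement **and** pressure on
the voxel grid. The equal-order pair is augmented by an optional transient
pressure-stabilization term $\tau \nabla p$ with
$\tau = c_{stab} h^2/(\lambda + 2\mu)$ acting only on pressure increments
(default $c_{stab} = 0.25$). On the one-dimensional consolidation benchmark
this term changes the error only in the third digit — the tabulated
compressibilities already regularize the pair — but it is kept for
robustness at small time steps. Time integration is backward Euler; the
load ramps linearly over 1 s in 10 increments by default (the load-time
history is not prescribed by the source model family; both the duration and
the schedule are configuration keys, and a `"step"` schedule exists for
benchmarks). The stimulus is evaluated at the final (peak-load) increment,
with an optional max-over-increments mode.

Boundary conditions for the scaffold template: encastre at $z = 0$; a
rigid, rotation-free plate tied to every node of the top face, carrying
$|F| = F_{UA} L^2$ (compression along $-z$, shear along $+x$); zero pore
pressure on the exterior *granulation* faces of the four lateral sides and
the bottom. The region under the plate is sealed — our reading of a tied
impermeable plate; scaffold-material faces are never drained. Sharing nodes
across the material interface *is* the tie constraint.

Verification: a frictionless homogeneous compression patch test reproduces
$E_{app} = E$ to machine precision; base reactions balance the applied load
to $10^{-6}$ relative; the 1-D consolidation column matches the closed-form
Terzaghi series (with $c_v = kME_c/(E_c + \alpha^2 M)$ and initial pressure
$\alpha M \sigma / (E_c + \alpha^2 M)$) to better than 1% relative $L_2$ at
$T_v \in \{0.1, 0.3, 0.7\}$, improving under mesh refinement.

```{r fem}
model <- build_fe_model(grid, load = load_case("compression", 0.1))
res <- solve_consolidation(model)
res
```

## Stimulus, phenotypes and the objective

Per granulation element the octahedral shear strain
$\gamma = \tfrac{2}{3}\sqrt{(\epsilon_1-\epsilon_2)^2 +
(\epsilon_2-\epsilon_3)^2 + (\epsilon_3-\epsilon_1)^2}$ and the Darcy
velocity magnitude $v$ (µm/s) combine into $S = \gamma/a + v/b$. The scale
constants $a = 0.0375$ and $b = 3$ µm/s are not restated in the source
article; they are the classical values of the cited mechano-regulation
lineage and are exposed as configuration keys. Whether "interstitial fluid
flow" means Darcy flux or seepage velocity (flux/porosity) is likewise
ambiguous; the default is flux, matching the original calibration, with
`measure = "seepage"` available.

Phenotype bands: resorption below 0.01, mature bone to 0.53, immature bone
to 1, cartilage to 3, fibrous above. The printed inequalities are open at
both ends; we close them as lower-inclusive half-open bins (cartilage keeps
its upper endpoint), a measure-zero convention that the property tests pin
down. The objective is
$BO\% = 100 \cdot V(\text{mature-bone elements}) / L^3$ — note the
denominator is the *total* model volume, so $BO\% \le (1 - V_f) \cdot 100$.

```{r mechanoreg}
field <- compute_stimulus_field(res)
bone_fraction(field, spec$L)
```

## Optimization

Finite-difference gradients, the staple of classical constrained-solver
workflows, are unreliable on a piecewise-constant voxelized objective, so the default is a two-stage
derivative-free search: a deterministic coarse scan of the feasible region
(5×5 points for budgets of 50+ evaluations, 3×3 below; the objective is
multimodal across the two topology branches and local polish alone can
miss the better branch), followed by penalized Nelder–Mead multistart from
the best scan point, the feasible-region centroid of each topology and one
seeded random feasible point — all subject to the dialect-selected
constraints and a shared evaluation budget. Infeasible trial points are evaluated
at their feasible projection with a quadratic penalty on the projection
distance, which keeps the search alive without ever crashing on a
constraint error; a `finite_difference_gradient` mode is provided for
fidelity to gradient-based practice. Stopping: evaluation budget or a
$10^{-3}$ mm design tolerance (none is prescribed by the source). The
returned optimum is always the best *feasible* visited point, so the
reported $(D_s, D_c)$ satisfies the constraints exactly. Runs are
bitwise-reproducible for a fixed seed and configuration; evaluations are
cached by `(Ds, Dc, load, resolution, dialect)`.

On analytic surrogates the search recovers interior optima to $<10^{-3}$ mm
and lands on the active constraint boundary when the unconstrained optimum
is infeasible. On the real pipeline it is checked against a 5×5 feasible
grid floor at equal resolution.

## What the desk-scale tests do and do not establish

The synthetic world of the test suite *is* the stated setup — the default
material constants, load lists (compression 0.05–1.5 MPa, shear 0.01–0.5
MPa), $L = 2.548$ mm and the published fixture geometries — but run at 1
unit cell and 6–16 voxels per cell edge instead of 64 cells at ~13 voxels.
A green suite therefore establishes correctness of the machinery
(geometry, poroelasticity, scoring, search) and the *qualitative*
load-trend reproduction (optimal $D_s$, $D_c$ non-increasing in the load
magnitude, under both compression and shear), not the published
full-resolution optima, which took ~1500 workstation-hours to compute.

One acceptance criterion is knowingly red, and we believe the criterion —
not the implementation — is at fault. At the prescribed coarse resolution
(8–12 voxels/cell) the thinnest validation geometry
$(D_s = 0.85, D_c = 0.55)$ has solid walls of ~25–37 µm, below half a
voxel. Its voxelized frame is 6-connected only from ~24 voxels/cell
upward, and the finite-element mesh (which also transmits force through
shared edge/corner nodes) has *no* base-to-plate load path at 8–16
voxels/cell. A body-fitted tetrahedral mesh at the same nominal 50 µm
element size conforms to the thin rim and does not suffer this. Rather
than report a near-singular solve, the package detects missing load paths
(a connected-components pass over the element graph; floating fragments
are dropped, which is exact for the loaded solution) and reports
$E_{app} = 0$ with a warning. The triplet orderings
($V_f$ and $E_{app}$ strictly decreasing with growing pore size) hold;
the open-interval bound $E_{app}/E \in (0, 1)$ fails for that single
geometry, honestly.

## Numerical choices, in one place

* voxel membership at voxel centers; boundary surfaces count as pore;
* $D_s = 2L_{uc}$ accepted as the closed upper boundary of topology L;
* chord bound strict ($C < D_c$), upper bounds inclusive;
* backward Euler, constant-step factorization reuse; sparse Cholesky for
  drained solves, sparse LU for the coupled saddle system;
* stabilization $c_{stab} = 0.25$ (validated: Terzaghi error 0.2–1.0%
  at the three test times, insensitive to $c_{stab} \in [0, 0.5]$);
* single-phase voxelizations at extreme feasible points (pore or solid
  unresolved) score $BO\% = 0$ rather than erroring inside the optimizer;
* plate displacement along the load direction defines $u_2$;
  $E_{app} = F_{UA} L / |u_2|$ for compression only.

## Known limitations

No healing-time simulation (the scoring is the instant-zero snapshot, as
in the source model); no large strain, contact, scaffold degradation or
nonlinear permeability; no body-fitted meshing, so thin-walled geometries
need ≥24 voxels/cell; STL export is the voxel boundary surface, not a
smoothed marching-cubes isosurface.
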