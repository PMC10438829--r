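---
title: "A stabilized equal-order finite element method for incompressible hyperelastodynamics and poroelastodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stabilized equal-order finite element method for incompressible hyperelastodynamics and poroelastodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvmsfem)
```

## The problem

Soft biological tissue such as myocardium is nearly incompressible, strongly
anisotropic (myofibres and collagen sheets), and perfused: blood moves
through the tissue's pores, so the *mixture* of skeleton and fluid changes
volume even though each constituent is incompressible. `dvmsfem` solves two
related problems on simplicial meshes with piecewise-linear (P1) elements
for every field:

* **incompressible hyperelastodynamics** — unknowns are the nodal velocity
  `v`, the pressure `p` (the Lagrange multiplier of `J = det F = 1`), and
  the displacement `u` recovered from `v`;
* **poroelastodynamics** — the above plus a dimensionless *added mass*
  field `m`, the volume of fluid gained per unit reference volume, with the
  skeleton mass balance `J - 1 = m` and a Darcy model for the pore flux.

In Lagrangian form the balance laws are

```
u̇ = v
(ρ0 + ρ0f m) v̇ = Div( Dev[P] - p H ) + ρ0 b
H : Grad v = ṁ                         (continuity; 0 for the hyperelastic case)
ṁ = Div( K0 Grad p + K0m Grad m ) + S  (added-mass balance, poro only)
```

with `H = J F^{-T}` the cofactor of the deformation gradient,
`Dev[P] = F DEV[S]` the deviatoric first Piola–Kirchhoff stress,
`K0 = J F^{-1} K F^{-T}` the pulled-back permeability,
`K0m = K0 · d(p^PV + p^c)/dm`, and `S` a pressure-dependent volumetric
source/sink. The *pore pressure* that drives Darcy flow and the sources is
the sum `p_pore = p + p^PV(m) + p^c(m)` of the incompressibility
multiplier, a pressure–volume law (quadratic `κ_s m` or the
exponential–logarithmic law with constants `q1, q2, q3`), and a compaction
pressure that activates as the porosity approaches its floor.

Note on conventions: the added mass is carried *dimensionless*
(`m := added fluid mass / ρ0f`, so `J - 1 = m` directly). The compaction
expressions combine `m` with the reference porosity (`m + φ0`), which is
only dimensionally consistent in this normalization; outputs report the
mass-density form `ρ0f m` where a mass is expected.

## Equal-order elements and the fine-scale stabilization

Equal-order P1–P1 velocity/pressure pairs violate the inf–sup (LBB)
condition: the discrete pressure admits checkerboard modes that the
divergence constraint cannot see, and the plain Galerkin system is singular
or wildly oscillatory. The variational multiscale closure used here models
the unresolved fine-scale velocity as

```
v' = -τ ( v̇ + H Grad p / ρ0s - b ),       τ = (c_τ/2) max( Δt_μ/100, min(Δt_μ, Δt) )
```

and inserts it into the continuity equation through the adjoint pairing,
which contributes `-(v', H Grad q)` to the discrete continuity residual.
With the minus sign of the adjoint pairing the pressure part of `v'`
produces `+ (τ/ρ0s)(H Grad p, H Grad q)` — a consistent pressure-Poisson
term that suppresses the checkerboard, exactly analogous to PSPG
stabilization. (Writing the term with the opposite sign yields an
*indefinite* Schur complement `B A⁻¹ Bᵀ - τ L` and a hard instability
within a few steps; the sign used here is the one the abstract multiscale
derivation produces, and the package's free-vibration and manufactured
tests confirm it is the stable one.)

The intrinsic time scale `τ` interpolates between the shear-wave transit
time `Δt_μ = min_e h^e / c_μ^e` and the time step, saturating at both ends.
The shear-wave speed uses the energy derivatives
`c_μ = sqrt((W1 + W2 + W4f + W4s + W8fs)/ρ0s)` with the same
tension-only clamp as the stress, evaluated by default at the current
deformation of each element once per step (`tau_state = "current"`;
`"reference"` freezes it). Defaults: `c_τ = 0.02`, the midpoint of the
workable range 0.01–0.03; `c_τ = 0` recovers the unstabilized P1–P1 pair
(the linear systems are then singular up to a machine-scale ridge that the
solver adds on the pressure block so the oscillatory baseline can still be
factorized and compared).

## Time integration and the nonlinear solver

Time stepping is BDF2 on the first-order system with a backward-Euler
bootstrap for the first step; the displacement is updated explicitly from
the same stencil, `u^{n+1} = (4u^n - u^{n-1} + 2Δt v^{n+1})/3`, so the
unknowns per step are `(v, p)` or `(v, p, m)`. Variable step sizes (from
step rejection) use the general two-step BDF coefficients. The CFL rule
`Δt = α_CFL min_e h^e/c_μ^e` with `α_CFL` in 0.1–1 keeps Newton economical;
the bending-column benchmark runs at `α_CFL = 0.5` with at most 3–5
iterations per step.

Newton's method solves each step with an element-level central
finite-difference tangent: the element residual is analytic (exact
constitutive derivatives), and its derivative with respect to the
element's own local unknowns is differenced column by column, reproducing
the exact sparsity of the analytic tangent with ~1e-9 relative accuracy.
The assembled tangent is verified in the test suite against global
directional differences of the full residual — an independent path.
Practical policies that matter on desk-scale problems:

* **Tangent reuse** (`jacobian_refresh`): `"iteration"` is plain Newton;
  `"step"` (default) factors once per step; `"lazy"` keeps a factorization
  across steps and rebuilds only when convergence degrades — the sparse LU
  is the dominant cost at the finest verification grids, so the
  long-horizon drivers default to `"lazy"`. Rows are equilibrated before
  factorization.
* **Robustness ladder**: backtracking line search; on failure a fresh
  tangent, then per-iteration tangents ("hot" mode); on persistent failure
  the step is halved up to 5 times. At the final halving level a stagnated
  iterate is accepted if its residual has already dropped well below the
  step's initial one — this occurs only at the sharp compaction well,
  where the leftover residual lives on a few porosity-floor nodes and is
  below the time-discretization error.
* **Tolerances**: convergence is relative (`rel_tol = 1e-6`) with a floor
  tied to the run's historical residual scale and to the assembly's
  cancellation roundoff. `abs_tol` defaults to 0 and should be set only
  with knowledge of the unit system (e.g. a Pa-scale problem at rest has a
  roundoff residual near 1e-9 that no relative criterion can beat).

### Constraint relaxation

The volumetric constraint is imposed in *rate* form (`H:Grad v = ṁ`), so
its integral `J - 1 - m` can drift secularly over thousands of steps.
The continuity equation therefore carries an optional Baumgarte-style
relaxation `(χ/Δt)(J - 1 - m)` (`constraint_relax`), consistent in the
sense that it vanishes on the constraint manifold. For the hyperelastic
problem the target `J = 1` is exact and the term is strongly consistent;
it is on by default (`χ = 0.5`) and also improves the observed pressure
convergence. For poroelasticity the element-level `J` and the nodal `m`
differ by an interpolation term of order `h²`, which the `1/Δt` scaling
amplifies to first order — so the manufactured poroelastic studies use the
pure rate form (`χ = 0`), while the long-horizon quasi-static drivers
(swelling, shrinking, ventricle) opt in with `χ = 0.5`, where drift
control matters and the mesh is fixed. With `χ = 0` the discrete energy of
a free vibration is non-increasing after the startup step; with `χ > 0`
small non-monotonicities of relative size ~1e-4 can appear.

### Compaction and the porosity floor

The compaction pressure is `p^c = c ε²/(ε² + (m + φ0 - φ_crit)²)` with
`ε = φ_crit = 0.001`. Two remarks the implementation depends on:

* The scale `c` must *oppose* extraction. Under a compressive load
  `P > κ_s φ0` the sink `S = -β_si p_pore` can only shut off when
  `p_pore = p + κ_s m + p^c → 0` with `p ≈ +P`, i.e. when `p^c` is large
  and *negative* near the floor. The solver's `compaction_update =
  "history_max"` therefore sets `c` to minus the running maximum of the
  spatial peak pore pressure (a single-step maximum would collapse to zero
  once `p_pore` equilibrates at zero and re-open drainage). With this
  update the shrinking cube pins at `m ≈ -(φ0 - φ_crit)` — a volume
  reduction just under 10% — independent of the load magnitude, and the
  pore pressure collapses to ≈ 0.
* Past the floor `d(p^PV + p^c)/dm` goes negative, which would make `K0m`
  an *anti*-diffusion; the solver clamps the factor at zero to keep the
  added-mass operator parabolic.

## Manufactured verification

Two closed-form shear motions on the unit cube drive the verification:
an anisotropic hyperelastic map `u* = (α Z² sin t, β Z sin t, 0)`
(volume-preserving, standard reinforced material, fibres along
`(1,1,1)/√3`) with a prescribed closed-form pressure, and an isotropic
poroelastic map `u* = (α X Z sin t, β Z sin t, 0)` whose added mass
`m* = α Z sin t` satisfies `J - 1 = m` identically. The body force (and
for the porous case the volumetric source) that makes the strong-form
balances hold exactly is derived *symbolically*: the package carries a
small expression-algebra layer (constant-folding constructors over base R
language objects, matrix products, cofactors, determinants, divergences,
differentiation via `stats::D`) that assembles the exact total stress
`Dev[P*] - p* H*` and compiles forcing, tractions and source to fast
vectorized callables. Construction-time checks evaluate the symbolic
strong-form residual at random space–time points (tolerance 1e-10), and
the test suite re-derives the stress divergence by Richardson finite
differences of the *numeric* constitutive evaluation — an independent
oracle. The fields are valid on the fibre-tension branch, `t` in `[0, π]`.

Boundary conditions follow the cases' definitions: zero velocity on the
bottom face, exact tractions elsewhere, and (porous case) exact Dirichlet
added mass on all faces. Initial BDF2 history starts with the
backward-Euler bootstrap; errors are measured as L2 norms with a degree-5
quadrature so the error integral does not pollute order estimates. The
convergence study uses grids `h ∈ {1/4, 1/8, 1/16}` with `Δt = 0.4 h`
(the pairing of the published coarse grid) run to `t = 0.5` — problem
sizes chosen so the full study completes on one desktop core.

Numerical findings worth recording:

* Displacement, velocity, pressure, pore pressure and added mass all
  converge at second order (least-squares slopes 1.8–2.0, pairwise
  ≥ 1.73) under these pairings.
* The fibre stretch is recovered at nodes by volume-weighted averaging of
  the element values; the recovery is superconvergent in the interior but
  first-order in the one-sided boundary patches, so its max-norm error at
  `h = 1/6` (≈ 0.0015) is *smaller* than the published level while its L2
  order sits near 1.5. A least-squares patch recovery would raise the
  boundary order at the cost of a less transparent definition; the simple
  average is kept.
* The porous case's reference permeability is not fixed by the case
  definition. The Darcy term feeds `K · t · curvature(δp)` into the
  added-mass equation, and since the pressure error scales as `C h²` its
  curvature is mesh-independent — an `h`-independent error floor
  proportional to `K`. Observing second-order added-mass convergence down
  to fine grids (as the published study does) therefore requires a small
  permeability; the case default is `K = 1e-5 I`, at which the Darcy terms
  are active but the floor sits below the discretization error of the
  grids used here.
* With `τ = c_τ Δt/2` tied to the time step, the hyperelastic pressure
  error at fixed `h` *grows* as `Δt → 0` (the stabilization weakens), the
  signature of an inf-sup-limited `O(h²/√τ)` component; under the study's
  `Δt ∝ h` pairing and with the constraint relaxation active the measured
  pressure orders are ≈ 1.7–1.9.

## Benchmarks

The drivers in `run_compressed_block()`, `run_column()`,
`run_swelling_cube()`, `run_shrinking_cube()` and `run_lv_demo()` carry
the published material constants as defaults (asserted in the test suite).
Geometric and loading details that the sources leave open were fixed once:

* compressed block: 10 cm × 10 cm domain, load on the central half of the
  top edge (the load region is tagged by facet centroid so coarse meshes
  remain valid); the porous variant's unprinted pressure–volume constant
  defaults to the load scale (`κ_s = 200 dyne/cm²`).
* columns: 1 m × 6 m × 1 m with the cross-section centred on the axis (so
  the twisting velocity `100 sin(πY/12)(Z, 0, -X)` spins about the column
  axis).
* shrinking cube: the load magnitude is not printed; the default is a
  400 Pa normal ramp over 0.5 s — a fraction of the 2 kPa skeleton
  modulus. The steady reduction is set by the porosity floor once drainage
  completes, not by the load; multi-kPa dead loads merely over-distort
  the corner elements of the very soft skeleton.
* idealized ventricle: a truncated half-ellipsoid shell (synthetic
  stand-in for image-derived anatomy) with a rule-based fibre field
  (helix angle +60° at the endocardium to −60° at the epicardium, sheets
  transmural), pressure applied on the endocardium as a follower load
  through the cofactor, and the base held against normal and
  circumferential motion by a direction-pinning penalty while radial
  expansion stays free. It reproduces qualitative behaviour only: with
  zero waveforms the pore pressure relaxes to the source/sink equilibrium
  (the exponential pressure–volume law has a large positive reference
  pressure, so the equilibrium added mass is slightly negative); under
  passive diastolic inflation the skeleton pressure is negative at both
  surfaces, reflecting fibre tension.

What the synthetic cases do *not* exercise: image-based geometry and fibre
architecture, spatially varying permeability, contact, and the
fluid-structure interaction of the ventricular cavity. Passing tests show
the discretization converges on smooth manufactured fields and reproduces
the benchmark mechanisms (checkerboard suppression, drainage arrest,
Darcy-driven swelling) — not that any particular physiological prediction
is accurate.

## A worked example

```{r example, eval = FALSE}
cs <- manufactured_case("hyper_aniso_shear")
out <- run_manufactured(cs, divisions = 6, dt = 0.05, t_end = 0.25)
out$linf["p"]       # max nodal pressure error, ~0.009 Pa
out$linf["lambda"]  # max nodal fibre-stretch error, ~0.0015

rep <- run_convergence(cs, divisions = c(4, 8, 16))
print(rep)          # errors per grid and least-squares orders
plot(rep)           # log-log error plot with an order-2 reference
```

## Limitations

* The sparse direct factorization limits practical meshes to a few tens of
  thousands of unknowns; no iterative or parallel solvers are provided.
* Mesh adaptation, curved boundaries, contact and growth are out of scope.
* The compaction model's literature form is internally inconsistent (the
  potential's derivative differs from the stated pressure by a factor of
  the regularization width); the pressure formula is implemented as
  stated, with the signed scale discussed above.
* The fine-scale closure is quasi-static; tracking the subscales with
  their own dynamics might recover full second-order pressure accuracy in
  the small-`Δt` limit.
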