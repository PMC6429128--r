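---
title: "Methods: rigid-body hydrodynamics and electrokinetics of glycoprotein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body hydrodynamics and electrokinetics of glycoprotein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrocomplex)
```

This vignette documents the models behind each stage of the package, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generators do and do not emulate, and the known
limitations.

## The problem

Antibody–receptor complexes in solution (the motivating system is an IgG
bound to one or two copies of a glycosylated receptor ectodomain) are
multi-lobed, flexible glycoproteins.  Their solution behaviour is probed
by size-exclusion chromatography with viscometry (molar mass M~w~ and
intrinsic viscosity [η]), dynamic light scattering (translational
diffusion D), and electrophoretic-mobility measurements (µ~e~).  On the
modelling side, conformational ensembles of rigid snapshots can be turned
into the same observables through rigid-body hydrodynamics, closing the
loop between structure and measurement.

## Solution-measurement reduction

**Einstein relation.**  For a rigid sphere the intrinsic viscosity is
[η] = 2.5 N~A~ V~e~ / M~w~ with V~e~ = (4/3)πr~h~³.  Treating the
measured [η] of a compact particle as that of its equivalent sphere gives
r~h~ = (3[η]M~w~ / 10πN~A~)^1/3^ (`radius_from_viscosity()`); the
inverse is `viscosity_from_radius()`, and the pair is exact to rounding.
Units follow the measurement conventions: M~w~ in g/mol, [η] in cm³/g,
r~h~ in nm.

**Stokes–Einstein.**  `stokes_einstein_radius()` computes
r~h~ = k~B~T/(6πηD).  The default solvent conditions are T = 293 K and
η = 1.002 mPa·s (water at 20 °C); both are explicit parameters because
published DLS radii are frequently computed with a buffer viscosity
slightly above that of pure water (≈1.02 mPa·s for a typical saline
buffer), and the conversion is meaningless without stating η.

**The two radii differ.**  The viscometric and diffusional equivalent
spheres are different functionals of shape; for compact glycoproteins
they agree within about 10%.  `build_table1()` therefore flags record
pairs whose two radii differ by more than 10% as anomalous rather than
averaging them.

## DLS cumulant analysis

The measured intensity autocorrelation g₂(t) is converted to the squared
field autocorrelation by the Siegert relation, [g₁]² = (g₂ − baseline)/β,
clipped below at zero (`g1_squared()`).  `cumulant_fit()` fits
ln g₁ = c₀ − Γt + (µ₂/2)t² by weighted least squares and reports
Γ and PDI = µ₂/Γ²; `diffusion_from_gamma()` applies D = Γ/q² with
q = (4πn/λ)sin(θ/2) from the instrument geometry (defaults 633 nm, 173°,
n = 1.33 — the common backscatter configuration — but always explicit
parameters, never baked into results).

Two numerical choices matter and are deliberate:

* **Fit window.**  Points are used while the *fitted* first-pass decay is
  above 1% of the intercept (`floor = 0.01`).  Using the fitted rather
  than the measured amplitude to close the window matters: with additive
  noise, measured tail points bounce above any floor long after the true
  decay has died, and those high-leverage points can corrupt the
  curvature (µ₂) term badly.  A first-order fit on the high-amplitude
  points (≥ 0.1) pins the rate; the second-order fit then runs on the
  window and weights that rate implies.
* **Weights.**  The fit is in log space; with additive noise of constant
  variance on g₂, the variance of ln g₁ scales as the inverse squared
  amplitude, so delog weights proportional to the squared (predicted)
  amplitude restore homoscedasticity.

Over 50 synthetic monodisperse traces with noise σ = 0.005 spanning
D = 10⁻⁷–10⁻⁶ cm²/s, the end-to-end median |ΔD|/D is ≈0.4% and the worst
case ≈2.5% (asserted in the test suite).  Multimodal size distributions
and regularised inversions (CONTIN-class) are out of scope.

## Electrokinetics

`zeta_from_mobility()` implements Henry's equation
ζ = 3ηµ~e~/(2ε f(κa)); `dhh_charge()` the Debye–Hückel–Henry effective
charge Z = 6πηaµ~e~(1 + κa)/(f(κa)e).  The two are algebraically linked —
Z = 4πεa(1 + κa)ζ/e — and the package tests this identity to 1e-12 over a
random parameter sweep, so the two reductions can never drift apart.

Parameter choices:

* **Henry's function.**  The exact result is a hydrodynamic integral;
  the package uses Ohshima's closed approximant
  f = 1 + ½[1 + 2.5/(κa(1 + 2e^{−κa}))]^{−3}, within about 1% everywhere,
  monotone, with the exact Hückel (f→1) and Smoluchowski (f→3/2) limits.
* **Debye parameter.**  κ⁻¹ = 0.304/√I nm for monovalent salt at 298 K
  (the standard constant, used verbatim at 298 K); at other temperatures
  the full expression with the water permittivity polynomial is used.
* **Conditions.**  Electrokinetic defaults are 298 K, η = 0.89 mPa·s,
  ε~r~ = 78.5 and I = 0.17 M (150 mM NaCl plus 20 mM Tris-HCl counted as
  fully dissociated at pH 7.5).  Hydrodynamic defaults are 293 K /
  1.002 mPa·s.  The mixed-temperature convention is common in practice;
  `validate_config()` surfaces it as a warning rather than silently
  harmonising.
* **Validity.**  The DHH inversion assumes |ζ| below the thermal voltage
  k~B~T/e (25.7 mV at 298 K); `build_table2()` warns when a record
  exceeds it.

**Theoretical charges.**  Z(pH) is a Henderson–Hasselbalch sum over
titratable groups with a standard side-chain pKa set (Asp 3.8, Glu 4.5,
His 6.5, Cys 8.3, Tyr 10.1, Lys 10.5, Arg 12.5, termini 8.0/3.6).  This
is a deliberate, clearly-labelled approximation to structure-based pKa
methods: it ignores environment shifts, so it reproduces the *scale* of
net charges and the pI of simple models, not per-residue detail.  The pI
is found by bisection on [0, 14] to |Z| < 10⁻⁶, which is well-posed
because Z(pH) is strictly decreasing for any non-empty model.

When records already carry published effective and theoretical charge
columns, `build_table2()` uses those printed values for the ΔZ column, so
transcribed tables reproduce exactly; the mobility-derived ζ and Z are
always recomputed alongside for consistency checks.

## Molecular surfaces

`triangulate_surface()` approximates the solvent-excluded (Connolly)
surface in three steps: a signed-distance grid over the probe-inflated
atomic spheres (field = min over atoms of |x − c| − (r + r~probe~)); a
marching-tetrahedra isosurface at zero; and an inward offset of every
vertex by the probe radius along the local distance-field gradient.
Marching tetrahedra on the Kuhn 6-tetrahedra cube decomposition is
face-consistent across the grid, so the raw mesh is watertight by
construction, and every mesh is validated as a closed oriented
2-manifold before it may reach the solver (violations there are hard
errors, not warnings).

Defaults: probe radius 1.5 Å (a water molecule), grid spacing 0.6 Å for
atomistic inputs.  Analytic bodies (spheres, ellipsoids) bypass the grid
entirely via exact geodesic tessellations (20k² triangles, vertices on
the surface to machine precision).  With probe radius 0 the construction
reduces to the union-of-spheres surface, which has closed-form area and
volume for one or two spheres — the validation cases in the test suite
(within 2% at 0.25 Å spacing for a single atom).  The inward-offset
approximation does not build exact toroidal reentrant patches; deep
crevices between lobes are slightly smoothed.  Interior cavities are not
removed unless `largest_component = TRUE`.

`coalesce()` reduces a mesh to a target triangle count by quadric
edge-collapse decimation with link-condition (manifoldness) and
normal-flip guards, then restores the enclosed volume exactly with a
uniform rescale about the volume centroid.  The Euler characteristic is
never changed, and the realised count lands within 5% of the target
(exactly on it for all tested inputs).

## Boundary-element hydrodynamics

The solver represents the Stokes flow around a rigid body by a
single-layer Stokeslet potential with constant force density per
triangle, collocated at triangle centroids, under stick (no-slip)
boundary conditions.  Numerical choices:

* **Self term.**  The singular self-integral is computed by splitting the
  triangle into three apex sub-triangles at the centroid: in polar
  coordinates the 1/r singularity cancels the area Jacobian, leaving a
  smooth 1-D integral evaluated by 16-point Gauss–Legendre.  An accurate
  self term is what makes the discretisation error cleanly O(1/N) and the
  1/N extrapolation meaningful.
* **Near field.**  Neighbouring triangles use subdivided quadrature
  (4-way refinement, depth 1–2 by distance); far pairs use the 3-point
  edge-midpoint rule.
* **Null space.**  The first-kind single-layer operator on a closed
  surface has a null direction along the surface normal (interior
  incompressibility); a rank completion along n(x)n(y)ᵀ removes it
  without affecting force, torque or deviatoric stresslet moments.
* **Conditioning.**  The grand resistance mixes units (ηL, ηL², ηL³);
  solves and inversions rebalance blocks by the body length scale first,
  without which nanometre-scale matrices are numerically singular.
* **Origin.**  D is evaluated at the centre of diffusion (the origin
  minimising the trace of the translational mobility block), found by an
  exact Newton step on the quadratic origin-shift objective.  For
  centred symmetric bodies this coincides with the centroid.

The resistance matrix is checked for symmetry (raw asymmetry below 10⁻³,
then symmetrised) and positive definiteness on every solve.

**Intrinsic viscosity.**  The solver computes the stresslet of the
force- and torque-free body in the five independent linear strain flows
and averages isotropically, then adds the rotary-Brownian
(orientational-entropy) contribution to the zero-shear viscosity,
(1/10ηV)·Σ~k~ T̃~k~ᵀC̃⁻¹T̃~k~, where T̃~k~ is the torque on the force-free
non-rotating body in strain flow k and C̃ the force-free rotational
resistance (Schur complement).  The decomposition is exact for bodies of
revolution: the package reproduces the classical zero-shear spheroid
factors (2.908 at axial ratio 2, 3.685 at 3) to better than 1%, and the
Einstein value 2.5 for the sphere where the Brownian term vanishes
identically.  The purely mechanical orientation average alone (2.58 and
2.79 for those spheroids) is the high-frequency value and would
understate zero-shear [η] of anisometric particles; both components are
exposed (`viscosity_factor_rigid`, `viscosity_factor_brownian`).  For
strongly non-axisymmetric bodies the Brownian term uses the same
isotropic-relaxation contraction, which is approximate (rotational
diffusion mode-mixing is neglected); for the mildly anisometric bodies
this package targets the effect is small.

**Extrapolation.**  Every hydrodynamic quantity is computed on meshes at
several triangle counts (default grid 500–4000 — desk-scale counts; the
extrapolation, not the absolute count, carries the accuracy) and
extrapolated linearly in 1/N by ordinary least squares
(`extrapolate_inf_triangles()`), reporting the intercept and the Pearson
correlation of the fit.  Sphere oracles: extrapolated D within 0.01% of
k~B~T/(6πηa), viscosity factor within 0.02% of 2.5, |r| > 0.999;
ellipsoid oracles (Perrin friction, axial ratios 2 and 3) within 2%.

**Ensembles.**  `ensemble_hydro()` treats each conformation as rigid,
meshes and extrapolates it independently, and reports ensemble mean ± sd
(the rigid-body approximation: segmental flexibility contributes only
through conformational spread, not through coupled internal dynamics —
bead-spring hydrodynamics is explicitly out of scope).

## Contact maps

Residue–residue contacts between two disjoint selections use
centre-of-mass distance strictly below 5 Å (mass-weighted by default; a
geometric-mean flag exists because the convention is often unstated in
the literature).  Persistence over an ensemble is the fraction of frames
in contact, and a pair is retained when the fraction is strictly greater
than the 0.90 threshold — both inequalities deliberately strict, read
literally from the field convention "presence larger than 90% … below
5 Å".  A crystallographic reference is a 1-frame ensemble, so
reference-vs-simulation comparisons (`compare_maps()`) use the same code
path.  Accelerated neighbour search is unnecessary at interface scale;
the implementation is the all-pairs scan it is tested against.

## Synthetic data: what it does and does not emulate

The generators provide deterministic, seeded stand-ins for every input:

* `pseudo_complex()` builds a Y-shaped three-lobe antibody surrogate with
  one or two elongated receptor lobes at the Fab tips (surrogate molar
  masses 149 + 88.7k kDa), with rigid hinge perturbations and per-atom
  jitter across models.  It emulates the *geometry class* — multi-lobed,
  flexible, with 1:1 smaller than 1:2 — not any particular structure:
  bead radii are coarse, there are no glycans, and no force-field realism
  is claimed.  Hydrodynamic numbers from it are self-consistency targets,
  never comparisons against measured complexes.
* `synth_correlogram()` produces exactly the single-exponential
  monodisperse g₂ the cumulant model assumes, plus Gaussian noise; real
  traces add baseline drift, afterpulsing and polydispersity, so passing
  recovery tests bounds estimator error, not instrument systematics.
* `synth_trajectory()` places scheduled residue pairs below/above the
  cutoff in exact frame counts, giving contact-persistence ground truth.
* `synth_titration()` builds known-pKa group sets with closed-form
  titration behaviour.

Test problem sizes (triangle grids of a few hundred to a few thousand,
8-model ensembles, 50-trace sweeps) were chosen as the smallest sizes at
which every oracle tolerance above is comfortably met; all scale up
linearly in the obvious parameters.

## Known limitations

* The SES is an offset-isosurface approximation; exact reentrant patches
  are not constructed.
* The dense direct solve scales as N³ in triangle count; counts much
  beyond ~5000 need out-of-core or iterative methods that are not
  implemented.
* The Brownian viscosity term is exact only for bodies of revolution.
* Sequence-level Henderson–Hasselbalch charges ignore structural pKa
  shifts; ΔZ columns built from them are indicative.
* Electrokinetics assumes a uniformly charged sphere (DHH); mobility of
  particles with strong charge asymmetry is governed by multipoles this
  model does not resolve.
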