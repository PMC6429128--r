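# hydrocomplex

Solution-state characterisation of antibody–receptor and other multi-lobed
glycoprotein complexes, combining measurement reduction (SEC–viscometry,
dynamic light scattering, electrophoretic mobility) with structure-based
rigid-body hydrodynamics.

The package is aimed at biophysicists who have (a) tabular solution
measurements — molar mass, intrinsic viscosity, diffusion coefficient,
electrophoretic mobility — and/or (b) atomic structures or conformational
ensembles of the species, and want the standard derived quantities on both
sides so they can be compared.

## What it computes

**Measurement side.**

* Einstein viscosity relation: [η] = 2.5·N_A·V_e/M_w with
  V_e = (4/3)πr_h³, inverted as r_h = (3[η]M_w / 10πN_A)^{1/3};
* Stokes–Einstein: r_h = k_BT / (6πηD);
* DLS cumulant analysis: weighted fit of
  ln g₁(t) = c₀ − Γt + (μ₂/2)t² on the Siegert-inverted trace,
  D = Γ/q², PDI = μ₂/Γ²;
* Henry's equation ζ = 3ημ_e / (2ε f(κa)) with Ohshima's approximant for
  f(κa), and the Debye–Hückel–Henry effective charge
  Z = 6πηaμ_e(1 + κa) / (f(κa)e), with κ⁻¹ = 0.304/√I nm at 298 K;
* Henderson–Hasselbalch net charge Z(pH) and isoelectric point from
  titratable-group sets or sequences.

**Structure side.**

* Rolling-probe (solvent-excluded) surface triangulation of atomic models,
  with quadric edge-collapse coalescence to target triangle counts;
* a boundary-element Stokes solver (first-kind single-layer Stokeslet
  formulation, constant elements, stick boundary conditions) giving the
  grand resistance matrix, the translational diffusion coefficient at the
  centre of diffusion, and the zero-shear intrinsic viscosity from the
  force- and torque-free stresslet plus the rotary-Brownian orientational
  term;
* extrapolation of every quantity to infinite triangle number via a linear
  fit in 1/N, and averaging over conformational ensembles (rigid-body
  approximation);
* persistent residue–residue contact maps across an ensemble (centre-of-mass
  distance below 5 Å in more than 90% of frames, by default).

Seeded synthetic generators (pseudo-atomic complexes, correlograms with
known decay, contact-scheduled trajectories, titration sets) provide every
input needed to exercise the pipeline without external data.

## Worked example

```r
library(hydrocomplex)

# Einstein-relation radius from SEC molar mass + intrinsic viscosity
radius_from_viscosity(88700, 6.4)    # 4.481 nm  -> prints as 4.5
radius_from_viscosity(149000, 6.5)   # 5.385 nm  -> prints as 5.4

# Stokes-Einstein radius from a DLS diffusion coefficient (293 K, 1.002 mPa s)
stokes_einstein_radius(4.46e-7)      # 4.802 nm

# DLS trace with known truth, recovered end to end
corr <- synth_correlogram(D = 4.46e-7, noise_sigma = 0.005, seed = 7)
dls_analyze(corr)
#>      gamma        pdi            D      r_h
#> 1 31157.76 0.01035067 4.486134e-07 4.774301

# sphere oracle for the boundary-element solver: Einstein coefficient 2.5
cond   <- solvent_conditions(temperature = 293, viscosity = 1.002)
meshes <- lapply(c(500, 1000, 2000, 4000), function(n) sphere_mesh(2, n))
scan   <- hydro_scan(meshes, cond, molecular_weight = 1e5)
scan$fit_viscosity_factor$intercept  # 2.49990  (exact value: 2.5)
scan$fit_D$intercept                 # 1.0709e-06 cm^2/s = kT/(6 pi eta a)
abs(scan$fit_D$correlation_r)        # 0.99999   (error linear in 1/N)
```

`gamma` is the mean decay rate of the correlogram (1/s), `pdi` the
polydispersity index (≈0 for a monodisperse synthetic trace), `D` the
recovered diffusion coefficient (within 0.6% of the 4.46×10⁻⁷ cm²/s used
to synthesise the trace), and `r_h` the corresponding Stokes–Einstein
radius in nm.  In the sphere scan, the extrapolated viscosity factor and
diffusion coefficient agree with the closed-form Einstein and Stokes
values to better than 0.1%.

An ensemble example, from the synthetic generator through surfaces to
ensemble-averaged hydrodynamics:

```r
st <- pseudo_complex("1:2", n_models = 8, jitter_rms = 1.0, seed = 42)
eh <- ensemble_hydro(st, cond, triangle_grid = c(500, 1000, 2000),
                     probe_radius = 1.5, grid_spacing = 1.5)
eh$summary   # mean and sd of D_t, [eta], r_h over the 8 conformations
```

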