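# saxsim

Simulation of small-angle scattering (SAXS/SANS) data from user-defined
geometric bead models, in R.

Small-angle scattering probes the nm-scale structure of particles in
solution, but the mapping from shape to scattering curve is indirect and
non-intuitive. `saxsim` lets researchers, students and model developers
build a particle of arbitrary shape from geometric subunits (spheres,
ellipsoids, cylinders, discs, cubes, cuboids, hollow and ring variants),
each with its own excess scattering length density ("contrast", which may
be negative), and then computes everything a virtual SAXS experiment
produces: the pair distance distribution p(r), the radius of gyration and
maximum dimension, the scattering intensity, and realistic noisy data that
can be fed straight into fitting software. A closed-form form-factor
library and a least-squares harness close the loop: simulated bead-model
data can be fitted with the corresponding analytic model to validate
either side.

## Method

A particle is represented as N point scatterers (default N = 5000) sampled
uniformly inside the subunit volumes at constant point density, each point
carrying an excess scattering length Δb = Δρ·V_point. The scattering
intensity of the dilute sample follows the Debye equation; rather than
evaluating sin(x)/x over all ~N²/2 pairs for every q, the pair distances
are first histogrammed with contrast-product weights

&nbsp;&nbsp;&nbsp;&nbsp;p_i = Σ_{j<k} Δb_j Δb_k, for r_jk in bin i,

and the intensity reduces to a single sum over bins,

&nbsp;&nbsp;&nbsp;&nbsp;P(q) = Σ_i p_i sinc(q r_i) / Σ_i p_i,

normalized so P(0) = 1 (self-terms excluded; p(0) = 0 prepended to the
exported distribution, which is scaled to unit maximum). From p(r) the
package reports Dmax and R_g² = ½ Σ r_i² p_i / Σ p_i.

Optional physics, all applied to I(q) only (p(r) always describes the
non-interacting particle):

- **Polydispersity** — a Gaussian distribution of a global size-scale
  factor s over [1 − 3σ_poly, 1 + 3σ_poly], each scale weighted by the
  Gaussian density times s⁶ (squared relative volume).
- **Structure factors** — Percus–Yevick hard spheres
  (S(q) = 1/(1 + 24ηG(A)/A), A = 2qR_HS) for repulsion, or a 2-D
  mass-fractal aggregate for aggregation, combined with the decoupling
  approximation S_eff = 1 + β(q)(S − 1), β = ⟨A(q)⟩²/P(q).
- **Interface roughness** — I(q)·exp(−½(qσ_R)²).
- **Noise** — σ(q) = s·√((I(q) + 0.05)/(5·10⁶·q)), mimicking typical
  synchrotron SAXS errors; simulated intensities are drawn from
  N(I(q), σ(q)).

## Worked example: a core-shell cylinder, simulated and refit

Build a core-shell cylinder by carving: a shell cylinder (R = 40 Å,
L = 400 Å, contrast +1) listed first, a core cylinder (R = 20 Å,
L = 360 Å, contrast −1) listed last so overlapping shell points are
removed:

```r
library(saxsim)
spec <- modelSpec(list(subunit("cylinder", c(40, 400), contrast =  1),
                       subunit("cylinder", c(20, 360), contrast = -1)),
                  nPoints = 5000, seed = 1)
cloud <- buildModel(spec)
cloud
#> PointCloud: 4116 points, 2 subunit(s), density 0.00203 pts/A^3
#>   points per subunit: 3198, 918

pd <- pairDistribution(cloud)
pd
#> PairDistribution: 1000 bins, dr = 0.4073 A, Dmax = 407.3 A, Rg = 128.3 A
```

884 shell points fell inside the core region and were removed (the total
is not topped back up, keeping the density constant). Dmax ≈ 407 Å is the
near-diagonal of the 80 × 400 Å outer body. Now simulate data and refine
the analytic core-shell cylinder model against it, fixing the core
contrast at −1:

```r
q   <- seq(0.001, 0.5, length.out = 400)
sim <- simulateData(scatteringIntensity(pd, q), seed = 101)
fit <- fitModel(sim, analyticModel("core_shell_cylinder",
         c(r_core = 20, l_core = 360, t_shell = 20,
           rho_core = -1, rho_shell = 1), fixed = "rho_core"))
fit
#> FitResult (core_shell_cylinder): reduced chi^2 = 1.35, converged = TRUE
#>   r_core          20.24 +/- 0.083
#>   l_core          366.7 +/- 1.8
#>   t_shell         19.73 +/- 0.13
#>   rho_core           -1  (fixed)
#>   rho_shell       1.044 +/- 0.014
#>   scale           1.012 +/- 0.0039
```

The refined geometry agrees with the generating model (20 / 360 / 20 Å)
to within a few quoted standard deviations; contrast and scale are
strongly correlated and scatter a few percent from realization to
realization of the 5000-point cloud.

A full run — p(r), I(q), simulated data, PDB export of the bead model,
projection plots and a run log — is one call:

```r
res <- runSimulation(runConfig(spec, outDir = "out", seed = 1))
```

A thin command-line wrapper with `simulate`, `fit` and `validate`
subcommands is installed under `inst/scripts/saxsim`.

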