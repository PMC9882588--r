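---
title: "Simulating small-angle scattering from bead models: methods and design"
author: "saxsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating small-angle scattering from bead models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsim)
```

# The model

`saxsim` simulates small-angle scattering (SAXS/SANS) from particles in
dilute solution. A particle is described as a set of geometric subunits —
sphere, tri-axial ellipsoid, cylinder, disc, cube, cuboid, hollow sphere,
hollow cube, cylindrical ring, discoidal ring — each with dimensions in
Å, a center-of-mass displacement, and an excess scattering length density
Δρ (contrast) in arbitrary relative units. Contrasts may be negative,
which is how solvent-matched or deuterated components are modelled.

The particle is realized as a Monte-Carlo bead model: `buildModel()`
samples `nPoints` (default 5000) positions uniformly within the subunit
volumes, allocated proportionally to the analytic subunit volumes so the
point density is constant across the whole model. Each point is a point
scatterer with excess scattering length Δb = Δρ · V_point, where
V_point = ΣV_k / N is the constant effective per-point volume. Atomic
form factors are neglected — beads are ideal points.

For a dilute sample of identical particles the intensity is the Debye
double sum over scatterer pairs. `pairDistribution()` first bins all
j &lt; k pair distances with weights Δb_j Δb_k (self-terms excluded) into
`nBins` bins of width dr, with bin centers r_i = (i − ½)dr; the transform
then needs sinc evaluations only per (q, bin):

$$P(q) = \frac{\sum_i p_i\,\mathrm{sinc}(q r_i)}{\sum_i p_i},
\qquad R_g^2 = \frac{\tfrac12\sum_i r_i^2 p_i}{\sum_i p_i}.$$

Normalization by the forward scattering makes P(0) = 1 and removes both
the particle number density and the effective bead volume from the
result. The exported p(r) gains a leading (0, 0) row and is scaled to
unit maximum absolute value.

## Overlap handling and multi-contrast particles

When subunits overlap, two behaviours are available:

* `excludeOverlap = TRUE` (default): points of *earlier-listed* subunits
  that fall inside *later-listed* subunits are removed. Later subunits
  therefore "carve" regions out of earlier ones — a core listed after a
  shell cuts its cavity out of the shell. The removed points are **not**
  resampled: topping the count back up would break the constant-density
  contract, so the realized point count can fall below `nPoints`.
* `excludeOverlap = FALSE`: all points are kept, and the effective
  contrast in the overlap region is the sum of the overlapping subunits'
  contrasts — useful for building contrast steps additively.

Which subunit's points survive a contested region is a design choice (the
behaviour, not the precedence, is the physical contract); the
later-subunit-wins rule was chosen because it makes the natural reading —
"add a core into this shell" — do the expected thing.

# Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `nPoints` | beads per model | 5000 | balances precision against the O(N²) pair cost; the standard working size for this class of simulator |
| `nBins` | p(r) bins | min(⌈√N_pairs⌉, 1000), ≥ 50 | √-rule balances bin noise vs resolution; the cap keeps the q-transform cheap (at N = 5000 the cap is active) |
| `sigmaPoly` | relative polydispersity | 0 | monodisperse by default |
| `nNodes` | size-scale quadrature nodes | 15 | reproduces a 201-node reference to < 0.1% over the resolvable part of test curves (asserted in the suite) |
| `sigmaR` | interface roughness (Å) | 0 | sharp interfaces by default |
| `rHS`, `eta` | hard-sphere radius (Å), volume fraction | — | Percus–Yevick validity requires η ≤ 0.5 |
| `fracR0`, `fracN`, `fracFraction` | aggregate block radius (Å), aggregation number, aggregated fraction | — | see the fractal reconstruction below |
| `noiseScale` | noise scale s | 1 | calibrated to typical synchrotron SAXS via the constants 5·10⁶ and 0.05 Å |
| q grid | linear, 0.001–0.5 Å⁻¹, 400 points | — | typical synchrotron range; q = 0 is excluded from the noise grid where σ diverges |

# Polydispersity

One global form of polydispersity is implemented: a Gaussian distribution
of a size-scale factor s applied to *all* pair distances,

$$p_{poly}(r) \propto \int_{1-3\sigma}^{1+3\sigma}
  p_s(r)\, e^{-\frac12\left(\frac{s-1}{\sigma}\right)^2} s^6\, ds,$$

where s⁶ is the squared relative volume v = s³, accounting for the
intensity of a particle scaling with the square of its volume (exact for
spheres, an approximation otherwise). The integral is evaluated by a
15-node midpoint rule; the Gaussian over ±3σ is smooth, and the constant
node spacing cancels in normalization. A single node sits exactly at
s = 1, so `nNodes = 1` reproduces the monodisperse path bit-for-bit —
a useful identity limit. Rg and Dmax are recomputed from the polydisperse
histogram (Dmax grows to Dmax·(1 + 3σ)). σ_poly must stay below 0.33 so
the smallest scale 1 − 3σ remains positive.

# Interactions

Structure factors modulate only I(q): the exported p(r) is always that of
the non-interacting particle, by contract (a p(r) of interacting
particles is a different object and is out of scope).

**Percus–Yevick hard spheres.** The closed-form S(q) with coefficients
α = (1+2η)²/(1−η)⁴, β = −6η(1+η/2)²/(1−η)⁴, γ = ηα/2. The three
trigonometric terms of G(A)/A suffer catastrophic cancellation as
A = 2qR_HS → 0, so below A = 0.1 they are replaced by their Taylor series
(1/3 − A²/30 + …, 1/4 − A²/36 + …, 1/6 − A²/48 + …), which reproduce the
compressibility limit S(0) = (1−η)⁴/(1+2η)² exactly (asserted to 1e-8).

**2-D fractal aggregates.** The mass-fractal structure factor is used
with the fractal dimension fixed at D = 2, which collapses the
Teixeira-type closed form to

$$S_{agg}(q) = 1 + \frac{2}{(q r_0)^2}\frac{(q\xi)^2}{1 + (q\xi)^2},
\qquad \xi = r_0\sqrt{(N_{agg}-1)/2},$$

with the cutoff ξ fixed by requiring S_agg(0) = N_agg exactly (an N-mer
scatters N times a monomer in the forward direction). This
parametrization — sharp forward normalization, D pinned at 2, free
(r₀, N_agg, aggregated fraction) — is a deliberate reconstruction with
the fewest free parameters; other cutoff conventions exist and would
differ at intermediate qξ. A partly aggregated sample is blended as
S = 1 + f·(S_agg − 1).

**Decoupling approximation.** For non-spherical particles the product
form P·S is corrected via S_eff = 1 + β(q)(S − 1) with
β = ⟨A(q)⟩²/P(q). The orientationally averaged amplitude of an arbitrary
bead cloud is not uniquely defined by the textbook formulas; here it is
defined as

$$\langle A(q)\rangle = \frac{\sum_j \Delta b_j\,
 \mathrm{sinc}(q\,|r_j - r_{com}|)}{\sum_j \Delta b_j},$$

about the contrast-weighted center of mass. This is exact for
centrosymmetric bodies and reduces to the classical sphere/ellipsoid
expressions; for a sphere β = 1 up to the first form-factor zero, which
the suite checks numerically. β is clipped to [0, 1] (beyond form-factor
zeros the ratio of two near-zero MC estimates is noise). β is computed
from the monodisperse cloud even when polydispersity is on — a documented
limitation consistent with applying the structure factor after P(q)
assembly.

**Roughness.** Sharp inter-subunit contrast steps can be softened by
I(q)·exp(−½(qσ_R)²), a Gaussian interface-smearing factor; σ_R is in Å
and only I(q) is affected.

# Simulated noise

Measurement errors follow the empirical synchrotron model

$$\sigma(q) = s\sqrt{\frac{I(q) + 0.05}{5\cdot 10^6\, q}},$$

and I_sim(q) ~ N(I(q), σ(q)) independently per grid point. Doubling s
doubles σ everywhere. Two conventions matter: q = 0 is dropped from the
noise grid (σ diverges), and negative simulated intensities are *kept*,
as in real background-subtracted SAXS data. The intensity entering the
model may itself be marginally negative at high q (Monte-Carlo speckle of
multi-contrast models); σ remains defined for I > −0.05, and the
implementation accepts exactly that range rather than requiring I ≥ 0,
since its own multi-contrast curves exercise it.

# Analytic models and fitting

Closed-form, P(0) = 1 normalized form factors are provided for the
sphere, the cylinder, the ellipsoid of revolution and the core-shell
cylinder. Orientational averages use fixed-order Gauss–Legendre
quadrature on cos α ∈ [0, 1]; 128 points reproduce a 1024-point reference
to 1e-8 on the core-shell test set (asserted). The core-shell cylinder
amplitude is

$$F = (\rho_c - \rho_s) V_c \psi_c + \rho_s V_o \psi_o,$$

with ψ the normalized cylinder amplitudes of the core and outer bodies;
a zero net forward amplitude (contrast-matched particle) raises an error
rather than dividing by ~0.

`fitModel()` minimizes χ² = Σ((I_sim − scale·P)/σ)² with bounded
Levenberg–Marquardt least squares. Because shell contrast and scale are
strongly correlated, the optimization restarts from a few
deterministically jittered initial values and keeps the best optimum.
Parameter standard deviations are the square roots of the diagonal of
χ²_red·(JᵀJ)⁻¹ with J the σ-weighted Jacobian at the optimum.

# Numerical choices

* sinc(0) = 1 (removable singularity), everywhere.
* The histogram bin width is dr = Dmax·(1 + 1e-9)/nBins so the largest
  observed distance falls inside the last bin.
* Largest-remainder rounding allocates points to subunits; ties break by
  subunit order. A two-sphere model with volume ratio 1:2 and N = 3000
  splits exactly 1000/2000.
* Rejection sampling from the axis-aligned bounding box is the single
  sampling path for all kinds — uniform by construction; boundary points
  count as inside.
* Subunits are axis-aligned (cylinder/disc/ring axis = z); there is no
  rotation parameter, only center-of-mass shifts.
* Degenerate subunits (volume < 1e-6 ų, or inner ≥ outer for
  hollow/ring kinds) are rejected at construction.
* A cloud with ΣΔb = 0 (fully contrast-matched) raises a distinct
  zero-forward-scattering error from the intensity and decoupling paths:
  P(q) is undefined there, and an error beats returning NaN.
* The sphere and disc amplitudes switch to series below x = 1e-2 / 1e-4
  to avoid cancellation; the Percus–Yevick branch switch is at A = 0.1.
* All randomness flows through explicit seeds; `buildModel()` and
  `simulateData()` save and restore the caller's RNG state, so identical
  specs and seeds give bit-identical clouds, data and output files.

# What the simulator's randomness implies for validation

The bead model is a *realization*: its P(q) is the exact form factor of
those 5000 beads, not of the ideal body. The expectation over
realizations equals the ideal form factor (self-terms are excluded for
exactly this reason), but each realization carries a speckle whose
relative size grows wherever P(q) is small — roughly like 1/N relative to
the forward scattering. Consequences the test suite makes explicit:

* At low q (Guinier region) the N = 5000 sphere and cylinder agree with
  the closed forms to better than 0.5%; Rg and Dmax to better than 1%.
* At high q, where the cylinder form factor has fallen below ~10⁻⁴ of
  the forward scattering, the speckle dominates: the largest q up to
  which a 5000-point cylinder (R = 50 Å, L = 400 Å) tracks the analytic
  curve within 5% at every grid point — a quantity the acceptance script
  measures — is limited by this floor, and quadrupling N shrinks the
  deviation roughly fourfold. On a log-intensity plot the same curves
  appear indistinguishable to much higher q, because the absolute
  deviations are tiny; the pointwise-relative criterion is the stricter
  reading.
* Fitted parameters inherit a realization-to-realization scatter that
  the fit's covariance (which only sees σ(q)) cannot report: refined
  shell contrasts of the core-shell test case scatter by a few percent
  across clouds even with noise-free data. Comparisons of single
  refinements should be read with that extra variance in mind.

The synthetic-data generator emulates dilute, orientationally averaged,
monodisperse-or-globally-scaled particles with ideal point beads and
q-independent incoherent-free backgrounds. It does not emulate atomic
form factors, resolution smearing, inter-particle correlations in p(r),
anisotropic polydispersity (one axis, aggregation number), or detector
artefacts — agreement of tests on these synthetic data therefore
validates the computational chain, not those physical effects.

# Known limitations

* Arbitrary meshes, voxel bodies and subunit rotations are out of scope.
* Only the Percus–Yevick and D = 2 fractal structure factors are
  provided; no sticky-hard-sphere or screened-Coulomb interactions.
* Structure factors never modify p(r) — deliberately.
* Polydispersity is a single global size-scale; analytic fitting models
  typically implement polydispersity per-dimension, so fitted
  polydisperse data may disagree between the two conventions.
* The CLI is a thin convenience wrapper; the R API is the interface.

# Problem sizes used by the test suite

The suite builds its fixtures in code: bead models of 150–5000 points,
10⁵-sample hit-fraction checks per subunit kind, a 10⁵-point noise grid
for pull calibration, and five 5000-point simulate-and-refit rounds for
the core-shell recovery check. The complete suite runs in well under a
minute on one CPU, the acceptance script in about 25 s.
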