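---
title: "Methods: regional biphasic characterization of disc tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional biphasic characterization of disc tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discmech)
```

## The model and its assumptions

`discmech` treats disc tissue as a linear biphasic mixture: an isotropic,
incompressible elastic solid matrix saturated by incompressible interstitial
fluid. Under confined compression the response reduces to a 1-D
consolidation problem for the local compressive strain $e(z,t)$,

$$\frac{\partial e}{\partial t} = H_A k \frac{\partial^2 e}{\partial z^2},$$

with the aggregate modulus $H_A$ (Pa) and hydraulic permeability $k$
(m$^4$N$^{-1}$s$^{-1}$) entering only through the consolidation diffusivity
$c = H_A k$ and the time scale $\tau = h^2/(H_A k)$. Drainage is
**single-sided**: the chamber's porous platen sits at the base and the
displacement probe is impermeable, so the drainage length is the full
specimen thickness $h$. The thickness used is the as-prepared micrometer
measurement; the creep phase is modeled about the post-relaxation
equilibrium state, which linear theory permits. Both choices are
assumptions the instrument description leaves open; they are fixed here and
used consistently by the generator and the fitter.

Key closed forms (drainage face $z=0$, loaded face $z=h$):

* step-load creep
  $\varepsilon(t) = \frac{\sigma_0}{H_A}\left[1 - 2\sum_{n\ge0}
  \frac{e^{-M_n^2 t/\tau}}{M_n^2}\right]$, $M_n = (n+\tfrac12)\pi$;
* ramped creep and ramp-and-hold relaxation by Duhamel superposition of the
  integrated step responses;
* relaxation eigenvalues are $n\pi$ (not $M_n$) because the constraint is
  the mean strain rather than the boundary strain.

### Numerical evaluation of the series

The eigenfunction series converge exponentially only for $t/\tau$ away from
zero; during a ramp the raw Duhamel series decays merely algebraically
($1/n^2$ for relaxation), which no practical truncation can push to the
$10^{-12}$ term tolerance. Each kernel therefore has two exactly equivalent
representations joined by the Jacobi theta transformation: the spectral
series for $t/\tau \ge 0.05$ and an image (erfc) series for
$t/\tau < 0.05$. The two branches agree to machine precision where both
converge, which the suite asserts; the switch point is therefore not a
tunable.

## The finite-difference oracle

`solve_consolidation()` discretizes the consolidation equation with a
$\theta$-scheme in time and a variable-spacing second-order Laplacian in
space, supporting stress control (Dirichlet strain at the drained face) and
displacement control (mean-strain constraint, reaction stress recovered by
superposition against the factorized operator). Three refinements keep the
oracle error one to two orders below the 1e-3 comparison tolerance used
throughout:

* geometric substepping after every load-history kink (including $t=0$),
  because step loads and ramp ends excite $\sqrt{t}$-singular transients;
* geometric spatial grading toward the drained face, where those transients
  live in a boundary layer of width $\sqrt{c\,\Delta t}$;
* Crank–Nicolson ($\theta = 0.5$) in the default oracle grid — the kink
  substepping suppresses the oscillations CN is prone to. The `grid1d`
  default remains backward Euler for general use.

Discrete fluid mass conservation (cumulative boundary outflow equals the
dilatation change) holds to round-off by construction of the telescoped
flux, and the suite checks it at $10^{-6}$.

## Parameter estimation

`fit_biphasic_creep()` minimizes squared displacement residuals of the
ramped solution times thickness, with $(\log H_A, \log k)$ as free
parameters (positivity for free; $k$ spans orders of magnitude) under a
Levenberg–Marquardt iteration with forward-difference Jacobians. The
applied stress is the recorded creep load over the specimen area, never
re-estimated. Initialization: $H_A^0 = \sigma_0/(1.05\,\varepsilon_{end})$
and $k^0$ from inverting the step solution at the observed half-rise time.
$R^2$ is computed against the mean observed displacement; 95% CI
half-widths come from the log-space Jacobian by the delta method. A trace
shorter than $0.2\,\hat\tau$ triggers a duration warning — truncation
inflates the $k$ confidence half-width several-fold, which the suite
asserts — and fits that stall return `converged = FALSE` rather than
erroring. Traces with no positive displacement trend are rejected as
data-quality errors; quantization-induced local non-monotonicity is not.

## Donnan swelling

Osmotic swelling uses the ideal monovalent Donnan law
$\pi = RT(\sqrt{c_F^2 + 4c^{*2}} - 2c^*)$ with all activity and osmotic
coefficients unity, and fixed charges bound to the matrix so that
deformation rescales FCD by the current water volume,
$c_F = c_{F0}\,\phi_{w0}/(J - 1 + \phi_{w0})$. FCD values are interpreted
per volume of interstitial water (the source table does not say; this is
the common convention). Bath concentration defaults to 150 mM NaCl; the
test temperature is not stated by the protocol, so 298 K (benchtop) is the
default and 310 K is a parameter away.

## The disc finite element model

`build_disc_mesh()` meshes half of an idealized bean-shaped disc
(mid-sagittal symmetry): a square-to-ellipse map with a posterior indent,
extruded to 6 mm height with 0.9 mm endplate (CEP) layers; the NP ellipse
is posteriorly biased and sized by bisection to 40% of the cross-section.
The published mesh was traced from dissection images that are not
available, so cross-section magnitudes are explicitly out of scope; region
orderings and the pressure-decay structure are in scope and asserted.

`solve_biphasic_fem()` is a mixed displacement–pressure (u–p) formulation
with equal-order trilinear interpolation and backward Euler. Choices worth
knowing:

* **Small-strain kinematics** despite the 10% ramp — the solid model is
  linear isotropic elastic; Lagrange strains are reported from the
  displacement gradient for peak tables. This is a documented deviation
  from a finite-deformation treatment.
* **Boundary conditions**: prescribed axial displacement on the top face
  (frictionless in plane — the loaded-surface condition is not stated in
  the protocol; frictionless is assumed), axially fixed frictionless
  bottom with rigid modes pinned, all exposed exterior surfaces drained
  ($p=0$) including endplate faces, symmetry plane impermeable and fixed
  laterally.
* **Time stepping**: first step ramp/200 against early-time pressure
  oscillation (a within-element pressure-range metric is reported); step
  sizes double every four steps and the hold step is capped at
  `hold_end/20`, because backward Euler otherwise underdamps the slow
  pressure-decay modes and the four-orders-of-magnitude pressure drop over
  the hold would be an artifact of the grid, not the physics.
* **Equilibration of the saddle point**: pressure columns and continuity
  rows are scaled by $E_{ref}/L_{ref}$; in SI units $k$ sits twenty orders
  below $E$ and the raw factorization is numerically rejected.
* **Swelling** adds $-\pi(J)\,I$ to the solid stress with the analytic
  tangent $d\pi/dJ$ in a Newton iteration per step; a free-swelling
  equilibration (top surface free, $p=0$) precedes the ramp, and the 10%
  compression is applied relative to the swollen top position — the swollen
  top surface is not flat, so a uniform additional displacement is the
  consistent interpretation of platen compression of the swollen disc.

Validation: a homogeneous cylinder under the same protocol matches the
classical unconfined-compression series solution's reaction force to within
3% at the coarse test resolution (measured ~1%), and the incompressible
instantaneous limit $3E/(2(1+\nu))$ of that series is itself verified
against the amplitude sum. With identical materials in all regions the NP
and AF partitions agree to <1%, while the CEP partition peaks ~13% higher —
a physical consequence of containing the drained endplate faces, not a
region-labeling artifact.

## The synthetic cohort generator

The generator emulates the stated experimental world: 16 AF / 10 NP / 10
CEP specimens from 3 donors; regional truths drawn from truncated normals
(lower truncation at 10% of the mean) with means and SDs from the
measurement tables (swelling-pressure SDs are backed out of the reported
95% CIs as $\mathrm{hw}\sqrt{n}/t_{n-1}$: 81.3 / 89.1 / 82.8 kPa for
NP/AF/CEP; porosity SD is not reported and is set to 0.05, a realistic
composition spread); specimen thickness 1.17 ± 0.35 mm (disc tissue) and
0.92 ± 0.21 mm (CEP); a 60 s offset-compression ramp (the protocol does not
state it; one minute is typical of displacement-controlled DMA moves);
relaxation equilibrium load constructed to equal swelling pressure times
area; creep under 20% of the *measured* (quantized) equilibrium load over a
5-minute ramp; displacement quantized to 1 µm and force to 1 mN. Porosity,
stiffness, swelling pressure and (weakly, with opposite sign) permeability
share a latent standard-normal composition factor whose loading
(`latent_coupling = 0.25`) was calibrated once so the pooled
porosity–stiffness Pearson correlation of a 300-specimen cohort lands near
−0.5; the calibration script ships as
`inst/calibration/coupling_cal.R` and the value has not been revisited
since. Draws implying a creep equilibrium strain above
15% violate the linear-theory premise and are resampled with a logged
count; donors contribute 5%-of-SD mean shifts, recorded but never modeled
in the statistics.

What a green test does establish: the estimation pipeline recovers the
generative truth through the instrument model, and the statistics stage has
its nominal operating characteristics under this world. What it does not:
real tissue violates several generator assumptions — strain-dependent
permeability, intrinsic solid viscoelasticity, fiber-reinforced anisotropy,
interdigitation artifacts at the porous platen — so green tests here say
nothing about bias under those effects.

## Statistics

Fixed-effects one-way ANOVA over region, pairwise Welch (unequal-variance)
t tests with Bonferroni–Holm step-down adjustment, t-based 95% CIs, and
pooled Pearson correlations of each outcome against porosity, all
implemented directly and cross-checked against independent base-R oracles
in the suite. The donor random-intercept mixed model used in the source
analysis is deliberately replaced by this fixed-effects treatment (the
generator's donor effects are small); the report header records the
deviation. The exact form of the original "generalized t-test" is not
specified; Welch contrasts are the stated approximation. Under a null
generator the Holm family rejects in ≤7% of 1000 replicates at
$\alpha = 0.05$; the two-cohort CEP-vs-NP stiffness comparison at the
configured gap (n = 8/10) is detected in ~79% of replicates. With the full
three-group family that power would be almost exactly 50% — a property of
the stated world's effect size, documented rather than tuned away.

## Known limitations

* No strain-dependent permeability or tension–compression nonlinearity;
  creep strains are kept ≤15% by construction.
* Equal-order u–p elements are not inf-sup stable; the small first step and
  the oscillation metric manage, not eliminate, early-time pressure noise.
* The disc cross-section is parametric, not specimen-specific; absolute
  FE magnitudes should not be compared against traced-geometry results.
* The statistics stage ignores donor clustering by design.
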