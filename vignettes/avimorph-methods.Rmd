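---
title: "Modelling morphing-wing inertia, pitch stability and its evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling morphing-wing inertia, pitch stability and its evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avimorph)
```

Birds reshape their wings in flight by flexing and extending the elbow and
wrist. Because mass moves with the skeleton, feathers and soft tissue, wing
morphing changes the bird's centre of gravity (CG) and its moment-of-inertia
tensor **I** — the quantities that, together with aerodynamic forces, govern
the rotational equations of motion. `avimorph` computes these inertial
characteristics analytically from dissection-style morphological
measurements, derives longitudinal static-stability and pitch-agility
metrics per wing configuration, and asks whether the resulting traits show
evidence of selection on a phylogeny.

This vignette records the model, its assumptions, the tunable parameters and
the numerical choices, in the spirit of a methods appendix.

## The composite-solid model

A bird is modelled as a rigid composite of simple solids with closed-form
mass properties. The catalogue has eight primitive kinds: solid and hollow
cylinders, solid frusta (truncated cones, with the cone as the zero-tip
limit), hollow frustum shells, ellipsoids, hemiellipsoids, flat polygonal
laminae and point masses. Each primitive carries its own mass, so tissue
densities are implied rather than assumed.

Component mapping (each named anatomical component maps to one primitive):

* body — head: ellipsoid; neck: cylinder; torso: hemiellipsoid cap +
  frustum + caudal cone (3 shapes); legs: 2 cylinders; tail: trapezoidal
  lamina — 8 shapes;
* each wing — 6 bones (4 hollow cylinders for the long bones; radiale and
  ulnare as point masses), 3 muscle-group frusta, and laminae for the
  propatagium/skin, coverts and tertiaries — 12 shapes;
* each flight feather — calamus (hollow cylinder), rachis cortex (hollow
  frustum shell) around a medullary core (frustum), and proximal and distal
  vane laminae — 5 shapes.

With 10 primaries, 10 secondaries and an extended neck this yields
`8 + 2 * (12 + 5 * 20) = 232` shapes. The feather count is variable and the
shape-count formula holds for any `(nP, nS)`.

Two conventions matter for cross-checking numbers against other
implementations:

* **Frame**: origin at the clavicle reference point (spinal cord cut at the
  clavicle), x positive cranial, y positive toward the right wing, z
  positive dorsal; right-handed.
* **Products of inertia**: tensors are stored as the dynamics matrix (the
  matrix multiplying angular velocity), i.e. off-diagonals are
  `-integral(xy) dm`. Published tables that report unsigned "I_xz" values are
  comparable in magnitude only.

### Wing pose

For a configuration (elbow, wrist), both interior joint angles are imposed
on a planar linkage (humerus–ulna–carpometacarpus). The wrist is constrained
to lie on the y axis through the shoulder — in line with the humeral head
in both x and z — which makes the effective shoulder angle configuration
dependent; the first secondary points caudally from the wrist, fixing wing
incidence. Secondaries attach along the ulna pointing caudally; primaries
attach along the hand and fan from caudal at the wrist to
`primary_fan_deg` (default 30°) past the hand direction at the tip, so
folding the hand sweeps the primaries naturally.

All wing structure lies in the plane of the shoulder. This is the model's
main geometric simplification: it cannot produce the dorsal CG shift with
extension that out-of-plane morphology gives real wings, so the z component
of the full-bird CG is constant across a sweep. Conclusions about x-axis CG
motion, spanwise wing CG motion and the inertia tensor are unaffected.

### Torso balance matching

The torso's measured balance point rarely coincides with the centroid of an
assumed torso geometry. The three torso sections keep their geometry fixed
while their mass split is adjusted by a single parameter, solved by
root-finding (tolerance 1e-9) so the composite torso CG matches the measured
`(torso_cg_x, torso_cg_z)` exactly; an unreachable balance point is an input
error reported with the feasible range. Component masses must sum to the
measured total within 2%; the residual is absorbed into the torso mass, and
larger discrepancies are rejected.

### Geometric ratios

A few dimensionless ratios are not direct measurements (bone wall ratio
0.55, bone slenderness 1/18, muscle taper, covert/tertiary strip chords as
fractions of secondary length, torso section fractions 0.2/0.5/0.3). They
are collected in `build_options()` with defaults chosen once as anatomically
plausible; all mass-dominant quantities come from the measured masses, so
these ratios perturb the tensors only through second moments of individual
components.

## Stability and agility metrics

Longitudinal positions for the stability metrics are measured aft of the
humeral head (positive toward the tail). The wing planform is reconstructed
from the built geometry — leading edge through shoulder, wrist and tip;
trailing edge through the tertiary strip and the feather tips — and the
quarter chord of the standard mean chord is

x_smc = ∫ c(y) x_c4(y) dy / ∫ c(y) dy over the half-span,

evaluated with a midpoint rule on 1,000 segments (`n_segments`). The
wing–body neutral point follows the power-law scaling
`x_np / c_r = (x_smc / c_r)^0.8`; the exponent is exposed (`np_exponent`)
for sensitivity analysis and `exponent = 1` reduces the map to the identity.
The static margin is `(x_np - x_cg) / c_r_max`, positive when the neutral
point is caudal to the CG (stable), with `c_r_max` the specimen's maximum
root chord over its range of motion. The pitch agility metric is

Δq̇/Δα ∝ (x_np − x_cg) · (m^0.12)^2 · S_max / I_yy,

which folds in the cruise-speed allometry `V ∝ m^0.12` and drops air density
and lift slope as shared constants. It therefore has proportional units: its
sign always equals the sign of the static margin, ratios between
configurations or species are meaningful, but absolute values are not
dimensional accelerations (and rescale with the unit of length).

## Range of motion

Joint angles are interior angles at three markers (elbow: markers 1–2–3
with the vertex at 2; wrist: 2–3–4 with the vertex at 3); frames missing
any of markers 1–4 are dropped with a logged count. A specimen's ROM is the
convex hull of its (elbow, wrist) observations. Sweeps evaluate a regular
grid clipped to the hull, always including the hull vertices so extrema
cannot be clipped away; the grid step defaults to 1°. The package's own
examples and the reproduction script use 5–15° grids, which this package
treats as its standard problem size: the reported extrema are stable well
below the trait differences the comparative analyses consume.

## Evolutionary analyses

Species means of the per-specimen trait extrema feed the comparative layer.

* **BM and OU fits.** Both models are fitted by maximum likelihood on an
  ultrametric tree. The OU model is single-regime with the root fixed at
  the optimum θ, giving tip covariance
  `σ²/(2α) · exp(−α d_ij) · (1 − exp(−2α t_ij))`; as α → 0 this converges
  to the BM covariance (verified to |ΔlogLik| < 1e-4 at α = 1e-8). The OU
  likelihood is profiled over α (θ and σ² concentrated out in closed form)
  with bounded multi-start optimization on α ∈ [1e-8, 50/tree height];
  boundary fits are flagged degenerate. AICc uses k = 2 (BM) and k = 3
  (OU). A profile-likelihood interval (`ou_theta_ci()`) is provided for θ
  because the Wald interval conditional on the fitted α undercovers.
* **Monte-Carlo likelihood ratios.** `pmc_bootstrap()` simulates traits
  under each fitted model, refits both to every simulated dataset, and
  reports the fraction of BM-simulated ratios exceeding the observed ratio
  together with the power (OU-simulated ratios above the BM 95th
  percentile). Refit failures are excluded and counted, never imputed.
* **Allometry.** Trait–mass slopes are tested against isometric nulls
  (0 for length-normalized CG traits, 5/3 for log inertia components) by
  phylogenetic generalized least squares with the BM correlation structure.
  This is a deterministic maximum-likelihood stand-in for MCMC-based
  phylogenetic mixed models: it answers the same slope-versus-null question
  and reduces exactly to ordinary least squares on a star phylogeny, but it
  is an approximation, not a reimplementation, of a Bayesian PGLMM.
* **Effect sizes.** Per specimen, `response ~ elbow * wrist` is fitted on
  scaled, mean-centred angles; partial η² is computed per term from
  Type-III sums of squares (`SS_term / (SS_term + SS_residual)`). When a
  noise-free response makes the residual sum of squares exactly zero, the
  sums of squares fall back to drop-one residual differences so that the
  definition extends continuously (η² = 1 for the driving term, 0 for
  inert terms).
* **CG-error bootstrap.** Each replicate shifts every specimen's combined
  torso+tail CG by a uniform draw within ±15% of its torso length, capped
  at 4 cm; the whole-bird CG moves by the torso+tail mass fraction of the
  shift, static margins are recomputed, species means rebuilt and the OU
  optimum refitted for the maximum and minimum static margin.

## The synthetic cohort

Because the builders, sweep and comparative layers need realistic inputs to
be testable, the package generates its own cohort: by default 22 species
spanning 0.02–3 kg (log-spaced), one or two specimens each, with lengths
scaling as mass^(1/3) and areas as mass^(2/3) under lognormal species
scatter (CV 0.12), fixed anatomical mass fractions jittered and renormalized
so component masses sum exactly, 10 primaries and 10 secondaries per wing,
and convex pentagon ROM hulls spanning roughly 55–150° (elbow) by 60–165°
(wrist). Marker traces are planar four-marker chains that reproduce
prescribed joint-angle pairs exactly, plus filler markers, under random
rigid motions and optional 0.5 mm Gaussian noise. Trees are pure-birth and
rescaled to unit height; traits are simulated from the exact Gaussian
covariance of the stated model, so recovery tests are internally consistent.

What the generator does *not* emulate: phylogenetic signal in morphology
(species deviations are independent), out-of-plane wing morphology, feather
overlap and porosity, air spaces in the body, and the error structure of
real dissection measurements. Passing tests therefore demonstrate that the
computational pipeline is correct and internally consistent at the study's
data shapes — not that the model is an accurate description of any
particular real species.

## Numerical choices

* Doubles and SI units throughout; degrees at interfaces, radians
  internally.
* Solid-of-revolution moments use 8-node Gauss–Legendre quadrature, exact
  for the polynomial integrands involved; lamina moments use the shoelace
  polygon formulas, orientation-independent by construction.
* Rotation matrices are validated to orthonormality (tolerance 1e-9);
  tensor symmetry and the principal-moment triangle inequality are checked
  at 1e-12 relative.
* Parallel-axis round trips and composition associativity hold to 1e-12
  relative; rotation spectrum invariance to 1e-10.
* The torso mass partition is solved by root-finding to 1e-9; the wrist
  alignment constraint is satisfied by construction (closed-form triangle
  solution, elbow placed caudal).
* Sweeps are deterministic for a fixed grid; all stochastic steps
  (generators, bootstraps, Monte-Carlo model selection) consume explicit
  integer seeds.

## Known limitations

* Planar wings: no dorsal CG shift with extension (above).
* The planform reconstruction from built geometry is a documented stand-in;
  a different leading/trailing-edge definition shifts x_smc slightly, which
  the configurable neutral-point exponent partially absorbs.
* The agility metric is proportional, not dimensional.
* Single-regime OU only; no multi-regime models, no measurement-error
  likelihoods, no MCMC.
* Rigid bodies: no aeroelasticity, added-mass or deformation effects.

## A minimal run

```{r, eval = TRUE}
cfg <- synthetic_config(seed = 1, n_species = 4, specimens_per_species = 1)
cohort <- generate_cohort(cfg)
m <- cohort$morphology[1, ]
f <- cohort$feathers[cohort$feathers$specimen_id == m$specimen_id, ]
model <- assemble_bird(m, f, elbow = 120, wrist = 140)
nrow(model)
bird_mass_properties(model)[, c("mass", "cg_x", "cg_z", "Ixx", "Iyy", "Izz")]
```

```{r, eval = TRUE}
sw <- sweep_rom(m, f, cohort$hulls[[m$specimen_id]], grid_step = 20)
specimen_extremes(sw)[, c("sm_max", "sm_min", "Ixx_fold", "Iyy_fold")]
```
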