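---
title: "Soma and neurite density imaging: models, fitting and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soma and neurite density imaging: models, fitting and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the compartment models, the dictionary fit, the Monte-Carlo
oracle, the resolution simulation study, the synthetic cohort, and the
numerical and design choices behind each. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The signal model

A pulsed-gradient spin-echo (PGSE) measurement is parameterised by the
gradient amplitude $G$ (mT/m), pulse duration $\delta$ (ms), pulse
separation $\Delta$ (ms) and direction; the diffusion weighting is
$b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$ with
$\gamma = 2.6751\times10^{8}\,\mathrm{rad\,s^{-1}T^{-1}}$. Units are
s/mm$^2$ for $b$, $\mu$m$^2$/ms for diffusivities, $\mu$m for radii and
ms for timings throughout; every conversion is centralised in the
acquisition module.

SANDI models the direction-averaged (powder) signal of grey matter as
three non-exchanging compartments:

$$\bar S(b)/S_0 = f_{neurite}\,A_{stick}(b; D_{in})
  + f_{soma}\,A_{sphere}(G,\delta,\Delta; R_s, D_{is})
  + f_{extra}\,A_{ec}(b; D_{ec}),$$

with $f_{neurite}+f_{soma}+f_{extra}=1$.

* **Stick** (zero-radius cylinder, the neurite model):
  $A = \sqrt{\pi/(4bD)}\,\operatorname{erf}(\sqrt{bD})$, a function of
  the product $bD$ only.
* **Ball / zeppelin** (extra-cellular Gaussian water): $e^{-bD}$, or
  for an axially symmetric tensor
  $e^{-bD_\perp}\sqrt{\pi/(4b\Delta D)}\operatorname{erf}(\sqrt{b\Delta D})$
  with $\Delta D = D_\parallel - D_\perp$; the zeppelin reduces to the
  ball at $D_\parallel = D_\perp$ and to the stick at $D_\perp = 0$
  (both reductions are tested).
* **Sphere** (soma): the Gaussian-phase-distribution (GPD) series of
  Murday–Cotts/Balinov for diffusion restricted inside an impermeable
  reflecting sphere. Its eigenvalues are set by the roots $a_m$ of
  $j_1'(x)=0$ (first root $\approx 2.0816$), found by bracketed
  root-finding on $(x^2-2)\sin x + 2x\cos x$ and cached. The series is
  truncated at $M = 20$ roots; because the terms decay like $m^{-4}$,
  the discarded tail is below $10^{-5}$ of $-\ln S$, and a precision
  warning is raised if the last retained term exceeds that share.

The sphere signal depends on $G$, $\delta$, $\Delta$ separately — not
only through $b$ — which is why soma-size resolution is a property of
the acquisition protocol, and why a 300 mT/m research system and an
80 mT/m clinical system genuinely differ.

### Validity of the GPD approximation

The GPD expression is itself an approximation: it replaces the phase
distribution of restricted spins by a Gaussian. The package carries an
independent Monte-Carlo oracle (below) precisely to delimit where that
approximation holds. At weak-to-moderate attenuation the two agree
within Monte-Carlo precision; at strong attenuation (large spheres on
high-b shells, e.g. a 12 $\mu$m sphere at $b = 3000$ s/mm$^2$ with
$\delta/\Delta = 19/36$ ms) the GPD value overestimates the true
(walker) signal by several percent — far beyond the walker's standard
error at $10^5$ walkers. The acceptance suite runs the strict 3-SE
comparison over radii $\{2, 5, 8, 12\}\,\mu$m on every shell of both
bundled protocols and reports each violating cell; the module tests
assert the physically meaningful claims (agreement in the GPD validity
regime, and a few-percent relative bound at strong attenuation). Users
should read fitted soma radii near the top of the dictionary range with
this model error in mind.

## Acquisition protocols

Two protocols are bundled:

* **Clinical (Prisma-like)**: $b = 0/700/1000/2000/3000$ s/mm$^2$ with
  $12/6/20/45/66$ measurements, $\delta/\Delta = 19/36$ ms; peak
  gradient 62.6 mT/m, inside an 80 mT/m hardware cap.
* **Research (CONNECTOM-like)**: $b = 0/1000/2000/3000/5000/7000/10000$
  s/mm$^2$ with $12/12/32/48/60/60/60$ measurements. Published
  research-scanner tables are not redistributed here, so a
  representative scheme is bundled; its timings were chosen as
  $\delta/\Delta = 10/25$ ms so that the top shell stays within the
  300 mT/m hardware cap (peak $\approx 254$ mT/m) — shorter pulse
  timings paired with $b = 10000$ s/mm$^2$ would require $>360$ mT/m,
  which no scanner of this class can play. Any scheme file in the
  plain-text dialect (`gx gy gz |G| Δ δ TE`, SI units) overrides the
  default wholesale.

Gradient directions are laid out per shell by seeded electrostatic
repulsion (antipodally symmetric Coulomb descent). The downstream
pipeline uses powder averages, which are insensitive to the exact
layout; the seed makes protocols bit-reproducible. Shell grouping uses
a 50 s/mm$^2$ b-tolerance, which separates all bundled shells
unambiguously.

## Dictionary fit

The AMICO-style linearisation builds a per-shell signal matrix of 13
atoms: one stick ($D_{in} = 2.4$), nine spheres ($D_{is} = 3.0$, radii
equally spaced 1.5–12 $\mu$m) and three balls
($D \in \{0.4, 1.6, 3.0\}$). Each voxel's powder vector $s$ is solved
as

$$\min_{w \ge 0}\; \lVert A w - s \rVert^2 + \lambda^2 \lVert w \rVert^2$$

by Lawson–Hanson NNLS on the Tikhonov-augmented system
(`pracma::lsqnonneg`). $\lambda$ is specified relative to the spectral
norm of $A$, default $10^{-3}$: a 5-shell clinical acquisition gives 5
equations for 13 unknowns, so the problem is under-determined by design
and the small ridge stabilises the weight spread. Fractions are weight
shares per atom class; because scaling $s$ by $c>0$ scales the
minimiser by $c$ exactly, fractions are scale-invariant (tested).
$\hat R$ is the weight-weighted mean sphere radius, undefined when the
sphere class carries less than $10^{-6}$ of the weight. Negative powder
values (possible after noise) are clamped to zero with a warning.

Two structural degeneracies deserve naming:

* **Stick vs sphere+ball**: on the bundled 7-shell research scheme the
  stick atom's powder signal is *exactly* representable (residual at
  machine precision) as a non-negative sphere+ball mixture, so class
  recovery for a pure stick signal is non-unique and solver-dependent.
  The acceptance suite asserts class recovery for all 13 atoms and
  reports this one honestly; sphere and ball atoms recover their class
  exactly.
* **Small spheres**: below roughly the dictionary's second radius, all
  sphere atoms produce near-unity signals on clinical shells, the
  ridge spreads weight across them, and $\hat R$ regresses toward the
  middle of the radius grid — the mechanism behind the systematic
  overestimation of small radii in the resolution study.

## Monte-Carlo oracle

The walker (compiled C++) simulates spins uniformly initialised inside
a sphere with specular wall reflection and sub-step splitting,
accumulating phase $\gamma \int G(t)\cdot x(t)\,dt$ with alternating
sign over the two pulses; the signal is the ensemble mean of
$\cos\phi$, with a standard error from the across-walker variance.
Because the trajectory does not depend on the gradient, one walk
serves every measurement of a scheme.

Defaults: $10^5$ walkers and a time step of $\delta/20$, refined
adaptively so the RMS step never exceeds $R/5$ (for small spheres the
wall curvature, not the pulse, limits the step). With
`adaptive = FALSE` the configured step is used as-is and a
discretisation warning is raised when it violates the $R/5$ rule.
Convergence at the $1/\sqrt{n}$ rate and the free-diffusion limit at
large $R$ are tested. A 1-D walker along seeded random orientations
provides the stick analogue.

## The resolution study

`run_scenario()` sweeps ground-truth sphere radius (1–15 $\mu$m, step
1) × sphere signal fraction (10–100% in the intra-cellular scenario;
10–50% when an extra-cellular tensor takes the remainder at 1:1
sphere:stick) with 100 Rician-noise repetitions per cell at SNR 50.
Noise is applied per measurement (as a scanner produces it) before
spherical averaging, so the powder mean enjoys a direction-count-
dependent effective SNR. Each cell records the **median** fitted
radius across repetitions — the median rather than the mean because
the Rician floor skews individual fits — and is classified
over/acceptable/under against a tolerance $\tau = 2\,\mu$m, about 1.5
dictionary grid steps.

Choices that were genuinely open, and how they were settled:

* **Substrate sphere diffusivity.** By default substrates use
  $D_{is} = 3.0$, matched to the dictionary, so the grids isolate
  protocol resolution. Drawing the substrate diffusivity from a wider
  range (`sphere_D_range = c(0.1, 3)`) is supported and adds model
  mismatch as a further confounder, but as a default it inverts the
  expected protocol ordering (the high-b research shells are punished
  hardest by low-diffusivity spheres) and breaks the monotonicity of
  recovery in sphere fraction, so the matched setting is the shipped
  study condition.
* **Threshold scan bound.** The recoverability threshold at a fraction
  is the smallest radius above which *every* scanned radius stays
  acceptable. The scan stops at the largest dictionary radius
  (12 $\mu$m): a 15 $\mu$m ground truth under a 12 $\mu$m-capped
  dictionary errs by at least $-3\,\mu$m no matter the protocol, so
  including it measures grid truncation, not resolution. The bound is
  an attribute of the grid and can be overridden. The fraction
  threshold mirrors the same "acceptable tail" definition along the
  other axis.
* **Tensor eigenvalues** for the extra-cellular component default to
  $(2.4, 0.8)\,\mu$m$^2$/ms, a typical extra-axonal anisotropy;
  config-exposed.
* **Problem sizes.** A full grid is 150 (or 75) cells × 100
  repetitions, i.e. 7,500–15,000 NNLS fits, and runs in the low
  minutes on one core; the oracle comparisons use $10^5$ walkers
  (standard error $\lesssim 0.003$ on a normalised signal, and far
  smaller at weak attenuation).

## The synthetic cohort

`generate_cohort()` emulates a patient/control study at the
demographic scale of a large single-centre MS cohort: 80 healthy
controls, 98 relapsing-remitting (RRMS) and 56 progressive (PMS)
patients. The printed effect structure it encodes:

* cortical $f_{soma}$ 0.34 ± 0.01 (HC) vs 0.33 ± 0.02 (MS);
* a positive outer-cortical-layer offset largest in PMS and a negative
  inner-layer offset in MS (directions fixed, magnitudes small and
  config-exposed, since only directions are established);
* a +0.03 subpial-vs-leukocortical $\Delta f_{soma}$ shift in RRMS
  only, on a lesion population that is ~7% subpial with a per-patient
  random intercept (SD 0.005) — numerous lesions per patient is what
  motivates the mixed model;
* lesion qT1 and MTsat mixed to population correlations of $-0.5$ and
  $+0.5$ with lesion $f_{soma}$;
* sNfL z-scores from slopes 0.334 per 10 cl white-matter lesion volume
  and 0.738 per 5% lesion $f_{soma}$, unit residual SD, measured in
  113 patients.

The statistical stages mirror the study design: Welch's test for the
whole-cortex contrast, a patient-random-intercept linear mixed model
(ML by default, REML optional; Satterthwaite p-values) for the
lesion-type contrast, Pearson correlations for qMRI, and an OLS sNfL
model with a likelihood-ratio comparison against the $f_{soma}$-free
reduced model.

What passing tests show — and what they do not: the suite verifies
type-I calibration (rejection rates within the binomial 95% interval
of $\alpha = 0.05$ over 500 null replicates), slope recovery (95% CIs
covering the generating slopes in ≥ 90% of 200 replicates at n = 113),
and exact noise-free recovery. Because the generator is Gaussian,
lesion counts are Poisson and covariate effects enter linearly, these
checks validate the *statistical machinery*, not the biological claims;
real cortical data carry partial-volume effects, CSF contamination,
spatial correlation and segmentation error that the generator does not
emulate.

## Known limitations

* No inter-compartment water exchange and no relaxation weighting; a
  single mean soma radius per voxel rather than a distribution.
* GPD model error at strong attenuation (quantified by the built-in
  walker, above); fitted radii near the dictionary cap inherit it.
* Diffusivities are fixed in the dictionary, not estimated; estimates
  in tissue whose diffusivities differ from the atoms' values will be
  biased, which is precisely the degeneracy the resolution study maps.
* The bundled research scheme is representative, not a copy of any
  scanner's table; conclusions that depend on the exact b-range or
  gradient ceiling should be re-run with a site-specific scheme file.
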