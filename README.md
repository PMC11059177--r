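# sandir — soma and neurite density imaging for clinical diffusion MRI

`sandir` implements a simplified SANDI (Soma And Neurite Density
Imaging) pipeline for multi-shell pulsed-gradient spin-echo (PGSE)
diffusion MRI of cortical grey matter, together with the simulation
machinery needed to ask the question every clinical user of SANDI must
ask first: *which soma radii and signal fractions can my protocol
actually resolve?*

It is aimed at diffusion-MRI methods researchers and neuroimaging
groups who want to apply soma-fraction mapping on clinical hardware
(~80 mT/m gradients) and need to quantify, on synthetic ground truth,
how far those estimates can be trusted — and at readers who want to
reproduce the accompanying cohort-level statistics on synthetic data.

## The model

SANDI decomposes the direction-averaged ("powder") diffusion signal of
each voxel into three compartments:

    S̄(b) / S0 = f_neurite · A_stick(b; D_in)
              + f_soma    · A_sphere(G, δ, Δ; R_s, D_is)
              + f_extra   · A_ec(b; D_ec)

* **Sticks** (neurites): `A_stick = √(π/(4bD)) · erf(√(bD))`.
* **Spheres** (cell bodies): Gaussian-phase-distribution (GPD,
  Murday–Cotts/Balinov) attenuation for diffusion restricted in an
  impermeable sphere of radius `R_s`, a function of the gradient
  amplitude G and pulse timings δ, Δ rather than of b alone — this is
  what makes soma size protocol-dependent.
* **Extra-cellular water**: isotropic Gaussian (ball) or axially
  symmetric tensor (zeppelin) compartments.

Fitting follows the AMICO linearisation: the nonlinear model is
expanded into a small dictionary of per-shell powder signals
(1 stick with D = 2.4 μm²/ms, 9 spheres with D = 3.0 μm²/ms and radii
equally spaced over 1.5–12 μm, 3 balls with D ∈ {0.4, 1.6, 3.0}
μm²/ms) and each voxel is solved as Tikhonov-regularised non-negative
least squares. `f_soma` is the sphere-class share of the fitted
weights; the soma-radius point estimate is the weight-weighted mean
sphere radius.

A compiled Monte-Carlo random walker (uniform initialisation, specular
wall reflection, phase accumulation over both gradient pulses) provides
an independent oracle for the analytic sphere signal, and a synthetic
cohort generator reproduces the effect structure of a patient/control
study (group differences in cortical f_soma, lesion-type contrasts,
qMRI correlations, serum neurofilament slopes) for calibrating the
statistical stages.

## Worked example

Simulate one cortical-like voxel on the bundled clinical protocol
(b = 0/700/1000/2000/3000 s/mm², δ/Δ = 19/36 ms) and fit it:

```r
library(sandir)

sch <- prisma_protocol()
sch
#> PGSE acquisition scheme: 149 measurements, 5 shells
#>   b =      0 s/mm2 :  12 directions (G = 0.0 mT/m)
#>   b =    700 s/mm2 :   6 directions (G = 30.2 mT/m)
#>   b =   1000 s/mm2 :  20 directions (G = 36.1 mT/m)
#>   b =   2000 s/mm2 :  45 directions (G = 51.1 mT/m)
#>   b =   3000 s/mm2 :  66 directions (G = 62.6 mT/m)

sub <- substrate(list(
  list(kind = "stick",  fraction = 0.35, diffusivity = 2.4),
  list(kind = "sphere", fraction = 0.45, radius = 7, diffusivity = 3.0),
  list(kind = "tensor", fraction = 0.20, eigenvalues = c(3.0, 3.0))))

sig    <- simulate_substrate_signal(sub, sch, noise_model(50), seed = 7)
powder <- spherical_mean(sig, sch)
round(powder, 4)
#>     b0   b700  b1000  b2000  b3000
#> 1.0000 0.6741 0.6090 0.5064 0.4448

fit <- fit_voxel(powder, build_dictionary(sch))
fit
#> SANDI fit: f_soma=0.596 f_neurite=0.053 f_extra=0.351 R_hat=6.90 um (rmse 1.70e-03)
```

The fitted soma radius (6.90 μm) sits close to the 7 μm ground truth,
while the fractions illustrate the stick/sphere/ball degeneracy of a
5-shell clinical acquisition: the compartment split is much less
identifiable than the radius, which is exactly what the resolution
study quantifies. The full radius × fraction recoverability grid for a
protocol is produced by:

```r
grid <- run_scenario(prisma_protocol(),
                     resolution_config(scenario = "intra", seed = 1))
recovery_threshold_radius(grid, f_s = 50)   # smallest reliable radius (um)
```

A command-line wrapper over the same functions is installed at
`inst/cli/sandi.R` (subcommands `fit`, `simulate`, `resolution-map`,
`cohort-sim`, `cohort-analyze`).

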