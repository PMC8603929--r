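---
title: "Conductivity imaging of brain tumours with crmrept: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductivity imaging of brain tumours with crmrept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmrept)
```

## The measurement and the model

At the Larmor frequency, tissue electrical conductivity $\sigma_H$ (S/m)
reflects the product of ion concentration and mobility. MR electrical
properties tomography (MREPT) estimates it without injected currents from
the transceive RF phase $\phi_{tr}$ measured by a spin-echo sequence. Two
estimators are implemented:

* **Phase-based estimate** — under a piecewise-constant assumption,
  $\sigma_H = \nabla^2\phi_{tr} / (2\mu_0\omega)$, evaluated voxelwise.
  It is local and fast but biased wherever $\nabla\sigma_H \neq 0$.
* **Convection–reaction (cr-MREPT) solve** — writing $u = 1/\sigma_H$,
  $$-c\,\nabla^2 u + \nabla\phi_{tr}\cdot\nabla u + (\nabla^2\phi_{tr})\,u
    = 2\mu_0\omega,$$
  a linear convection–reaction equation in $u$ with an artificial diffusion
  term $c$ that suppresses the node-to-node oscillations of the otherwise
  convection-dominated discrete problem. The factor 2 on the right-hand
  side absorbs the transmit/receive split of the transceive phase; the
  phase is never divided by two anywhere in the package.

The forward model used by the simulator is the divergence-form twin of the
same physics, $\nabla\cdot(\sigma_H^{-1}\nabla\phi_{tr}) = 2\mu_0\omega$,
solved with Dirichlet boundary values. Because forward and inverse operators
describe the same continuum equation, simulated data exercise the full
inverse problem; deliberate model error can be introduced by smoothing the
conductivity before the forward solve. Full-wave electromagnetic simulation
is out of scope.

The operating frequency defaults to $f = 42.577\,\mathrm{MHz/T} \times B_0$,
i.e. ~400 MHz at 9.4 T. All internal mathematics is SI (metres, radians,
S/m); voxel spacing is carried in millimetres and converted at the
boundaries. Grids are indexed (z, y, x), voxel-centred, 0-based in specs.

## Synthetic study conditions

The phantom generator reproduces the acquisition geometry of a preclinical
brain-tumour protocol: one (or more) coronal slices of 128 x 64 voxels at
0.313 x 0.313 mm in-plane and 0.3 mm slice thickness; a multi-spin-echo
train with first echo 8 ms, echo spacing 8 ms, 10 echoes; 4 receive
channels; DWI with b = 0, 1000 and 2000 s/mm^2 along 15
electrostatically-spread directions.

The default six-region phantom assigns literature tissue values for a rat
glioblastoma model at 9.4 T: conductivity (S/m) 0.44 (contralateral
cortex), 0.96 (tumour rim), 0.93 (viable tumour), 0.84 (necrotic core),
0.72 (ventricles), 0.77 (peritumoral edema); mean diffusivity (um^2/ms)
0.69, 0.81, 0.76, 0.89, 1.23, 0.89 for the same regions. The ventricles
are drawn enlarged, consistent with the tumour-induced hydrocephalus such
models develop. The three-session day schedule (days 8, 11, 14 after
implantation) raises tumour conductivity over time while leaving tumour MD
flat, and omits the necrotic core on day 8, when it has not yet formed.

Choices the protocol does not pin down, fixed once here:

* **T2 values** (40–110 ms across tissues) are nuisance parameters that
  only drive the echo-magnitude decay; they are plausible for 9.4 T but
  not measured quantities.
* **Coil model**: four Gaussian-magnitude lobes centred at the in-plane
  corners with smooth low-order polynomial phase offsets. Channel 1 is the
  strongest element and carries the zero-offset convention, so the
  reference offset that referenceless combination necessarily leaves in
  the combined phase is exactly the PDE-consistent transceive phase.
* **Noise**: i.i.d. complex Gaussian per channel/echo; magnitude images are
  therefore Rician. The MSME channel noise default (sd 0.005 for unit M0,
  magnitude SNR ~200 on the strongest channel) is calibrated so that
  per-VOI conductivity spreads match the 0.05–0.25 S/m spreads reported
  for this tissue set; the DWI default (sd 0.02, SNR 50) matches a typical
  respiratory-triggered EPI acquisition.

Every stochastic function takes an explicit seed; the pipeline splits all
stage seeds from one root seed, so a run is reproducible bit for bit.

What the generator does **not** emulate: B1 magnitude inhomogeneity beyond
smooth sensitivity lobes, motion and pulsation, susceptibility or
eddy-current phase, chemical shift, partial volume at slice level, and
inter-animal variability. Passing tests therefore demonstrate correctness
of the numerics and robustness to thermal noise, not robustness to every
artefact of in vivo data.

## Phase processing

**Channel combination** follows a two-step referenceless scheme: the
channel with the highest mean magnitude serves as reference; each
channel's offset map is estimated as the low-pass-filtered (Gaussian,
radius 3 voxels) phase of channel x conj(reference), echoes pooled; offsets
are subtracted and channels summed with magnitude-squared weights. The
residual error of this estimate is concentrated near image borders where
the sensitivity lobes vary fastest.

**Unwrapping** is a quality-guided flood fill with exact congruence: each
voxel's output equals its input plus an integer multiple of 2pi, the
integers are retained, and re-wrapping reproduces the input bitwise.
Disconnected mask components are unwrapped independently and each carries
an arbitrary global 2pi k constant — harmless, since only derivatives of
the phase enter reconstruction. Any field whose true neighbour differences
exceed pi (violating the Itoh condition) is unrecoverable by any
unwrapper; the simulated fields respect it.

**Echo averaging** uses per-voxel weights $w_n = M_n^2 / \sum_k M_k^2$,
the phase-noise-optimal weighting for complex Gaussian noise given that
spin-echo transceive phase is TE-independent in expectation while
magnitudes decay with T2. Weights are returned for audit and sum to one
per voxel.

**Presmoothing**: the combined phase is Gaussian-smoothed (radius 3
voxels) before reconstruction. At 0.3 mm resolution a tissue interface is
a sub-voxel kink in the phase; differentiating an unresolved kink produces
locally inconsistent convection/reaction coefficients whose errors advect
downstream through the solve. Smoothing resolves the interface over a few
voxels at the cost of blur that the erosion step (below) keeps out of the
region statistics. Interior Laplacians of smooth fields are unaffected.

## Discretisation and numerical choices

* Derivatives: 3-point central differences or separable Savitzky–Golay
  local-quadratic filters (radius 2 by default in the pipeline); both are
  exact on quadratics. Voxels within the kernel radius of the grid edge
  are invalid.
* The solve is 2-D per slice by default (slice thickness 0.3 mm is
  comparable to the 0.313 mm in-plane spacing, and the reference workflow
  reconstructs per-slice images); z derivatives switch on automatically
  for grids thick enough to support the kernel.
* Convection is centrally differenced where the local mesh Peclet number
  $|\nabla\phi| h / (2c) \le 2$ and first-order upwinded elsewhere, so
  stability never rests on $c$ alone.
* **Choice of c** (auto mode): $c = 0.25\,h\,q_{25}(|\nabla\phi_{tr}|)$
  per slice — the lower quartile of the in-plane gradient magnitude sets
  the scale, putting the weakly-convected quarter of the domain at
  Peclet <= 2. Sizing c from the gradient *maximum* instead (an obvious
  alternative) over-stabilizes: the maximum lives at the domain corners of
  the roughly quadratic phase, and the resulting diffusion length of ~4
  voxels visibly biases small structures such as the ventricles even
  without noise. The diffusion coefficient remains a single constant per
  slice, as the equation assumes.
* **Boundary condition**: Dirichlet values for $u$ on the ring of the
  differentiable domain, taken from the phase-based estimate after 3x3
  median filtering, Gaussian smoothing (radius 6) and clipping to
  [0.05, 10] S/m. The heavy smoothing prevents phase noise from leaking
  into the solution through the boundary, to which the interior solution
  is sensitive. A user-supplied scalar or array overrides this.
* Non-physical results ($u \le 0$, or $\sigma \ge 10$ S/m) are masked out
  with a warning, never clipped.
* **Erosion**: voxels within a configurable graph distance (default 2, 3
  for the widest-interface phantoms) of any region-label boundary are
  excluded from region statistics, because Laplacian-based reconstruction
  blurs interfaces by construction.

## Diffusion fitting

The tensor is fitted per voxel by ordinary least squares on
$\ln S = \ln S_0 - b\, g^T D g$, both shells entering one mono-exponential
fit (no kurtosis term; with b up to 2000 s/mm^2 this is a deliberate
simplification and matches how a single MD value is usually reported).
The fit is exact on noiseless data; negative eigenvalues, which the linear
fit permits at low SNR, are flagged and propagated rather than clipped.
MD = trace(D)/3 is eigen-decomposition-free. Voxels with non-positive
signal are refitted on their positive subset when it still spans the
design, otherwise masked.

## Region statistics

Summaries report mean, sample SD (n-1) and median per region over valid
voxels. Cross-region and cross-day comparisons use Welch's
unequal-variance two-tailed t-test (pooled-variance available by flag);
Welch is the safer default when nothing guarantees equal variances.
MD–conductivity correlation is Pearson's r with the usual t transform,
computed on per-region per-day means by default (voxel pooling available);
with six regions and three days that is at most 17 pairs, so the default
correlation is a coarse summary by design. No multiple-testing correction
is applied by default, mirroring how such VOI analyses are usually
reported; `p.adjust` on the output columns is one line away.

## Problem sizes used in the tests

The test-suite and acceptance runs use single-slice 128 x 64 grids (the
acquisition matrix), 20–100 seeded replicates for Monte-Carlo properties,
and 10 000 replicates for t-test calibration. These sizes make the whole
suite run in minutes on one CPU while leaving the Monte-Carlo acceptance
margins (e.g. 48/50, 95/100) statistically meaningful.

## Known limitations

* The 2-D per-slice solve ignores through-slice phase curvature; on real
  multi-slice data this biases $\sigma_H$ where anatomy varies rapidly
  across slices.
* Reconstruction quality near tissue interfaces is limited by the
  presmoothing/erosion trade-off; reported region values are interior
  values.
* The boundary ring inherits phase-based bias; regions touching the image
  border would be unreliable (none of the phantom regions do).
* The correlation analysis assumes shared grids; no registration is
  implemented or emulated.
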