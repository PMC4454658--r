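---
title: "Photometric-stereo surface reconstruction and scanner quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photometric-stereo surface reconstruction and scanner quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoscan)
```

## The measurement problem

Quantitative phenotyping of surface structures — reptile scales, insect
ommatidia, skin micro-ornamentation — needs surface geometry at the tens of
micrometres scale over objects centimetres to a metre across. A robotic
multi-light scanner gets there by combining two complementary image-based
reconstructions: multiview stereo, which recovers accurate low-frequency
shape but no micro-relief, and photometric stereo (PS), which recovers
per-pixel surface orientation — hence exquisite micro-relief — but
accumulates a smooth low-frequency bias when the orientations are
integrated. `stereoscan` implements the computational chain between those
raw images and a fused, unbiased, detailed surface, together with the
quality-control analytics such a scanner needs: positional repeatability,
vibration attenuation, and optical resolution budgets. A synthetic-scene
generator stands in for the hardware so every stage is testable.

## The photometric-stereo model

A surface patch with unit normal $n$ and diffuse albedo $\rho$, lit by a
distant light $i$ with unit direction $l_i$ and relative intensity $s_i$,
images as

$$ I_i = \rho \, s_i \max(0, n \cdot l_i). $$

Writing $g = \rho n$, each light contributes one linear equation
$I_i = s_i\, g \cdot l_i$, so three non-coplanar lights determine $g$; the
scanner uses 30 so that corrupted observations can be discarded and noise
averaged down. `estimate_normals()` sorts the per-pixel intensities and
drops the lowest `trim_low` fraction (cast or attached shadows read too
dark) and the highest `trim_high` fraction (specular highlights read too
bright) before solving the normal equations of the remaining system;
$n = g/\lVert g\rVert$ and $\rho = \lVert g\rVert$. The defaults
(`trim_low = 0.2`, `trim_high = 0.1`, `min_lights = 3`) are this package's
choice of the simplest rank-based rejection consistent with removing
shadows and specularities over a 30-light rig; with 30 lights they tolerate
up to six shadowed and three specular observations per pixel. Ties in the
intensity sort break by light index, pixels are marked invalid (never
guessed) when fewer than `min_lights` observations survive, when the
albedo falls below `albedo_floor` ($10^{-6}$ of full scale, rejecting
dark/pure-noise pixels), or when the solved normal faces away from the
camera.

The renderer in `render_stack()` is the exact forward model of this
inverse problem — distant lights, orthographic camera, normals from
central differences of the height field — plus the physical nuisances the
estimator must survive: an optional Blinn-style specular lobe (present
only to exercise the outlier-rejection path, not for physical fidelity),
cast shadows found by ray-marching the height field toward each light at
half-pixel steps, additive Gaussian sensor noise, and quantization
(16-bit by default). Geometry is deterministic; only the noise consumes
the seed. What the synthetic scenes deliberately do *not* model —
near-field light falloff, interreflection, subsurface scattering, Bayer
demosaicing — means a pass on synthetic data bounds algorithmic error
only; real-scanner accuracy additionally depends on those effects and on
calibration quality.

## From normals to heights

`normals_to_gradients()` converts normals to slopes $p = -n_x/n_z$,
$q = -n_y/n_z$, masking pixels with $n_z$ below `min_nz` (default 0.05,
i.e. slopes steeper than about 87°) rather than producing unbounded
gradients. Two integrators are provided because they fail differently:

* `integrate_fourier()` — the frequency-domain least-squares
  (Frankot–Chellappa) projection. It inverts the package's own
  central-difference operator exactly (the transfer function is
  $i\sin\omega$, not $i\omega$), so periodic surfaces round-trip to
  machine precision, but periodicity is assumed: a constant-gradient ramp
  is *not* recoverable, and pure-Nyquist modes (where $\sin\omega = 0$)
  are unobservable and set to zero.
* `integrate_poisson()` — the default. Minimises
  $\sum_\text{edges}(\Delta z - g)^2$ with natural (Neumann) boundary
  conditions; the normal equations diagonalise exactly in the discrete
  cosine basis, so the solve is direct, deterministic, and recovers a
  constant-gradient plane exactly up to the integration constant.

Both in-fill invalid pixels with zero gradients before the global solve
and re-mask afterwards (keeping the solvers dense and deterministic), and
both fix the unobservable integration constant by the zero-mean convention
over valid pixels. The two discretisations differ per mode by a
$\cos^2(\omega/2)$ factor — edge gradients in the Poisson solver are the
mean of the two adjacent pixel slopes — so cross-solver agreement tightens
quadratically with the dominant wavelength; the test suite checks
$10^{-4}$ relative agreement on a 512-pixel-period surface.
`curl_residual()` reports $|\partial p/\partial y - \partial q/\partial x|$
as a per-pixel integrability diagnostic: exactly zero for discrete
gradients of any surface, strictly positive under noise.

## Hybrid fusion

Given an unbiased low-frequency surface $z_{low}$ (resampled multiview
output; resampling is the caller's job) and PS gradients $(p, q)$ on the
same grid, `fuse()` returns the minimiser of the screened-Poisson
objective

$$ \lambda \sum (z - z_{low})^2 \;+\; \sum \lvert \nabla z - (p,q) \rvert^2 , $$

solved in the same DCT basis. Per frequency the result is a convex blend
with PS weight $\mu/(\lambda + \mu)$, $\mu = 2\!-\!2\cos\omega$, so
$\lambda$ sets a crossover wavelength: detail finer than it follows the
gradients, shape coarser than it follows $z_{low}$, and the distance of
the fused surface to $z_{low}$ is provably monotone in $\lambda$. The
default $\lambda = (2\pi/32)^2$ puts the crossover at 32 pixels; choose
the crossover at or below the wavelength where the low-frequency source
stops being trustworthy — when correcting a bias band of wavelength
$\geq 50$ px, a crossover of 64 px preserves the PS detail band to within
a few percent energy. `lowpass_bias()` (a hard radial Fourier cutoff)
both fabricates smooth bias surfaces from seeded random fields and
produces detail-free low-frequency stand-ins from truth surfaces in the
test fixtures.

## Visual hull and scan planning

`carve()` reproduces the baseline silhouette method: a voxel survives iff
its centre projects inside the silhouette in every view that sees it
(nearest-pixel lookup, boundary pixels counting as inside — the hull is
conservative and always contains the object when silhouettes are exact),
and voxels outside all viewing frusta are removed. There is deliberately
no partial-voxel antialiasing; the mode is expected to be much coarser
than photometric reconstruction. `hull_surface()` extracts the boundary
faces as a closed triangle mesh for export. The synthetic silhouette
rasteriser dilates by half a pixel diagonal so that the containment
guarantee survives pixelisation.

`generate_poses()` places cameras on a parametric envelope (half-cylinder
or half-ellipsoid) concentric with an idealised target surface, each
looking along the local inward normal, sampled so nearest-neighbour
footprints on the target overlap by at least the requested fraction
(default 0.6, a configurable choice: multiview matching wants generous
overlap but no standard number exists). Footprints come from the
thin-lens magnification $m = f/(d-f)$; steps are footprint
$\times(1-\text{overlap})$, and because curvature slightly rotates
neighbouring footprints the planner re-verifies the realised overlap with
`estimate_overlap()` (locally planar patch intersection on the target,
Sutherland–Hodgman clipping) and densifies deterministically until it is
met. Poses respect a minimum working distance (default 160 mm, a 105 mm
macro lens's close-focus limit). Robot reachability, joint limits and
collision checking are out of scope — poses are pure geometry.

## Quality-control analytics

**Positional repeatability.** `estimate_shift()` estimates the integer
2-D shift between two images of the same scene by exhaustively minimising,
over the $(2K+1)^2$ window ($K = 50$ by default), the mean Euclidean RGB
distance $\sqrt{\smash{(R_A\!-\!R_B)^2 + (G_A\!-\!G_B)^2 + (B_A\!-\!B_B)^2}}$
over $N \approx 5000$ sampled pixels (8-bit intensity units). This
discrepancy is sometimes written as a bare sum of squared channel
differences; the Euclidean (radical) form is used here so the threshold
$T$ acts on an intensity-scaled distance. Sampling is without
replacement, seeded, and fixed per image pair (cheaper and
lower-variance than resampling at every candidate shift), restricted to
an interior margin of $K$ so every candidate shift is defined. Exact ties in the
minimum break toward the smallest $|X|+|Y|$, then row-major order. Pairs
whose minimal discrepancy exceeds $T = 10$ are flagged and excluded from
`repeatability_stats()`, which is how rotational/axial misalignment — the
translation-only model's blind spot — is kept out of the statistics.
Rotation and scale are deliberately not estimated.

**Vibration attenuation.** `blur_metric()` scores frames on a 0 (sharp) to
1 (blurred) scale by re-blurring: a 9-tap uniform low-pass is applied
horizontally and vertically, and the fraction of neighbour-difference
variation that survives is compared; already-blurred frames lose little
(score near 1), sharp frames lose much (score near 0); the final score is
the larger of the two directions, and a constant frame scores 1 by
convention (it has no sharpness to lose). `fit_attenuation()` subtracts
the basal blur $B_0$ (mean of the last 30 of 150 frames, which are
vibration-free), fits $A e^{-t/T}$ to the earlier frames by nonlinear
least squares from a log-linear start (negative values kept — clipping
would bias the fit), and reports the attenuation time
$t_{att} = T \ln(A/A_{th})$ with $A_{th} = 0.005$, floored at 0; a series
that never exceeds $A_{th}$ gets the conservative $t_{att} = 0.1$ s floor
without fitting.

Two numerical notes on the attenuation fixtures. The blur noise floor is
taken as SD 0.002, because a still camera's normalised blur oscillates
with amplitude never exceeding 0.005 and the maximum of 150 Gaussian draws
sits near $2.7\sigma$. And the recovery tests use a strong-vibration
condition ($A = 0.15$, $T = 0.3$ s, i.e. $t_{att} \approx 1$ s, the
high-velocity end of realistic runs): for weak, fast-decaying vibrations
(say $A = 0.05$, $T = 0.2$ s) only a handful of frames carry signal and
the Cramér–Rao bound alone puts the relative scatter of $\hat T$ at
4–5 percent, so no estimator can certify 5 percent recovery there — the
implementation runs within about 1.3× of that bound.

**Optics calculators.** `usaf_resolution()` implements
$R = 2^{\text{group} + (\text{element}-1)/6}$ lp/mm with the line-pair
period $1000/R$ µm at 1:1; `depth_of_field()` the symmetrical-lens
quotient $2sNcf^2(s-f) / (f^4 - N^2c^2(s-f)^2)$ with an explicit error
once the denominator leaves the valid (pre-hyperfocal) regime; and
`nyquist_feature()` the sampling limit $2 \times$ pixel pitch /
magnification.

## Problem sizes and reproducibility

The test suite renders 256² image stacks under 30 lights for the
photometric-stereo accuracy checks, 128² surfaces for fusion, 48³ voxel
grids over 22 views for the hull, and full $K = 50$ shift searches on
160² RGB fixtures — sizes at which every property is measurable in
seconds while leaving the algorithms nothing to hide behind. All
randomness flows through explicit seeds; identical seeds give identical
scenes bit for bit, and differing seeds change only noise, never
geometry. Heights and pitches are carried in micrometres throughout;
mesh export (`write_mesh()`) converts to millimetres at a single point.

## Known limitations

Uncalibrated photometric stereo (unknown light directions), near-field
falloff correction, per-channel colour normals, mesh-domain (as opposed
to height-field) fusion, rotational/scale image registration, and raw
sensor formats are all out of scope. The distant-light approximation of a
near-field LED ring is a modelling choice: at a 16 cm working distance the
direction error across a small field of view is small but not zero, and
it is one of the real-data effects the synthetic suite does not measure.
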