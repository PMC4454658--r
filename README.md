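# stereoscan

Surface reconstruction and quality control for robotic multi-light 3D
scanners used in quantitative phenotyping — recovering the
micro-geometry of biological surfaces (reptile scales, insect ommatidia,
calibrated microsphere targets) from photographs taken under many
calibrated illumination directions.

The package implements the full computational chain such a scanner needs,
with a synthetic-scene generator standing in for the hardware:

* **Photometric stereo** — per-pixel surface normals and albedo from an
  image stack under L ≥ 3 non-coplanar directional lights, by inverting
  the Lambertian model *I&#8342; = ρ s&#8342; max(0, n·l&#8342;)* with
  rank-based rejection of shadowed (lowest fraction) and specular
  (highest fraction) observations per pixel.
* **Normal integration** — Frankot–Chellappa frequency-domain and
  Poisson/Neumann (DCT-diagonalised) least-squares solvers turning
  gradient fields into height fields, with a curl-residual integrability
  diagnostic.
* **Hybrid fusion** — the screened-Poisson blend
  *min&#8343; λ Σ(z − z_low)² + Σ|∇z − (p,q)|²* that merges unbiased
  low-frequency geometry (e.g. multiview stereo) with the high-frequency
  photometric gradients into one unbiased, detailed surface.
* **Visual hull** — voxel carving from calibrated silhouettes, with
  closed-mesh surface extraction.
* **Scan planning** — camera poses on concentric parametric envelopes
  (half-cylinder / half-ellipsoid) with guaranteed footprint overlap
  between neighbouring views.
* **Quality control** — exhaustive integer-shift estimation for
  positional repeatability (mean Euclidean RGB discrepancy, exclusion
  threshold T = 10), a no-reference re-blurring metric with exponential
  vibration-attenuation fitting (*t_att = T ln(A/A_th)*), and the optics
  calculators: USAF-1951 resolving power
  *R = 2^(group + (element−1)/6)* lp/mm, symmetrical-lens depth of field
  *2sNcf²(s−f) / (f⁴ − N²c²(s−f)²)*, and the Nyquist feature-size limit
  *2 × pixel pitch / magnification*.

## Worked example

Render a calibrated target under a 30-LED rig, recover its normals, and
integrate them back into a surface:

```r
library(stereoscan)

rig <- ring_light_rig()                      # 30 lights on 3 rings
spec <- scene_spec("sphere_cap", nrow = 128, ncol = 128, pitch = 4.9,
                   diameter_um = 400, cap_height_um = 50,
                   noise_sd = 0.002, seed = 1)
truth <- make_height_field(spec)
stack <- render_stack(truth, rig, spec)
stack
#> <image_stack> 30 lights x 128 x 128 px, pitch 4.9 um

nf <- estimate_normals(stack, trim_low = 0.2, trim_high = 0.1)
surface <- integrate_poisson(normals_to_gradients(nf))
surface
#> <height_field> 128 x 128 px, pitch 4.9 um, z in [-3.714, 46.26] um (0 invalid px)

err <- normal_angle_error(nf, surface_normals(truth))
median(err[nf$valid])                        # 0.064 degrees
d <- surface$heights - truth$heights; d <- d - mean(d)
sqrt(mean(d^2))                              # 0.070 um height RMSE
```

A median normal error of 0.06° and a height RMSE of 0.07 µm (0.14 % of
the 50 µm relief) on a noisy 16-bit stack show the estimator and
integrator operating at the sensor's quantization floor. The QC
calculators give the scanner's resolution budget directly:

```r
usaf_resolution(6, 4)
#> $lp_mm      90.50967      # finest resolved three-bar pattern
#> $period_um  11.04854      # line-pair period at 1:1

depth_of_field(s = 400, N = 32)
#> 6.85                      # mm of sharp focus at f/32, 40 cm

fit_attenuation(make_blur_series(A = 0.15, T_decay = 0.3,
                                 noise_sd = 0.002, seed = 1))
#> <attenuation_fit> A = 0.1498, T = 0.3082 s, t_att = 1.048 s
```

`vignettes/photometric-stereo-scanning.Rmd` documents the models, the
numerical choices and the limits of what the synthetic tests demonstrate.

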