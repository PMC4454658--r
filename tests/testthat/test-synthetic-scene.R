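test_that("height-field generators match their closed forms", {
  flat <- make_height_field(scene_spec("flat", nrow = 64, ncol = 64,
                                       pitch = 4.9))
  expect_true(all(flat$heights == 0))
  expect_equal(flat$pitch, 4.9)

  ## hemisphere cap: max height = radius at the centre, circular support
  sp <- scene_spec("sphere_cap", nrow = 65, ncol = 65, pitch = 1,
                   diameter_um = 40)
  hf <- make_height_field(sp)
  expect_equal(max(hf$heights), 20)
  expect_equal(hf$heights[33, 33], 20)
  ## independent closed form: z = sqrt(r^2 - d^2) at distance d from centre
  x <- (1:65) - 33
  d2 <- outer(x^2, x^2, `+`)
  expected <- sqrt(pmax(400 - d2, 0))
  expect_equal(hf$heights, expected, tolerance = 1e-12)
  expect_true(all(hf$heights[d2 > 400] == 0))

  ## monolayer: peaks along a lattice row are spaced one sphere diameter
  spm <- scene_spec("microsphere_monolayer", nrow = 96, ncol = 96,
                    pitch = 2, diameter_um = 40)
  hm <- make_height_field(spm)
  ## top of a resting sphere is twice the radius (apex may fall off-grid)
  expect_equal(max(hm$heights), 40, tolerance = 1e-2)
  rmax <- which(hm$heights == max(hm$heights), arr.ind = TRUE)[1, 1]
  prof <- hm$heights[rmax, ]
  pk <- which(prof > 39 &
                prof >= c(-Inf, prof[-96]) & prof >= c(prof[-1], -Inf))
  expect_gt(length(pk), 2)
  spacing <- diff(pk) * 2 # um
  expect_equal(spacing, rep(40, length(spacing)), tolerance = 0.06)
})

test_that("three-bar target encodes USAF bar widths", {
  sp <- scene_spec("three_bar_target", nrow = 160, ncol = 160, pitch = 5,
                   group = 2, element = 1, bar_height_um = 5)
  hf <- make_height_field(sp)
  ## group 2 element 1: R = 4 lp/mm -> 250 um line pair -> 125 um bars,
  ## i.e. 25 px at 5 um pitch
  mid <- hf$heights[80, ]
  runs <- rle(mid > 0)
  bar_px <- runs$lengths[runs$values]
  expect_equal(length(bar_px), 3)
  expect_equal(bar_px, rep(25, 3), tolerance = 0.05)
})

test_that("geometry is seed-independent and noise is seed-reproducible", {
  s1 <- scene_spec("sinusoid", nrow = 32, ncol = 32, noise_sd = 0.01,
                   seed = 1, amplitude_um = 3, period_x_um = 40)
  s2 <- scene_spec("sinusoid", nrow = 32, ncol = 32, noise_sd = 0.01,
                   seed = 2, amplitude_um = 3, period_x_um = 40)
  expect_identical(make_height_field(s1)$heights,
                   make_height_field(s2)$heights)
  rig <- rig4()
  hf <- make_height_field(s1)
  expect_identical(render_stack(hf, rig, s1)$pixels,
                   render_stack(hf, rig, s1)$pixels)
  expect_false(identical(render_stack(hf, rig, s1)$pixels,
                         render_stack(hf, rig, s2)$pixels))
})

test_that("rendering follows the Lambertian forward model", {
  sp <- scene_spec("flat", nrow = 8, ncol = 8, bits = 0)
  hf <- make_height_field(sp)
  ## light along the surface normal: every pixel exactly 1
  st <- render_stack(hf, light_rig(matrix(c(0, 0, 1), 1)), sp)
  expect_true(all(st$pixels == 1))
  ## light in the surface plane: clamped to 0
  st0 <- render_stack(hf, light_rig(matrix(c(1, 0, 0), 1)), sp)
  expect_true(all(st0$pixels == 0))

  ## oblique light on a sphere cap matches the analytic n . l
  spc <- scene_spec("sphere_cap", nrow = 64, ncol = 64, pitch = 1,
                    diameter_um = 200, cap_height_um = 30, bits = 0)
  hfc <- make_height_field(spc)
  l <- c(0.3, -0.2, 0.933)
  l <- l / sqrt(sum(l^2))
  st <- render_stack(hfc, light_rig(matrix(l, 1)), spc)
  ## analytic normal of the sphere: (x, y, z + r - h) / r on the cap
  x <- (1:64) - 32.5
  r <- 100; h <- 30
  xx <- matrix(x, 64, 64)
  yy <- t(xx)
  zz <- hfc$heights + (r - h)
  on_cap <- hfc$heights > 2 # away from the rim where the substrate kinks
  ndotl <- (xx * l[1] + yy * l[2] + zz * l[3]) / r
  expect_lt(max(abs(st$pixels[1, , ][on_cap] - pmax(ndotl, 0)[on_cap])),
            0.02) # central differences vs analytic slope
})

test_that("rendered intensities stay within physical bounds", {
  rig <- rig6()
  for (kind in c("sinusoid", "sphere_cap")) {
    sp <- scene_spec(kind, nrow = 32, ncol = 32, pitch = 2, albedo = 0.7,
                     bits = 0, diameter_um = 50, amplitude_um = 4,
                     period_x_um = 16)
    st <- render_stack(make_height_field(sp), rig, sp)
    expect_gte(min(st$pixels), 0)
    expect_lte(max(st$pixels), 0.7 + 1e-12)
  }
})

test_that("cast shadows appear behind an occluding wall", {
  ## a tall wall on a flat floor, light from the low +x direction
  z <- matrix(0, 48, 48)
  z[20:22, ] <- 100
  hf <- height_field(z, pitch = 1)
  sp <- scene_spec("flat", nrow = 48, ncol = 48, bits = 0,
                   cast_shadows = TRUE)
  l <- c(1, 0, 0.4); l <- l / sqrt(sum(l^2))
  st <- render_stack(hf, light_rig(matrix(l, 1)), sp)
  ## the light sits toward +x, so floor beyond the wall (rows > 22) faces
  ## it unobstructed while floor at rows < 20 lies in the cast shadow
  expect_gt(st$pixels[1, 30, 24], 0.3)
  expect_equal(st$pixels[1, 10, 24], 0)
  ## without shadowing the same pixel is lit
  sp2 <- scene_spec("flat", nrow = 48, ncol = 48, bits = 0)
  expect_gt(render_stack(hf, light_rig(matrix(l, 1)), sp2)$pixels[1, 10, 24],
            0.3)
})

test_that("shifted pairs follow the row/column shift convention", {
  set.seed(42)
  img <- matrix(runif(100 * 120), 100, 120)
  pr <- make_shifted_pair(img, 0, 0)
  expect_identical(pr$a, pr$b)
  ## content of A at (r, c) appears at (r + dx, c + dy) in B
  pr <- make_shifted_pair(img, 3, -12)
  expect_equal(pr$b[60 + 3, 60 - 12], pr$a[60, 60])
  ## exhaustive oracle: only the true shift gives zero discrepancy
  samp <- as.matrix(expand.grid(30:70, 30:70))
  expect_equal(shift_discrepancy(pr$a, pr$b, 3, -12, samp), 0)
  others <- vapply(c(-2, 0, 2), function(dx)
    shift_discrepancy(pr$a, pr$b, dx, -12 + dx, samp), numeric(1))
  expect_true(all(others > 1))
  expect_error(make_shifted_pair(img, 150, 0), "exceeds")
})

test_that("blur series realise the decaying-exponential model", {
  bs <- make_blur_series(A = 0, T_decay = 1, B0 = 0.25)
  expect_true(all(bs$values == 0.25))
  expect_length(bs$values, 150) # 30 fps x 5 s
  bs2 <- make_blur_series(A = 0.05, T_decay = 0.2, B0 = 0.3)
  ## closed form at t = T: B0 + A / e
  i <- which.min(abs(bs2$times - 0.2))
  expect_equal(bs2$values[i], 0.3 + 0.05 * exp(-1), tolerance = 1e-12)
  expect_identical(make_blur_series(0.05, 0.2, noise_sd = 0.01, seed = 9),
                   make_blur_series(0.05, 0.2, noise_sd = 0.01, seed = 9))
  expect_true(all(bs2$values >= 0 & bs2$values <= 1))
})

test_that("rendering then estimating normals closes the loop", {
  ## the renderer's central-difference normals are recovered by the
  ## estimator with no noise, shadows or trimming
  rig <- rig6()
  sp <- scene_spec("sinusoid", nrow = 48, ncol = 48, pitch = 2, bits = 0,
                   amplitude_um = 6, period_x_um = 32, period_y_um = 24)
  hf <- make_height_field(sp)
  nf <- estimate_normals(render_stack(hf, rig, sp), trim_low = 0,
                         trim_high = 0)
  err <- normal_angle_error(nf, surface_normals(hf))
  expect_lt(max(err[nf$valid]), 1e-5)
})
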