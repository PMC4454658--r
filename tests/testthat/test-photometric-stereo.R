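test_that("rig conditioning flags coplanar light sets", {
  ## three lights in the plane z = x + y through the origin
  d <- rbind(c(1, 0, 1), c(0, 1, 1), c(0.5, 0.5, 1))
  d <- d / sqrt(rowSums(d^2))
  rc <- rig_condition(light_rig(d))
  expect_equal(rc$rank, 2)
  expect_true(rc$deficient)
  expect_equal(rig_condition(light_rig(diag(3)))$condition, 1)
  rc30 <- rig_condition(ring_light_rig())
  expect_equal(rc30$rank, 3)
  expect_false(rc30$deficient)
})

test_that("estimation inverts the forward model exactly on clean data", {
  ## flat Lambertian, 4 lights: normals (0,0,1), albedo 1 everywhere
  sp <- scene_spec("flat", nrow = 12, ncol = 12, bits = 0)
  nf <- estimate_normals(render_stack(make_height_field(sp), rig4(), sp),
                         trim_low = 0, trim_high = 0)
  expect_true(all(nf$valid))
  expect_equal(max(abs(nf$normals[, , 3] - 1)), 0)
  expect_equal(max(abs(nf$albedo - 1)), 0, tolerance = 1e-12)

  ## known oblique normal (0.6, 0, 0.8), albedo 0.5: plane z = -0.75 x
  pitch <- 2
  z <- outer((1:16) * pitch * (-0.75), rep(0, 16), `+`)
  hf <- height_field(z, pitch)
  sp2 <- scene_spec("flat", nrow = 16, ncol = 16, albedo = 0.5, bits = 0)
  nf2 <- estimate_normals(render_stack(hf, rig6(), sp2),
                          trim_low = 0, trim_high = 0)
  ## interior pixels carry the exact central-difference slope
  expect_equal(nf2$normals[8, 8, ], c(0.6, 0, 0.8), tolerance = 1e-9)
  expect_equal(nf2$albedo[8, 8], 0.5, tolerance = 1e-9)
})

test_that("intensity-rank trimming rejects shadows and speculars", {
  rig <- ring_light_rig()
  sp <- scene_spec("sphere_cap", nrow = 96, ncol = 96, pitch = 2, bits = 0,
                   diameter_um = 160, cap_height_um = 30)
  hf <- make_height_field(sp)
  st <- corrupt_stack(render_stack(hf, rig, sp), n_shadow = 5, n_spec = 3,
                      noise_sd = 0.01, seed = 21)
  nf <- estimate_normals(st, trim_low = 0.2, trim_high = 0.1)
  err <- normal_angle_error(nf, surface_normals(hf))
  expect_lt(median(err[nf$valid], na.rm = TRUE), 2)
  expect_true(all(nf$used_lights[nf$valid] >= 3))
})

test_that("albedo scales with intensity while normals are unchanged", {
  rig <- rig6()
  sp <- scene_spec("sinusoid", nrow = 24, ncol = 24, pitch = 2, bits = 0,
                   amplitude_um = 4, period_x_um = 24)
  st <- render_stack(make_height_field(sp), rig, sp)
  nf1 <- estimate_normals(st, trim_low = 0, trim_high = 0)
  st2 <- image_stack(st$pixels * 0.37, rig, st$pitch)
  nf2 <- estimate_normals(st2, trim_low = 0, trim_high = 0)
  expect_equal(nf2$albedo, nf1$albedo * 0.37, tolerance = 1e-12)
  expect_equal(nf2$normals, nf1$normals, tolerance = 1e-12)
})

test_that("light order does not affect the solution", {
  rig <- ring_light_rig()
  sp <- scene_spec("sphere_cap", nrow = 32, ncol = 32, pitch = 2, bits = 0,
                   diameter_um = 60, cap_height_um = 15, noise_sd = 0.01,
                   seed = 4)
  st <- render_stack(make_height_field(sp), rig, sp)
  perm <- c(17:30, 1:16)
  rig_p <- light_rig(rig$directions[perm, ], rig$intensities[perm])
  st_p <- image_stack(st$pixels[perm, , ], rig_p, st$pitch)
  nf <- estimate_normals(st)
  nf_p <- estimate_normals(st_p)
  expect_equal(nf_p$normals, nf$normals, tolerance = 1e-12)
  expect_equal(nf_p$albedo, nf$albedo, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged, not mis-solved", {
  ## coplanar rig is a hard error
  d <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2), c(2, 1, 3))
  d <- d / sqrt(rowSums(d^2)) # all satisfy z = x + y
  st <- image_stack(array(0.5, c(4, 4, 4)), light_rig(d), 1)
  expect_error(estimate_normals(st), "rank")

  ## an all-dark pixel is invalid, not an error
  sp <- scene_spec("flat", nrow = 8, ncol = 8, bits = 0)
  st2 <- render_stack(make_height_field(sp), rig4(), sp)
  st2$pixels[, 3, 5] <- 0
  nf <- estimate_normals(st2, trim_low = 0, trim_high = 0)
  expect_false(nf$valid[3, 5])
  expect_true(all(is.na(nf$normals[3, 5, ])))
  expect_true(all(nf$valid[-(8 * 4 + 3)]))
})

test_that("noiseless accuracy holds across surfaces and rigs", {
  for (rig in list(rig4(), rig6(), ring_light_rig())) {
    for (kind in c("sinusoid", "sphere_cap")) {
      sp <- scene_spec(kind, nrow = 40, ncol = 40, pitch = 2, bits = 0,
                       diameter_um = 70, cap_height_um = 20,
                       amplitude_um = 5, period_x_um = 26, period_y_um = 40)
      hf <- make_height_field(sp)
      nf <- estimate_normals(render_stack(hf, rig, sp), trim_low = 0,
                             trim_high = 0)
      err <- normal_angle_error(nf, surface_normals(hf))
      expect_lt(median(err[nf$valid]), 0.1)
    }
  }
})
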