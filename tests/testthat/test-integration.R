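test_that("normals convert to slopes with grazing pixels masked", {
  n <- array(0, c(4, 4, 3))
  n[, , 3] <- 1
  n[2, 2, ] <- c(0.6, 0, 0.8)
  n[3, 3, ] <- c(0, 0.8, 0.6)
  n[4, 4, ] <- c(sqrt(1 - 0.03^2), 0, 0.03) # grazing, below the floor
  nf <- structure(list(normals = n, valid = matrix(TRUE, 4, 4), pitch = 1),
                  class = "normal_field")
  g <- normals_to_gradients(nf, min_nz = 0.05)
  expect_equal(g$p[2, 2], -0.75)
  expect_equal(g$q[2, 2], 0)
  expect_equal(g$q[3, 3], -0.8 / 0.6)
  expect_false(g$valid[4, 4])
  expect_true(all(g$valid[-16]))
  expect_equal(g$p[1, 1], 0)
})

test_that("Fourier integration inverts periodic gradients to machine precision", {
  z0 <- integrate_fourier(gradient_field(matrix(0, 16, 16),
                                         matrix(0, 16, 16), 1))
  expect_true(all(z0$heights == 0))
  ## periodic product surface, circular central-difference gradients
  sp <- scene_spec("sinusoid", nrow = 64, ncol = 96, pitch = 1,
                   amplitude_um = 5, period_x_um = 16, period_y_um = 24)
  hf <- make_height_field(sp)
  z <- integrate_fourier(height_gradients(hf, circular = TRUE))
  expect_lt(max(abs(z$heights - (hf$heights - mean(hf$heights)))) / 5, 1e-6)
})

test_that("Poisson integration recovers a constant-gradient plane", {
  g <- gradient_field(matrix(0.3, 24, 30), matrix(-0.12, 24, 30), pitch = 2)
  z <- integrate_poisson(g)
  truth <- outer((1:24) * 2 * 0.3, (1:30) * 2 * -0.12, `+`)
  expect_equal(z$heights, truth - mean(truth), tolerance = 1e-10)
  z0 <- integrate_poisson(gradient_field(matrix(0, 8, 8),
                                         matrix(0, 8, 8), 1))
  expect_equal(max(abs(z0$heights)), 0, tolerance = 1e-12)
  expect_error(integrate_poisson(gradient_field(matrix(0, 1, 1),
                                                matrix(0, 1, 1), 1)))
})

test_that("the two integrators agree on smooth periodic surfaces", {
  ## the solvers discretise gradients differently (spectral central
  ## difference vs edge-averaged forward difference); the per-mode ratio is
  ## cos^2(w/2), so agreement is tested on a long-period surface
  sp <- scene_spec("sinusoid", nrow = 512, ncol = 512, pitch = 1,
                   amplitude_um = 5, period_x_um = 512, period_y_um = 512)
  g <- height_gradients(make_height_field(sp), circular = TRUE)
  zf <- integrate_fourier(g)
  zp <- integrate_poisson(g)
  expect_lt(rmse_free(zf$heights, zp$heights) /
              sqrt(mean(zf$heights^2)), 1e-4)
})

test_that("integration is linear in the gradients", {
  set.seed(8)
  mk <- function(seed) {
    set.seed(seed)
    hf <- height_field(gauss_blur(matrix(rnorm(32 * 32), 32), 2), 1)
    height_gradients(hf)
  }
  g1 <- mk(1); g2 <- mk(2)
  gc <- gradient_field(2 * g1$p - 0.5 * g2$p, 2 * g1$q - 0.5 * g2$q, 1)
  z1 <- integrate_poisson(g1)$heights
  z2 <- integrate_poisson(g2)$heights
  zc <- integrate_poisson(gc)$heights
  expect_equal(zc, 2 * z1 - 0.5 * z2, tolerance = 1e-9)
  ## zero-mean convention over valid pixels
  expect_equal(mean(zc), 0, tolerance = 1e-12)
  expect_equal(mean(integrate_fourier(g1)$heights), 0, tolerance = 1e-12)
})

test_that("sphere-cap round trip through rendering and estimation", {
  rig <- ring_light_rig()
  sp <- scene_spec("sphere_cap", nrow = 96, ncol = 96, pitch = 2, bits = 0,
                   diameter_um = 200, cap_height_um = 24)
  hf <- make_height_field(sp)
  nf <- estimate_normals(render_stack(hf, rig, sp), trim_low = 0,
                         trim_high = 0)
  z <- integrate_poisson(normals_to_gradients(nf))
  expect_lt(rmse_free(z$heights, hf$heights) / 24, 0.02)
})

test_that("curl residual separates integrable from rotational fields", {
  ## exact discrete gradients of any surface are curl-free
  sp <- scene_spec("sinusoid", nrow = 32, ncol = 32, pitch = 2,
                   amplitude_um = 4, period_x_um = 20, period_y_um = 12)
  g <- height_gradients(make_height_field(sp))
  expect_lt(curl_residual(g)$mean, 1e-10)
  ## p = y, q = 0 has unit curl on the interior
  p <- matrix(rep(1:20, each = 20), 20, 20)
  cr <- curl_residual(gradient_field(p, matrix(0, 20, 20), 1))
  expect_equal(cr$residual[2:19, 2:19], matrix(1, 18, 18))
  expect_true(all(is.na(cr$residual[1, ])))
  ## noise strictly increases the residual
  set.seed(3)
  gn <- gradient_field(g$p + rnorm(1024, sd = 0.05),
                       g$q + rnorm(1024, sd = 0.05), 2)
  expect_gt(curl_residual(gn)$mean, curl_residual(g)$mean)
})
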