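# Standard fusion fixture: a bumpy "scale field" truth, its low-pass
# version standing in for unbiased coarse geometry, and photometric
# gradients corrupted by a smooth low-frequency bias surface.
fusion_fixture <- function(n = 128, bias_sd = 8, seed = 2) {
  spb <- scene_spec("microsphere_monolayer", nrow = n, ncol = n,
                    pitch = 4.9, diameter_um = 40)
  truth <- make_height_field(spb)
  low <- lowpass_bias(truth, cutoff = 0.03)
  set.seed(seed)
  bias <- lowpass_bias(height_field(matrix(rnorm(n * n), n), 4.9),
                       cutoff = 0.02)
  bias$heights <- bias$heights / stats::sd(bias$heights) * bias_sd
  biased <- height_field(truth$heights + bias$heights, 4.9)
  list(truth = truth, low = low, bias = bias,
       ps_grad = height_gradients(biased))
}

test_that("gradients of the low surface reproduce it for any lambda", {
  fx <- fusion_fixture(64)
  gl <- height_gradients(fx$low)
  rng <- diff(range(fx$low$heights))
  for (lam in c(0.01, 0.4, 50)) {
    fused <- fuse(fx$low, gl, lam)
    expect_lt(rmse_free(fused$heights, fx$low$heights) / rng, 1e-3)
  }
})

test_that("fusion beats both inputs on biased synthetic scans", {
  fx <- fusion_fixture()
  fused <- fuse(fx$low, fx$ps_grad)
  ps_only <- integrate_poisson(fx$ps_grad)
  r_fused <- rmse_free(fused$heights, fx$truth$heights)
  r_ps <- rmse_free(ps_only$heights, fx$truth$heights)
  r_low <- rmse_free(fx$low$heights, fx$truth$heights)
  expect_lt(r_fused, r_ps)
  expect_lt(r_fused, r_low)
})

test_that("large lambda pins the fusion to the low-frequency input", {
  fx <- fusion_fixture(64)
  fused <- fuse(fx$low, fx$ps_grad, lambda_lf = 1e6)
  expect_lt(rmse_free(fused$heights, fx$low$heights) /
              diff(range(fx$low$heights)), 1e-3)
})

test_that("distance to the low surface is monotone in lambda", {
  fx <- fusion_fixture(96)
  lams <- 10^seq(-3, 2, by = 1)
  r <- vapply(lams, function(l)
    rmse_free(fuse(fx$low, fx$ps_grad, l)$heights, fx$low$heights),
    numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("fusion is deterministic and preserves high-frequency detail", {
  fx <- fusion_fixture()
  f1 <- fuse(fx$low, fx$ps_grad)
  f2 <- fuse(fx$low, fx$ps_grad)
  expect_identical(f1$heights, f2$heights)
  ## with the crossover placed below the bias band (64 px crossover for a
  ## 50 px-wavelength bias cutoff), the energy above the cutoff matches
  ## the PS-only integration within 5%
  hipass_energy <- function(z, cutoff = 0.02) {
    H <- nrow(z); W <- ncol(z)
    fx_ <- (0:(H - 1)) / H; fx_ <- pmin(fx_, 1 - fx_)
    fy_ <- (0:(W - 1)) / W; fy_ <- pmin(fy_, 1 - fy_)
    fr <- sqrt(outer(fx_^2, fy_^2, `+`))
    Z <- stats::fft(z)
    sum(Mod(Z[fr > cutoff])^2)
  }
  ps_only <- integrate_poisson(fx$ps_grad)
  f_lo <- fuse(fx$low, fx$ps_grad, lambda_lf = (2 * pi / 64)^2)
  e_f <- hipass_energy(f_lo$heights)
  e_p <- hipass_energy(ps_only$heights)
  expect_lt(abs(e_f - e_p) / e_p, 0.05)
})

test_that("low-pass filtering is idempotent on its stated band", {
  set.seed(7)
  field <- height_field(matrix(rnorm(64 * 64), 64), 1)
  lp <- lowpass_bias(field, cutoff = 0.1)
  ## power above the cutoff is removed entirely
  Z <- stats::fft(lp$heights)
  f <- (0:63) / 64; f <- pmin(f, 1 - f)
  fr <- sqrt(outer(f^2, f^2, `+`))
  expect_lt(sum(Mod(Z[fr > 0.1])^2) / sum(Mod(Z)^2), 0.01)
  ## near-zero cutoff leaves only the constant mean
  lp0 <- lowpass_bias(field, cutoff = 1e-6)
  expect_equal(max(abs(lp0$heights - mean(field$heights))), 0,
               tolerance = 1e-9)
  ## deterministic
  expect_identical(lowpass_bias(field, 0.1)$heights, lp$heights)
  expect_error(lowpass_bias(field, 0.6), "Nyquist")
})

test_that("fusion rejects mismatched grids and weights", {
  fx <- fusion_fixture(64)
  small <- height_field(matrix(0, 16, 16), 4.9)
  expect_error(fuse(small, fx$ps_grad), "mismatch")
  expect_error(fuse(fx$low, fx$ps_grad, lambda_lf = 0), "lambda")
})
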