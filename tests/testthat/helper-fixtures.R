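# Shared fixtures, built in code.

# Offset-free root-mean-square difference between two height matrices.
rmse_free <- function(a, b) {
  d <- a - b
  d <- d - mean(d)
  sqrt(mean(d^2))
}

# Small non-coplanar rigs.
rig4 <- function() {
  light_rig(rbind(c(0, 0, 1), c(0.5, 0, 1), c(0, 0.5, 1),
                  c(-0.4, -0.4, 1)) /
              sqrt(c(1, 1.25, 1.25, 1.32)))
}

rig6 <- function() {
  th <- 2 * pi * (0:5) / 6
  light_rig(cbind(0.5 * cos(th), 0.5 * sin(th), rep(sqrt(0.75), 6)))
}

# Separable Gaussian blur with replicate padding (independent of the
# package's 9-tap metric filter).
gauss_blur <- function(m, sigma, half = 15L) {
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
              m[rep(nrow(m), half), , drop = FALSE])
  m2 <- apply(mp, 2, function(v) stats::filter(v, k))
  m2 <- m2[(half + 1):(half + nrow(m)), , drop = FALSE]
  mp <- cbind(m2[, rep(1L, half), drop = FALSE], m2,
              m2[, rep(ncol(m2), half), drop = FALSE])
  m3 <- t(apply(mp, 1, function(v) stats::filter(v, k)))
  m3[, (half + 1):(half + ncol(m)), drop = FALSE]
}

# Corrupt a rendered stack: per pixel, zero `n_shadow` randomly chosen
# observations and saturate `n_spec`, then add Gaussian noise.
corrupt_stack <- function(stack, n_shadow, n_spec, noise_sd, seed) {
  d <- dim(stack$pixels)
  L <- d[1]; npx <- d[2] * d[3]
  I <- matrix(aperm(stack$pixels, c(2, 3, 1)), npx, L)
  set.seed(seed)
  for (i in seq_len(npx)) {
    idx <- sample.int(L, n_shadow + n_spec)
    if (n_shadow > 0) I[i, idx[seq_len(n_shadow)]] <- 0
    if (n_spec > 0) I[i, idx[n_shadow + seq_len(n_spec)]] <- 1
  }
  if (noise_sd > 0) I <- I + stats::rnorm(length(I), sd = noise_sd)
  I <- pmax(I, 0)
  image_stack(aperm(array(I, c(d[2], d[3], L)), c(3, 1, 2)),
              stack$rig, stack$pitch)
}

# Equatorial + polar camera ring around the origin with spherical
# silhouettes of a ball, for hull tests.
sphere_views <- function(n_equatorial, radius, with_poles = TRUE,
                         dist = 150, img = c(240L, 240L)) {
  poses <- lapply(seq_len(n_equatorial), function(i) {
    a <- 2 * pi * (i - 1) / n_equatorial
    look_at_pose(dist * c(cos(a), sin(a), 0), c(0, 0, 0), focal_mm = 50,
                 pixel_pitch_um = 100, image_size = img)
  })
  if (with_poles) {
    poses <- c(poses, list(
      look_at_pose(c(0, 1e-4, dist), c(0, 0, 0), 50, 100, img, up = c(1, 0, 0)),
      look_at_pose(c(0, 1e-4, -dist), c(0, 0, 0), 50, 100, img, up = c(1, 0, 0))))
  }
  masks <- lapply(poses, render_sphere_silhouette, center = c(0, 0, 0),
                  radius = radius)
  silhouette_set(masks, poses)
}
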