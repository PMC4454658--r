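#' Gradient field container
#'
#' Per-pixel surface slopes `p = dz/dx` (row direction) and `q = dz/dy`
#' (column direction), dimensionless (micrometre per micrometre), with the
#' pixel pitch and a validity mask.
#'
#' @param p,q Numeric matrices of slopes.
#' @param pitch Pixel pitch in micrometres.
#' @param valid Logical validity mask (default all valid).
#' @return An object of class `gradient_field`.
#' @export
gradient_field <- function(p, q, pitch, valid = NULL) {
  if (!is.matrix(p) || !identical(dim(p), dim(q)))
    stopf("'p' and 'q' must be matrices of equal dimension")
  check_number(pitch, "pitch", min = 0, strict_min = TRUE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(p), ncol(p))
  if (any(!is.finite(p[valid])) || any(!is.finite(q[valid])))
    stopf("gradients must be finite on valid pixels")
  structure(list(p = p, q = q, pitch = pitch, valid = valid),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d px (%d valid), pitch %.3g um\n",
              nrow(x$p), ncol(x$p), sum(x$valid), x$pitch))
  invisible(x)
}

#' Convert a normal field to surface gradients
#'
#' `p = -n_x / n_z`, `q = -n_y / n_z` on pixels whose camera-facing
#' component `n_z` is at least `min_nz`; grazing or invalid pixels are
#' masked, never an error.
#'
#' @param nf A `normal_field` from [estimate_normals()].
#' @param min_nz Floor on `n_z` below which a pixel is masked (avoids
#'   unbounded slopes at grazing normals).
#' @return A [gradient_field()].
#' @examples
#' # a normal of (0.6, 0, 0.8) has slope p = -0.75
#' @export
normals_to_gradients <- function(nf, min_nz = 0.05) {
  n <- nf$normals
  nz <- n[, , 3]
  ok <- nf$valid & !is.na(nz) & nz >= min_nz
  p <- matrix(0, nrow(nz), ncol(nz)); q <- p
  p[ok] <- -n[, , 1][ok] / nz[ok]
  q[ok] <- -n[, , 2][ok] / nz[ok]
  gradient_field(p, q, nf$pitch, ok)
}

# Zero-fill invalid pixels and return per-pixel-unit gradients (height
# change per pixel step, micrometres).
grad_per_pixel <- function(g) {
  P <- g$p * g$pitch; Q <- g$q * g$pitch
  P[!g$valid] <- 0; Q[!g$valid] <- 0
  list(P = P, Q = Q)
}

zero_mean_field <- function(z, pitch, valid) {
  z <- z - mean(z[valid])
  height_field(z, pitch, valid)
}

#' Frequency-domain least-squares integration of a gradient field
#'
#' The Fourier (Frankot--Chellappa) method: projects the gradient field
#' onto the space of integrable surfaces in the frequency domain and
#' inverts the discrete central-difference operator exactly. Assumes the
#' surface is periodic across the grid; non-periodic content (e.g. a
#' constant-gradient ramp) is not recoverable by this solver -- use
#' [integrate_poisson()] for such surfaces. Invalid pixels are in-filled
#' with zero gradients before the global solve and re-masked afterwards.
#' The unobservable integration constant is fixed by the zero-mean
#' convention over valid pixels.
#'
#' @param g A [gradient_field()].
#' @return A [height_field()] (micrometres, zero mean over valid pixels).
#' @export
integrate_fourier <- function(g) {
  if (!inherits(g, "gradient_field")) stopf("'g' must be a gradient_field")
  H <- nrow(g$p); W <- ncol(g$p)
  if (H < 2L || W < 2L) stopf("grid must be at least 2x2")
  gp <- grad_per_pixel(g)
  Fp <- stats::fft(gp$P); Fq <- stats::fft(gp$Q)
  ## frequency response of the circular central-difference operator
  sx <- sin(2 * pi * (0:(H - 1)) / H)
  sy <- sin(2 * pi * (0:(W - 1)) / W)
  Dx <- matrix(1i * sx, H, W)
  Dy <- matrix(1i * sy, H, W, byrow = TRUE)
  den <- Re(Dx * Conj(Dx) + Dy * Conj(Dy))
  num <- Conj(Dx) * Fp + Conj(Dy) * Fq
  Z <- num
  nz <- den > .Machine$double.eps
  Z[nz] <- num[nz] / den[nz]
  Z[!nz] <- 0 # DC and pure-Nyquist modes: unobservable, set to zero
  z <- Re(stats::fft(Z, inverse = TRUE)) / (H * W)
  zero_mean_field(z, g$pitch, g$valid)
}

# 2-D DCT transform pair built from cached orthonormal basis matrices.
dct2 <- function(x) dct_basis(nrow(x)) %*% x %*% t(dct_basis(ncol(x)))
idct2 <- function(x) t(dct_basis(nrow(x))) %*% x %*% dct_basis(ncol(x))

# Divergence-style right-hand side of the gradient least-squares normal
# equations: edge gradients are the mean of the two adjacent pixel slopes,
# and b[i] = g_in - g_out with missing border edges dropped (Neumann).
poisson_rhs <- function(P, Q) {
  H <- nrow(P); W <- ncol(P)
  ex <- (P[-H, , drop = FALSE] + P[-1, , drop = FALSE]) / 2 # (H-1) x W
  ey <- (Q[, -W, drop = FALSE] + Q[, -1, drop = FALSE]) / 2 # H x (W-1)
  b <- matrix(0, H, W)
  b[-1, ] <- b[-1, ] + ex
  b[-H, ] <- b[-H, ] - ex
  b[, -1] <- b[, -1] + ey
  b[, -W] <- b[, -W] - ey
  b
}

#' Poisson integration of a gradient field with Neumann boundary
#'
#' Solves the discrete least-squares problem `min sum |grad z - (p, q)|^2`
#' whose normal equations are a Poisson equation with natural (Neumann)
#' boundary conditions taken from the gradients themselves. The system is
#' diagonalised exactly by the discrete cosine transform, so the solver is
#' direct and deterministic; a constant-gradient plane is recovered exactly
#' up to the integration constant. This is the default integrator for
#' non-periodic surfaces. Invalid pixels are in-filled with zero gradients
#' and re-masked; the output is zero-mean over valid pixels.
#'
#' @param g A [gradient_field()].
#' @return A [height_field()].
#' @export
integrate_poisson <- function(g) {
  if (!inherits(g, "gradient_field")) stopf("'g' must be a gradient_field")
  H <- nrow(g$p); W <- ncol(g$p)
  if (H < 2L || W < 2L) stopf("grid must be at least 2x2")
  gp <- grad_per_pixel(g)
  b <- poisson_rhs(gp$P, gp$Q)
  B <- dct2(b)
  mu <- outer(neumann_eigenvalues(H), rep(1, W)) +
    outer(rep(1, H), neumann_eigenvalues(W))
  Z <- B
  Z[1, 1] <- 0
  Z[-1] <- B[-1] / mu[-1]
  Z[1, 1] <- 0
  z <- idct2(Z)
  zero_mean_field(z, g$pitch, g$valid)
}

#' Integrability (curl) residual of a gradient field
#'
#' For the exact gradients of any surface, the cross-derivatives agree:
#' `dp/dy = dq/dx`. Noisy or corrupted photometric-stereo gradients violate
#' this, so the absolute curl `|dp/dy - dq/dx|` (central differences on the
#' interior, in per-micrometre units) is a per-pixel diagnostic of
#' non-integrability.
#'
#' @param g A [gradient_field()].
#' @return List with `residual` (matrix, `NA` on the one-pixel border) and
#'   `mean` over interior valid pixels.
#' @export
curl_residual <- function(g) {
  p <- g$p; q <- g$q; s <- g$pitch
  H <- nrow(p); W <- ncol(p)
  if (H < 3L || W < 3L) stopf("grid must be at least 3x3 for the curl")
  res <- matrix(NA_real_, H, W)
  dp_dy <- (p[2:(H - 1), 3:W] - p[2:(H - 1), 1:(W - 2)]) / (2 * s)
  dq_dx <- (q[3:H, 2:(W - 1)] - q[1:(H - 2), 2:(W - 1)]) / (2 * s)
  res[2:(H - 1), 2:(W - 1)] <- abs(dp_dy - dq_dx)
  ok <- g$valid & !is.na(res)
  list(residual = res, mean = mean(res[ok]))
}
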