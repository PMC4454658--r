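#' Fuse low-frequency geometry with photometric-stereo gradients
#'
#' Photometric stereo yields accurate micro-geometry but a biased overall
#' (low-frequency) shape, while multiview stereo gives the opposite. The
#' hybrid surface is the minimiser of the screened-Poisson objective
#' \deqn{\lambda \sum (z - z_{low})^2 + \sum |\nabla z - (p, q)|^2,}
#' a linear system diagonalised exactly by the discrete cosine transform
#' (Neumann boundary). As `lambda_lf` grows the result approaches the
#' low-frequency input; as it shrinks toward zero it approaches pure
#' integration of the gradients (with the mean pinned to the low-frequency
#' surface).
#'
#' @param low A [height_field()] with unbiased low-frequency geometry
#'   (e.g. resampled multiview-stereo output); grid and pitch must match
#'   `ps_grad`.
#' @param ps_grad A [gradient_field()] of photometric-stereo slopes.
#' @param lambda_lf Positive data-term weight, units of 1/pixel^2. The
#'   default `(2 * pi / 32)^2` places the crossover between the two
#'   sources at a wavelength of about 32 pixels.
#' @return A [height_field()] on the same grid (not mean-centred: the
#'   low-frequency surface fixes the absolute level).
#' @examples
#' # exact gradients of `low` reproduce `low` for any lambda
#' @export
fuse <- function(low, ps_grad, lambda_lf = (2 * pi / 32)^2) {
  if (!inherits(low, "height_field")) stopf("'low' must be a height_field")
  if (!inherits(ps_grad, "gradient_field"))
    stopf("'ps_grad' must be a gradient_field")
  if (!identical(dim(low$heights), dim(ps_grad$p)))
    stopf("grid mismatch: low is %d x %d, gradients %d x %d",
          nrow(low$heights), ncol(low$heights),
          nrow(ps_grad$p), ncol(ps_grad$p))
  if (abs(low$pitch - ps_grad$pitch) > 1e-9 * low$pitch)
    stopf("pitch mismatch between 'low' and 'ps_grad'")
  check_number(lambda_lf, "lambda_lf", min = 0, strict_min = TRUE)
  H <- nrow(low$heights); W <- ncol(low$heights)
  gp <- grad_per_pixel(ps_grad)
  b <- poisson_rhs(gp$P, gp$Q)
  Z0 <- dct2(low$heights)
  B <- dct2(b)
  mu <- outer(neumann_eigenvalues(H), rep(1, W)) +
    outer(rep(1, H), neumann_eigenvalues(W))
  Z <- (lambda_lf * Z0 + B) / (lambda_lf + mu)
  z <- idct2(Z)
  height_field(z, low$pitch, low$mask & ps_grad$valid)
}

#' Low-pass filter a height field
#'
#' Keeps only spatial frequencies at or below `cutoff` (cycles per pixel,
#' radial, hard cutoff in the Fourier domain). Applied to a seeded random
#' field this fabricates the smooth low-frequency bias surface that
#' corrupts synthetic photometric-stereo output in fusion tests; applied
#' to a detailed truth surface it produces a detail-free low-frequency
#' version of it. A cutoff approaching zero leaves only the constant mean.
#'
#' @param field A [height_field()].
#' @param cutoff Radial spatial frequency cutoff, cycles/pixel, in
#'   `(0, 0.5]` (0.5 is Nyquist).
#' @return A [height_field()] with identical grid, pitch and mask.
#' @export
lowpass_bias <- function(field, cutoff) {
  if (!inherits(field, "height_field")) stopf("'field' must be a height_field")
  check_number(cutoff, "cutoff", min = 0)
  if (cutoff > 0.5) stopf("'cutoff' must not exceed the Nyquist frequency 0.5")
  z <- field$heights
  H <- nrow(z); W <- ncol(z)
  fx <- (0:(H - 1)) / H; fx <- pmin(fx, 1 - fx)
  fy <- (0:(W - 1)) / W; fy <- pmin(fy, 1 - fy)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  Z <- stats::fft(z)
  Z[fr > cutoff] <- 0
  zf <- Re(stats::fft(Z, inverse = TRUE)) / (H * W)
  height_field(zf, field$pitch, field$mask)
}
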