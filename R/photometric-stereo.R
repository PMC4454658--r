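#' Per-pixel surface normals by robust photometric stereo
#'
#' Inverts the Lambertian forward model `I_i = intensity_i * (g . l_i)`
#' per pixel over many calibrated lights, after rank-based rejection of
#' corrupted observations: at each pixel the L intensities are sorted and
#' the lowest `floor(trim_low * L)` (shadow candidates) and highest
#' `floor(trim_high * L)` (specular candidates) are discarded before the
#' least-squares solve. The normal is `g / |g|`, the albedo `|g|`.
#'
#' Pixels are marked invalid when fewer than `min_lights` observations
#' remain, when the recovered albedo falls below `albedo_floor` (all-dark
#' or pure-noise pixels), or when the solved normal does not face the
#' camera. Ties in the intensity sort are broken by light index, so the
#' result is deterministic.
#'
#' @param stack An [image_stack()].
#' @param trim_low Fraction of lowest-intensity observations dropped per
#'   pixel (shadow rejection), default 0.2.
#' @param trim_high Fraction of highest-intensity observations dropped per
#'   pixel (specular rejection), default 0.1.
#' @param min_lights Minimum retained observations for a valid solve.
#' @param albedo_floor Albedo below which a pixel is marked invalid,
#'   fraction of full scale.
#' @return An object of class `normal_field`: `normals` (H x W x 3, unit,
#'   `NA` where invalid), `albedo`, `valid`, `used_lights`.
#' @examples
#' sp <- scene_spec("flat", nrow = 8, ncol = 8)
#' rig <- light_rig(rbind(c(0, 0, 1), c(0.5, 0, 1), c(0, 0.5, 1),
#'                        c(-0.5, 0.5, 1)) / sqrt(c(1, 1.25, 1.25, 1.5)))
#' nf <- estimate_normals(render_stack(make_height_field(sp), rig, sp),
#'                        trim_low = 0, trim_high = 0)
#' @export
estimate_normals <- function(stack, trim_low = 0.2, trim_high = 0.1,
                             min_lights = 3L, albedo_floor = 1e-6) {
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  check_number(trim_low, "trim_low", min = 0)
  check_number(trim_high, "trim_high", min = 0)
  if (trim_low + trim_high >= 1) stopf("trim_low + trim_high must be < 1")
  if (min_lights < 3L) stopf("'min_lights' must be >= 3")
  rig <- stack$rig
  rc <- rig_condition(rig)
  if (rc$deficient)
    stopf("light rig is rank %d; photometric stereo needs 3 non-coplanar directions",
          rc$rank)
  L <- rig$L
  d <- dim(stack$pixels); H <- d[2]; W <- d[3]
  npx <- H * W
  ## pixels x lights observation matrix
  I <- matrix(aperm(stack$pixels, c(2, 3, 1)), npx, L)
  n_lo <- floor(trim_low * L)
  n_hi <- floor(trim_high * L)
  if (L - n_lo - n_hi < 3L)
    stopf("trimming leaves fewer than 3 of %d lights", L)
  ## per-pixel intensity ranks; ties broken by light index
  if (n_lo > 0 || n_hi > 0) {
    rk <- t(apply(I, 1L, rank, ties.method = "first"))
    Wm <- (rk > n_lo & rk <= (L - n_hi)) * 1
  } else {
    Wm <- matrix(1, npx, L)
  }
  A <- rig$directions * rig$intensities # a_i = s_i * l_i
  a1 <- A[, 1]; a2 <- A[, 2]; a3 <- A[, 3]
  ## normal equations (sum over retained lights of a a') g = sum a I,
  ## assembled for every pixel at once
  M11 <- drop(Wm %*% (a1 * a1)); M12 <- drop(Wm %*% (a1 * a2))
  M13 <- drop(Wm %*% (a1 * a3)); M22 <- drop(Wm %*% (a2 * a2))
  M23 <- drop(Wm %*% (a2 * a3)); M33 <- drop(Wm %*% (a3 * a3))
  WI <- Wm * I
  b1 <- drop(WI %*% a1); b2 <- drop(WI %*% a2); b3 <- drop(WI %*% a3)
  ## closed-form 3x3 solve (cofactor expansion), vectorised over pixels
  c11 <- M22 * M33 - M23 * M23
  c12 <- M13 * M23 - M12 * M33
  c13 <- M12 * M23 - M13 * M22
  det <- M11 * c11 + M12 * c12 + M13 * c13
  c22 <- M11 * M33 - M13 * M13
  c23 <- M12 * M13 - M11 * M23
  c33 <- M11 * M22 - M12 * M12
  ok <- is.finite(det) & abs(det) > .Machine$double.eps * (M11 + M22 + M33)^3
  det[!ok] <- 1
  g1 <- (c11 * b1 + c12 * b2 + c13 * b3) / det
  g2 <- (c12 * b1 + c22 * b2 + c23 * b3) / det
  g3 <- (c13 * b1 + c23 * b2 + c33 * b3) / det
  albedo <- sqrt(g1^2 + g2^2 + g3^2)
  used <- rowSums(Wm)
  valid <- ok & used >= min_lights & albedo > albedo_floor & g3 > 0
  inv <- !valid
  n1 <- g1 / albedo; n2 <- g2 / albedo; n3 <- g3 / albedo
  n1[inv] <- NA_real_; n2[inv] <- NA_real_; n3[inv] <- NA_real_
  albedo[inv] <- 0
  normals <- array(c(n1, n2, n3), c(H, W, 3L))
  structure(list(normals = normals,
                 albedo = matrix(albedo, H, W),
                 valid = matrix(valid, H, W),
                 used_lights = matrix(as.integer(used), H, W),
                 pitch = stack$pitch),
            class = "normal_field")
}

#' @export
print.normal_field <- function(x, ...) {
  cat(sprintf("<normal_field> %d x %d px (%d valid), pitch %.3g um\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid), x$pitch))
  invisible(x)
}

#' Angular error between two normal fields
#'
#' Per-pixel angle in degrees between estimated normals and a reference
#' (an `H x W x 3` array such as [surface_normals()] output). Convenience
#' diagnostic for accuracy checks on synthetic scenes.
#'
#' @param nf A `normal_field`.
#' @param ref Reference normals, H x W x 3.
#' @return Matrix of angles (degrees), `NA` on invalid pixels.
#' @export
normal_angle_error <- function(nf, ref) {
  dp <- nf$normals[, , 1] * ref[, , 1] + nf$normals[, , 2] * ref[, , 2] +
    nf$normals[, , 3] * ref[, , 3]
  acos(pmin(pmax(dp, -1), 1)) * 180 / pi
}
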