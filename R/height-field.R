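#' Height field container
#'
#' A height field is the package's representation of a reconstructed or
#' synthetic surface: a rectangular grid of heights in micrometres, a
#' physical pixel pitch, and a per-pixel validity mask.
#'
#' @param heights Numeric matrix of surface heights (micrometres).
#' @param pitch Physical size of one pixel (micrometres), `> 0`.
#' @param mask Logical matrix of per-pixel validity; defaults to all valid.
#'
#' @return An object of class `height_field` with elements `heights`,
#'   `pitch` and `mask`.
#' @examples
#' hf <- height_field(matrix(0, 8, 8), pitch = 4.9)
#' @export
height_field <- function(heights, pitch, mask = NULL) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stopf("'heights' must be a numeric matrix")
  if (nrow(heights) < 2L || ncol(heights) < 2L)
    stopf("height field must be at least 2x2")
  check_number(pitch, "pitch", min = 0, strict_min = TRUE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(heights), ncol(heights))
  if (!identical(dim(mask), dim(heights)))
    stopf("'mask' dimensions must match 'heights'")
  if (any(!is.finite(heights[mask])))
    stopf("heights must be finite on valid pixels")
  structure(list(heights = heights, pitch = pitch, mask = mask),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  h <- x$heights[x$mask]
  cat(sprintf("<height_field> %d x %d px, pitch %.3g um, z in [%.4g, %.4g] um (%d invalid px)\n",
              nrow(x$heights), ncol(x$heights), x$pitch,
              if (length(h)) min(h) else NA, if (length(h)) max(h) else NA,
              sum(!x$mask)))
  invisible(x)
}

#' Scene specification for synthetic surfaces
#'
#' Describes a ground-truth surface and its appearance for the synthetic
#' renderer: geometry kind and parameters, albedo, an optional specular lobe,
#' sensor noise and quantization depth.
#'
#' Geometry kinds:
#' \describe{
#'   \item{`flat`}{plane at height 0.}
#'   \item{`sphere_cap`}{spherical cap of `diameter_um` and cap height
#'     `cap_height_um` (default `diameter_um / 2`, i.e. a hemisphere) centred
#'     on the grid, resting on a flat substrate.}
#'   \item{`sinusoid`}{`z = amplitude_um * sin(2 pi x / period_x_um + phase_x)
#'     * cos(2 pi y / period_y_um + phase_y)`; `period_y_um = Inf` gives a 1-D
#'     grating. `x` is the row direction, `y` the column direction.}
#'   \item{`microsphere_monolayer`}{hexagonally packed spheres of
#'     `diameter_um` resting on a substrate (nearest-neighbour centre spacing
#'     equals the diameter), emulating a calibrated microsphere target.}
#'   \item{`three_bar_target`}{three raised bars encoding a USAF-1951
#'     group/element: bar width is half the line-pair period
#'     `1000 / usaf_resolution(group, element)` micrometres.}
#' }
#'
#' @param kind Geometry kind, see Details.
#' @param nrow,ncol Grid size in pixels.
#' @param pitch Pixel pitch in micrometres.
#' @param albedo Constant albedo or matrix, in `[0, 1]`.
#' @param specular_strength Strength of the Blinn-style specular lobe
#'   (0 disables it).
#' @param specular_exponent Shininess exponent of the specular lobe.
#' @param noise_sd Additive Gaussian sensor noise, as a fraction of full
#'   scale, applied before quantization.
#' @param bits Quantization depth in bits (default 16).
#' @param cast_shadows Whether the renderer should ray-march cast shadows.
#' @param seed Random seed controlling the noise (geometry is deterministic).
#' @param ... Kind-specific geometry parameters (`diameter_um`,
#'   `cap_height_um`, `amplitude_um`, `period_x_um`, `period_y_um`,
#'   `phase_x`, `phase_y`, `group`, `element`, `bar_height_um`).
#'
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec("sphere_cap", nrow = 64, ncol = 64, pitch = 4.9,
#'                  diameter_um = 40)
#' @export
scene_spec <- function(kind = c("flat", "sphere_cap", "sinusoid",
                                "microsphere_monolayer", "three_bar_target"),
                       nrow = 64L, ncol = 64L, pitch = 4.9, albedo = 1,
                       specular_strength = 0, specular_exponent = 32,
                       noise_sd = 0, bits = 16L, cast_shadows = FALSE,
                       seed = NULL, ...) {
  kind <- match.arg(kind)
  check_number(nrow, "nrow", min = 2); check_number(ncol, "ncol", min = 2)
  check_number(pitch, "pitch", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(bits, "bits", min = 0) # 0 disables quantization
  check_number(specular_strength, "specular_strength", min = 0)
  extra <- list(...)
  if (kind %in% c("sphere_cap", "microsphere_monolayer")) {
    d <- extra$diameter_um
    if (is.null(d)) stopf("kind '%s' requires 'diameter_um'", kind)
    check_number(d, "diameter_um", min = 0, strict_min = TRUE)
  }
  if (kind == "three_bar_target") {
    if (is.null(extra$group) || is.null(extra$element))
      stopf("kind 'three_bar_target' requires 'group' and 'element'")
  }
  structure(c(list(kind = kind, nrow = as.integer(nrow),
                   ncol = as.integer(ncol), pitch = pitch, albedo = albedo,
                   specular_strength = specular_strength,
                   specular_exponent = specular_exponent,
                   noise_sd = noise_sd, bits = as.integer(bits),
                   cast_shadows = isTRUE(cast_shadows), seed = seed),
              extra),
            class = "scene_spec")
}

#' Generate a synthetic ground-truth surface
#'
#' Builds the height field described by a [scene_spec()]. Geometry is fully
#' deterministic; the spec's seed only affects rendering noise.
#'
#' @param spec A [scene_spec()].
#' @return A [height_field()].
#' @examples
#' hf <- make_height_field(scene_spec("sphere_cap", nrow = 64, ncol = 64,
#'                                    pitch = 1, diameter_um = 40))
#' max(hf$heights) # 20 um at the centre
#' @export
make_height_field <- function(spec) {
  if (!inherits(spec, "scene_spec")) stopf("'spec' must be a scene_spec")
  H <- spec$nrow; W <- spec$ncol; pitch <- spec$pitch
  x <- (seq_len(H) - (H + 1) / 2) * pitch # row coordinate, um, centred
  y <- (seq_len(W) - (W + 1) / 2) * pitch
  z <- switch(spec$kind,
    flat = matrix(0, H, W),
    sphere_cap = {
      r <- spec$diameter_um / 2
      hcap <- if (is.null(spec$cap_height_um)) r else spec$cap_height_um
      if (hcap <= 0 || hcap > r)
        stopf("'cap_height_um' must be in (0, radius]")
      ## sphere centre sits below the substrate so the cap pokes out by hcap
      d2 <- outer(x^2, y^2, `+`)
      zc <- sqrt(pmax(r^2 - d2, 0)) - (r - hcap)
      pmax(zc, 0)
    },
    sinusoid = {
      A <- spec$amplitude_um %||% 1
      px <- spec$period_x_um %||% (H * pitch / 4)
      py <- spec$period_y_um %||% Inf
      phx <- spec$phase_x %||% 0; phy <- spec$phase_y %||% 0
      sx <- sin(2 * pi * x / px + phx)
      cy <- if (is.finite(py)) cos(2 * pi * y / py + phy) else rep(1, W)
      A * outer(sx, cy)
    },
    microsphere_monolayer = {
      d <- spec$diameter_um; r <- d / 2
      ## hexagonal lattice: rows of centres spaced d*sqrt(3)/2 apart,
      ## alternate rows offset by d/2; nearest-neighbour spacing = d
      row_sp <- d * sqrt(3) / 2
      ci <- seq(min(x) - d, max(x) + d, by = row_sp)
      z <- matrix(0, H, W)
      for (i in seq_along(ci)) {
        off <- if (i %% 2 == 0) d / 2 else 0
        cj <- seq(min(y) - d + off, max(y) + d, by = d)
        for (cy0 in cj) {
          dx2 <- (x - ci[i])^2
          keep_r <- which(dx2 < r^2)
          if (!length(keep_r)) next
          dy2 <- (y - cy0)^2
          keep_c <- which(dy2 < r^2)
          if (!length(keep_c)) next
          d2 <- outer(dx2[keep_r], dy2[keep_c], `+`)
          ## top surface of a sphere resting on the substrate
          zs <- r + sqrt(pmax(r^2 - d2, 0))
          zs[d2 >= r^2] <- 0
          z[keep_r, keep_c] <- pmax(z[keep_r, keep_c], zs)
        }
      }
      z
    },
    three_bar_target = {
      res <- usaf_resolution(spec$group, spec$element)
      bar_w <- res$period_um / 2 # one bar = half a line pair
      bar_h <- spec$bar_height_um %||% 1
      ## three bars along y (columns), each bar_w wide, spaced bar_w,
      ## length 5 * bar_w along x, centred on the grid
      z <- matrix(0, H, W)
      xin <- abs(x) <= 2.5 * bar_w
      for (k in -1:1) {
        yc <- k * 2 * bar_w
        yin <- abs(y - yc) <= bar_w / 2
        z[xin, yin] <- bar_h
      }
      z
    })
  height_field(z, pitch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete gradients of a height field
#'
#' Central differences in the interior with one-sided differences at the
#' borders (or circular central differences for periodic surfaces). Slopes
#' are dimensionless (micrometre per micrometre).
#'
#' @param hf A [height_field()].
#' @param circular Use circular (wrap-around) central differences, exact for
#'   periodic surfaces.
#' @return A [gradient_field()] with `p = dz/dx` (row direction) and
#'   `q = dz/dy` (column direction).
#' @export
height_gradients <- function(hf, circular = FALSE) {
  z <- hf$heights; s <- hf$pitch
  H <- nrow(z); W <- ncol(z)
  p <- matrix(0, H, W); q <- matrix(0, H, W)
  if (circular) {
    up <- z[c(H, 1:(H - 1)), , drop = FALSE]
    dn <- z[c(2:H, 1), , drop = FALSE]
    p <- (dn - up) / (2 * s)
    lf <- z[, c(W, 1:(W - 1)), drop = FALSE]
    rt <- z[, c(2:W, 1), drop = FALSE]
    q <- (rt - lf) / (2 * s)
  } else {
    p[2:(H - 1), ] <- (z[3:H, ] - z[1:(H - 2), ]) / (2 * s)
    p[1, ] <- (z[2, ] - z[1, ]) / s
    p[H, ] <- (z[H, ] - z[H - 1, ]) / s
    q[, 2:(W - 1)] <- (z[, 3:W] - z[, 1:(W - 2)]) / (2 * s)
    q[, 1] <- (z[, 2] - z[, 1]) / s
    q[, W] <- (z[, W] - z[, W - 1]) / s
  }
  gradient_field(p, q, s, hf$mask)
}

#' Surface normals of a height field
#'
#' Unit normals derived from the discrete gradients, oriented toward the
#' camera (positive z component). This is the renderer's ground truth.
#'
#' @inheritParams height_gradients
#' @return H x W x 3 array of unit normals.
#' @export
surface_normals <- function(hf, circular = FALSE) {
  g <- height_gradients(hf, circular = circular)
  nrm <- sqrt(g$p^2 + g$q^2 + 1)
  n <- array(0, c(nrow(g$p), ncol(g$p), 3L))
  n[, , 1] <- -g$p / nrm
  n[, , 2] <- -g$q / nrm
  n[, , 3] <- 1 / nrm
  n
}
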