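#' Photometric-stereo image stack
#'
#' Co-registered per-light images of one view: an `L x H x W` array of
#' linear intensities in `[0, 1]`, the [light_rig()] that produced them and
#' the pixel pitch.
#'
#' @param pixels Numeric `L x H x W` array, finite and non-negative.
#' @param rig The [light_rig()]; `L` must match `dim(pixels)[1]`.
#' @param pitch Pixel pitch in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, rig, pitch) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("'pixels' must be an L x H x W array")
  if (!inherits(rig, "light_rig")) stopf("'rig' must be a light_rig")
  if (dim(pixels)[1] != rig$L)
    stopf("stack has %d images but rig has %d lights", dim(pixels)[1], rig$L)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stopf("intensities must be finite and >= 0")
  check_number(pitch, "pitch", min = 0, strict_min = TRUE)
  structure(list(pixels = pixels, rig = rig, pitch = pitch),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d lights x %d x %d px, pitch %.3g um\n",
              d[1], d[2], d[3], x$pitch))
  invisible(x)
}

#' Render a surface under a directional light rig
#'
#' Forward model of the scanner in photometric-stereo mode (one light on at
#' a time): for light `i`, the image is
#' `albedo * max(0, n . l_i) * intensity_i`, with normals taken from the
#' height field by central differences, an optional Blinn-style specular
#' lobe, optional cast shadows found by ray-marching toward the light,
#' then additive Gaussian noise and quantization. Distant lights and an
#' orthographic camera are assumed.
#'
#' @param height A [height_field()].
#' @param rig A [light_rig()].
#' @param spec A [scene_spec()] supplying albedo, specular, noise,
#'   quantization and shadow settings (geometry fields are ignored).
#' @return An [image_stack()].
#' @examples
#' sp <- scene_spec("flat", nrow = 8, ncol = 8)
#' st <- render_stack(make_height_field(sp), light_rig(diag(3)[3, , drop = FALSE]), sp)
#' all(st$pixels == 1) # n . l = 1 everywhere
#' @export
render_stack <- function(height, rig, spec) {
  if (!inherits(height, "height_field")) stopf("'height' must be a height_field")
  if (!inherits(rig, "light_rig")) stopf("'rig' must be a light_rig")
  n <- surface_normals(height)
  H <- nrow(height$heights); W <- ncol(height$heights)
  alb <- spec$albedo
  if (is.matrix(alb)) {
    if (!identical(dim(alb), dim(height$heights)))
      stopf("albedo map dimensions must match the height field")
  } else alb <- matrix(alb, H, W)
  ks <- spec$specular_strength %||% 0
  ke <- spec$specular_exponent %||% 32
  pix <- array(0, c(rig$L, H, W))
  for (i in seq_len(rig$L)) {
    l <- rig$directions[i, ]
    ndotl <- n[, , 1] * l[1] + n[, , 2] * l[2] + n[, , 3] * l[3]
    img <- alb * pmax(ndotl, 0)
    if (ks > 0) {
      h <- l + c(0, 0, 1); h <- h / sqrt(sum(h^2))
      ndoth <- n[, , 1] * h[1] + n[, , 2] * h[2] + n[, , 3] * h[3]
      img <- img + ks * pmax(ndoth, 0)^ke
    }
    if (isTRUE(spec$cast_shadows)) {
      img[shadow_mask(height, l)] <- 0
    }
    pix[i, , ] <- img * rig$intensities[i]
  }
  if ((spec$noise_sd %||% 0) > 0 || (spec$bits %||% 0) > 0) {
    pix <- with_seed(spec$seed, {
      out <- pix
      if (spec$noise_sd > 0)
        out <- out + stats::rnorm(length(out), sd = spec$noise_sd)
      if (!is.null(spec$bits) && spec$bits > 0) {
        levels <- 2^spec$bits - 1
        out <- round(pmin(pmax(out, 0), 1) * levels) / levels
      } else out <- pmax(out, 0)
      out
    })
  }
  image_stack(pix, rig, height$pitch)
}

# Cast-shadow test by height-field ray marching toward the light with a
# half-pixel step. A pixel is shadowed when the marched ray passes below
# the surface. Lights at or below the horizon shadow everything.
shadow_mask <- function(height, l, step_frac = 0.5) {
  z <- height$heights; s <- height$pitch
  H <- nrow(z); W <- ncol(z)
  if (l[3] <= 1e-12) return(matrix(TRUE, H, W))
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  shadowed <- matrix(FALSE, H, W)
  alive <- !shadowed
  step <- step_frac * s
  zmax <- max(z)
  t <- step
  tmax <- (zmax - min(z)) / l[3] + step
  while (t <= tmax && any(alive)) {
    idx <- which(alive)
    r <- rr[idx] + t * l[1] / s
    c <- cc[idx] + t * l[2] / s
    inside <- r >= 1 & r <= H & c >= 1 & c <= W
    zr <- z[idx] + t * l[3]
    done <- !inside | zr > zmax
    hit <- inside & interp_bilinear(z, r, c) > zr + 1e-9
    shadowed[idx[hit]] <- TRUE
    alive[idx[hit | done]] <- FALSE
    t <- t + step
  }
  shadowed
}

#' Fabricate an integer-shifted image pair
#'
#' Builds the fixture for the positional-repeatability analysis: `imageB`
#' is `imageA` translated by `(dx, dy)` whole pixels, with independent
#' Gaussian noise added to each image. The shift convention follows the
#' repeatability algorithm: content at row/column `(r, c)` of A appears at
#' `(r + dx, c + dy)` in B. Translation wraps around the borders, so the
#' pair is an exact shifted copy everywhere at distance `>= max(|dx|,|dy|)`
#' from the edges.
#'
#' @param image Matrix (grayscale) or H x W x 3 array in `[0, 1]`.
#' @param dx,dy Integer shift in rows and columns.
#' @param noise_sd Gaussian noise SD (fraction of full scale) per image.
#' @param seed Seed for the two independent noise draws.
#' @return List with elements `a` and `b`.
#' @export
make_shifted_pair <- function(image, dx, dy, noise_sd = 0, seed = NULL) {
  dims <- dim(image)
  H <- dims[1]; W <- dims[2]
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= H || abs(dy) >= W)
    stopf("shift (%d, %d) exceeds image extent %d x %d", dx, dy, H, W)
  ri <- ((seq_len(H) - 1 - dx) %% H) + 1
  ci <- ((seq_len(W) - 1 - dy) %% W) + 1
  b <- if (length(dims) == 3L) image[ri, ci, , drop = FALSE] else image[ri, ci]
  with_seed(seed, {
    if (noise_sd > 0) {
      a <- image + stats::rnorm(length(image), sd = noise_sd)
      b <- b + stats::rnorm(length(b), sd = noise_sd)
      list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1))
    } else list(a = image, b = b)
  })
}

#' Synthesise a vibration blur series
#'
#' Fabricates the per-position blur trace of the vibration-attenuation
#' analysis: an exponentially decaying blur `B0 + A * exp(-t / T)` sampled
#' at `fps` frames per second over a dwell of `dwell_s` seconds, with
#' additive Gaussian noise, clipped to `[0, 1]`. The defaults (30 fps, 5 s)
#' give the 150 frames acquired per position during a scan.
#'
#' @param A Initial vibration blur amplitude (`>= 0`).
#' @param T_decay Exponential decay time constant in seconds (`> 0`).
#' @param B0 Basal (vibration-free) blur level.
#' @param fps Frames per second.
#' @param dwell_s Dwell time at the position, seconds.
#' @param noise_sd Gaussian noise SD on the blur values.
#' @param seed Seed for the noise.
#' @return An object of class `blur_series`: list with `times` (s),
#'   `values` in `[0, 1]` and `fps`.
#' @examples
#' bs <- make_blur_series(A = 0.05, T_decay = 0.2)
#' length(bs$values) # 150
#' @export
make_blur_series <- function(A, T_decay, B0 = 0.3, fps = 30, dwell_s = 5,
                             noise_sd = 0, seed = NULL) {
  check_number(A, "A", min = 0)
  check_number(T_decay, "T_decay", min = 0, strict_min = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  n <- round(fps * dwell_s)
  t <- (seq_len(n) - 1) / fps
  v <- B0 + A * exp(-t / T_decay)
  v <- with_seed(seed, {
    if (noise_sd > 0) v + stats::rnorm(n, sd = noise_sd) else v
  })
  blur_series(t, pmin(pmax(v, 0), 1), fps)
}

#' @rdname make_blur_series
#' @param times Sample times in seconds, strictly increasing.
#' @param values Blur scores in `[0, 1]`.
#' @export
blur_series <- function(times, values, fps = 30) {
  if (length(times) != length(values)) stopf("times/values length mismatch")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(values < 0 | values > 1)) stopf("blur values must lie in [0, 1]")
  structure(list(times = times, values = values, fps = fps),
            class = "blur_series")
}
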