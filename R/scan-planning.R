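#' Scanning envelope specification
#'
#' Describes two concentric parametric surfaces -- the scanning envelope on
#' which the camera moves and the idealised target surface it looks at --
#' together with the optics that determine the camera footprint and the
#' requested footprint overlap between neighbouring views.
#'
#' For `half_cylinder` the axis lies along world x with the half above the
#' xy-plane (`z >= 0`); `envelope` and `target` are `c(radius_mm,
#' length_mm)`. For `half_ellipsoid` they are the three semi-axes
#' `c(a, b, c)` in mm (upper half, `z >= 0`).
#'
#' The camera footprint on the target is computed from the thin-lens
#' magnification `m = f / (d - f)` at working distance `d` (envelope to
#' target along the local normal): footprint = sensor size / m. It can be
#' overridden with `footprint_mm`.
#'
#' @param kind `"half_cylinder"` or `"half_ellipsoid"`.
#' @param envelope,target Envelope / target dimensions (mm), see Details.
#' @param overlap Required footprint-area overlap fraction between
#'   nearest-neighbour views, in `[0, 1)`. Default 0.6.
#' @param focal_mm Lens focal length (mm).
#' @param sensor_mm Sensor size `c(width, height)` (mm); width maps to
#'   image columns.
#' @param pixel_pitch_um Sensor pixel pitch (micrometres).
#' @param footprint_mm Optional explicit footprint `c(width, height)` (mm)
#'   on the target, bypassing the thin-lens computation.
#' @param min_working_mm Minimum admissible working distance (mm); the
#'   default 160 mm is the close-focus limit of a 105 mm macro lens.
#' @param min_spacing_mm Smallest meaningful pose spacing (mm); a requested
#'   overlap that drives the step below this is infeasible.
#' @return An object of class `envelope_spec`.
#' @export
envelope_spec <- function(kind = c("half_cylinder", "half_ellipsoid"),
                          envelope, target, overlap = 0.6, focal_mm = 105,
                          sensor_mm = c(36, 24), pixel_pitch_um = 4.9,
                          footprint_mm = NULL, min_working_mm = 160,
                          min_spacing_mm = 1) {
  kind <- match.arg(kind)
  envelope <- as.numeric(envelope); target <- as.numeric(target)
  nd <- if (kind == "half_cylinder") 2L else 3L
  if (length(envelope) != nd || length(target) != nd)
    stopf("'%s' needs %d dimensions for envelope and target", kind, nd)
  if (any(envelope <= 0) || any(target <= 0))
    stopf("envelope and target dimensions must be positive")
  if (kind == "half_cylinder" && target[1] >= envelope[1])
    stopf("the envelope must strictly enclose the target (radius)")
  if (kind == "half_ellipsoid" && any(target >= envelope))
    stopf("the envelope must strictly enclose the target (semi-axes)")
  if (overlap < 0 || overlap >= 1) stopf("'overlap' must lie in [0, 1)")
  structure(list(kind = kind, envelope = envelope, target = target,
                 overlap = overlap, focal_mm = focal_mm,
                 sensor_mm = as.numeric(sensor_mm),
                 pixel_pitch_um = pixel_pitch_um,
                 footprint_mm = footprint_mm,
                 min_working_mm = min_working_mm,
                 min_spacing_mm = min_spacing_mm),
            class = "envelope_spec")
}

footprint_at <- function(spec, working_mm) {
  if (!is.null(spec$footprint_mm)) return(as.numeric(spec$footprint_mm))
  if (working_mm <= spec$focal_mm)
    stopf("working distance %.1f mm is not beyond the focal length", working_mm)
  m <- spec$focal_mm / (working_mm - spec$focal_mm)
  spec$sensor_mm / m
}

#' Generate camera poses over a scanning envelope
#'
#' Samples the envelope on a regular parameter grid whose steps are chosen
#' so that the camera footprints of nearest-neighbour poses overlap by at
#' least the requested fraction on the target surface, each pose looking
#' along the local inward normal. The grid is traversed in boustrophedon
#' order (alternate parameter rows reversed) so consecutive poses are
#' always neighbours; the result is deterministic.
#'
#' For a cylinder the circumferential step is `w * (1 - overlap)` of
#' footprint arc on the target and the axial step `h * (1 - overlap)`;
#' abutting tiles (overlap 0) give an angular step of exactly one
#' footprint arc.
#'
#' @param spec An [envelope_spec()].
#' @param image_size Image size recorded in each pose, `c(rows, cols)`.
#' @return List of [camera_pose()] objects with attributes `n_axial` /
#'   `n_angular` (cylinder) or `n_elev` / `n_azim` (ellipsoid).
#' @export
generate_poses <- function(spec, image_size = c(480L, 640L)) {
  if (!inherits(spec, "envelope_spec")) stopf("'spec' must be an envelope_spec")
  step_fac <- 1 - spec$overlap
  if (spec$kind == "half_cylinder") {
    Re <- spec$envelope[1]; Len <- spec$envelope[2]
    Rt <- spec$target[1]
    d <- Re - Rt
    if (d < spec$min_working_mm)
      stopf("working distance %.1f mm is below the %.0f mm minimum",
            d, spec$min_working_mm)
    ## image columns (sensor width) run along the cylinder axis, rows along
    ## the circumference, so the wide footprint side covers the long axis
    fp <- footprint_at(spec, d)
    step_arc <- fp[2] * step_fac
    step_ax <- fp[1] * step_fac
    if (step_arc < spec$min_spacing_mm)
      stopf("infeasible overlap %.2f: circumferential step %.3g mm below the %.3g mm minimum (footprint height %.3g mm)",
            spec$overlap, step_arc, spec$min_spacing_mm, fp[2])
    if (step_ax < spec$min_spacing_mm)
      stopf("infeasible overlap %.2f: axial step %.3g mm below the %.3g mm minimum (footprint width %.3g mm)",
            spec$overlap, step_ax, spec$min_spacing_mm, fp[1])
    arc_total <- pi * Rt
    n_th <- max(2L, ceiling(arc_total / step_arc) + 1L)
    n_ax <- max(2L, ceiling(Len / step_ax) + 1L)
    build <- function(n_th, n_ax) {
      th <- seq(0, pi, length.out = n_th)
      ax <- seq(0, Len, length.out = n_ax)
      poses <- list()
      for (i in seq_along(ax)) {
        th_i <- if (i %% 2 == 1) th else rev(th)
        for (t in th_i) {
          pos <- c(ax[i], Re * cos(t), Re * sin(t))
          tgt <- c(ax[i], Rt * cos(t), Rt * sin(t))
          poses[[length(poses) + 1L]] <-
            look_at_pose(pos, tgt, spec$focal_mm, spec$pixel_pitch_um,
                         image_size, up = c(1, 0, 0))
        }
      }
      poses
    }
    ## curvature slightly rotates neighbouring footprints, so verify the
    ## realised overlap with the estimator and densify until it is met
    tg <- list(kind = "half_cylinder", dims = spec$target)
    for (it in 1:20) {
      poses <- build(n_th, n_ax)
      ov_th <- estimate_overlap(poses[[1]], poses[[2]], tg,
                                sensor_mm = spec$sensor_mm)
      ov_ax <- estimate_overlap(poses[[1]], poses[[2 * n_th]], tg,
                                sensor_mm = spec$sensor_mm)
      grow <- FALSE
      if (ov_th < spec$overlap) { n_th <- n_th + 1L; grow <- TRUE }
      if (ov_ax < spec$overlap) { n_ax <- n_ax + 1L; grow <- TRUE }
      if (!grow) break
    }
    attr(poses, "n_axial") <- n_ax
    attr(poses, "n_angular") <- n_th
    poses
  } else {
    ee <- spec$envelope; tt <- spec$target
    d_polar <- ee[3] - tt[3]
    if (d_polar < spec$min_working_mm)
      stopf("working distance %.1f mm (polar) is below the %.0f mm minimum",
            d_polar, spec$min_working_mm)
    fp <- footprint_at(spec, d_polar)
    ## parameter steps from footprint arcs on the target's largest sections
    step_el <- fp[2] * step_fac / max(tt)
    step_az <- fp[1] * step_fac / max(tt[1], tt[2])
    if (fp[1] * step_fac < spec$min_spacing_mm ||
        fp[2] * step_fac < spec$min_spacing_mm)
      stopf("infeasible overlap %.2f: pose spacing below %.3g mm (footprint %.3g x %.3g mm)",
            spec$overlap, spec$min_spacing_mm, fp[1], fp[2])
    n_el <- max(2L, ceiling((pi / 2) / step_el) + 1L)
    el <- seq(0.1, pi / 2, length.out = n_el) # avoid the degenerate rim
    n_az <- max(3L, ceiling(pi / step_az) + 1L)
    az <- seq(0, pi, length.out = n_az)
    poses <- list()
    for (i in seq_along(el)) {
      az_i <- if (i %% 2 == 1) az else rev(az)
      for (a in az_i) {
        u <- c(cos(el[i]) * cos(a), cos(el[i]) * sin(a), sin(el[i]))
        pos <- ee * u
        tgt <- tt * u
        poses[[length(poses) + 1L]] <-
          look_at_pose(pos, tgt, spec$focal_mm, spec$pixel_pitch_um,
                       image_size,
                       up = if (abs(u[3]) < 0.95) c(0, 0, 1) else c(1, 0, 0))
      }
    }
    attr(poses, "n_elev") <- n_el
    attr(poses, "n_azim") <- n_az
    poses
  }
}

## Ray / target-surface intersection. `target` is a list:
##   list(kind = "half_cylinder", dims = c(R, L))
##   list(kind = "half_ellipsoid", dims = c(a, b, c))
##   list(kind = "plane")  (the z = 0 plane, used in tests)
ray_target_hit <- function(origin, dir, target) {
  if (target$kind == "plane") {
    if (abs(dir[3]) < 1e-12) return(NULL)
    t <- -origin[3] / dir[3]
    if (t <= 0) return(NULL)
    return(list(point = origin + t * dir, normal = c(0, 0, 1)))
  }
  if (target$kind == "half_cylinder") {
    R <- target$dims[1]
    a <- dir[2]^2 + dir[3]^2
    b <- 2 * (origin[2] * dir[2] + origin[3] * dir[3])
    cc <- origin[2]^2 + origin[3]^2 - R^2
    disc <- b^2 - 4 * a * cc
    if (a < 1e-14 || disc < 0) return(NULL)
    ## camera is outside, take the first (nearer) intersection
    t <- (-b - sqrt(disc)) / (2 * a)
    if (t <= 0) t <- (-b + sqrt(disc)) / (2 * a)
    if (t <= 0) return(NULL)
    pt <- origin + t * dir
    nrm <- c(0, pt[2], pt[3]); nrm <- nrm / sqrt(sum(nrm^2))
    return(list(point = pt, normal = nrm))
  }
  if (target$kind == "half_ellipsoid") {
    s <- target$dims
    o <- origin / s; dd <- dir / s
    a <- sum(dd^2); b <- 2 * sum(o * dd); cc <- sum(o^2) - 1
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NULL)
    t <- (-b - sqrt(disc)) / (2 * a)
    if (t <= 0) t <- (-b + sqrt(disc)) / (2 * a)
    if (t <= 0) return(NULL)
    pt <- origin + t * dir
    nrm <- pt / s^2; nrm <- nrm / sqrt(sum(nrm^2))
    return(list(point = pt, normal = nrm))
  }
  stopf("unknown target kind '%s'", target$kind)
}

## Footprint rectangle of a pose on the target: centre at the axis-target
## intersection, edges along the camera x/y directions projected into the
## local tangent plane, sized by the thin-lens footprint at the actual
## working distance. Returns centre, in-plane unit axes and half-extents.
pose_footprint <- function(pose, target, focal_mm = pose$focal_mm,
                           sensor_mm = c(36, 24)) {
  axis <- pose$rotation[3, ]
  hit <- ray_target_hit(pose$position, axis, target)
  if (is.null(hit)) stopf("pose optical axis does not intersect the target")
  d <- sqrt(sum((hit$point - pose$position)^2))
  if (d <= focal_mm) stopf("target closer than the focal length")
  m <- focal_mm / (d - focal_mm)
  fp <- sensor_mm / m
  proj <- function(v) {
    w <- v - sum(v * hit$normal) * hit$normal
    w / sqrt(sum(w^2))
  }
  ex <- proj(pose$rotation[1, ]) # image columns (sensor width)
  ey0 <- pose$rotation[2, ]
  ey <- ey0 - sum(ey0 * hit$normal) * hit$normal -
    sum(ey0 * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  list(center = hit$point, ex = ex, ey = ey,
       half = c(fp[1] / 2, fp[2] / 2))
}

## Sutherland-Hodgman clip of polygon `poly` (n x 2) against the
## axis-aligned rectangle [-hx, hx] x [-hy, hy]; returns the clipped area.
clip_rect_area <- function(poly, hx, hy) {
  clip_halfplane <- function(pts, a, b, c) {
    ## keep a*x + b*y <= c
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      P <- pts[i, ]; Q <- pts[if (i == n) 1 else i + 1, ]
      pin <- a * P[1] + b * P[2] <= c
      qin <- a * Q[1] + b * Q[2] <= c
      if (pin) out <- rbind(out, P)
      if (xor(pin, qin)) {
        t <- (c - a * P[1] - b * P[2]) /
          (a * (Q[1] - P[1]) + b * (Q[2] - P[2]))
        out <- rbind(out, P + t * (Q - P))
      }
    }
    out
  }
  p <- poly
  p <- clip_halfplane(p, 1, 0, hx)
  p <- clip_halfplane(p, -1, 0, hx)
  p <- clip_halfplane(p, 0, 1, hy)
  p <- clip_halfplane(p, 0, -1, hy)
  if (nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Footprint overlap between two camera poses
#'
#' Fraction of pose `a`'s footprint area on the target surface that is also
#' covered by pose `b`'s footprint, computed on locally planar patches at
#' the axis-target intersections (adequate at envelope scale). Identical
#' poses give 1; footprints separated beyond their extent give 0.
#'
#' @param a,b [camera_pose()] objects whose axes intersect the target.
#' @param target Target surface: `list(kind, dims)` with kind
#'   `"half_cylinder"` (`dims = c(radius, length)`), `"half_ellipsoid"`
#'   (`dims` = semi-axes) or `"plane"` (z = 0).
#' @param sensor_mm Sensor size `c(width, height)` (mm).
#' @return Overlap fraction in `[0, 1]`.
#' @export
estimate_overlap <- function(a, b, target, sensor_mm = c(36, 24)) {
  fa <- pose_footprint(a, target, sensor_mm = sensor_mm)
  fb <- pose_footprint(b, target, sensor_mm = sensor_mm)
  ## corners of b's rectangle, expressed in a's tangent-plane frame
  corners <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  pts3 <- t(apply(corners, 1, function(s) {
    fb$center + s[1] * fb$half[1] * fb$ex + s[2] * fb$half[2] * fb$ey
  }))
  rel <- sweep(pts3, 2, fa$center)
  poly <- cbind(rel %*% fa$ex, rel %*% fa$ey)
  inter <- clip_rect_area(poly, fa$half[1], fa$half[2])
  inter / (4 * fa$half[1] * fa$half[2])
}
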