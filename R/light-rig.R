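#' Calibrated directional light rig
#'
#' The multi-light illumination geometry used for photometric stereo:
#' unit direction vectors pointing from the surface toward each light
#' (object frame, z toward the camera) and relative intensities.
#'
#' Directions whose norm deviates from 1 by more than `1e-6` are
#' renormalised with a warning; deviations above `1e-2` are an error
#' (a calibration that far off is treated as corrupt).
#'
#' @param directions L x 3 numeric matrix of light directions.
#' @param intensities Relative intensity per light (scalar recycled).
#'
#' @return An object of class `light_rig` with `directions`, `intensities`
#'   and light count `L`.
#' @examples
#' rig <- light_rig(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)) /
#'                  sqrt(c(1, 2, 2)))
#' @export
light_rig <- function(directions, intensities = 1) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L || nrow(directions) < 1L)
    stopf("'directions' must be an L x 3 matrix")
  if (any(!is.finite(directions))) stopf("light directions must be finite")
  nrm <- sqrt(rowSums(directions^2))
  dev <- abs(nrm - 1)
  if (any(dev > 1e-2))
    stopf("light direction(s) %s deviate from unit norm by more than 1e-2",
          paste(which(dev > 1e-2), collapse = ", "))
  if (any(dev > 1e-6)) {
    warning("renormalising light directions with norm deviation > 1e-6")
  }
  directions <- directions / nrm
  L <- nrow(directions)
  intensities <- rep_len(as.numeric(intensities), L)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stopf("intensities must be finite and positive")
  structure(list(directions = directions, intensities = intensities, L = L),
            class = "light_rig")
}

#' @export
print.light_rig <- function(x, ...) {
  rc <- rig_condition(x)
  cat(sprintf("<light_rig> %d lights, rank %d, condition %.3g%s\n",
              x$L, rc$rank, rc$condition,
              if (rc$deficient) " [RANK DEFICIENT]" else ""))
  invisible(x)
}

#' Conditioning report for a light rig
#'
#' Photometric stereo needs at least three non-coplanar light directions;
#' this reports the rank and condition number of the L x 3 direction matrix
#' and flags coplanar (rank-deficient) rigs.
#'
#' @param rig A [light_rig()].
#' @return List with `rank`, `condition` (ratio of extreme singular values)
#'   and `deficient` flag (`rank < 3`).
#' @examples
#' rig_condition(light_rig(diag(3)))$condition # 1
#' @export
rig_condition <- function(rig) {
  if (!inherits(rig, "light_rig")) stopf("'rig' must be a light_rig")
  sv <- svd(rig$directions, nu = 0, nv = 0)$d
  tol <- max(dim(rig$directions)) * max(sv) * .Machine$double.eps
  rnk <- sum(sv > tol)
  list(rank = rnk,
       condition = if (min(sv) > 0) max(sv) / min(sv) else Inf,
       deficient = rnk < 3L)
}

#' Ring-arranged light rig
#'
#' Builds a rig of lights on concentric rings around the optical axis, the
#' geometry of a conical LED illumination basket: `counts[i]` lights evenly
#' spaced in azimuth at polar angle `polar_deg[i]` from the axis. Alternate
#' rings are rotated by half an azimuthal step so directions never repeat.
#' The default 6/12/12 arrangement gives 30 non-coplanar directions.
#'
#' @param counts Number of lights per ring.
#' @param polar_deg Polar angle of each ring, degrees from the optical axis.
#' @param intensities Relative intensities (recycled across lights).
#' @return A [light_rig()].
#' @examples
#' rig <- ring_light_rig() # 30 lights on 3 rings
#' @export
ring_light_rig <- function(counts = c(6L, 12L, 12L),
                           polar_deg = c(20, 35, 50), intensities = 1) {
  if (length(counts) != length(polar_deg))
    stopf("'counts' and 'polar_deg' must have equal length")
  dirs <- do.call(rbind, lapply(seq_along(counts), function(i) {
    n <- counts[i]; th <- polar_deg[i] * pi / 180
    az <- 2 * pi * (seq_len(n) - 1) / n + (i %% 2) * pi / n
    cbind(sin(th) * cos(az), sin(th) * sin(az), rep(cos(th), n))
  }))
  light_rig(dirs, intensities)
}
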