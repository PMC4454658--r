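#' No-reference perceptual blur metric
#'
#' Scores how blurred a frame is on a 0 (completely sharp) to 1
#' (completely blurred) scale by re-blurring: the image is convolved with a
#' strong low-pass filter (a 9-tap uniform 1-D kernel, horizontally and
#' vertically) and the loss of neighbour-to-neighbour intensity variation
#' is compared with the original. A sharp image changes a lot under the
#' filter (low score) while an already-blurred one barely changes (high
#' score). The final score is the larger of the horizontal and vertical
#' normalized scores. A constant image contains no sharpness to lose and
#' scores 1 by convention.
#'
#' @param frame Grayscale matrix in `[0, 1]` (RGB arrays are averaged to
#'   luminance), at least 2 x 2.
#' @param taps Length of the uniform blurring kernel (odd, default 9).
#' @return Blur score in `[0, 1]`.
#' @export
blur_metric <- function(frame, taps = 9L) {
  if (length(dim(frame)) == 3L) frame <- apply(frame, c(1, 2), mean)
  if (!is.matrix(frame) || nrow(frame) < 2L || ncol(frame) < 2L)
    stopf("'frame' must be at least a 2 x 2 matrix")
  taps <- as.integer(taps)
  if (taps < 3L || taps %% 2L == 0L) stopf("'taps' must be odd and >= 3")
  h <- taps %/% 2L
  pad_filter <- function(m, vertical) {
    ## replicate-pad along the filtered dimension, then uniform moving mean
    if (vertical) {
      mp <- rbind(m[rep(1L, h), , drop = FALSE], m,
                  m[rep(nrow(m), h), , drop = FALSE])
      out <- apply(mp, 2, function(v) stats::filter(v, rep(1 / taps, taps)))
      matrix(out[(h + 1):(h + nrow(m)), ], nrow(m), ncol(m))
    } else {
      mp <- cbind(m[, rep(1L, h), drop = FALSE], m,
                  m[, rep(ncol(m), h), drop = FALSE])
      out <- t(apply(mp, 1, function(v) stats::filter(v, rep(1 / taps, taps))))
      matrix(out[, (h + 1):(h + ncol(m))], nrow(m), ncol(m))
    }
  }
  score_dir <- function(vertical) {
    b <- pad_filter(frame, vertical)
    if (vertical) {
      d_f <- abs(diff(frame)); d_b <- abs(diff(b))
    } else {
      d_f <- abs(t(diff(t(frame)))); d_b <- abs(t(diff(t(b))))
    }
    s_f <- sum(d_f)
    if (s_f <= 0) return(1)
    v <- pmax(d_f - d_b, 0)
    (s_f - sum(v)) / s_f
  }
  max(score_dir(TRUE), score_dir(FALSE))
}

#' Fit the vibration-attenuation model to a blur series
#'
#' The post-motion vibration analysis: the basal (vibration-free) blur
#' `B0` is the mean of the last `basal_frames` values; the normalised blur
#' `B_norm = B - B0` of the remaining frames is fitted with the decaying
#' exponential `A * exp(-t / T)` (log-linear initialisation refined by
#' nonlinear least squares), and the attenuation time is the moment the
#' fitted amplitude falls below the stillness threshold `A_th`:
#' `t_att = T * ln(A / A_th)`, floored at 0. If every normalised blur is
#' already below `A_th` the series shows no vibration signal and the
#' conservative floor `t_att = 0.1 s` is reported without fitting.
#' Negative `B_norm` values are kept (not clipped) so the fit is unbiased.
#'
#' @param series A [blur_series()].
#' @param basal_frames Number of trailing frames defining the basal level
#'   (default 30).
#' @param A_th Blur threshold below which the camera counts as still
#'   (default 0.005).
#' @return An object of class `attenuation_fit`: `A`, `T_decay` (s),
#'   `t_att` (s), `A_th`, `B0`, `floor_applied`.
#' @examples
#' fit <- fit_attenuation(make_blur_series(A = 0.05, T_decay = 0.2))
#' fit$t_att # 0.2 * log(0.05 / 0.005) = 0.4605 s
#' @export
fit_attenuation <- function(series, basal_frames = 30L, A_th = 0.005) {
  if (!inherits(series, "blur_series")) stopf("'series' must be a blur_series")
  n <- length(series$values)
  if (n <= basal_frames)
    stopf("series length %d must exceed basal_frames = %d", n, basal_frames)
  B0 <- mean(series$values[(n - basal_frames + 1):n])
  head_idx <- seq_len(n - basal_frames)
  t <- series$times[head_idx]
  bn <- series$values[head_idx] - B0
  if (all(bn < A_th)) {
    return(structure(list(A = NA_real_, T_decay = NA_real_, t_att = 0.1,
                          A_th = A_th, B0 = B0, floor_applied = TRUE),
                     class = "attenuation_fit"))
  }
  ## log-linear initialisation on the clearly positive samples
  pos <- which(bn > max(bn) * 1e-3)
  init <- unname(stats::coef(stats::lm(log(bn[pos]) ~ t[pos])))
  A0 <- exp(init[1])
  T0 <- if (init[2] < 0) -1 / init[2] else diff(range(t)) / 2
  fit <- try(minpack.lm::nlsLM(bn ~ A * exp(-t / Td),
                               start = list(A = A0, Td = T0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stopf("exponential fit failed: %s", attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); Td <- unname(cf["Td"])
  if (!is.finite(Td) || Td <= 0) {
    res <- stats::resid(fit)
    stopf("fit produced non-positive time constant T = %.4g (residual RMS %.4g)",
          Td, sqrt(mean(res^2)))
  }
  t_att <- max(0, Td * log(A / A_th))
  structure(list(A = A, T_decay = Td, t_att = t_att, A_th = A_th, B0 = B0,
                 floor_applied = FALSE),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  if (x$floor_applied) {
    cat(sprintf("<attenuation_fit> below threshold %.3g, t_att floored at %.2g s\n",
                x$A_th, x$t_att))
  } else {
    cat(sprintf("<attenuation_fit> A = %.4g, T = %.4g s, t_att = %.4g s\n",
                x$A, x$T_decay, x$t_att))
  }
  invisible(x)
}
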