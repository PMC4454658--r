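#' Configuration of the repeatability shift search
#'
#' Parameters of the exhaustive integer-shift estimator used to quantify
#' camera positional repeatability: `N` randomly sampled pixels compared
#' between the two images, a search window of half-width `K` pixels, and
#' the exclusion threshold `T` on the minimal mean discrepancy (8-bit
#' intensity units) above which a pair is dropped from the statistics as
#' affected by rotational or axial misalignment.
#'
#' @param N Number of sampled pixels (default 5000).
#' @param K Half-width of the shift search window in pixels (default 50).
#' @param T Exclusion threshold on the minimal discrepancy, 0--255 scale
#'   (default 10).
#' @param seed Seed controlling the pixel sample.
#' @return An object of class `shift_search_config`.
#' @export
shift_search_config <- function(N = 5000L, K = 50L, T = 10, seed = NULL) {
  check_number(N, "N", min = 1)
  check_number(K, "K", min = 0)
  check_number(T, "T", min = 0, strict_min = TRUE)
  structure(list(N = as.integer(N), K = as.integer(K), T = T, seed = seed),
            class = "shift_search_config")
}

as_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (length(dim(img)) != 3L) stopf("images must be H x W or H x W x C")
  img * 255
}

#' Mean discrepancy between an image pair at a candidate shift
#'
#' Superimposes image A and image B shifted by `(X, Y)` pixels (X in rows /
#' "height", Y in columns / "width") and averages, over the sampled pixels,
#' the Euclidean distance between corresponding RGB triplets on the 0--255
#' intensity scale:
#' `sqrt((R_A - R_B)^2 + (G_A - G_B)^2 + (B_A - B_B)^2)`.
#' A pixel at `(r, c)` in A is compared with `(r + X, c + Y)` in B.
#'
#' @param imgA,imgB Images in `[0, 1]`, matrices or H x W x 3 arrays of
#'   equal size.
#' @param X,Y Candidate integer shift (rows, columns).
#' @param sample Two-column matrix of sampled (row, col) pixel coordinates
#'   in A; all shifted counterparts must fall inside B.
#' @return Mean discrepancy `F(X, Y)` (>= 0, 8-bit intensity units).
#' @export
shift_discrepancy <- function(imgA, imgB, X, Y, sample) {
  A <- as_rgb255(imgA); B <- as_rgb255(imgB)
  if (!identical(dim(A), dim(B))) stopf("images must have identical size")
  sample <- as.matrix(sample)
  if (!nrow(sample)) stopf("'sample' must contain at least one pixel")
  r <- sample[, 1]; c <- sample[, 2]
  rb <- r + as.integer(X); cb <- c + as.integer(Y)
  if (any(rb < 1 | rb > nrow(A) | cb < 1 | cb > ncol(A)))
    stopf("shifted sample falls outside image B")
  ss <- 0
  for (ch in seq_len(dim(A)[3])) {
    d <- A[cbind(r, c, ch)] - B[cbind(rb, cb, ch)]
    ss <- ss + d^2
  }
  mean(sqrt(ss))
}

#' Estimate the integer shift between two images
#'
#' Exhaustive minimisation of the mean discrepancy [shift_discrepancy()]
#' over the `(2K+1)^2` shift grid, on a fixed random sample of `N` pixels
#' drawn (without replacement, seeded) from the interior of A at a margin
#' of `K` pixels so every candidate shift is defined. Equal minima are
#' broken deterministically: smallest `|X| + |Y|` first, then row-major
#' order. The pair is flagged for exclusion when the minimal discrepancy
#' exceeds the threshold `T`, the signature of rotational/axial shifts the
#' translation-only model cannot capture.
#'
#' @inheritParams shift_discrepancy
#' @param cfg A [shift_search_config()].
#' @return An object of class `shift_estimate`: `X_min`, `Y_min`, `F_min`,
#'   `excluded`.
#' @export
estimate_shift <- function(imgA, imgB, cfg = shift_search_config()) {
  A <- as_rgb255(imgA); B <- as_rgb255(imgB)
  if (!identical(dim(A), dim(B))) stopf("images must have identical size")
  H <- dim(A)[1]; W <- dim(A)[2]; K <- cfg$K
  if (H < 2 * K + 2 || W < 2 * K + 2)
    stopf("images (%d x %d) too small for search half-width K = %d", H, W, K)
  rows <- (K + 1):(H - K); cols <- (K + 1):(W - K)
  navail <- length(rows) * length(cols)
  n <- min(cfg$N, navail)
  pick <- with_seed(cfg$seed, sample.int(navail, n))
  r <- rows[((pick - 1) %% length(rows)) + 1]
  c <- cols[((pick - 1) %/% length(rows)) + 1]
  nch <- dim(A)[3]
  Av <- lapply(seq_len(nch), function(ch) A[cbind(r, c, ch)])
  shifts <- as.matrix(expand.grid(X = -K:K, Y = -K:K))
  Fv <- numeric(nrow(shifts))
  lin0 <- r # row part reused
  for (i in seq_len(nrow(shifts))) {
    rb <- lin0 + shifts[i, 1]
    cb <- c + shifts[i, 2]
    ss <- 0
    for (ch in seq_len(nch)) {
      d <- Av[[ch]] - B[(ch - 1) * H * W + (cb - 1) * H + rb]
      ss <- ss + d * d
    }
    Fv[i] <- mean(sqrt(ss))
  }
  fmin <- min(Fv)
  cand <- which(Fv <= fmin)
  if (length(cand) > 1L) {
    l1 <- abs(shifts[cand, 1]) + abs(shifts[cand, 2])
    cand <- cand[order(l1, cand)][1]
  }
  structure(list(X_min = unname(shifts[cand, 1]),
                 Y_min = unname(shifts[cand, 2]),
                 F_min = fmin, excluded = fmin > cfg$T),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> (X, Y) = (%d, %d), F = %.4g%s\n",
              x$X_min, x$Y_min, x$F_min,
              if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}

#' Convert a pixel measure to micrometres
#'
#' @param px Value in pixels.
#' @param pixel_pitch_um Sensor pixel pitch (micrometres/pixel).
#' @return Value in micrometres.
#' @examples
#' px_to_um(8.65, 4.9) # 42.4 um mean shift magnitude
#' @export
px_to_um <- function(px, pixel_pitch_um = 4.9) px * pixel_pitch_um

#' Summary statistics of a repeatability test
#'
#' Aggregates the shift estimates of all image pairs of a repeatability
#' run: per-axis mean and SD of the shifts, mean and SD of the shift
#' magnitude `sqrt(X^2 + Y^2)`, and the Pearson correlation between X and
#' Y shifts, in pixels and micrometres. Estimates flagged `excluded`
#' (discrepancy above threshold) are dropped first.
#'
#' @param estimates List of [estimate_shift()] results.
#' @param pixel_pitch_um Sensor pixel pitch (micrometres/pixel).
#' @return List with `n`, `n_excluded`, per-axis `mean_px` / `sd_px` /
#'   `mean_um` / `sd_um` (named X, Y), `magnitude_mean_px`,
#'   `magnitude_sd_px`, their micrometre versions, and `pearson_xy`.
#' @export
repeatability_stats <- function(estimates, pixel_pitch_um = 4.9) {
  keep <- !vapply(estimates, `[[`, logical(1), "excluded")
  n_exc <- sum(!keep)
  est <- estimates[keep]
  if (!length(est)) stopf("all %d estimates are excluded", n_exc)
  X <- vapply(est, `[[`, numeric(1), "X_min")
  Y <- vapply(est, `[[`, numeric(1), "Y_min")
  if (length(est) < 2L)
    stopf("at least 2 non-excluded estimates are needed for SDs")
  mag <- sqrt(X^2 + Y^2)
  mean_px <- c(X = mean(X), Y = mean(Y))
  sd_px <- c(X = stats::sd(X), Y = stats::sd(Y))
  list(n = length(est), n_excluded = n_exc,
       mean_px = mean_px, sd_px = sd_px,
       mean_um = px_to_um(mean_px, pixel_pitch_um),
       sd_um = px_to_um(sd_px, pixel_pitch_um),
       magnitude_mean_px = mean(mag), magnitude_sd_px = stats::sd(mag),
       magnitude_mean_um = px_to_um(mean(mag), pixel_pitch_um),
       magnitude_sd_um = px_to_um(stats::sd(mag), pixel_pitch_um),
       pearson_xy = if (stats::sd(X) > 0 && stats::sd(Y) > 0)
         stats::cor(X, Y) else NA_real_)
}
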