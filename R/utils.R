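#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
# seed = NULL runs the code with the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a seed to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

# Bilinear interpolation of matrix `z` at fractional (row, col) positions.
# Positions outside the grid are clamped to the border.
interp_bilinear <- function(z, r, c) {
  H <- nrow(z); W <- ncol(z)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  z00 <- z[cbind(r0, c0)];     z10 <- z[cbind(r0 + 1L, c0)]
  z01 <- z[cbind(r0, c0 + 1L)]; z11 <- z[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * z00 + fr * (1 - fc) * z10 +
    (1 - fr) * fc * z01 + fr * fc * z11
}

# Orthonormal DCT-II basis matrix (rows = frequency index k = 0..N-1).
# Eigenvectors of the Neumann graph Laplacian of a path; cached per size.
dct_cache <- new.env(parent = emptyenv())
dct_basis <- function(N) {
  key <- as.character(N)
  if (!is.null(dct_cache[[key]])) return(dct_cache[[key]])
  k <- 0:(N - 1)
  C <- outer(k, k, function(k, n) cos(pi * (2 * n + 1) * k / (2 * N)))
  C <- C * sqrt(2 / N)
  C[1, ] <- C[1, ] / sqrt(2)
  dct_cache[[key]] <- C
  C
}

# Eigenvalues of the 1-D Neumann Laplacian (A'A for forward differences).
neumann_eigenvalues <- function(N) 2 - 2 * cos(pi * (0:(N - 1)) / N)
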