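# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its RNG state from a seed that
#' is a deterministic function of the master seed and a short label, so a whole
#' run is reproducible from one integer and independent stages do not share
#' RNG streams.
#'
#' @param seed Master seed (integer).
#' @param ... Label components (coerced to character) identifying the stage.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = "_"),
                      character(1)), collapse = "/")
  ints <- utf8ToInt(key)
  h <- sum(ints * seq_along(ints)) %% 1000003
  # multipliers kept small enough that the double arithmetic stays exact
  as.integer(((abs(seed) %% 2147483647) * 69069 + h * 9973) %% 2147483647)
}

#' Logarithmically spaced sequence
#' @param from,to Positive endpoints.
#' @param n Length.
#' @return Numeric vector.
#' @keywords internal
logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Causal convolution of a time series with a kernel
#'
#' `y[t] = sum_j k[j] * x[t - j + 1]`, truncated to the length of `x` (the
#' standard fMRI convention for hRF convolution).
#'
#' @param x Numeric vector.
#' @param kernel Numeric kernel.
#' @return Numeric vector, same length as `x`.
#' @export
conv_ts <- function(x, kernel) {
  n <- length(x)
  nk <- length(kernel)
  xp <- c(rep(0, nk - 1), x)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 1)
  as.numeric(y[nk:(nk + n - 1)])
}

# Lower-triangular banded matrix C with C[t, j] = kernel[t - j + 1], so that
# C %*% x performs the causal convolution above. Used to convolve many series
# at once with one BLAS call.
conv_matrix <- function(kernel, n) {
  C <- matrix(0, n, n)
  nk <- length(kernel)
  for (j in seq_len(n)) {
    tt <- j:min(n, j + nk - 1)
    C[tt, j] <- kernel[tt - j + 1]
  }
  C
}

# Convolve each row of M (series in rows) with kernel.
conv_rows <- function(M, kernel) {
  n <- ncol(M)
  M %*% t(conv_matrix(kernel, n))
}

#' Spatially smooth standard Gaussian random field
#'
#' An iid Gaussian field convolved with a Gaussian kernel of standard deviation
#' `ell` (grid units) along rows and columns, then re-standardized to zero mean
#' and unit variance. Used by the hemisphere generator so that vertex-wise
#' tuning varies smoothly over the sheet like real cortical surface maps.
#'
#' @param nr,nc Grid dimensions.
#' @param ell Correlation length in grid units; `0` yields an iid field.
#' @return `nr x nc` numeric matrix.
#' @keywords internal
smooth_field <- function(nr, nc, ell = 2) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (ell <= 0) return(z)
  sm <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * ell^2))
    K / rowSums(K)
  }
  f <- sm(nr) %*% z %*% t(sm(nc))
  (f - mean(f)) / stats::sd(as.vector(f))
}

# Minimal JSON sidecar writer for numeric/character scalars and vectors.
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
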