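# pRF model fitting: coarse-to-fine estimation of the 2D circular Gaussian
# (x0, y0, sigma) per vertex, and the stimulus-contrast (ON/OFF) null model
# whose prediction tracks total stimulated area rather than position.
#
# The coarse stage scores an exhaustive (x0, y0, sigma) grid. Because scale
# and an additive constant are fitted per candidate by closed-form least
# squares, the grid R^2 of a candidate is the squared correlation between
# its hRF-convolved prediction and the data, so the whole grid is scored
# with one matrix product against predictions that are precomputed once per
# aperture movie (prf_fit_grid). The fine stage is a Nelder-Mead refinement
# from the grid optimum.

#' Predicted BOLD time course of a circular-Gaussian pRF
#'
#' [prf_neural_response()] composed with hRF convolution; amplitude-free
#' (unit scale).
#'
#' @param apertures An `aperture_movie`.
#' @param x0,y0,sigma pRF parameters (deg; `sigma > 0`).
#' @param kernel hRF kernel; defaults to `hrf(apertures$tr)`.
#' @return Numeric vector, one value per timepoint.
#' @export
predict_prf <- function(apertures, x0, y0, sigma, kernel = hrf(apertures$tr)) {
  conv_ts(prf_neural_response(apertures, x0, y0, sigma), kernel)
}

#' Predicted BOLD time course of the stimulus-contrast model
#'
#' The mask area per timepoint (deg^2), hRF-convolved, unit scale: the
#' prediction of a vertex with no spatial selectivity.
#'
#' @inheritParams predict_prf
#' @return Numeric vector, one value per timepoint.
#' @export
predict_contrast <- function(apertures, kernel = hrf(apertures$tr)) {
  conv_ts(aperture_area(apertures), kernel)
}

#' Precompute the coarse pRF search grid for an aperture movie
#'
#' Builds hRF-convolved predictions for every candidate on an exhaustive
#' grid: (x0, y0) on a square lattice of spacing `pos_step` within
#' `+/- radius`, crossed with log-spaced sigma levels. Candidates are ordered
#' row-major in (x0, y0, sigma) so grid argmax ties break on the first
#' candidate in that order.
#'
#' @param apertures An `aperture_movie`.
#' @param pos_step Lattice spacing in deg.
#' @param sigmas Sigma levels in deg; default 20 log-spaced in `[0.25, 24]`.
#' @param kernel hRF kernel.
#' @return A `prf_grid` object reused across vertices by [fit_prf()].
#' @export
prf_fit_grid <- function(apertures, pos_step = 1,
                         sigmas = logspace(0.25, 24, 20),
                         kernel = hrf(apertures$tr)) {
  r <- apertures$radius
  xs <- seq(-floor(r / pos_step) * pos_step, floor(r / pos_step) * pos_step,
            by = pos_step)
  params <- expand.grid(sigma = sigmas, y0 = xs, x0 = xs,
                        KEEP.OUT.ATTRS = FALSE)[, c("x0", "y0", "sigma")]
  n_time <- apertures$n_time
  C <- conv_matrix(kernel, n_time)
  npos <- length(xs)^2
  P <- matrix(0, n_time, nrow(params))
  # group by sigma: one cells x positions Gaussian block per level
  pos <- expand.grid(y0 = xs, x0 = xs, KEEP.OUT.ATTRS = FALSE)
  for (si in seq_along(sigmas)) {
    s <- sigmas[si]
    G <- exp(-(outer(apertures$x, pos$x0, "-")^2 +
                 outer(apertures$y, pos$y0, "-")^2) / (2 * s^2)) *
      apertures$cell_area / (2 * pi * s^2)
    neural <- crossprod(apertures$masks, G)       # time x positions
    cols <- si + (seq_len(npos) - 1) * length(sigmas)
    P[, cols] <- C %*% neural
  }
  mu <- colMeans(P)
  Pc <- sweep(P, 2, mu)
  nrm <- sqrt(colSums(Pc^2))
  ok <- nrm > 1e-10
  Pn <- Pc
  Pn[, ok] <- sweep(Pc[, ok, drop = FALSE], 2, nrm[ok], "/")
  structure(list(apertures = apertures, kernel = kernel, params = params,
                 P = P, Pn = Pn, valid = ok,
                 center_index = which.min(params$x0^2 + params$y0^2),
                 conv = C),
            class = "prf_grid")
}

#' @export
print.prf_grid <- function(x, ...) {
  cat(sprintf("<prf_grid> %d candidates (%d sigma levels) x %d timepoints\n",
              nrow(x$params), length(unique(x$params$sigma)),
              nrow(x$P)))
  invisible(x)
}

#' Variance explained of a fitted prediction
#'
#' `R^2 = 1 - SSE / SStot` for the fitted series
#' `scale * prediction + intercept`, clipped to `[0, 1]`; defined as 0 for a
#' zero-variance data series.
#'
#' @param y Data vector.
#' @param prediction Model prediction (unit scale).
#' @param scale,intercept Fitted amplitude and offset.
#' @return R^2 in `[0, 1]`.
#' @export
variance_explained <- function(y, prediction, scale, intercept) {
  if (any(!is.finite(prediction))) stop("prediction contains non-finite values")
  sstot <- sum((y - mean(y))^2)
  if (sstot < 1e-24) return(0)
  sse <- sum((y - (scale * prediction + intercept))^2)
  clamp(1 - sse / sstot, 0, 1)
}

# least-squares scale + intercept of y on pred
ls_scale <- function(y, pred) {
  vp <- stats::var(pred)
  b <- if (vp < 1e-24) 0 else stats::cov(pred, y) / vp
  a <- mean(y) - b * mean(pred)
  c(scale = b, intercept = a)
}

prf_fit_row <- function(x0, y0, sigma, scale, intercept, r2, model,
                        r2_grid = NA_real_, degenerate = FALSE) {
  pol <- if (is.na(x0) || is.na(y0)) c(NA_real_, NA_real_) else to_polar(x0, y0)
  data.frame(model = model, x0 = x0, y0 = y0, sigma = sigma, scale = scale,
             intercept = intercept, r2 = r2, rho = unname(pol[1]),
             theta = unname(pol[2]), r2_grid = r2_grid,
             degenerate = degenerate, row.names = NULL)
}

#' Fit the circular-Gaussian pRF model to one vertex
#'
#' Stage 1 scores the exhaustive candidate grid (first-encountered maximum in
#' row-major (x0, y0, sigma) order on ties). Stage 2 refines (x0, y0,
#' log sigma) with Nelder-Mead from the grid optimum; the returned fit never
#' scores below the grid optimum. An all-constant series is flagged
#' degenerate and returned with `r2 = 0` at the grid center.
#'
#' @param y Time series (PSC units) of one vertex.
#' @param grid A `prf_grid` from [prf_fit_grid()].
#' @param refine Run the Nelder-Mead stage (default TRUE).
#' @param refine_tol Relative convergence tolerance of the refinement.
#' @param max_iter Nelder-Mead iteration cap.
#' @return One-row data.frame: `model` (`"prf"`), `x0`, `y0`, `sigma`,
#'   `scale`, `intercept`, `r2`, `rho`, `theta`, `r2_grid`, `degenerate`.
#' @export
fit_prf <- function(y, grid, refine = TRUE, refine_tol = 1e-4, max_iter = 400) {
  stopifnot(inherits(grid, "prf_grid"))
  ap <- grid$apertures
  if (length(y) != nrow(grid$P))
    stop("series length does not match the aperture movie")
  if (stats::sd(y) < 1e-12) {
    p <- grid$params[grid$center_index, ]
    return(prf_fit_row(p$x0, p$y0, p$sigma, 0, mean(y), 0, "prf",
                       degenerate = TRUE))
  }
  yc <- y - mean(y)
  yn <- yc / sqrt(sum(yc^2))
  r <- as.numeric(crossprod(grid$Pn, yn))
  r[!grid$valid] <- -Inf
  r2 <- r^2
  r2[!is.finite(r2)] <- -Inf
  best <- which.max(r2)                      # first max in row-major order
  pb <- grid$params[best, ]
  r2_grid <- max(r2[best], 0)

  bx <- pb$x0; by <- pb$y0; bs <- pb$sigma; br2 <- r2_grid
  if (refine) {
    sig_rng <- range(grid$params$sigma)
    r_max <- ap$radius
    obj <- function(par) {
      s <- exp(par[3])
      # refinement stays inside the searched domain: center within the
      # stimulated field, sigma within the coarse grid's range
      if (s < sig_rng[1] || s > sig_rng[2] ||
          abs(par[1]) > r_max || abs(par[2]) > r_max) return(1)
      pred <- as.numeric(grid$conv %*%
                           prf_neural_response(ap, par[1], par[2], s))
      pc <- pred - mean(pred)
      den <- sum(pc^2)
      if (den < 1e-20) return(1)
      1 - sum(pc * yc)^2 / (den * sum(yc^2))
    }
    opt <- stats::optim(c(pb$x0, pb$y0, log(pb$sigma)), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = refine_tol, maxit = max_iter))
    if (1 - opt$value > br2) {
      bx <- opt$par[1]; by <- opt$par[2]; bs <- exp(opt$par[3])
      br2 <- 1 - opt$value
    }
  }
  pred <- as.numeric(grid$conv %*% prf_neural_response(ap, bx, by, bs))
  sc <- ls_scale(y, pred)
  r2_final <- variance_explained(y, pred, sc["scale"], sc["intercept"])
  prf_fit_row(bx, by, bs, unname(sc["scale"]), unname(sc["intercept"]),
              max(r2_final, r2_grid), "prf", r2_grid = r2_grid)
}

#' Fit the stimulus-contrast (ON/OFF) model to one vertex
#'
#' Least-squares scale and intercept on the hRF-convolved mask-area
#' regressor; no spatial parameters.
#'
#' @param y Time series (PSC units).
#' @param apertures An `aperture_movie`.
#' @param kernel hRF kernel.
#' @return One-row data.frame as in [fit_prf()] with `model = "contrast"`
#'   and `sigma = NA`.
#' @export
fit_contrast <- function(y, apertures, kernel = hrf(apertures$tr)) {
  pred <- predict_contrast(apertures, kernel)
  sc <- ls_scale(y, pred)
  r2 <- variance_explained(y, pred, sc["scale"], sc["intercept"])
  out <- prf_fit_row(NA_real_, NA_real_, NA_real_, unname(sc["scale"]),
                     unname(sc["intercept"]), r2, "contrast")
  out$rho <- NA_real_; out$theta <- NA_real_
  out
}

#' Fit the pRF model to many vertices
#' @param Y Vertices x timepoints matrix (PSC units) or `ts_matrix`.
#' @inheritParams fit_prf
#' @return Data.frame with one row per vertex.
#' @export
fit_prf_many <- function(Y, grid, refine = TRUE, refine_tol = 1e-4,
                         max_iter = 400) {
  if (inherits(Y, "ts_matrix")) Y <- Y$values
  out <- lapply(seq_len(nrow(Y)), function(i)
    fit_prf(Y[i, ], grid, refine, refine_tol, max_iter))
  cbind(vertex = seq_len(nrow(Y)), do.call(rbind, out))
}

#' Cartesian pRF center to polar coordinates
#'
#' Eccentricity `rho = sqrt(x0^2 + y0^2)` and polar angle `theta` in
#' `[0, 360)` degrees, 0 at the right horizontal meridian, counterclockwise
#' positive; the origin maps to `(0, 0)`.
#'
#' @param x0,y0 Center coordinates in deg.
#' @return Numeric vector `c(rho, theta)`.
#' @export
to_polar <- function(x0, y0) {
  rho <- sqrt(x0^2 + y0^2)
  theta <- if (rho == 0) 0 else (atan2(y0, x0) * 180 / pi) %% 360
  c(rho = rho, theta = theta)
}
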