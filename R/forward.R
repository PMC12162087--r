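# Forward model: per-TR neural amplitudes implied by a schedule and a
# vertex's tuning, the circular-Gaussian pRF response to aperture movies,
# and BOLD synthesis (hRF convolution + drift + Gaussian noise + baseline).

amp_table <- function(tuning) {
  # amplitude (PSC units) each condition label drives, per vertex
  list(
    radial_in  = tuning$gain2d,
    radial_out = tuning$gain2d,
    cw         = tuning$gain2d,
    ccw        = tuning$gain2d,
    static     = 0 * tuning$gain2d,
    blank      = 0 * tuning$gain2d,
    coherent   = tuning$gain3d,
    scrambled  = tuning$gain3d * (1 - tuning$coh_sel),
    unpaired   = tuning$gain2d,
    paired     = tuning$gain2d * (1 - tuning$opponency))
}

#' Neural time course implied by a schedule for one vertex
#'
#' Boxcar amplitudes per TR: 2D-run moving blocks drive `gain2d` and static
#' blocks nothing; 3D-run coherent blocks drive `gain3d` and scrambled blocks
#' `gain3d * (1 - coh_sel)`; opponent-run unpaired blocks drive `gain2d` and
#' paired blocks `gain2d * (1 - opponency)`.
#'
#' @param tuning One-row data.frame (or list) with fields `gain2d`, `gain3d`,
#'   `coh_sel`, `opponency`.
#' @param schedule A `block_schedule`.
#' @param n_tr Optional number of TRs.
#' @return Numeric vector, one amplitude per TR.
#' @export
neural_response <- function(tuning, schedule, n_tr = NULL) {
  lab <- schedule_labels(schedule, n_tr)
  amps <- amp_table(tuning)
  unknown <- setdiff(unique(lab), names(amps))
  if (length(unknown) > 0)
    stop("unknown condition label: ", paste(unknown, collapse = ", "))
  vapply(lab, function(l) amps[[l]][1], numeric(1), USE.NAMES = FALSE)
}

#' Neural time courses for a whole hemisphere
#' @param hemi A `synthetic_hemisphere`.
#' @param schedule A `block_schedule`.
#' @param n_tr Optional number of TRs.
#' @return Vertices x TR matrix of amplitudes.
#' @export
neural_matrix <- function(hemi, schedule, n_tr = NULL) {
  lab <- schedule_labels(schedule, n_tr)
  amps <- amp_table(hemi$tuning)
  unknown <- setdiff(unique(lab), names(amps))
  if (length(unknown) > 0)
    stop("unknown condition label: ", paste(unknown, collapse = ", "))
  A <- vapply(lab, function(l) amps[[l]], numeric(nrow(hemi$tuning)))
  matrix(A, nrow = nrow(hemi$tuning))
}

#' Circular-Gaussian pRF response to an aperture movie
#'
#' `response(t) = sum_cells mask(t) * G(x - x0, y - y0; sigma)` with the
#' Gaussian normalized by its untruncated full-field integral, so a mask
#' covering the whole field yields a response of at most 1 (equal to 1 when
#' the Gaussian is fully contained in the field).
#'
#' @param apertures An `aperture_movie`.
#' @param x0,y0 pRF center in deg.
#' @param sigma pRF size (Gaussian SD) in deg (> 0).
#' @return Numeric vector, one response per timepoint.
#' @export
prf_neural_response <- function(apertures, x0, y0, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  g <- exp(-((apertures$x - x0)^2 + (apertures$y - y0)^2) / (2 * sigma^2)) *
    apertures$cell_area / (2 * pi * sigma^2)
  as.numeric(crossprod(apertures$masks, g))
}

#' Simulate a BOLD time series from a neural time course
#'
#' Convolves the neural course with the canonical hRF, then adds a linear
#' drift (total excursion `drift_slope` PSC over the run), iid Gaussian noise
#' with SD `noise_sd`, and a constant `baseline` (raw signal units; leave at
#' 0 to stay in PSC units). Deterministic given `seed`.
#'
#' @param neural Numeric vector of per-TR amplitudes (PSC units).
#' @param noise_sd Gaussian noise SD in PSC units (>= 0).
#' @param drift_slope Linear drift amplitude over the run, PSC units.
#' @param seed Integer seed.
#' @param tr Seconds per timepoint.
#' @param baseline Constant added to the signal.
#' @return Numeric vector the length of `neural`.
#' @export
simulate_bold <- function(neural, noise_sd = 0, drift_slope = 0, seed = 1,
                          tr = 1, baseline = 0) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n <- length(neural)
  y <- conv_ts(neural, hrf(tr)) +
    drift_slope * seq(-0.5, 0.5, length.out = n) + baseline
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "bold"))
    y <- y + stats::rnorm(n, sd = noise_sd)
  }
  y
}

#' Simulate a full localizer run for a hemisphere
#'
#' Vectorized version of [simulate_bold()] over all vertices, sharing one
#' drift and per-vertex iid noise.
#'
#' @param hemi A `synthetic_hemisphere`.
#' @param schedule A `block_schedule`.
#' @param noise_sd Noise SD (PSC units).
#' @param drift_slope Drift amplitude over the run (PSC units).
#' @param baseline Raw-signal baseline (default 100, so [to_psc()] applies).
#' @param seed Integer seed.
#' @return A `ts_matrix` (units `"raw"` when `baseline > 0`, else `"psc"`).
#' @export
simulate_run <- function(hemi, schedule, noise_sd = 0.5, drift_slope = 1,
                         baseline = 100, seed = 1) {
  A <- neural_matrix(hemi, schedule)
  n <- ncol(A)
  Y <- conv_rows(A, hrf(schedule$tr))
  Y <- Y + matrix(drift_slope * seq(-0.5, 0.5, length.out = n),
                  nrow(Y), n, byrow = TRUE) + baseline
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "run", nrow(Y), n))
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y), n)
  }
  ts_matrix(Y, schedule$tr, units = if (baseline > 0) "raw" else "psc")
}

#' Simulate a pRF-mapping run for a hemisphere
#'
#' Each vertex responds through its circular-Gaussian pRF to the aperture
#' movie, scaled by its mapping-stimulus response amplitude (`prf_gain`, a
#' stimulus-vs-blank PSC amplitude, distinct from the moving-minus-static
#' 2D-motion gain), convolved with the hRF, plus drift, noise and baseline.
#'
#' @inheritParams simulate_run
#' @param apertures An `aperture_movie`.
#' @param vertices Optional vertex subset (indices); default all.
#' @return A `ts_matrix` over the selected vertices.
#' @export
simulate_prf_run <- function(hemi, apertures, noise_sd = 0.5, drift_slope = 1,
                             baseline = 100, seed = 1, vertices = NULL) {
  tun <- hemi$tuning
  if (!is.null(vertices)) tun <- tun[vertices, , drop = FALSE]
  nv <- nrow(tun)
  n <- apertures$n_time
  resp <- matrix(0, nv, n)
  chunk <- 512
  for (s in seq(1, nv, by = chunk)) {
    e <- min(nv, s + chunk - 1)
    G <- vapply(s:e, function(i) {
      exp(-((apertures$x - tun$prf_x0[i])^2 + (apertures$y - tun$prf_y0[i])^2) /
            (2 * tun$prf_sigma[i]^2)) *
        apertures$cell_area / (2 * pi * tun$prf_sigma[i]^2)
    }, numeric(length(apertures$x)))
    resp[s:e, ] <- t(crossprod(apertures$masks, G))
  }
  resp <- resp * tun$prf_gain
  Y <- conv_rows(resp, hrf(apertures$tr))
  Y <- Y + matrix(drift_slope * seq(-0.5, 0.5, length.out = n),
                  nv, n, byrow = TRUE) + baseline
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "prfrun", nv, n))
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nv, n)
  }
  ts_matrix(Y, apertures$tr, units = if (baseline > 0) "raw" else "psc")
}

#' Export a time-series matrix as dense binary + JSON sidecar
#' @param ts A `ts_matrix`.
#' @param prefix Output path prefix (`<prefix>.bin`, `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_ts_bin <- function(ts, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.numeric(ts$values), con)
  close(con)
  write_sidecar(list(n_vertices = nrow(ts$values), n_time = ncol(ts$values),
                     tr = ts$tr, units = ts$units, order = "column-major"),
                paste0(prefix, ".json"))
  invisible(prefix)
}
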