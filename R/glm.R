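# General linear model: canonical hRF, design matrices, percent signal
# change, pseudoinverse beta estimation and the three localizer contrasts.

#' Canonical hemodynamic response function
#'
#' Double-gamma kernel (response gamma with mode at 6 s, undershoot gamma
#' with mode at 15 s weighted 1/6), sampled at the TR over a 32 s support and
#' normalized to unit sum so convolution preserves block amplitude.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @return Numeric kernel of length `ceiling(32 / tr)`.
#' @export
hrf <- function(tr = 1) {
  if (tr <= 0) stop("tr must be positive")
  n <- ceiling(32 / tr)
  t <- (seq_len(n) - 1) * tr
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Build a GLM design matrix from a block schedule
#'
#' One column per condition label (boxcar over the full block duration
#' convolved with the canonical hRF), plus a constant, a linear drift ramp
#' normalized to `[-0.5, 0.5]`, and optionally six nuisance (head motion)
#' regressors. Blank periods are the implicit baseline and get no column.
#'
#' @param schedule A `block_schedule`.
#' @param nuisance Optional `n_tr x 6` matrix of nuisance regressors.
#' @param n_tr Number of timepoints; defaults to the schedule duration.
#' @return A `design_matrix`: list with `values` (timepoints x regressors),
#'   `labels` (column names) and `tr`.
#' @export
build_design <- function(schedule, nuisance = NULL, n_tr = NULL) {
  validate_schedule(schedule)
  tr <- schedule$tr
  lab <- schedule_labels(schedule, n_tr)
  n <- length(lab)
  conds <- setdiff(unique(schedule$blocks$condition), "blank")
  if (length(conds) == 0) stop("schedule contains no task conditions")
  k <- hrf(tr)
  cols <- vapply(conds, function(cn) conv_ts(as.numeric(lab == cn), k), numeric(n))
  drift <- seq(-0.5, 0.5, length.out = n)
  X <- cbind(cols, constant = 1, drift = drift)
  labels <- c(conds, "constant", "drift")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (ncol(nuisance) != 6) stop("nuisance must have 6 columns")
    if (nrow(nuisance) != n) stop("nuisance length mismatch: ", nrow(nuisance),
                                  " rows vs ", n, " timepoints")
    X <- cbind(X, nuisance)
    labels <- c(labels, paste0("nuisance", 1:6))
  }
  colnames(X) <- labels
  structure(list(values = X, labels = labels, tr = tr), class = "design_matrix")
}

#' Convert a time-series matrix to percent signal change
#'
#' `psc = 100 * (y - mean) / mean`, per vertex; each output row has zero mean.
#'
#' @param ts Numeric matrix, vertices x timepoints, or a `ts_matrix`.
#' @return Same shape, in PSC units (a `ts_matrix` if one was supplied).
#' @export
to_psc <- function(ts) {
  is_tsm <- inherits(ts, "ts_matrix")
  Y <- if (is_tsm) ts$values else as.matrix(ts)
  m <- rowMeans(Y)
  bad <- which(abs(m) < 1e-12)
  if (length(bad) > 0)
    stop("zero-mean vertex cannot be converted to percent signal change: vertex ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- 100 * (Y - m) / m
  if (is_tsm) ts_matrix(out, ts$tr, units = "psc") else out
}

#' Estimate GLM beta weights by pseudoinverse
#'
#' `betas = pinv(X) %*% y` for every vertex. For multiple runs fit each run
#' separately and combine with [average_runs()].
#'
#' @param ts Vertices x timepoints matrix in PSC units (or a `ts_matrix` with
#'   `units == "psc"`).
#' @param design A `design_matrix` (or plain timepoints x regressors matrix).
#' @return Vertices x regressors matrix of betas, columns named by regressor.
#' @export
fit_glm <- function(ts, design) {
  Y <- if (inherits(ts, "ts_matrix")) {
    if (!identical(ts$units, "psc"))
      stop("time series must be in percent signal change units (see to_psc)")
    ts$values
  } else as.matrix(ts)
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  if (ncol(Y) != nrow(X))
    stop("dimension mismatch: ", ncol(Y), " timepoints vs ", nrow(X), " design rows")
  P <- MASS::ginv(X)            # regressors x timepoints
  B <- Y %*% t(P)
  colnames(B) <- colnames(X)
  B
}

#' Average beta estimates across runs
#' @param beta_list List of vertices x regressors matrices with matching shape.
#' @return Element-wise arithmetic mean (equal run weights).
#' @export
average_runs <- function(beta_list) {
  stopifnot(length(beta_list) >= 1)
  d <- dim(beta_list[[1]])
  for (b in beta_list) if (!identical(dim(b), d)) stop("run beta shapes differ")
  Reduce(`+`, beta_list) / length(beta_list)
}

#' Form a localizer contrast from beta weights
#'
#' Mean of the positive-label betas minus mean of the negative-label betas,
#' per vertex. The three study contrasts are: 2D motion = mean(moving
#' directions) - static; 3D motion = coherent - scrambled; opponency =
#' unpaired - paired.
#'
#' @param betas Vertices x regressors matrix from [fit_glm()].
#' @param positive,negative Character vectors of regressor labels.
#' @param name Optional contrast name attached as an attribute.
#' @return Numeric vector (one value per vertex, PSC units).
#' @export
contrast_map <- function(betas, positive, negative, name = NULL) {
  missing <- setdiff(c(positive, negative), colnames(betas))
  if (length(missing) > 0)
    stop("unknown regressor label: ", paste(missing, collapse = ", "))
  pos <- rowMeans(betas[, positive, drop = FALSE])
  neg <- rowMeans(betas[, negative, drop = FALSE])
  out <- pos - neg
  if (!is.null(name)) attr(out, "contrast") <- name
  out
}

#' Lightweight time-series container
#' @param values Vertices x timepoints matrix.
#' @param tr Seconds per timepoint.
#' @param units `"raw"` or `"psc"`.
#' @return A `ts_matrix`.
#' @export
ts_matrix <- function(values, tr = 1, units = c("raw", "psc")) {
  units <- match.arg(units)
  structure(list(values = as.matrix(values), tr = tr, units = units),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d vertices x %d timepoints (tr = %g s, %s)\n",
              nrow(x$values), ncol(x$values), x$tr, x$units))
  invisible(x)
}

#' Export a design matrix as TSV
#' @param design A `design_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
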