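# Validation statistics: R1 myelin proxy, within/between-ROI t tests with
# the study's df conventions (one-sample n-1; pooled two-sample
# n1 + n2 - 2, matching the printed df 389 = 296 + 95 - 2; paired
# hemispheres pairs - 1), decile profiles, the lightweight cohort simulator
# and the group-level report.

#' Longitudinal relaxation rate from T1
#'
#' `R1 = 1 / T1`, the myelin-density proxy (e.g. the average gray-matter T1
#' of 1.331 s corresponds to 0.751 s^-1). Rounded only at presentation.
#'
#' @param t1 T1 relaxation time in seconds (> 0, vectorized).
#' @return R1 in s^-1.
#' @export
r1_from_t1 <- function(t1) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  1 / t1
}

roi_comparison <- function(measure, statistic, df, p, direction, test) {
  structure(list(measure = measure, statistic = statistic, df = df, p = p,
                 direction = direction, test = test),
            class = "roi_comparison")
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat(sprintf("<%s t-test> %s: t(%g) = %.4f, p = %.3g\n",
              x$test, x$measure, x$df, x$statistic, x$p))
  invisible(x)
}

check_n <- function(x, n_min, what) {
  if (length(x) < n_min) stop(what, " requires at least ", n_min, " values")
}

#' One-sample t test of vertex values against zero
#'
#' @param values Numeric vector (n >= 2) of per-vertex values.
#' @param mu Null mean (default 0).
#' @param measure Label carried into the result.
#' @return An `roi_comparison` with df = n - 1 and a two-sided p.
#' @export
one_sample_t <- function(values, mu = 0, measure = "value") {
  check_n(values, 2, "one-sample t")
  if (stats::sd(values) < 1e-14)
    stop("zero-variance sample: one-sample t is undefined")
  tt <- stats::t.test(values, mu = mu)
  roi_comparison(measure, unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, sign(mean(values) - mu), "one-sample")
}

#' Pooled-variance two-sample t test (hMT/MST vs pFST convention)
#'
#' Student's t with pooled variance, df = n_a + n_b - 2; `direction` is the
#' sign of mean(a) - mean(b). Welch's correction is available behind
#' `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param one_tailed If TRUE, p is one-tailed for mean(a) > mean(b).
#' @param var_equal Pooled variance (default) or Welch.
#' @param measure Label carried into the result.
#' @return An `roi_comparison`.
#' @export
two_sample_t <- function(a, b, one_tailed = FALSE, var_equal = TRUE,
                         measure = "value") {
  check_n(a, 2, "two-sample t"); check_n(b, 2, "two-sample t")
  if (stats::sd(c(a - mean(a), b - mean(b))) < 1e-14)
    stop("zero pooled variance: two-sample t is undefined")
  alt <- if (one_tailed) "greater" else "two.sided"
  tt <- stats::t.test(a, b, var.equal = var_equal, alternative = alt)
  roi_comparison(measure, unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, sign(mean(a) - mean(b)), "two-sample")
}

#' Paired t test across hemispheres
#'
#' One-sample t on the paired differences, df = pairs - 1.
#'
#' @param a,b Numeric vectors of equal length (>= 2 pairs).
#' @param measure Label carried into the result.
#' @return An `roi_comparison`.
#' @export
paired_t <- function(a, b, measure = "value") {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  check_n(a, 2, "paired t")
  d <- a - b
  if (stats::sd(d) < 1e-14)
    stop("zero-variance differences: paired t is undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  roi_comparison(measure, unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, sign(mean(d)), "paired")
}

#' Decile profile of two ROI distributions
#'
#' The 10th..100th linear-interpolation percentiles of each distribution and
#' the sign of the ROI-b-minus-ROI-a slope at each decile (the dot-plot
#' connecting lines of the validation figure: negative slopes mean
#' hMT/MST > pFST).
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return Data.frame: `percentile`, `value_a`, `value_b`, `slope_sign`.
#' @export
decile_profile <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("decile profile requires non-empty samples")
  p <- seq(0.1, 1, by = 0.1)
  qa <- stats::quantile(values_a, p, type = 7, names = FALSE)
  qb <- stats::quantile(values_b, p, type = 7, names = FALSE)
  data.frame(percentile = 100 * p, value_a = qa, value_b = qb,
             slope_sign = sign(qb - qa))
}

#' Simulate a lightweight cohort of hemisphere measurements
#'
#' Generates per-vertex values of the four validation measures (2D motion,
#' 3D motion, opponency, R1) for both ROIs in every hemisphere of a cohort,
#' with a hemisphere-level random effect on top of vertex-level spread. This
#' is the group-statistics stand-in for running the full imaging pipeline on
#' every hemisphere: designed ROI effect gaps enter through `effects`, and a
#' null cohort (for type-I calibration) sets both ROI means equal.
#'
#' @param n_subjects Number of subjects (2 hemispheres each; default 9, so
#'   18 hemispheres).
#' @param effects Named list of `c(hMTMST = , pFST = )` mean pairs per
#'   measure. Defaults follow the study's orderings (hMT/MST > pFST for 2D
#'   motion, opponency, R1; pFST >= hMT/MST for 3D motion).
#' @param n_vertices `c(hMTMST = , pFST = )` vertex counts per ROI.
#' @param hemi_sd Hemisphere-level random-effect SD (same units as the
#'   measure; R1 uses `hemi_sd_r1`).
#' @param vertex_sd Vertex-level SD (R1 uses `vertex_sd_r1`).
#' @param hemi_sd_r1,vertex_sd_r1 SDs for the R1 measure (s^-1 scale).
#' @param seed Integer seed.
#' @return A `cohort`: list of hemispheres, each
#'   `list(subject, hemisphere, values)` where `values[[measure]]` is a list
#'   of per-vertex vectors `hMTMST` and `pFST`.
#' @export
simulate_cohort <- function(n_subjects = 9,
                            effects = list(
                              motion2d  = c(hMTMST = 2.0,   pFST = 0.8),
                              motion3d  = c(hMTMST = 0.5,   pFST = 1.5),
                              opponency = c(hMTMST = 1.2,   pFST = 0.12),
                              r1        = c(hMTMST = 0.838, pFST = 0.792)),
                            n_vertices = c(hMTMST = 296, pFST = 95),
                            hemi_sd = 0.2, vertex_sd = 0.5,
                            hemi_sd_r1 = 0.01, vertex_sd_r1 = 0.05,
                            seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  hemis <- list()
  for (s in seq_len(n_subjects)) {
    for (h in c("L", "R")) {
      set.seed(derive_seed(seed, "cohort", s, h))
      vals <- list()
      for (m in names(effects)) {
        hs <- if (m == "r1") hemi_sd_r1 else hemi_sd
        vs <- if (m == "r1") vertex_sd_r1 else vertex_sd
        vals[[m]] <- list(
          hMTMST = effects[[m]]["hMTMST"] + stats::rnorm(1, sd = hs) +
            stats::rnorm(n_vertices["hMTMST"], sd = vs),
          pFST = effects[[m]]["pFST"] + stats::rnorm(1, sd = hs) +
            stats::rnorm(n_vertices["pFST"], sd = vs))
      }
      hemis[[length(hemis) + 1]] <- list(subject = s, hemisphere = h,
                                         values = vals)
    }
  }
  structure(list(hemispheres = hemis, n_subjects = n_subjects, seed = seed),
            class = "cohort")
}

#' Group-level validation report
#'
#' Per measure: per-hemisphere ROI means, the group mean and SE across
#' hemispheres, the paired t test hMT/MST vs pFST, and the number of
#' hemispheres with an individually significant one-tailed two-sample test
#' (tested in the direction of the group-level difference).
#'
#' @param cohort A `cohort` from [simulate_cohort()] (or the same structure
#'   assembled from pipeline output).
#' @param alpha Per-hemisphere significance level.
#' @return A `group_report`: list with `summary` (data.frame, one row per
#'   measure) and `hemisphere_means` (long data.frame).
#' @export
group_report <- function(cohort, alpha = 0.05) {
  hemis <- cohort$hemispheres
  if (length(hemis) < 2) stop("group report requires >= 2 hemispheres")
  measures <- names(hemis[[1]]$values)
  rows <- list(); means_rows <- list()
  for (m in measures) {
    mh <- vapply(hemis, function(h) mean(h$values[[m]]$hMTMST), numeric(1))
    mp <- vapply(hemis, function(h) mean(h$values[[m]]$pFST), numeric(1))
    pt <- paired_t(mh, mp, measure = m)
    dir_up <- mean(mh) >= mean(mp)
    nsig <- sum(vapply(hemis, function(h) {
      a <- h$values[[m]]$hMTMST; b <- h$values[[m]]$pFST
      tt <- if (dir_up) two_sample_t(a, b, one_tailed = TRUE, measure = m)
            else two_sample_t(b, a, one_tailed = TRUE, measure = m)
      tt$p < alpha
    }, logical(1)))
    n <- length(hemis)
    rows[[m]] <- data.frame(
      measure = m,
      mean_hMTMST = mean(mh), se_hMTMST = stats::sd(mh) / sqrt(n),
      mean_pFST = mean(mp), se_pFST = stats::sd(mp) / sqrt(n),
      paired_t = pt$statistic, df = pt$df, p = pt$p,
      direction = pt$direction, n_sig_hemispheres = nsig, n_hemispheres = n)
    means_rows[[m]] <- data.frame(
      measure = m,
      subject = vapply(hemis, `[[`, 0, "subject"),
      hemisphere = vapply(hemis, `[[`, "", "hemisphere"),
      hMTMST = mh, pFST = mp)
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 hemisphere_means = do.call(rbind, c(means_rows, list(make.row.names = FALSE))),
                 alpha = alpha),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
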