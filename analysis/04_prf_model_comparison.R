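#!/usr/bin/env Rscript
# Stage 4 — pRF model vs stimulus-contrast model across regions.
#
# Simulates mapping runs for a sample of vertices from each ground-truth
# region (combined bar + wedge + ring protocol at a 61-cell raster for
# tractability), fits the circular-Gaussian pRF model and the
# stimulus-contrast (ON/OFF) null model to each vertex, and compares the
# variance explained. The expected signature: the pRF model wins clearly in
# the V1-like region and in hMT/MST, but adds almost nothing over the
# contrast model in pFST, whose pRFs exceed the 12.2 deg aperture.

library(fstloc)

dir.create("results", showWarnings = FALSE)
set.seed(20)
n_per_region <- 25
noise_sd <- 0.5

ap <- concat_apertures(
  gen_prf_apertures("bar", 12.2, 61, 8, 1, 3),
  gen_prf_apertures("wedge", 12.2, 61, 8, 1, 3),
  gen_prf_apertures("ring", 12.2, 61, 8, 1, 3))
grid <- prf_fit_grid(ap)
hemi <- make_hemisphere(seed = 1)

rows <- list()
for (rg in c("V1like", "hMTMST", "pFST")) {
  idx <- sample(which(hemi$region == rg), n_per_region)
  ts <- simulate_prf_run(hemi, ap, noise_sd = noise_sd, drift_slope = 0,
                         baseline = 0, seed = 7, vertices = idx)
  for (i in seq_along(idx)) {
    y <- ts$values[i, ]
    fp <- fit_prf(y, grid)
    fc <- fit_contrast(y, ap)
    rows[[length(rows) + 1]] <- data.frame(
      region = rg, vertex = idx[i],
      true_sigma = hemi$tuning$prf_sigma[idx[i]],
      sigma_hat = fp$sigma, ecc_hat = fp$rho,
      r2_prf = fp$r2, r2_contrast = fc$r2)
  }
}
fits <- do.call(rbind, rows)
write.csv(fits, "results/prf_model_comparison.csv", row.names = FALSE)

cat("\nVariance explained by region (median over vertices)\n")
agg <- aggregate(cbind(r2_prf, r2_contrast, sigma_hat, true_sigma) ~ region,
                 fits, median)
agg$r2_gap <- agg$r2_prf - agg$r2_contrast
print(agg, row.names = FALSE, digits = 3)
cat("\npFST pRF sizes are underestimated and its pRF model adds little\n")
cat("over the stimulus-contrast model, as expected for receptive fields\n")
cat("at or beyond the stimulus aperture.\n")
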