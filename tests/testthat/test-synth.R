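test_that("hemisphere generator is deterministic with the documented layout", {
  h1 <- make_hemisphere(seed = 3)
  h2 <- make_hemisphere(seed = 3)
  h3 <- make_hemisphere(seed = 4)
  expect_identical(h1$tuning, h2$tuning)
  expect_false(identical(h1$tuning, h3$tuning))
  expect_equal(as.vector(table(h1$region)[c("V1like", "hMTMST", "pFST")]),
               c(200, 296, 95))
  # pFST centroid anterior and/or inferior to hMT/MST
  th <- h1$tuning
  ch <- colMeans(th[th$region == "hMTMST", c("row", "col")])
  cf <- colMeans(th[th$region == "pFST", c("row", "col")])
  expect_true(cf["col"] > ch["col"] || cf["row"] > ch["row"])
  # pRF size ordering is wide enough to survive vertex spread
  ms <- tapply(th$prf_sigma, th$region, mean)
  expect_true(ms["pFST"] > ms["hMTMST"] && ms["hMTMST"] > ms["V1like"])
  expect_true(mean(th$t1[th$region == "hMTMST"]) < 1.331)
})

test_that("a zero-jitter atlas equals the truth and invalid configs fail", {
  h <- make_hemisphere(hemisphere_config(atlas_jitter = 0), seed = 1)
  expect_identical(as.character(h$atlas), as.character(h$region))
  expect_equal(dice(region_mask(h, "pFST"), region_mask(h, "pFST", atlas = TRUE)), 1)
  bad <- hemisphere_config()
  bad$regions$hMTMST$center <- c(500, 4)
  expect_error(make_hemisphere(bad), "outside the grid")
  bad2 <- hemisphere_config(
    grid = c(20, 20),
    regions = list(V1like = list(center = c(5, 5), n = 200),
                   hMTMST = list(center = c(10, 15), n = 296),
                   pFST = list(center = c(15, 18), n = 95)))
  expect_error(make_hemisphere(bad2), "exceed")
  bad3 <- hemisphere_config()
  bad3$means$t1["pFST"] <- 1.1      # would invert the myelination ordering
  expect_error(make_hemisphere(bad3), "T1 ordering")
})

test_that("neural response follows the boxcar amplitude rules", {
  tun <- list(gain2d = 1, gain3d = 2, coh_sel = 0.5, opponency = 0.4)
  so <- build_opponent_schedule(5, 4)
  r <- neural_response(tun, so)
  expect_equal(r[1:5], rep(1, 5))       # unpaired drives gain2d
  expect_equal(r[6:10], rep(0.6, 5))    # paired: gain2d * (1 - opponency)
  tun$opponency <- 0
  expect_equal(unique(neural_response(tun, so)), 1)
  tun$opponency <- 1
  r <- neural_response(tun, so)
  expect_equal(r[6:10], rep(0, 5))
  s3 <- build_3d_schedule(5, 1, blank_s = 0)
  r3 <- neural_response(tun, s3)
  expect_equal(r3, c(rep(2, 5), rep(1, 5)))  # scrambled: gain3d * (1 - coh_sel)
  bad <- so; bad$blocks$condition[1] <- "zap"
  expect_error(neural_response(tun, bad), "unknown condition")
})

test_that("pRF forward response integrates the Gaussian under the mask", {
  # even raster: no cell column sits exactly on the vertical meridian
  ap <- gen_prf_apertures("ring", radius = 12.2, grid_size = 80, n_steps = 4,
                          step_s = 1, ring_thickness = 12.2)
  g_full <- prf_neural_response(ap, 0, 0, 1)[4]   # step 4: full-field mask
  expect_equal(g_full, 1, tolerance = 1e-3)
  empty_ap <- ap; empty_ap$masks[] <- 0
  expect_equal(prf_neural_response(empty_ap, 0, 0, 1), rep(0, ap$n_time))
  # half-field mask over a centered Gaussian captures half its mass
  half_ap <- ap; half_ap$masks[half_ap$x < 0, ] <- 0
  expect_equal(prf_neural_response(half_ap, 0, 0, 1)[4], 0.5, tolerance = 0.02)
  expect_error(prf_neural_response(ap, 0, 0, 0), "sigma")
})

test_that("BOLD synthesis is exact in the noiseless limit and calibrated in noise", {
  expect_equal(simulate_bold(rep(0, 50)), rep(0, 50))
  x <- c(rep(0, 10), rep(1, 20), rep(0, 20))
  expect_equal(simulate_bold(x, noise_sd = 0), conv_ts(x, hrf(1)))
  resid <- simulate_bold(rep(0, 1e4), noise_sd = 1, seed = 8)
  expect_equal(sd(resid), 1, tolerance = 0.05)
  expect_error(simulate_bold(x, noise_sd = -1), "noise_sd")
  # simulator never yields non-finite values
  h <- make_hemisphere(hemisphere_config(grid = c(24, 24),
    regions = list(V1like = list(center = c(6, 4), n = 20),
                   hMTMST = list(center = c(8, 14), n = 40),
                   pFST = list(center = c(12, 17), n = 12))), seed = 2)
  ts <- simulate_run(h, build_opponent_schedule(5, 4), noise_sd = 2, seed = 3)
  expect_true(all(is.finite(ts$values)))
})
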