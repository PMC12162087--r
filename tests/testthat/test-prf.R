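# pRF model fitting against brute-force and closed-form oracles.

test_that("polar transform follows the meridian conventions", {
  expect_equal(to_polar(0, 0), c(rho = 0, theta = 0))
  expect_equal(to_polar(0, 5), c(rho = 5, theta = 90))
  p <- to_polar(-3, -4)
  expect_equal(unname(p[1]), 5)
  expect_equal(unname(p[2]), 233.1301, tolerance = 1e-4)
})

test_that("variance explained matches its definition and edge cases", {
  y <- rnorm(50)
  expect_equal(variance_explained(y, y, 1, 0), 1)
  expect_equal(variance_explained(y, rep(1, 50), 0, mean(y)), 0)
  expect_equal(variance_explained(rep(2, 50), y, 1, 0), 0)  # zero-variance data
  # construct y = prediction + orthogonal residual of equal power
  set.seed(31)
  p <- rnorm(80); p <- p - mean(p)
  r <- rnorm(80); r <- r - mean(r)
  r <- r - p * sum(p * r) / sum(p^2)
  r <- r * sqrt(sum(p^2) / sum(r^2))
  expect_equal(variance_explained(p + r, p, 1, 0), 0.5, tolerance = 1e-12)
})

test_that("contrast-model predictions track stimulated area", {
  # rotating wedge: constant area, flat prediction after the hRF transient
  wap <- gen_prf_apertures("wedge", 12.2, 41, 8, step_s = 3)
  pw <- predict_contrast(wap)
  late <- pw[32:length(pw)]
  expect_lt(diff(range(late)) / mean(late), 0.02)
  # expanding ring: prediction equals the convolved annulus-area course
  rap <- gen_prf_apertures("ring", 12.2, 41, 8, step_s = 1)
  expect_equal(predict_contrast(rap), conv_ts(aperture_area(rap), hrf(1)))
})

test_that("mirror-symmetric pRFs see a single bar sweep in reverse", {
  ap1 <- gen_prf_apertures("bar", 12.2, 41, 8, step_s = 1, directions = 0)
  a <- predict_prf(ap1, 4, 2, 1.5)
  b <- predict_prf(ap1, -4, 2, 1.5)
  # compare at the neural stage (convolution is causal, so reverse before hRF)
  na <- prf_neural_response(ap1, 4, 2, 1.5)
  nb <- prf_neural_response(ap1, -4, 2, 1.5)
  expect_equal(na, rev(nb), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("a giant pRF degenerates to the stimulus-contrast prediction", {
  ap <- bar_ap()
  p_big <- predict_prf(ap, 0, 0, 200)
  p_area <- predict_contrast(ap)
  expect_gt(cor(p_big, p_area), 0.999)
})

test_that("the coarse grid stage matches a brute-force search oracle", {
  ap <- bar_ap()
  xs <- seq(-12, 12, by = 4)
  sigmas <- c(1, 4, 12)
  g <- prf_fit_grid(ap, pos_step = 4, sigmas = sigmas)
  set.seed(77)
  for (i in 1:4) {
    y <- sim_map_series(ap, runif(1, -6, 6), runif(1, -6, 6),
                        runif(1, 0.8, 6), amp = 1, noise = 0.3, seed = 70 + i)
    fit <- fit_prf(y, g, refine = FALSE)
    oracle <- brute_prf_grid(y, ap, xs, sigmas, hrf(1))
    expect_equal(c(fit$x0, fit$y0, fit$sigma), unname(oracle$par))
    expect_equal(fit$r2_grid, oracle$r2, tolerance = 1e-8)
  }
})

test_that("zero-noise fits recover the generating parameters", {
  g <- bar_grid()
  cases <- rbind(c(3, 0, 1), c(-5.3, 4.1, 2.5), c(0, 0, 1.2), c(6, -2, 5))
  for (i in seq_len(nrow(cases))) {
    y <- sim_map_series(bar_ap(), cases[i, 1], cases[i, 2], cases[i, 3])
    f <- fit_prf(y, g)
    expect_lt(abs(f$x0 - cases[i, 1]), 0.1)
    expect_lt(abs(f$y0 - cases[i, 2]), 0.1)
    expect_lt(abs(f$sigma - cases[i, 3]) / cases[i, 3], 0.05)
    expect_gte(f$r2, f$r2_grid)          # refinement never loses ground
    expect_gt(f$r2, 0.999)
  }
})

test_that("pure noise wins little variance and degenerate input is flagged", {
  g <- bar_grid()
  set.seed(55)
  r2s <- replicate(5, fit_prf(rnorm(bar_ap()$n_time), g, refine = FALSE)$r2_grid)
  expect_lt(max(r2s), 0.25)
  expect_lt(mean(r2s), 0.1)
  f0 <- fit_prf(rep(0, bar_ap()$n_time), g)
  expect_true(f0$degenerate)
  expect_equal(f0$r2, 0)
  expect_error(fit_prf(rnorm(10), g), "length")
})

test_that("the contrast model fit is exact on its own prediction", {
  ap <- bar_ap()
  pred <- predict_contrast(ap)
  f <- fit_contrast(2.5 * pred + 1, ap)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$scale, 2.5, tolerance = 1e-8)
  # orthogonal series: no variance captured
  set.seed(6)
  o <- rnorm(length(pred))
  o <- o - mean(o)
  pc <- pred - mean(pred)
  o <- o - pc * sum(pc * o) / sum(pc^2)
  expect_lt(fit_contrast(o, ap)$r2, 1e-10)
})
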