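test_that("R1 is the reciprocal relaxation rate", {
  expect_equal(round(r1_from_t1(1.331), 3), 0.751)
  expect_equal(r1_from_t1(1), 1)
  expect_equal(r1_from_t1(2), 0.5)
  expect_equal(r1_from_t1(c(1, 2)), c(1, 0.5))
  expect_error(r1_from_t1(0), "positive")
  expect_error(r1_from_t1(-1.2), "positive")
})

test_that("t statistics match the hand formulas to 1e-10", {
  set.seed(19)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1))
    a <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(3:30, 1))
    p <- rnorm(length(a))
    expect_equal(one_sample_t(x)$statistic, hand_one_sample_t(x), tolerance = 1e-10)
    expect_equal(two_sample_t(a, b)$statistic, hand_pooled_two_sample_t(a, b),
                 tolerance = 1e-10)
    expect_equal(paired_t(a, p)$statistic, hand_paired_t(a, p), tolerance = 1e-10)
  }
})

test_that("df conventions and worked examples hold", {
  expect_equal(one_sample_t(c(2, 0, 2, 0))$statistic, sqrt(3), tolerance = 1e-10)
  expect_equal(one_sample_t(c(2, 0, 2, 0))$df, 3)
  # 296 vs 95 vertices gives the pooled df of 389
  set.seed(2)
  tt <- two_sample_t(rnorm(296), rnorm(95))
  expect_equal(tt$df, 389)
  expect_equal(two_sample_t(c(0, 2), c(1, 3))$statistic,
               hand_pooled_two_sample_t(c(0, 2), c(1, 3)), tolerance = 1e-12)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # 18 hemisphere pairs give df 17; differences {1, 3} give t = 2
  expect_equal(paired_t(rnorm(18), rnorm(18))$df, 17)
  expect_equal(paired_t(c(2, 4), c(1, 1))$statistic, 2, tolerance = 1e-12)
  expect_equal(paired_t(c(2, 4), c(1, 1))$df, 1)
})

test_that("degenerate samples are rejected with messages", {
  expect_error(one_sample_t(rep(0, 5)), "zero-variance")
  expect_error(one_sample_t(1), "at least")
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero-variance")
  expect_error(paired_t(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("decile profiles interpolate percentiles and sign the slopes", {
  a <- rnorm(200)
  d0 <- decile_profile(a, a)
  expect_equal(d0$slope_sign, rep(0, 10))
  d1 <- decile_profile(a, a + 1)
  expect_equal(d1$slope_sign, rep(1, 10))
  d2 <- decile_profile(1:100, 1:100)
  expect_equal(d2$value_a[5], 50.5)     # interpolated 50th percentile
  expect_equal(d2$percentile, seq(10, 100, 10))
  expect_error(decile_profile(numeric(0), a), "non-empty")
})

test_that("the designed cohort reproduces the group-level orderings", {
  co <- simulate_cohort(seed = 11)
  expect_length(co$hemispheres, 18)
  gr <- group_report(co)
  s <- gr$summary
  expect_equal(s$df, rep(17, 4))
  # hMT/MST > pFST for 2D motion, opponency and R1; pFST >= hMT/MST for 3D
  expect_equal(s$direction[s$measure %in% c("motion2d", "opponency", "r1")],
               rep(1, 3))
  expect_equal(s$direction[s$measure == "motion3d"], -1)
  expect_lt(s$p[s$measure == "opponency"], 1e-4)
  expect_gt(s$n_sig_hemispheres[s$measure == "opponency"], 15 * 0.8)
  # dropping a hemisphere drops the paired df by one
  co17 <- co; co17$hemispheres <- co17$hemispheres[-1]
  expect_equal(group_report(co17)$summary$df[1], 16)
})

test_that("vertex values within a hemisphere carry the designed gap", {
  co <- simulate_cohort(n_subjects = 1, seed = 5)
  h <- co$hemispheres[[1]]
  expect_length(h$values$opponency$hMTMST, 296)
  expect_length(h$values$opponency$pFST, 95)
  tt <- two_sample_t(h$values$opponency$hMTMST, h$values$opponency$pFST)
  expect_equal(tt$df, 389)
  expect_gt(tt$statistic, 5)
})
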