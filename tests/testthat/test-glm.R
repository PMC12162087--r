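test_that("the canonical hRF kernel is unit-sum with a 6 s peak", {
  for (tr in c(1, 0.5)) {
    k <- hrf(tr)
    expect_length(k, ceiling(32 / tr))
    expect_equal(sum(k), 1)
    peak_t <- (which.max(k) - 1) * tr
    expect_lte(abs(peak_t - 6), tr / 2)
  }
  expect_error(hrf(0), "tr")
})

test_that("design matrices carry one hRF boxcar per condition plus confounds", {
  s3 <- build_3d_schedule(10, 2)
  X <- build_design(s3)
  expect_equal(ncol(X$values), 4)      # 2 conditions + constant + drift
  expect_setequal(X$labels, c("coherent", "scrambled", "constant", "drift"))
  expect_equal(range(X$values[, "drift"]), c(-0.5, 0.5))
  expect_equal(X$values[, "constant"], rep(1, nrow(X$values)))

  s2 <- build_2d_schedule(15, 1)
  expect_equal(ncol(build_design(s2)$values), 7)   # 4 motion + static + 2

  nui <- matrix(rnorm(nrow(X$values) * 6), ncol = 6)
  expect_equal(ncol(build_design(s3, nuisance = nui)$values), 10)
  expect_error(build_design(s3, nuisance = nui[, 1:3]), "6 columns")
  expect_error(build_design(s3, nuisance = nui[-1, ]), "mismatch")
  blanked <- s3; blanked$blocks$condition[] <- "blank"
  expect_error(build_design(blanked), "no task conditions")
})

test_that("percent signal change matches its defining formula", {
  expect_equal(as.vector(to_psc(matrix(5, 1, 10))), rep(0, 10))
  expect_equal(as.vector(to_psc(matrix(c(90, 110), 1))), c(-10, 10))
  Y <- matrix(100 + rnorm(300), 3, 100)
  P <- to_psc(Y)
  expect_equal(rowMeans(P), rep(0, 3), tolerance = 1e-12)
  expect_equal(P[2, ], 100 * (Y[2, ] - mean(Y[2, ])) / mean(Y[2, ]))
  Y[2, ] <- Y[2, ] - mean(Y[2, ])
  expect_error(to_psc(Y), "vertex 2")
})

test_that("pseudoinverse betas equal the normal-equations solution", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(20:60, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    b_pkg <- fit_glm(matrix(y, 1), X)
    expect_equal(as.vector(b_pkg), as.vector(normal_eq_betas(X, y)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless GLM recovers exact coefficients and is linear", {
  s <- build_3d_schedule(10, 3)
  X <- build_design(s)
  b_true <- c(coherent = 1.4, scrambled = 0.3, constant = 0.2, drift = -0.8)
  y <- as.vector(X$values %*% b_true)
  b_hat <- fit_glm(matrix(y, 1), X)
  expect_equal(as.vector(b_hat), unname(b_true), tolerance = 1e-8)
  expect_equal(as.vector(fit_glm(matrix(0, 1, nrow(X$values)), X)), rep(0, 4))
  expect_error(fit_glm(matrix(y[-1], 1), X), "mismatch")
  # contrasts are linear in the data
  c1 <- contrast_map(b_hat, "coherent", "scrambled")
  c3 <- contrast_map(fit_glm(matrix(3 * y, 1), X), "coherent", "scrambled")
  expect_equal(c3, 3 * c1)
  expect_equal(contrast_map(b_hat, "coherent", "coherent"), 0)
  expect_error(contrast_map(b_hat, "coherent", "nothere"), "unknown regressor")
})

test_that("run averaging takes the equal-weight mean", {
  b1 <- matrix(1, 2, 3); b2 <- matrix(3, 2, 3)
  expect_equal(average_runs(list(b1, b2)), matrix(2, 2, 3))
  expect_error(average_runs(list(b1, matrix(1, 3, 3))), "shapes")
})
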