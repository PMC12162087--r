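test_that("percentile thresholding keeps the expected top fraction", {
  m <- matrix(0:99, 10, 10)
  expect_equal(sum(percentile_threshold(m, 95)), 5)
  expect_true(all(percentile_threshold(matrix(7, 5, 5), 95)))
  # monotone: raising q never adds vertices
  set.seed(3)
  m2 <- matrix(rnorm(400), 20, 20)
  lo <- percentile_threshold(m2, 90)
  hi <- percentile_threshold(m2, 95)
  expect_true(all(lo[hi]))
  expect_error(percentile_threshold(m2, 89), "90")
  expect_error(percentile_threshold(m2, 96), "95")
})

test_that("cluster extraction is 4-connected with deterministic ordering", {
  expect_equal(connected_clusters(matrix(FALSE, 4, 4)), list())
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_length(connected_clusters(diagm), 2)
  m <- matrix(FALSE, 8, 8)
  m[2:4, 2:4] <- TRUE; m[7, 7] <- TRUE
  cl <- connected_clusters(m)
  expect_equal(vapply(cl, length, 0L), c(9L, 1L))
  expect_setequal(cl[[1]], which(matrix(seq_len(64), 8, 8) %in% which(m))[1:9])
})

test_that("overlap scenarios are classified as drawn", {
  a <- matrix(FALSE, 6, 6); b <- matrix(FALSE, 6, 6)
  a[1:2, 1:2] <- TRUE; b[5:6, 5:6] <- TRUE
  expect_equal(classify_scenario(a, b), "disjoint")
  sub <- matrix(FALSE, 6, 6); sup <- matrix(FALSE, 6, 6)
  sub[2:3, 2:3] <- TRUE; sup[1:4, 1:4] <- TRUE
  expect_equal(classify_scenario(sub, sup), "overlap_3d_superset")
  expect_equal(classify_scenario(sup, sub), "overlap_2d_superset")
  expect_error(classify_scenario(a, matrix(FALSE, 5, 5)), "shape")
})

test_that("DICE, centroid distance and surface area match hand arithmetic", {
  a <- matrix(FALSE, 10, 10); a[1:2, 1:5] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[9:10, 6:10] <- TRUE
  expect_equal(dice(a, b), 0)
  c <- matrix(FALSE, 10, 10); c[1:2, 4:8] <- TRUE   # |a|=|b|=10, overlap 4
  expect_equal(dice(a, c), 0.4)
  expect_equal(dice(a, c), dice(c, a))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)

  p <- matrix(FALSE, 10, 10); p[1, 1] <- TRUE
  q <- matrix(FALSE, 10, 10); q[4, 5] <- TRUE       # 3-4-5 triangle
  expect_equal(centroid_distance(p, q), 5)
  expect_equal(centroid_distance(p, p), 0)
  b1 <- matrix(FALSE, 20, 20); b1[2:3, 2:3] <- TRUE
  b2 <- matrix(FALSE, 20, 20); b2[12:13, 2:3] <- TRUE
  expect_equal(centroid_distance(b1, b2), 10)
  expect_equal(centroid_distance(b1, b2, spacing = 2), 20)
  expect_error(centroid_distance(p, matrix(FALSE, 10, 10)), "empty")

  expect_equal(surface_area(matrix(FALSE, 5, 5)), 0)
  expect_equal(surface_area(matrix(TRUE, 10, 10), 1), 100)
  expect_equal(surface_area(matrix(TRUE, 8, 12), 3.14), 301.44)
  expect_error(surface_area(a, 0), "vertex_area")
})

# two-region fixture: an hMT/MST-like block plus candidate clusters on a
# 20 x 20 sheet over a low-amplitude scattered background (seeded, so the
# percentile thresholds land between background and activation values)
fixture_maps <- function(anterior_val = 10, posterior_val = 10) {
  set.seed(321)
  base <- matrix(runif(400, 0, 0.1), 20, 20)
  m2 <- base; m3 <- base
  m2[8:11, 8:11] <- 20                     # hMT/MST block (2D)
  m3[8:11, 8:11] <- 20                     # 3D also covers it
  m3[13:15, 12:14] <- anterior_val         # anterior/inferior candidate
  m3[3:5, 3:5] <- posterior_val            # posterior/superior candidate
  list(m2 = m2, m3 = m3)
}

test_that("delineation selects the anterior/inferior candidate", {
  mp <- fixture_maps()
  roi <- delineate(mp$m2, mp$m3, min_size = 5)
  expect_equal(sum(roi$hMTMST), 16)
  expect_true(all(which(roi$pFST) %in% which(row(roi$pFST) >= 13)))
  ch <- colMeans(which(roi$hMTMST, arr.ind = TRUE))
  cf <- colMeans(which(roi$pFST, arr.ind = TRUE))
  expect_true(cf["col"] > ch["col"] || cf["row"] > ch["row"])
  expect_equal(roi$threshold_2d, 95)
  # labels disjoint and 4-connected
  expect_equal(sum(roi$hMTMST & roi$pFST), 0)
  expect_length(connected_clusters(roi$pFST), 1)
})

test_that("delineation is invariant to adding a constant to both maps", {
  mp <- fixture_maps()
  r1 <- delineate(mp$m2, mp$m3, min_size = 5)
  r2 <- delineate(mp$m2 + 7, mp$m3 + 7, min_size = 5)
  expect_identical(r1$labels, r2$labels)
})

test_that("thresholds relax toward the 90th percentile when needed", {
  # only 4 candidate vertices clear the 95th percentile (below the minimum
  # cluster size); the rest of the candidate emerges at a lower threshold
  set.seed(321)
  base <- matrix(runif(400, 0, 0.1), 20, 20)
  m2 <- base; m2[8:11, 8:11] <- 20
  m3 <- base; m3[8:11, 8:11] <- 20
  m3[13, 12:15] <- 30
  m3[14, 12:15] <- 1
  roi <- delineate(m2, m3, min_size = 5)
  expect_lt(roi$threshold_2d, 95)
  expect_gte(roi$threshold_2d, 90)
  expect_gte(sum(roi$pFST), 5)
})

test_that("a hemisphere with no qualifying candidate flags an empty pFST", {
  set.seed(321)
  base <- matrix(runif(400, 0, 0.1), 20, 20)
  m2 <- base; m2[8:11, 8:11] <- 20
  roi <- delineate(m2, base, min_size = 5)
  expect_false(roi$pfst_found)
  expect_equal(sum(roi$pFST), 0)
  expect_equal(sum(roi$hMTMST), 16)
})
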