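test_that("eccentricity-speed profiles match their closed forms", {
  expect_equal(radial_speed(0), 0)
  expect_equal(radial_speed(2.5), 12 * sqrt(2.5 / 10))   # = 6 deg/s
  expect_equal(radial_speed(2.5), 6)
  expect_equal(radial_speed(10), 12)
  expect_equal(rotational_speed(10), 12)
  # rotational scaling stays perceptible near the fovea
  expect_gt(rotational_speed(0.1), radial_speed(0.1))
})

test_that("2D dot movie keeps dots in the aperture, within lifetime, speed-capped", {
  s <- build_2d_schedule(5, 1, blank_s = 5)
  m <- gen_2d_dot_movie(s, seed = 4, frame_rate = 20, store = "frames")
  expect_equal(m$stats$n_frames, 45 * 20)
  expect_lte(m$stats$max_ecc, 10)
  expect_lte(m$stats$max_age, 0.5 + 1e-9)
  expect_lte(m$stats$max_speed, 12 + 1e-9)
  # non-blank frames hold exactly 250 dots; blank frames none
  nd <- vapply(m$frames, nrow, 0L)
  expect_true(all(nd[m$condition_labels == "blank"] == 0))
  expect_true(all(nd[m$condition_labels != "blank"] == 250))
  # radial-block speeds follow the square-root profile exactly
  f_rad <- which(m$condition_labels %in% c("radial_in", "radial_out"))[5]
  d <- m$frames[[f_rad]]
  expect_equal(d$speed, radial_speed(sqrt(d$x^2 + d$y^2)), tolerance = 1e-12)
  # static blocks freeze positions (except respawns, which reset age)
  f_st <- which(m$condition_labels == "static")
  i <- f_st[10]
  a <- m$frames[[i]]; b <- m$frames[[i + 1]]
  survived <- b$age > 1 / 20
  expect_equal(b$x[survived], a$x[survived])
  expect_equal(b$y[survived], a$y[survived])
})

test_that("2D dot movie is deterministic given the seed", {
  s <- build_2d_schedule(5, 1, blank_s = 0)
  m1 <- gen_2d_dot_movie(s, seed = 9, frame_rate = 10, store = "frames")
  m2 <- gen_2d_dot_movie(s, seed = 9, frame_rate = 10, store = "frames")
  m3 <- gen_2d_dot_movie(s, seed = 10, frame_rate = 10, store = "frames")
  expect_identical(m1$frames, m2$frames)
  expect_false(identical(m1$frames, m3$frames))
})

test_that("2D dot movie rejects schedules with unknown condition labels", {
  s <- build_2d_schedule(5, 1)
  s$blocks$condition[1] <- "wobble"
  expect_error(gen_2d_dot_movie(s, seed = 1), "unknown condition")
})

test_that("opponent movie: 300 dots, 150 left / 150 right, pairing geometry", {
  mp <- gen_opponent_movie("paired", duration = 1, seed = 2, frame_rate = 60,
                           store = "frames")
  expect_equal(mp$stats$min_dots, 300)
  expect_equal(mp$stats$max_dots, 300)
  # pair lifetime: 1 deg of relative travel at 10 deg/s closing speed
  expect_lte(mp$stats$max_age, 0.1 + 1e-9)
  expect_lte(mp$stats$max_pair_sep, 0.5 + 1e-9)
  for (f in c(1, 17, 60)) {
    d <- mp$frames[[f]]
    expect_equal(nrow(d), 300)
    expect_equal(sum(d$direction == 1), 150)
    expect_equal(sum(d$direction == -1), 150)
    expect_true(all(sqrt(d$x^2 + d$y^2) <= 10 + 1e-9))
    # members of a pair share their y-coordinate and sit within 0.5 deg
    byp <- split(d, d$pair_id)
    expect_true(all(vapply(byp, function(p) diff(p$y) == 0, logical(1))))
    expect_true(all(vapply(byp, function(p) abs(diff(p$x)) <= 0.5 + 1e-9,
                           logical(1))))
  }
  mu <- gen_opponent_movie("unpaired", duration = 1, seed = 2, frame_rate = 60,
                           store = "frames")
  expect_equal(mu$stats$min_dots, 300)
  d <- mu$frames[[30]]
  expect_equal(sum(d$direction == 1), 150)   # same marginal direction split
  expect_true(all(sqrt(d$x^2 + d$y^2) <= 10 + 1e-9))
  expect_error(gen_opponent_movie("sideways", 1, 1), "arg")
})
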