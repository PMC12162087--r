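test_that("2D localizer schedule reproduces the block-design arithmetic", {
  s <- build_2d_schedule(15, 3)
  expect_equal(stimulus_duration(s), 360)          # 6 min of stimulation
  expect_equal(sum(s$blocks$condition != "blank"), 24)
  expect_equal(s$blocks$condition[nrow(s$blocks)], "blank")
  expect_equal(s$blocks$duration[nrow(s$blocks)], 15)
  expect_equal(s$total_duration, 375)

  s1 <- build_2d_schedule(15, 1)
  expect_equal(sum(s1$blocks$condition != "blank"), 8)
  expect_equal(stimulus_duration(s1), 120)

  # hand enumeration: (10, 2) gives 4 directions x 2 reps x (move + static)
  # = 16 blocks of 10 s = 160 s of stimulation
  s2 <- build_2d_schedule(10, 2)
  expect_equal(sum(s2$blocks$condition != "blank"), 16)
  expect_equal(stimulus_duration(s2), 160)
  moving <- s2$blocks$condition[seq(1, 16, by = 2)]
  expect_equal(sort(as.vector(table(moving))), rep(2, 4))
  expect_setequal(unique(moving), c("radial_in", "radial_out", "cw", "ccw"))
})

test_that("3D and opponent schedules reproduce the printed durations", {
  s3 <- build_3d_schedule(10, 15)
  expect_equal(stimulus_duration(s3), 300)         # 5 min
  expect_equal(sum(s3$blocks$condition != "blank"), 30)
  expect_equal(build_3d_schedule(10, 1)$blocks$condition[1:2],
               c("coherent", "scrambled"))
  expect_equal(stimulus_duration(build_3d_schedule(5, 4)), 40)

  so <- build_opponent_schedule(15, 21)
  expect_equal(so$total_duration, 315)             # 5 m 15 s
  expect_equal(so$blocks$condition[1], "unpaired")
  expect_equal(build_opponent_schedule(15, 2)$total_duration, 30)
  expect_equal(build_opponent_schedule(10, 5)$total_duration, 50)
  expect_equal(build_opponent_schedule(10, 5, start = "paired")$blocks$condition[1],
               "paired")
})

test_that("schedule invariants hold across random valid parameterizations", {
  set.seed(41)
  for (i in 1:15) {
    bs <- sample(c(5, 10, 15, 20), 1)
    reps <- sample(1:4, 1)
    s <- build_2d_schedule(bs, reps)
    expect_silent(validate_schedule(s))
    expect_equal(stimulus_duration(s), 4 * reps * 2 * bs)
    s3 <- build_3d_schedule(bs, reps)
    expect_equal(stimulus_duration(s3), 2 * reps * bs)
    nb <- sample(2:9, 1)
    so <- build_opponent_schedule(bs, nb)
    expect_equal(so$total_duration, nb * bs)
    # strict alternation
    expect_true(all(so$blocks$condition[-1] != so$blocks$condition[-nb]))
  }
})

test_that("invalid schedule parameters are rejected with a message", {
  expect_error(build_2d_schedule(0, 3), "block_s")
  expect_error(build_2d_schedule(15, 0), "reps")
  expect_error(build_3d_schedule(-1, 15), "block_s")
  expect_error(build_opponent_schedule(15, 1), "n_blocks")
})

test_that("per-TR labels and events export are consistent with the blocks", {
  s <- build_3d_schedule(10, 2, tr = 1, blank_s = 5)
  lab <- schedule_labels(s)
  expect_length(lab, 45)
  expect_equal(lab[1:10], rep("coherent", 10))
  expect_equal(lab[11:20], rep("scrambled", 10))
  expect_equal(lab[41:45], rep("blank", 5))
  expect_equal(label_at_time(s, 10.5), "scrambled")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(s, path)
  ev <- read.delim(path)
  expect_named(ev, c("onset", "duration", "trial_type"))
  expect_equal(ev$onset, s$blocks$onset)
  expect_equal(ev$trial_type, s$blocks$condition)
})
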