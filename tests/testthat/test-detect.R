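test_that("referencing zeroes the dark1 mean and shifts all samples equally", {
  base <- c(rnorm(100, 0, 0.1), rnorm(100, 2, 0.1))
  blk <- make_two_phase_trace(base[1:100] + 3.2, base[101:200] + 3.2)
  ref <- reference_torsion(blk)
  d1 <- ref$samples$phase == "dark1"
  expect_equal(mean(ref$samples$eyeR_t[d1]), 0, tolerance = 1e-12)
  expect_equal(ref$samples$eyeR_t,
               blk$samples$eyeR_t - mean(blk$samples$eyeR_t[d1]),
               tolerance = 1e-12)
  # an already-zero-mean dark1 phase leaves the block unchanged
  blk0 <- make_two_phase_trace(base[1:100] - mean(base[1:100]), base[101:200])
  ref0 <- reference_torsion(blk0)
  expect_equal(ref0$samples$eyeR_t, blk0$samples$eyeR_t, tolerance = 1e-12)

  bad <- blk
  bad$samples$valid_L[bad$samples$phase == "dark1"] <- FALSE
  bad$samples$valid_R[bad$samples$phase == "dark1"] <- FALSE
  expect_error(reference_torsion(bad), "dark1")
})

test_that("blink detection follows the bilateral-dropout rule", {
  n <- 500
  expect_identical(nrow(detect_blinks(make_trace(rnorm(n)))), 0L)

  # both eyes invalid for 15 frames at 50 Hz -> one blink of 300 ms
  vl <- vr <- rep(TRUE, n); vl[101:115] <- vr[101:115] <- FALSE
  blk <- make_trace(rnorm(n, 0, 0.01), valid_L = vl, valid_R = vr)
  ev <- detect_blinks(blk)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration, 300)
  expect_identical(ev$onset_index, 101L)
  expect_identical(ev$offset_index, 115L)

  # one eye alone invalid is a pupil-detection artifact, not a blink
  vl <- rep(TRUE, n); vl[101:108] <- FALSE
  expect_identical(nrow(detect_blinks(make_trace(rnorm(n), valid_L = vl))), 0L)

  blk2 <- make_trace(rnorm(n))
  blk2$samples$valid_L <- NULL
  expect_error(detect_blinks(blk2), "validity")
})

test_that("pre/post positions are read at exactly the safety times", {
  # step trace: torsion 4.0 before a 300 ms gap, 1.5 after (noiseless)
  n <- 400
  torsion <- c(rep(4, 200), rep(1.5, 200))
  vl <- vr <- rep(TRUE, n); vl[201:215] <- vr[201:215] <- FALSE
  blk <- make_trace(torsion, valid_L = vl, valid_R = vr)
  ev <- detect_blinks(blk)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$usable)
  expect_equal(ev$pre_t, 4.0)
  expect_equal(ev$post_t, 1.5)
  expect_equal(ev$pre_time, ev$onset_time - 0.140)
  expect_equal(ev$post_time, ev$offset_time + 0.200)
})

test_that("blinks with colliding safety windows are flagged unusable", {
  n <- 600
  vl <- vr <- rep(TRUE, n)
  vl[101:115] <- vr[101:115] <- FALSE
  vl[122:136] <- vr[122:136] <- FALSE   # second blink 140 ms after the first
  ev <- detect_blinks(make_trace(rnorm(n, 0, 0.01), valid_L = vl, valid_R = vr))
  expect_identical(nrow(ev), 2L)
  expect_false(any(ev$usable[1]))       # post read inside blink 2's window
  # a blink at the block edge has no room for its pre read
  vl <- vr <- rep(TRUE, n); vl[3:17] <- vr[3:17] <- FALSE
  ev <- detect_blinks(make_trace(rnorm(n, 0, 0.01), valid_L = vl, valid_R = vr))
  expect_false(ev$usable[1])
})

test_that("no position read ever falls inside a blink safety window", {
  sim <- simulate_block(tiny_config(seed = 9))
  ref <- reference_torsion(sim$block)
  ev <- detect_blinks(ref)
  use <- ev[ev$usable, ]
  for (j in seq_len(nrow(use))) {
    inside_pre <- use$pre_time[j] > ev$onset_time - 0.14 + 1e-6 &
      use$pre_time[j] < ev$offset_time + 0.2 - 1e-6
    inside_post <- use$post_time[j] > ev$onset_time - 0.14 + 1e-6 &
      use$post_time[j] < ev$offset_time + 0.2 - 1e-6
    expect_false(any(inside_pre))
    expect_false(any(inside_post))
  }
})

test_that("blink recovery is exact without noise and >= 99% with noise", {
  nl <- simulate_block(noiseless_config(seed = 10))
  det <- detect_blinks(nl$block)
  tr <- nl$truth$blinks
  expect_identical(nrow(det), nrow(tr))
  expect_equal(det$onset_time, tr$onset_time, tolerance = 1 / 50)
  expect_equal(det$offset_time, tr$offset_time, tolerance = 1 / 50)

  sims <- simulate_experiment(tiny_config(), n_blocks = 2, seed = 10)
  hit <- total <- 0
  for (s in sims) {
    det <- detect_blinks(s$block)
    for (t0 in s$truth$blinks$onset_time) {
      total <- total + 1
      if (any(abs(det$onset_time - t0) < 0.05)) hit <- hit + 1
    }
  }
  expect_gte(hit / total, 0.99)
})

test_that("a constant-velocity drift yields a single slow phase and no fasts", {
  fs <- 50
  tor <- c(rep(0, 100), cumsum(rep(2 / fs, 300)))
  blk <- make_trace(tor, phase = c(rep("dark1", 100), rep("flow1", 300)))
  ph <- segment_nystagmus(blk, detect_blinks(blk))
  fl <- ph[ph$phase == "flow1", ]
  expect_identical(sum(fl$kind == "fast"), 0L)
  expect_identical(sum(fl$kind == "slow"), 1L)
  expect_equal(fl$mean_velocity[fl$kind == "slow"], 2, tolerance = 0.05)
})

test_that("a noiseless sawtooth is segmented at the constructed indices", {
  fs <- 50
  n_dark <- 100
  t_flow <- seq_len(500) / fs
  tor <- cumsum(rep(3 / fs, 500))          # 3 deg/s drift
  resets <- seq(50, 450, by = 50)          # fast resets of -2 deg
  for (r in resets) {
    u <- min_jerk(((seq_len(500)) - r) / 3)  # 60 ms = 3 samples
    tor <- tor - 2 * u
  }
  blk <- make_trace(c(rep(0, n_dark), tor),
                    phase = c(rep("dark1", n_dark), rep("flow1", 500)))
  ph <- segment_nystagmus(blk, detect_blinks(blk))
  fast <- ph[ph$kind == "fast", ]
  expect_identical(nrow(fast), length(resets))
  for (i in seq_along(resets)) {
    expect_lte(abs(fast$onset_index[i] - (n_dark + resets[i])), 3)
    expect_equal(fast$amplitude[i], -2, tolerance = 0.25)
    if (i > 1)
      expect_equal(fast$preceding_slow_amplitude[i], 3, tolerance = 0.6)
  }
})

test_that("segmentation is invariant to a constant torsion offset", {
  sim <- simulate_block(noiseless_config(seed = 13))
  ref <- reference_torsion(sim$block)
  blinks <- detect_blinks(ref)
  a <- segment_nystagmus(ref, blinks)
  shifted <- ref
  for (col in c("eyeL_t", "eyeR_t"))
    shifted$samples[[col]] <- shifted$samples[[col]] + 5
  b <- segment_nystagmus(shifted, blinks)
  expect_identical(a$kind, b$kind)
  expect_identical(a$onset_index, b$onset_index)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
})

test_that("mirroring the flow direction mirrors fast-phase directions", {
  cw <- simulate_block(noiseless_config(flow_direction = "cw", seed = 14))
  ccw <- simulate_block(noiseless_config(flow_direction = "ccw", seed = 14))
  pc <- analyze_block(cw$block)$fasts
  pc <- pc[pc$phase %in% c("flow1", "flow2"), ]
  pw <- analyze_block(ccw$block)$fasts
  pw <- pw[pw$phase %in% c("flow1", "flow2"), ]
  expect_true(all(pc$torsional_shift < 0))
  expect_true(all(pw$torsional_shift > 0))
})
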