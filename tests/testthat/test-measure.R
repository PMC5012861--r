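test_that("blink shift measurement is post minus pre in every channel", {
  n <- 400
  torsion <- c(rep(4, 200), rep(1.52, 200))
  vl <- vr <- rep(TRUE, n); vl[201:215] <- vr[201:215] <- FALSE
  blk <- make_trace(torsion, valid_L = vl, valid_R = vr,
                    h = c(rep(1, 200), rep(0.5, 200)),
                    v = c(rep(-2, 200), rep(-1, 200)))
  blinks <- detect_blinks(blk)
  m <- measure_barms(blk, blinks, segment_nystagmus(blk, blinks))
  expect_identical(nrow(m), 1L)
  expect_equal(m$torsional_shift, -2.48)
  expect_equal(m$h_shift, -0.5)
  expect_equal(m$v_shift, 1)
  expect_equal(m$pre_t, 4)
})

test_that("zero gain and zero pre-blink torsion give zero shift", {
  cfg <- noiseless_config(
    barm_gain_by_phase = c(dark1 = 0, flow = 0, dark2 = 0),
    hv_barm_gain = 0, seed = 16)
  sim <- simulate_block(cfg)
  expect_lt(max(abs(sim$truth$blinks$shift_t)), 1e-8)
})

test_that("measured BARM shifts equal logged truth exactly without noise", {
  sim <- simulate_block(noiseless_config(seed = 17))
  out <- analyze_block(sim$block)
  tr <- sim$truth$blinks
  m <- out$barms
  expect_gt(nrow(m), 5)
  idx <- vapply(m$onset_time, function(t)
    which.min(abs(tr$onset_time - t)), integer(1))
  expect_true(all(abs(tr$onset_time[idx] - m$onset_time) < 0.05))
  # flow phases: exact (drive suppressed across the measurement window);
  # darkness: the post read happens ~0.7 s into the dark decay, so the
  # measured shift includes that small decay
  fl <- m$phase %in% c("flow1", "flow2")
  expect_gt(sum(fl), 2)
  # exact up to rare events where a fast phase lands on the read sample
  expect_lt(median(abs(m$torsional_shift[fl] - tr$shift_t[idx][fl])), 1e-6)
  expect_lt(quantile(abs(m$torsional_shift[fl] - tr$shift_t[idx][fl]), 0.9),
            1e-5)
  expect_lt(quantile(abs(m$pre_t[fl] - tr$pre_t[idx][fl]), 0.9), 1e-5)
  expect_lt(max(abs(m$torsional_shift[!fl] - tr$shift_t[idx][!fl])), 0.25)
})

test_that("fast-phase shift measurements are definitional", {
  fs <- 50
  tor <- c(rep(0, 100), cumsum(rep(3 / fs, 200)))
  tor <- tor - 2 * min_jerk((seq_along(tor) - 200) / 3)  # 5.97 -> 3.97 reset
  blk <- make_trace(tor, phase = c(rep("dark1", 100), rep("flow1", 200)))
  ph <- segment_nystagmus(blk, detect_blinks(blk))
  m <- measure_fast_phase_shifts(ph, "cw")
  expect_identical(nrow(m), 1L)
  expect_equal(m$torsional_shift, -2, tolerance = 0.25)
  expect_equal(m$pre_shift_position, tor[200], tolerance = 0.3)
})

test_that("blank shifts carry only the drift accrued around the blank", {
  cfg <- noiseless_config(include_blanks = TRUE, seed = 18)
  sim <- simulate_block(cfg)
  out <- analyze_block(sim$block)
  m <- measure_blank_shifts(out$block, sim$truth$blanks, blinks = out$blinks)
  expect_gt(nrow(m), 10)
  # with no resetting injected at blanks, the measured shift must equal the
  # latent drift between the two read times exactly (noise-free run)
  lat <- sim$truth$latent
  fs <- cfg$sampling_rate
  pre_lat <- lat$t[round((m$onset_time - 0.14) * fs) + 1]
  post_lat <- lat$t[round((m$onset_time + m$duration / 1000 + 0.2) * fs) + 1]
  expect_lt(max(abs(m$torsional_shift - (post_lat - pre_lat))), 1e-5)
  expect_true(all(m$duration %in% (cfg$blank_durations * 1000)))
})

test_that("coil decomposition recovers constructed two-bump kinematics", {
  fs <- 200
  tt <- (seq_len(1200) - 1) / fs
  onset <- 2
  # bump 1: +1 deg excursion peaking in velocity at +110 ms, returning
  # exponentially (the canonical transient); bump 2: -2 deg displacement,
  # velocity peak at +180 ms (70 ms after bump 1)
  d1 <- 0.1; d2 <- 0.1
  t1s <- onset + 0.11 - d1 / 2
  bump1 <- min_jerk((tt - t1s) / d1)
  late <- tt > t1s + d1
  bump1[late] <- exp(-(tt[late] - (t1s + d1)) / 0.22)
  pos <- bump1 - 2 * min_jerk((tt - (onset + 0.18 - d2 / 2)) / d2)
  samples <- data.frame(
    time_s = tt, eyeL_h = 0, eyeL_v = 0, eyeL_t = pos,
    eyeR_h = 0, eyeR_v = 0, eyeR_t = pos,
    valid_L = TRUE, valid_R = TRUE, phase = "flow1",
    stimulus_state = "flow_cw", stringsAsFactors = FALSE)
  coil <- eye_trace_block(samples, modality = "coil", sampling_rate = fs)
  cc <- decompose_coil_blinks(coil, data.frame(onset_time = onset))
  expect_true(cc$usable)
  expect_false(cc$merged)
  expect_equal(cc$comp1_peak_time, 110, tolerance = 12)
  expect_equal(cc$comp2_latency, 70, tolerance = 12)
  expect_lt(cc$comp2_amplitude, -1.5)
})

test_that("zero-BARM simulations leave only the stereotyped first component", {
  cfg <- noiseless_config(
    barm_gain_by_phase = c(dark1 = 0, flow = 0, dark2 = 0),
    hv_barm_gain = 0, seed = 19)
  sim <- simulate_block(cfg)
  coil <- render_coil(sim$block, sim$truth, cfg)
  out <- analyze_block(sim$block)
  cc <- decompose_coil_blinks(coil, out$blinks[out$blinks$usable, ])
  ok <- cc$usable
  expect_gt(sum(ok), 3)
  # residual-modeling leaves a small floor on apparent comp-2 displacement
  expect_lt(mean(abs(cc$comp2_amplitude[ok]), na.rm = TRUE), 0.25)
  expect_lt(max(abs(cc$comp2_amplitude[ok]), na.rm = TRUE), 0.8)
  expect_gt(mean(cc$comp1_amplitude[ok] > 0, na.rm = TRUE), 0.9)
})

test_that("the merged-component case is classified by experimental phase", {
  cfg <- tiny_config(subject_s_merged = TRUE, seed = 20)
  sim <- simulate_block(cfg)
  coil <- render_coil(sim$block, sim$truth, cfg)
  out <- analyze_block(sim$block)
  cc <- decompose_coil_blinks(coil, out$blinks[out$blinks$usable, ])
  merged <- cc[cc$merged & cc$usable, ]
  expect_gt(nrow(merged), 0)
  expect_true(all(merged$merged_class[merged$phase %in% c("flow1", "flow2")]
                  == "comp2"))
  expect_true(all(merged$merged_class[merged$phase %in% c("dark1", "dark2")]
                  == "comp1"))
})

test_that("main-sequence fits satisfy exact and degenerate cases", {
  ev <- data.frame(amplitude = c(1, -2, 3, 1.5), peak_velocity = c(30, 60, 90, 45))
  fit <- main_sequence(ev, "exact")
  expect_equal(fit$slope, 30, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  too_few <- main_sequence(ev[1:2, ], "few")
  expect_true(!is.null(too_few$reason))
  flat <- main_sequence(data.frame(amplitude = c(1, 1, 1),
                                   peak_velocity = c(30, 31, 29)), "flat")
  expect_match(flat$reason, "degenerate")
})

test_that("the main-sequence Wilcoxon matches the exact permutation oracle", {
  a <- data.frame(amplitude = 1, peak_velocity = c(10, 11, 12))
  b <- data.frame(amplitude = 1, peak_velocity = c(20, 21, 22))
  fit_a <- main_sequence(rbind(a, data.frame(amplitude = 2,
                                             peak_velocity = 22)), "a")
  fit_b <- main_sequence(rbind(b, data.frame(amplitude = 2,
                                             peak_velocity = 42)), "b")
  cmpv <- compare_main_sequences(
    fit_a, fit_b, a, b)
  # exhaustive permutation oracle for the rank-sum of two samples of 3
  vals <- c(a$peak_velocity, b$peak_velocity)
  obs <- sum(rank(vals)[1:3])
  perms <- combn(6, 3)
  stat <- apply(perms, 2, function(ix) sum(rank(vals)[ix]))
  p_oracle <- 2 * min(mean(stat <= obs), mean(stat >= obs))
  expect_equal(cmpv$wilcox_p, p_oracle, tolerance = 1e-12)
})
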