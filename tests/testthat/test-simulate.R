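test_that("no stimulus and no noise leaves latent torsion at zero", {
  cfg <- noiseless_config(flow_speed = 0, blink_rate = 0.001, seed = 4)
  sim <- simulate_block(cfg)
  expect_lt(max(abs(sim$truth$latent$t)), 1e-6)
  expect_identical(nrow(sim$truth$fast_phases), 0L)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- tiny_config(seed = 99)
  a <- simulate_block(cfg)
  b <- simulate_block(cfg)
  expect_identical(a$block$samples, b$block$samples)
  expect_identical(a$truth$blinks, b$truth$blinks)
  expect_identical(a$truth$fast_phases, b$truth$fast_phases)
})

test_that("latent torsion obeys conservation in a noiseless run", {
  # no blinks, no saturation, no decay: the end-of-flow torsion must equal
  # integrated slow drift plus the summed (signed) fast-phase amplitudes
  cfg <- noiseless_config(blink_rate = 1e-4, torsion_ceiling = 1e6,
                          dark_drift_time_constant = 1e9,
                          barm_deadzone = 1e-9, seed = 12)
  sim <- simulate_block(cfg)
  stopifnot(nrow(sim$truth$blinks) == 0)
  fs <- cfg$sampling_rate
  end_flow1 <- which(sim$truth$latent$time < 100)  # dark1 40 + flow1 60
  T_end <- sim$truth$latent$t[max(end_flow1)]
  fast <- sim$truth$fast_phases
  fast <- fast[fast$onset_time < 100, ]
  drift <- cfg$slow_phase_velocity_mean * 60   # CW positive, driven 60 s
  expect_equal(T_end, drift + sum(fast$amplitude), tolerance = 0.05)
})

test_that("mirroring the flow direction mirrors the latent trace", {
  cw <- simulate_block(noiseless_config(flow_direction = "cw", seed = 21))
  ccw <- simulate_block(noiseless_config(flow_direction = "ccw", seed = 21))
  expect_lt(max(abs(cw$truth$latent$t + ccw$truth$latent$t)), 1e-6)
})

test_that("noiseless BARM shifts follow the dead-zoned gain law", {
  cfg <- noiseless_config(seed = 31)
  sim <- simulate_block(cfg)
  bl <- sim$truth$blinks
  fl <- bl[bl$phase %in% c("flow1", "flow2"), ]
  expect_gt(nrow(fl), 5)
  expected <- cfg$barm_gain_by_phase[["flow"]] *
    oracle_barm_drive(fl$pre_t, cfg$barm_deadzone, cfg$barm_deadzone_ref)
  expect_equal(fl$shift_t, expected, tolerance = 1e-8)
  # at the reference torsion the response is exactly gain x position
  expect_equal(cfg$barm_gain_by_phase[["flow"]] *
                 oracle_barm_drive(cfg$barm_deadzone_ref, cfg$barm_deadzone,
                                   cfg$barm_deadzone_ref),
               cfg$barm_gain_by_phase[["flow"]] * cfg$barm_deadzone_ref)
})

test_that("blink-free blocks build to a plateau inside the configured range", {
  cfg <- sim_config(blink_rate = 1e-4, seed = 7)
  ests <- vapply(c(7, 8), function(s) {
    cfg$seed <- s
    plateau_estimate(simulate_block(cfg)$truth)
  }, numeric(1))
  expect_true(all(ests > 2.5 & ests < 8.5))
  expect_true(mean(ests) > 3 && mean(ests) < 8)
})

test_that("blink process matches the configured rate and durations", {
  cfg <- sim_config(seed = 5)
  sims <- simulate_experiment(cfg, n_blocks = 2, seed = 5)
  bl <- do.call(rbind, lapply(sims, function(s) s$truth$blinks))
  rate <- nrow(bl) / (2 * 900) * 60
  expect_gt(rate, 13); expect_lt(rate, 22)
  expect_true(all(bl$duration >= 0.15 & bl$duration <= 0.5))
  # bilateral invalidity across the blink samples
  s <- sims[[1]]$block$samples
  tr <- sims[[1]]$truth$blinks
  fs <- sims[[1]]$block$sampling_rate
  for (i in seq_len(min(nrow(tr), 20))) {
    i0 <- floor(tr$onset_time[i] * fs) + 1L
    idx <- i0:(i0 + round(tr$duration[i] * fs) - 1L)
    expect_true(all(!s$valid_L[idx] & !s$valid_R[idx]))
    expect_true(all(is.na(s$eyeR_t[idx])))
  }
})

test_that("video and coil modalities agree on pre/post-blink torsion", {
  cfg <- noiseless_config(seed = 8)
  sim <- simulate_block(cfg)
  coil <- render_coil(sim$block, sim$truth, cfg)
  bl <- sim$truth$blinks
  expect_gt(nrow(bl), 3)
  cs <- coil$samples
  lat <- sim$truth$latent
  fs_c <- coil$sampling_rate
  fs_v <- cfg$sampling_rate
  diffs <- c()
  for (i in seq_len(nrow(bl))) {
    for (tt in c(bl$onset_time[i] - 0.14, bl$offset_time[i] + 0.2)) {
      ci <- round(tt * fs_c) + 1L
      vi <- round(tt * fs_v) + 1L
      if (ci < 1 || ci > nrow(cs) || vi < 1 || vi > nrow(lat)) next
      diffs <- c(diffs, cs$eyeR_t[ci] - lat$t[vi])
    }
  }
  # systematic modality differences: the settling return tail of the
  # stereotyped first component, plus grid mismatch when a read lands on a
  # fast phase in flight
  expect_lt(median(abs(diffs)), 0.15)
  expect_lt(quantile(abs(diffs), 0.95), 0.55)
})

test_that("blank schedule follows the half-sine gap law and duration set", {
  cfg <- sim_config(include_blanks = TRUE, seed = 44)
  set.seed(44)
  blanks <- schedule_blanks(cfg)
  expect_gt(nrow(blanks), 20)
  expect_true(all(blanks$duration %in% cfg$blank_durations))
  gaps <- diff(blanks$onset_time) - blanks$duration[-nrow(blanks)]
  gaps <- gaps[gaps > 0 & gaps < 20]  # drop the phase boundary
  expect_true(all(gaps >= 0 & gaps <= 10 + 1e-9))
  # inverse-transform sampler against the analytic half-sine CDF
  set.seed(1)
  x <- barmkit:::sample_halfsine_gap(1e5, cfg)
  ks <- suppressWarnings(stats::ks.test(x, function(q)
    (1 - cos(pi * pmin(pmax(q, 0), 10) / 10)) / 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(x), 5, tolerance = 0.05)
  expect_error(schedule_blanks(sim_config(blank_durations = numeric(0))))
})

test_that("experiments balance flow directions and reject odd block counts", {
  sims <- simulate_experiment(tiny_config(), n_blocks = 4, seed = 3)
  dirs <- vapply(sims, function(s) s$truth$flow_direction, character(1))
  expect_identical(sum(dirs == "cw"), 2L)
  expect_error(simulate_experiment(tiny_config(), n_blocks = 3, seed = 1),
               "even")
})
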