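# Synthetic generator of experimental blocks: latent torsional nystagmus with
# blink-associated resetting movements, observed through a video or coil
# modality. The latent state is advanced sample by sample so that fast-phase
# amplitudes and BARM shifts can feed back on the current torsion; saccadic
# displacements are applied as steps during the state loop and smoothed into
# minimum-jerk profiles at render time.

# OKN drive latencies around a stimulus blank: the slow-phase drive dies
# shortly after the pattern disappears and re-engages only some time after it
# returns.
.blank_drive_off_latency <- 0.10
.blank_drive_on_latency <- 0.30

#' Simulate one experimental block
#'
#' Generates the latent 3D eye state over the four-phase schedule (fixation
#' in darkness I, optic flow I, fixation in darkness II, optic flow II) and
#' returns its video-modality observation together with the ground-truth log.
#'
#' The latent torsion integrates slow-phase drift toward the flow direction,
#' is reset by fast phases (amplitude = slow-amplitude gain x preceding slow
#' amplitude + weak position gain x current torsion + noise, beating against
#' the flow) and by BARMs at blinks (shift = phase gain x pre-blink torsion +
#' noise), and in darkness decays exponentially toward zero. Blinks replace
#' video samples of both eyes with invalid markers; observation noise is a
#' slow artifact drift plus white noise per channel.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `block` (an `eye_trace_block`) and `truth`
#'   (a `barm_truth` ground-truth log).
#' @export
simulate_block <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)

  fs <- config$sampling_rate
  dt <- 1 / fs
  ptab <- phase_table(config)
  total <- ptab$end[4]
  n <- round(total * fs)
  times <- (seq_len(n) - 1) * dt
  dir <- if (config$flow_direction == "cw") 1 else -1

  phase_idx <- findInterval(times, ptab$start)
  is_flow <- phase_idx %in% c(2L, 4L)

  # Per-block draws: slow-phase velocity and blink-free build-up plateau.
  # The fast-phase amplitude setpoint a0 is anchored to the configured mean
  # velocity, so blocks with stronger or weaker optokinetic following build
  # to higher or lower torsion levels, as real blocks do.
  v_block <- config$slow_phase_velocity_block %||%
    max(0.3, stats::rnorm(1, config$slow_phase_velocity_mean,
                          config$slow_phase_velocity_sd))
  plateau <- config$plateau_block %||%
    stats::runif(1, config$plateau_range[1], config$plateau_range[2])
  s_bar <- config$slow_phase_velocity_mean * config$fast_phase_interval_mean
  a0 <- max(0.1, (1 - config$fast_phase_slowamp_gain) * s_bar -
              config$fast_phase_position_gain * plateau)
  t_ceil <- config$torsion_ceiling

  blinks <- draw_blinks(config, total)
  nb <- nrow(blinks)
  blanks <- if (config$include_blanks) schedule_blanks(config) else
    data.frame(onset_time = numeric(0), duration = numeric(0))

  # Drive mask: optic flow present and neither blink suppression nor a blank
  # (with its drive latencies) suspends the slow-phase drive.
  suppressed <- rep(FALSE, n)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      # a sample's drive applies to the increment entering it; suppression
      # is anchored to the sample grid on which the pupil disappears and
      # reappears, which is also the grid the detector reads from
      on_idx <- floor(blinks$onset_time[i] * fs) + 1L
      off_idx <- on_idx + round(blinks$duration[i] * fs) - 1L
      i0 <- max(1L, on_idx - round(config$blink_suppression_pre * fs) + 1L)
      i1 <- min(n, off_idx + 1L + round(config$blink_suppression_post * fs))
      suppressed[i0:i1] <- TRUE
    }
  }
  drive <- is_flow & !suppressed
  if (config$flow_speed == 0) drive[] <- FALSE  # no stimulus, no following
  if (nrow(blanks) > 0) {
    for (i in seq_len(nrow(blanks))) {
      i0 <- max(1L, floor((blanks$onset_time[i] + .blank_drive_off_latency) * fs) + 2L)
      i1 <- min(n, floor((blanks$onset_time[i] + blanks$duration[i] +
                            .blank_drive_on_latency) * fs) + 1L)
      drive[i0:i1] <- FALSE
    }
  }

  # Pre-generated randomness for the state loop. The torsional wander is a
  # stationary OU process with its own correlation time, independent of the
  # dark-decay dynamics of stimulus-driven deviations.
  W <- ou_path(n, dt, config$torsion_wander_sd, config$torsion_wander_tau)
  decay_f <- exp(-dt / config$dark_drift_time_constant)
  a_hv <- exp(-dt / config$hv_wander_tau)
  sd_hv_inn <- config$hv_wander_sd * sqrt(1 - a_hv^2)
  zh <- stats::rnorm(n, 0, sd_hv_inn)
  zv <- stats::rnorm(n, 0, sd_hv_inn)
  zb_t <- stats::rnorm(max(nb, 1), 0, config$barm_noise_sd)
  # the fast-phase setpoint wanders around (not away from) the block's
  # equilibrium, so the wander is centered within the block
  setp <- ou_path(n, dt, config$fast_phase_setpoint_sd,
                  config$fast_phase_setpoint_tau)
  setp <- setp - mean(setp)
  # dead-zoned BARM drive, normalized to the nominal gain at the reference
  # operating torsion
  dz2 <- config$barm_deadzone^2
  ref2 <- config$barm_deadzone_ref^2
  barm_drive <- function(T) T * (T^2 / (T^2 + dz2)) * ((ref2 + dz2) / ref2)
  zb_h <- stats::rnorm(max(nb, 1), 0, 0.3)
  zb_v <- stats::rnorm(max(nb, 1), 0, 0.3)

  blink_at <- integer(n)
  if (nb > 0) {
    bidx <- pmin(pmax(floor(blinks$onset_time * fs) + 1L, 1L), n)
    blink_at[bidx] <- seq_len(nb)
  }

  d_fp <- main_seq_duration(config$fast_phase_main_seq_slope)
  d2 <- main_seq_duration(config$comp2_main_seq_slope)
  # Nominal start of the resetting displacement inside the blink: the second
  # component's velocity peaks comp2_latency after the first component's peak.
  barm_t0 <- (config$comp1_peak_latency_mean +
                (if (config$subject_s_merged) 0 else config$comp2_latency_mean)) /
    1000 - d2 / 2

  # State loop ----------------------------------------------------------
  Tb <- 0; D <- 0       # base torsion (drift + wander + decay) and summed resets
  Hs <- 0; Vs <- 0      # latent horizontal / vertical deviation
  Dh <- 0; Dv <- 0
  s_anchor <- 0
  v_cur <- max(0.3, stats::rnorm(1, v_block, config$slow_phase_velocity_jitter_sd))
  # saccadic refractoriness: intervals shorter than ~0.35 s would merge
  # adjacent fast phases at the video rate
  # fast-phase rate adapts to the block's slow-phase velocity (faster
  # following -> more frequent beats), keeping resetting capacity in step
  interval_block <- max(0.45, config$fast_phase_interval_mean *
                          (config$slow_phase_velocity_mean / v_block)^0.35)
  # shifted gamma: a 0.35 s saccadic refractory floor plus gamma-distributed
  # excess, so the configured dispersion survives the floor
  draw_interval <- function()
    0.35 + stats::rgamma(1, shape = config$fast_phase_interval_shape,
                         scale = (interval_block - 0.35) /
                           config$fast_phase_interval_shape)
  timer <- draw_interval()
  cur_phase <- 0L

  Tb_path <- numeric(n); Hb_path <- numeric(n); Vb_path <- numeric(n)
  T_lat <- numeric(n); H_lat <- numeric(n); V_lat <- numeric(n)

  fp_t <- numeric(0); fp_amp <- numeric(0); fp_slow <- numeric(0)
  fp_pre <- numeric(0); fp_phase <- integer(0)
  bl_pre_t <- numeric(nb); bl_post_t <- numeric(nb)
  bl_pre_h <- numeric(nb); bl_post_h <- numeric(nb)
  bl_pre_v <- numeric(nb); bl_post_v <- numeric(nb)

  gains <- config$barm_gain_by_phase

  for (k in seq_len(n)) {
    ph <- phase_idx[k]
    if (ph != cur_phase) {         # phase transition
      cur_phase <- ph
      s_anchor <- Tb + D + W[k]
      v_cur <- max(0.3, stats::rnorm(1, v_block,
                                     config$slow_phase_velocity_jitter_sd))
      timer <- draw_interval()
    }
    dark <- ph == 1L || ph == 3L
    if (dark) {                    # decay of driven torsion toward zero
      Tt <- (Tb + D) * decay_f
      Tb <- Tt - D
    }
    if (drive[k]) {
      # slow-phase drive saturating toward the mechanical torsion limit
      sat <- 1 - (max(0, (Tb + D + W[k]) * dir) / t_ceil)^4
      Tb <- Tb + v_cur * dir * dt * max(0, sat)
    } else if (ph == 3L && !suppressed[k] && config$flow_speed > 0) {
      # optokinetic afternystagmus: decaying residual slow drift in the
      # second darkness phase
      v_okan <- config$okan_gain * v_block *
        exp(-(times[k] - ptab$start[3]) / config$okan_tau)
      Tb <- Tb + v_okan * dir * dt
    }
    Hs <- Hs * a_hv + zh[k]
    Vs <- Vs * a_hv + zv[k]

    b <- blink_at[k]
    if (b > 0L) {                  # blink: apply the BARM to the latent state
      Tt <- Tb + D + W[k]
      key <- if (dark) (if (ph == 1L) "dark1" else "dark2") else "flow"
      shift <- gains[[key]] * barm_drive(Tt) + zb_t[b]
      bl_pre_t[b] <- Tt; bl_post_t[b] <- Tt + shift
      Hpre <- Hs + Dh; Vpre <- Vs + Dv
      sh_h <- config$hv_barm_gain * Hpre + zb_h[b]
      sh_v <- config$hv_barm_gain * Vpre + zb_v[b]
      bl_pre_h[b] <- Hpre; bl_post_h[b] <- Hpre + sh_h
      bl_pre_v[b] <- Vpre; bl_post_v[b] <- Vpre + sh_v
      D <- D + shift; Dh <- Dh + sh_h; Dv <- Dv + sh_v
      s_anchor <- Tb + D + W[k]
    } else if (drive[k]) {         # fast-phase clock runs only under drive
      timer <- timer - dt
      if (timer <= 0) {
        Tt <- Tb + D + W[k]
        s_acc <- Tt - s_anchor
        A <- a0 + setp[k] + config$fast_phase_slowamp_gain * abs(s_acc) +
          config$fast_phase_position_gain * Tt * dir +
          stats::rnorm(1, 0, config$fast_phase_noise_sd)
        A <- max(A, config$fast_phase_min_amplitude)
        fp_t <- c(fp_t, times[k]); fp_amp <- c(fp_amp, -A * dir)
        fp_slow <- c(fp_slow, s_acc); fp_pre <- c(fp_pre, Tt)
        fp_phase <- c(fp_phase, ph)
        D <- D - A * dir
        s_anchor <- Tt - A * dir
        v_cur <- max(0.3, stats::rnorm(1, v_block,
                                       config$slow_phase_velocity_jitter_sd))
        timer <- draw_interval()
      }
    }
    Tb_path[k] <- Tb + W[k]; Hb_path[k] <- Hs; Vb_path[k] <- Vs
    T_lat[k] <- Tb + D + W[k]; H_lat[k] <- Hs + Dh; V_lat[k] <- Vs + Dv
  }

  fast <- data.frame(onset_time = fp_t, amplitude = fp_amp,
                     slow_amplitude = fp_slow, pre_position = fp_pre,
                     duration = rep(d_fp, length(fp_t)),
                     peak_velocity = 1.875 * abs(fp_amp) / d_fp,
                     phase = phase_levels[fp_phase],
                     stringsAsFactors = FALSE)
  if (nb > 0) {
    blinks$pre_t <- bl_pre_t; blinks$post_t <- bl_post_t
    blinks$shift_t <- bl_post_t - bl_pre_t
    blinks$pre_h <- bl_pre_h; blinks$shift_h <- bl_post_h - bl_pre_h
    blinks$pre_v <- bl_pre_v; blinks$shift_v <- bl_post_v - bl_pre_v
    blinks$phase <- phase_levels[phase_idx[pmin(pmax(
      floor(blinks$onset_time * fs) + 1L, 1L), n)]]
  } else {
    blinks$pre_t <- blinks$post_t <- blinks$shift_t <- numeric(0)
    blinks$pre_h <- blinks$shift_h <- numeric(0)
    blinks$pre_v <- blinks$shift_v <- numeric(0)
    blinks$phase <- character(0)
  }

  # Displacement events used to render smooth latent traces at any rate.
  ev_fast <- data.frame(t_start = fast$onset_time, amp = fast$amplitude,
                        dur = rep(d_fp, nrow(fast)),
                        step_time = fast$onset_time,
                        channel = rep("t", nrow(fast)),
                        stringsAsFactors = FALSE)
  ev_barm <- data.frame(t_start = rep(blinks$onset_time + barm_t0, 3),
                        amp = c(blinks$shift_t, blinks$shift_h, blinks$shift_v),
                        dur = rep(d2, 3L * nb),
                        step_time = rep(blinks$onset_time, 3),
                        channel = rep(c("t", "h", "v"), each = nb),
                        stringsAsFactors = FALSE)
  events <- rbind(ev_fast, ev_barm)

  latent <- list(
    time = times,
    t = render_latent(times, Tb_path, T_lat, events[events$channel == "t", ], fs),
    h = render_latent(times, Hb_path, H_lat, events[events$channel == "h", ], fs),
    v = render_latent(times, Vb_path, V_lat, events[events$channel == "v", ], fs))

  truth <- structure(list(
    blinks = blinks, fast_phases = fast, blanks = blanks,
    latent = data.frame(time = times, t = latent$t, h = latent$h,
                        v = latent$v),
    render = list(time = times, base = cbind(t = Tb_path, h = Hb_path,
                                             v = Vb_path), events = events),
    phase_gains = gains, flow_direction = config$flow_direction,
    v_block = v_block, plateau = plateau, config = config),
    class = "barm_truth")

  block <- observe_video(latent, phase_idx, blinks, blanks, config, ptab)
  list(block = block, truth = truth)
}

# Render a smooth latent trace: base path + displacement steps replaced by
# minimum-jerk profiles. `lat_step` already contains the instantaneous steps,
# so each event adds amp * (min_jerk(u) - step(u)).
render_latent <- function(times, base, lat_step, events, fs) {
  out <- lat_step
  if (nrow(events) == 0) return(out)
  n <- length(times)
  for (i in seq_len(nrow(events))) {
    t0 <- events$t_start[i]; d <- events$dur[i]; A <- events$amp[i]
    ts <- events$step_time[i]
    i0 <- floor(min(t0, ts) * fs) + 1L
    i1 <- ceiling((t0 + d) * fs) + 1L
    if (i1 < 1L || i0 > n) next
    idx <- max(1L, i0):min(n, i1)
    u <- (times[idx] - t0) / d
    # the step was applied at the blink/fast-phase onset sample, which for
    # BARMs precedes t_start; remove it wherever it is already present
    step_at <- as.numeric(times[idx] >= ts)
    out[idx] <- out[idx] + A * (min_jerk(u) - step_at)
  }
  out
}

# Blink flurry process: gamma-distributed flurry onsets, geometric flurry
# sizes, within-flurry spacing just wide enough to keep safety windows apart.
draw_blinks <- function(config, total) {
  rate_s <- config$blink_rate / 60
  size_mean <- config$blink_flurry_size_mean
  # 0.85: flurries clipped at phase ends and overlapping flurry draws lower
  # the realized rate; the factor recenters it on the configured value
  flurry_interval <- 0.85 * size_mean / rate_s
  onsets <- numeric(0); durs <- numeric(0)
  t <- stats::rgamma(1, shape = 2, scale = flurry_interval / 2)
  while (t < total) {
    size <- 1L + stats::rgeom(1, 1 / size_mean)
    tt <- t
    for (j in seq_len(size)) {
      dur <- min(0.5, max(0.15, stats::rnorm(1, config$blink_duration_mean,
                                             config$blink_duration_sd) / 1000))
      if (tt + dur + 0.25 > total) break
      onsets <- c(onsets, tt); durs <- c(durs, dur)
      tt <- tt + dur + 0.34 +
        abs(stats::rnorm(1, config$blink_flurry_gap_mean, 0.15)) + 0.05
    }
    t_next <- t + stats::rgamma(1, shape = 2, scale = flurry_interval / 2)
    t <- max(t_next, tt + 1.0)
  }
  keep <- onsets > 0.5
  data.frame(onset_time = onsets[keep], duration = durs[keep],
             offset_time = onsets[keep] + durs[keep])
}

#' Schedule stimulus-blanking events
#'
#' Draws the blanking intervals of the afference-hypothesis control: within
#' each optic-flow phase, inter-blank onset gaps follow a half-sine density
#' peaking at `blank_gap_peak` seconds with width `blank_gap_width` (support
#' 0 to twice the peak), sampled by inverse transform; durations are drawn
#' uniformly from `blank_durations`. Blanks suspend the slow-phase drive and
#' inject no resetting shift.
#'
#' @param config A [sim_config()] object.
#' @return A data frame with `onset_time`, `duration`, `offset_time` (s).
#' @export
schedule_blanks <- function(config) {
  config <- validate_sim_config(config)
  if (length(config$blank_durations) == 0)
    stop("blank_durations must not be empty", call. = FALSE)
  ptab <- phase_table(config)
  out <- list()
  for (p in c(2L, 4L)) {
    t <- ptab$start[p] + sample_halfsine_gap(1, config)
    while (TRUE) {
      dur <- sample(config$blank_durations, 1)
      if (t + dur > ptab$end[p] - 1) break
      out[[length(out) + 1L]] <- c(t, dur)
      t <- t + dur + sample_halfsine_gap(1, config)
    }
  }
  if (length(out) == 0)
    return(data.frame(onset_time = numeric(0), duration = numeric(0),
                      offset_time = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(onset_time = m[, 1], duration = m[, 2],
             offset_time = m[, 1] + m[, 2])
}

# Inverse-transform sampling of the half-sine inter-blank gap density
# f(x) ~ sin(pi x / (2 peak)) on [0, 2 peak]: CDF F(x) = (1 - cos(pi x /
# (2 peak))) / 2, so x = (2 peak / pi) acos(1 - 2u).
sample_halfsine_gap <- function(n, config) {
  u <- stats::runif(n)
  (2 * config$blank_gap_peak / pi) * acos(1 - 2 * u)
}

# Video observation: latent + common slow artifact drift + per-eye white
# noise; blink samples of both eyes invalid, plus occasional unilateral
# pupil-detection artifacts.
observe_video <- function(latent, phase_idx, blinks, blanks, config, ptab) {
  n <- length(latent$time)
  fs <- config$sampling_rate
  dt <- 1 / fs
  drift_sd <- config$video_drift_sd
  ch <- function(channel) {
    lat <- latent[[channel]]
    drift <- ou_path(n, dt, drift_sd[[channel]], config$video_drift_tau)
    w <- config$video_white_sd[[channel]]
    list(L = lat + drift + stats::rnorm(n, 0, w),
         R = lat + drift + stats::rnorm(n, 0, w))
  }
  hh <- ch("h"); vv <- ch("v"); tt <- ch("t")

  valid_L <- rep(TRUE, n); valid_R <- rep(TRUE, n)
  for (i in seq_len(nrow(blinks))) {
    i0 <- floor(blinks$onset_time[i] * fs) + 1L
    i1 <- i0 + round(blinks$duration[i] * fs) - 1L
    idx <- max(1L, i0):min(n, i1)
    valid_L[idx] <- FALSE; valid_R[idx] <- FALSE
  }
  # unilateral dropouts (pupil-detection artifacts)
  n_art <- stats::rpois(1, config$artifact_rate / 60 * ptab$end[4])
  if (n_art > 0) {
    for (j in seq_len(n_art)) {
      t0 <- stats::runif(1, 0, ptab$end[4])
      near_blink <- nrow(blinks) > 0 &&
        any(t0 > blinks$onset_time - 0.4 & t0 < blinks$offset_time + 0.4)
      if (near_blink) next
      idx <- floor(t0 * fs) + seq_len(sample.int(3, 1))
      idx <- idx[idx >= 1 & idx <= n]
      if (stats::runif(1) < 0.5) valid_L[idx] <- FALSE else valid_R[idx] <- FALSE
    }
  }

  stim <- rep("off", n)
  flow_lab <- if (config$flow_direction == "cw") "flow_cw" else "flow_ccw"
  stim[phase_idx %in% c(2L, 4L)] <- flow_lab
  for (i in seq_len(nrow(blanks))) {
    i0 <- floor(blanks$onset_time[i] * fs) + 1L
    i1 <- i0 + round(blanks$duration[i] * fs) - 1L
    stim[max(1L, i0):min(n, i1)] <- "blanked"
  }

  samples <- data.frame(
    time_s = latent$time,
    eyeL_h = hh$L, eyeL_v = vv$L, eyeL_t = tt$L,
    eyeR_h = hh$R, eyeR_v = vv$R, eyeR_t = tt$R,
    valid_L = valid_L, valid_R = valid_R,
    phase = phase_levels[phase_idx], stimulus_state = stim,
    stringsAsFactors = FALSE)
  pos_cols <- c("eyeL_h", "eyeL_v", "eyeL_t")
  samples[!valid_L, pos_cols] <- NA_real_
  pos_cols <- c("eyeR_h", "eyeR_v", "eyeR_t")
  samples[!valid_R, pos_cols] <- NA_real_

  eye_trace_block(samples, modality = "video", sampling_rate = fs)
}

#' Simulate a balanced multi-block experiment
#'
#' Runs [simulate_block()] for `n_blocks` blocks with the two flow
#' directions represented equally, deriving one sub-seed per block from
#' `seed`.
#'
#' @param config Base [sim_config()]; its `flow_direction` and `seed` are
#'   overridden per block.
#' @param n_blocks Even number of blocks.
#' @param seed Integer master seed.
#' @return A list of `list(block, truth)` entries, one per block.
#' @export
simulate_experiment <- function(config, n_blocks = 16, seed = 1L) {
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  if (n_blocks %% 2 != 0)
    stop("n_blocks must be even so both flow directions are represented equally",
         call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_blocks)
  dirs <- rep(c("cw", "ccw"), length.out = n_blocks)
  # stratified block characteristics, balanced within each flow direction:
  # slow-phase velocities and plateaus follow their population distributions
  # without block-sampling excess across the (finite) experiment
  strat <- function(p) p[sample.int(length(p))]
  vels <- numeric(n_blocks); plats <- numeric(n_blocks)
  for (d in c("cw", "ccw")) {
    idx <- which(dirs == d)
    q <- (seq_along(idx) - 0.5) / length(idx)
    vels[idx] <- strat(pmax(0.3, stats::qnorm(
      q, config$slow_phase_velocity_mean, config$slow_phase_velocity_sd)))
    plats[idx] <- strat(config$plateau_range[1] +
                          q * diff(config$plateau_range))
  }
  lapply(seq_len(n_blocks), function(i) {
    cfg <- config
    cfg$flow_direction <- dirs[i]
    cfg$seed <- sub_seeds[i]
    cfg$slow_phase_velocity_block <- vels[i]
    cfg$plateau_block <- plats[i]
    simulate_block(cfg)
  })
}

#' Blink-free build-up plateau of a block's latent nystagmus
#'
#' Time-averaged latent torsion magnitude over the second half of the first
#' optic-flow phase: with blinks disabled this estimates the block's
#' build-up plateau.
#'
#' @param truth A `barm_truth` log.
#' @return Plateau estimate in degrees.
#' @export
plateau_estimate <- function(truth) {
  ptab <- phase_table(truth$config)
  sel <- truth$latent$time >= (ptab$start[2] + ptab$end[2]) / 2 &
    truth$latent$time < ptab$end[2]
  mean(abs(truth$latent$t[sel]))
}
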