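# Search-coil modality: rendering of the two-component blink movement and
# its decomposition. The coil keeps measuring through lid closure, so each
# blink shows (1) a stereotyped extorsional / nasal / downward transient
# whose velocity peaks ~127 ms after blink onset and which then returns
# toward baseline, and (2) the resetting component proper, a minimum-jerk
# displacement equal to the BARM shift whose velocity peaks ~73 ms after the
# first component's peak and follows an 18.6 (deg/s)/deg main sequence.

coil_rate <- 200

#' Render the search-coil observation of a simulated block
#'
#' Re-observes the latent state of a simulated block at 200 Hz with no
#' dropouts: outside blinks the coil trace is the same latent nystagmus;
#' at each blink the instantaneous latent resetting step is replaced by the
#' two-component movement described above, with per-blink draws of the
#' component-1 amplitude and peak latency and of the component-2 latency.
#'
#' @param block The video-modality `eye_trace_block` of the same run (used
#'   for consistency checks).
#' @param truth The `barm_truth` log returned by [simulate_block()].
#' @param config The [sim_config()] used for the run.
#' @return A coil-modality `eye_trace_block` (200 Hz, all samples valid)
#'   with an attribute `components`: the per-blink ground-truth component
#'   parameters actually rendered.
#' @export
render_coil <- function(block, truth, config) {
  stopifnot(inherits(truth, "barm_truth"))
  config <- validate_sim_config(config)
  rtime <- truth$render$time
  total <- rtime[length(rtime)] + (rtime[2] - rtime[1])
  bl <- truth$blinks
  if (nrow(bl) > 0 &&
      (any(bl$onset_time < 0) || any(bl$offset_time > total)))
    stop("ground-truth log inconsistent with block: blink outside time range",
         call. = FALSE)
  if (nrow(truth$fast_phases) > 0 &&
      any(truth$fast_phases$onset_time > total))
    stop("ground-truth log inconsistent with block: fast phase outside range",
         call. = FALSE)

  set.seed((config$seed %% 536870912L) + 31L)
  fs <- coil_rate
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs

  base <- truth$render$base
  bt <- stats::approx(rtime, base[, "t"], tt, rule = 2)$y
  bh <- stats::approx(rtime, base[, "h"], tt, rule = 2)$y
  bv <- stats::approx(rtime, base[, "v"], tt, rule = 2)$y

  ev <- truth$render$events
  fast_ev <- ev[ev$channel == "t" & !(ev$step_time %in% bl$onset_time), ,
                drop = FALSE]

  nb <- nrow(bl)
  d2 <- main_seq_duration(config$comp2_main_seq_slope)
  comp <- data.frame(onset_time = bl$onset_time,
                     c1_amp = numeric(nb), c1_h = numeric(nb),
                     c1_v = numeric(nb), c1_peak_time = numeric(nb),
                     c2_latency = numeric(nb), c2_peak_time = numeric(nb),
                     c2_amp = bl$shift_t %||% numeric(nb))
  add_t <- numeric(n); add_h <- numeric(n); add_v <- numeric(n)
  win_idx <- function(t_lo, t_hi) {
    i0 <- max(1L, floor(t_lo * fs) + 1L)
    i1 <- min(n, ceiling(t_hi * fs) + 1L)
    if (i0 > i1) integer(0) else i0:i1
  }
  d1 <- config$comp1_duration / 1000
  tau1 <- config$comp1_return_tau / 1000
  if (nb > 0) {
    for (i in seq_len(nb)) {
      on <- bl$onset_time[i]
      c1a <- max(0.2, stats::rnorm(1, config$comp1_amplitude_mean,
                                   config$comp1_amplitude_sd))
      c1h <- stats::rnorm(1, config$comp1_h_amplitude, 0.3)
      c1v <- stats::rnorm(1, config$comp1_v_amplitude, 0.4)
      c1lat <- max(0.06, stats::rnorm(1, config$comp1_peak_latency_mean,
                                      config$comp1_peak_latency_sd) / 1000)
      c2lat <- if (config$subject_s_merged) 0 else
        max(0.02, stats::rnorm(1, config$comp2_latency_mean,
                               config$comp2_latency_sd) / 1000)
      t1p <- on + c1lat
      t2p <- t1p + c2lat
      comp$c1_amp[i] <- c1a; comp$c1_h[i] <- c1h; comp$c1_v[i] <- c1v
      comp$c1_peak_time[i] <- t1p
      comp$c2_latency[i] <- c2lat * 1000
      comp$c2_peak_time[i] <- t2p

      # component 1 (exponential return decayed to ~0 past 12 tau)
      idx <- win_idx(t1p - d1 / 2, t1p + d1 / 2 + 12 * tau1)
      if (length(idx) > 0) {
        pr <- comp1_profile(tt[idx], t1p, d1, tau1)
        add_t[idx] <- add_t[idx] + c1a * pr
        add_h[idx] <- add_h[idx] + c1h * pr
        add_v[idx] <- add_v[idx] + c1v * pr
      }

      # resetting displacement: replace the instantaneous latent step at
      # blink onset with the minimum-jerk component-2 movement
      idx <- win_idx(min(on, t2p - d2 / 2), t2p + d2 / 2)
      if (length(idx) > 0) {
        pr2 <- min_jerk((tt[idx] - (t2p - d2 / 2)) / d2) -
          as.numeric(tt[idx] >= on)
        add_t[idx] <- add_t[idx] + bl$shift_t[i] * pr2
        add_h[idx] <- add_h[idx] + bl$shift_h[i] * pr2
        add_v[idx] <- add_v[idx] + bl$shift_v[i] * pr2
      }
    }
  }

  # fast phases: minimum-jerk correction of their instantaneous steps
  for (i in seq_len(nrow(fast_ev))) {
    t0 <- fast_ev$t_start[i]; d <- fast_ev$dur[i]
    idx <- win_idx(t0, t0 + d)
    if (length(idx) > 0)
      add_t[idx] <- add_t[idx] + fast_ev$amp[i] *
        (min_jerk((tt[idx] - t0) / d) - as.numeric(tt[idx] >= t0))
  }

  # latent step paths at the coil rate: cumulative displacement steps
  step_path <- function(ev_times, ev_amps) {
    if (length(ev_times) == 0) return(numeric(n))
    o <- order(ev_times)
    c(0, cumsum(ev_amps[o]))[findInterval(tt, ev_times[o]) + 1L]
  }
  step_t <- step_path(c(bl$onset_time, fast_ev$t_start),
                      c(bl$shift_t, fast_ev$amp))
  step_h <- step_path(bl$onset_time, bl$shift_h)
  step_v <- step_path(bl$onset_time, bl$shift_v)

  lat_t <- bt + step_t + add_t
  lat_h <- bh + step_h + add_h
  lat_v <- bv + step_v + add_v

  ptab <- phase_table(config)
  phase_idx <- findInterval(tt, ptab$start)
  stim <- rep("off", n)
  flow_lab <- if (truth$flow_direction == "cw") "flow_cw" else "flow_ccw"
  stim[phase_idx %in% c(2L, 4L)] <- flow_lab
  if (nrow(truth$blanks) > 0) {
    for (i in seq_len(nrow(truth$blanks))) {
      sel <- tt >= truth$blanks$onset_time[i] &
        tt < truth$blanks$offset_time[i]
      stim[sel] <- "blanked"
    }
  }

  noise <- config$noise_sd_coil
  samples <- data.frame(
    time_s = tt,
    eyeL_h = lat_h + stats::rnorm(n, 0, noise[["h"]]),
    eyeL_v = lat_v + stats::rnorm(n, 0, noise[["v"]]),
    eyeL_t = lat_t + stats::rnorm(n, 0, noise[["t"]]),
    eyeR_h = lat_h + stats::rnorm(n, 0, noise[["h"]]),
    eyeR_v = lat_v + stats::rnorm(n, 0, noise[["v"]]),
    eyeR_t = lat_t + stats::rnorm(n, 0, noise[["t"]]),
    valid_L = TRUE, valid_R = TRUE,
    phase = phase_levels[phase_idx], stimulus_state = stim,
    stringsAsFactors = FALSE)
  out <- eye_trace_block(samples, modality = "coil", sampling_rate = fs)
  attr(out, "components") <- comp
  out
}

# Component-1 waveform: minimum-jerk excursion to 1 peaking in velocity at
# t_peak (outward duration d1), followed by an exponential return toward 0.
comp1_profile <- function(tt, t_peak, d1, tau) {
  t_start <- t_peak - d1 / 2
  t_end <- t_start + d1
  out <- min_jerk((tt - t_start) / d1)
  late <- tt > t_end
  out[late] <- exp(-(tt[late] - t_end) / tau)
  out
}

#' Re-measure event peak velocities on a coil trace
#'
#' Saccadic peak velocities are badly attenuated at video rates (a 60 ms
#' fast phase spans three 50 Hz samples), so main-sequence kinematics are
#' measured on the 200 Hz coil trace: for each event interval the peak
#' Savitzky--Golay velocity (35 ms window) within the interval is returned.
#'
#' @param coil_block A coil-modality `eye_trace_block`.
#' @param onset_time,offset_time Event interval bounds (s).
#' @param eye Which eye's torsion channel to read.
#' @return Numeric vector of signed peak velocities (deg/s).
#' @export
coil_peak_velocities <- function(coil_block, onset_time, offset_time,
                                 eye = c("right", "left")) {
  stopifnot(inherits(coil_block, "eye_trace_block"))
  eye <- match.arg(eye)
  s <- coil_block$samples
  fs <- coil_block$sampling_rate
  pos <- s[[eye_cols(eye)["t"]]]
  w <- round(0.035 * fs); if (w %% 2 == 0) w <- w + 1
  vel <- sg_velocity(pos, fs, w)
  t0 <- s$time_s[1]
  n <- nrow(s)
  vapply(seq_along(onset_time), function(i) {
    i0 <- max(1L, round((onset_time[i] - t0) * fs) + 1L)
    i1 <- min(n, round((offset_time[i] - t0) * fs) + 1L)
    seg <- vel[i0:i1]
    if (all(is.na(seg))) return(NA_real_)
    seg[which.max(abs(seg))]
  }, numeric(1))
}

#' Decompose coil-trace blink movements into their two components
#'
#' For each blink window the torsional velocity (Savitzky--Golay derivative)
#' is scanned for component 1 -- the first extorsional (positive) velocity
#' extremum after blink onset -- and component 2 -- the subsequent extremum
#' whose sign matches the net resetting direction. The trace is partitioned
#' at the minimum-speed point between the two peaks; component amplitudes
#' are read from the position trace on either side of the partition. Blinks
#' without a resolvable second extremum are flagged `merged` and, following
#' the merged-component convention, classified as component 1 in darkness
#' and component 2 during optic flow.
#'
#' @param coil_block A coil-modality `eye_trace_block`.
#' @param blinks Blink intervals: a data frame with `onset_time` (s), e.g.
#'   video-detected blinks or the ground-truth blink table.
#' @param comp1_threshold,comp2_threshold Minimum peak speeds (deg/s).
#' @param search_window Seconds after blink onset searched for component 1.
#' @param comp1_duration,comp1_return_tau,comp2_duration Shape parameters
#'   (ms) of the canonical component waveforms used to subtract the
#'   overlapping other component before peak location; defaults match
#'   [sim_config()].
#' @param eye Which eye's torsion channel to decompose.
#' @return A data frame (class `coil_components`): per blink the component-1
#'   peak time (ms from onset) and torsional amplitude, the component-2
#'   peak-velocity latency (ms after the comp-1 peak), signed amplitude and
#'   peak velocity, plus `merged`, `merged_class` and `usable` flags.
#' @export
decompose_coil_blinks <- function(coil_block, blinks,
                                  comp1_threshold = 6, comp2_threshold = 5.5,
                                  search_window = 0.28,
                                  comp1_duration = 100,
                                  comp1_return_tau = 220,
                                  comp2_duration = 1000 * 1.875 / 18.6,
                                  eye = c("right", "left")) {
  stopifnot(inherits(coil_block, "eye_trace_block"))
  if (coil_block$modality != "coil")
    stop("decompose_coil_blinks expects a coil-modality block", call. = FALSE)
  eye <- match.arg(eye)
  s <- coil_block$samples
  fs <- coil_block$sampling_rate
  pos <- s[[eye_cols(eye)["t"]]]
  w_det <- round(0.055 * fs); if (w_det %% 2 == 0) w_det <- w_det + 1
  w_meas <- round(0.035 * fs); if (w_meas %% 2 == 0) w_meas <- w_meas + 1
  vel_det <- sg_velocity(pos, fs, w_det)
  vel_meas <- sg_velocity(pos, fs, w_meas)
  pos_sm <- signal::sgolayfilt(pos, p = 2, n = w_det)
  pos_lt <- signal::sgolayfilt(pos, p = 2, n = w_meas)  # light smoothing
  n <- nrow(s)
  t0 <- s$time_s[1]
  idx_of <- function(tt) pmin(pmax(round((tt - t0) * fs) + 1L, 1L), n)

  d1s <- comp1_duration / 1000
  tau1s <- comp1_return_tau / 1000
  d2s <- comp2_duration / 1000
  # canonical component velocity templates for unit amplitude (deg/s)
  mjv <- function(u) ifelse(u > 0 & u < 1, 30 * u^2 * (1 - u)^2, 0)
  comp1_vel <- function(t, t1p, amp) {
    t_start <- t1p - d1s / 2
    v <- amp / d1s * mjv((t - t_start) / d1s)
    late <- t > t_start + d1s
    v[late] <- -amp / tau1s * exp(-(t[late] - (t_start + d1s)) / tau1s)
    v
  }
  comp2_vel <- function(t, t2p, amp)
    amp / d2s * mjv((t - (t2p - d2s / 2)) / d2s)

  res <- lapply(seq_len(nrow(blinks)), function(i) {
    on <- blinks$onset_time[i]
    out <- data.frame(onset_time = on, comp1_peak_time = NA_real_,
                      comp1_amplitude = NA_real_,
                      comp2_latency = NA_real_, comp2_amplitude = NA_real_,
                      comp2_peak_velocity = NA_real_,
                      merged = FALSE, merged_class = NA_character_,
                      usable = FALSE, phase = NA_character_,
                      stringsAsFactors = FALSE)
    i_on <- idx_of(on)
    i_hi <- idx_of(on + search_window)
    i_base <- idx_of(on - 0.05)
    i_endw <- idx_of(on + 0.5)
    if (i_endw >= n || i_base <= 1 || i_on >= n) return(out)  # window clipped
    out$phase <- s$phase[i_on]

    # component 1: peak of the first extorsional (positive) velocity lobe.
    # Within the first suprathreshold run the running maximum is tracked
    # until the velocity falls below 60% of it, so noise bumps on the
    # rising slope do not trigger an early peak and a later same-sign
    # second component is not mistaken for component 1.
    i_lo <- idx_of(on + 0.05)  # the lid takes ~50 ms to perturb the globe
    first_lobe <- function(v) {
      seg <- v[i_lo:i_hi]
      # a qualifying lobe must be dominant, not a threshold-grazing bump
      thr <- max(comp1_threshold, 0.5 * max(seg, na.rm = TRUE))
      above <- which(seg >= thr)
      if (length(above) == 0) return(NA_integer_)
      r0 <- above[1]
      vmax <- seg[r0]; imax <- r0
      i <- r0
      while (i < length(seg)) {
        i <- i + 1L
        if (is.na(seg[i]) || seg[i] < 0.6 * vmax) break
        if (seg[i] > vmax) { vmax <- seg[i]; imax <- i }
      }
      i_lo + imax - 1L
    }
    i1p <- first_lobe(vel_det)
    if (is.na(i1p)) return(out)  # no extorsional extremum
    t1p_time <- s$time_s[i1p]
    c1a_hat <- max(0, vel_meas[i1p] * d1s / 1.875)
    out$comp1_peak_time <- (t1p_time - on) * 1000

    # net resetting direction across the blink movement; without an
    # appreciable net displacement there is no resetting component to
    # resolve (the first component returns to baseline)
    net <- pos_sm[i_endw] - pos_sm[i_base]
    s2 <- sign(net)
    if (abs(net) < 0.3) {
      out$comp2_amplitude <- net
      out$comp1_amplitude <- pos_lt[idx_of(t1p_time + d1s / 2)] -
        pos_lt[i_base]
      out$usable <- TRUE
      return(out)
    }

    # component 2: strongest extremum of the resetting sign after comp 1,
    # located on the residual after subtracting the comp-1 template
    j0 <- idx_of(t1p_time + 0.02)
    j1 <- idx_of(t1p_time + 0.22)
    tw <- s$time_s[j0:j1]
    seg2 <- (vel_det[j0:j1] - comp1_vel(tw, t1p_time, c1a_hat)) * s2
    loc2 <- which(diff(sign(diff(seg2))) == -2) + 1L
    loc2 <- loc2[seg2[loc2] >= comp2_threshold]
    if (s2 == 0 || length(loc2) == 0) {
      # unresolved second component: merged-components convention
      out$merged <- TRUE
      out$merged_class <- if (s$phase[i_on] %in% c("flow1", "flow2"))
        "comp2" else "comp1"
      out$comp2_amplitude <- net
      out$usable <- TRUE
      return(out)
    }
    i2p_loc <- loc2[which.max(seg2[loc2])]
    f2p <- refine_peak(seg2, i2p_loc)
    t2p_time <- tw[1] + (f2p - 1) / fs
    i2p <- j0 + i2p_loc - 1L
    # re-locate the comp-1 peak on the comp-2-subtracted velocity
    vel_clean <- vel_det
    k0 <- max(1L, idx_of(t2p_time - d2s))
    k1 <- min(n, idx_of(t2p_time + d2s))
    vel_clean[k0:k1] <- vel_clean[k0:k1] -
      comp2_vel(s$time_s[k0:k1], t2p_time, net)
    i1p2 <- first_lobe(vel_clean)
    if (!is.na(i1p2)) {
      f1p <- refine_peak(vel_clean, i1p2)
      t1p_time <- s$time_s[1] + (f1p - 1) / fs
      i1p <- i1p2
      out$comp1_peak_time <- (t1p_time - on) * 1000
    }
    lat_ms <- (t2p_time - t1p_time) * 1000
    if (lat_ms > 160) {
      # implausibly late second peak: the two components could not be
      # separated reliably for this blink
      out$merged <- TRUE
      out$merged_class <- if (s$phase[i_on] %in% c("flow1", "flow2"))
        "comp2" else "comp1"
      out$comp2_amplitude <- net
      out$usable <- TRUE
      return(out)
    }
    out$comp2_latency <- lat_ms
    out$comp2_peak_velocity <- vel_meas[i2p]

    # amplitudes, template-consistently: component 2 carries the net
    # displacement minus the modeled residual of component 1's return;
    # component 1 is the peak extorsional excursion after removing the
    # component-2 displacement
    c1_resid <- c1a_hat * exp(-(s$time_s[i_endw] -
                                  (t1p_time + d1s / 2)) / tau1s)
    out$comp2_amplitude <- net - c1_resid
    k1e <- idx_of(t1p_time + d1s / 2)  # end of the outward movement
    out$comp1_amplitude <- pos_lt[k1e] -
      net * min_jerk((s$time_s[k1e] - (t2p_time - d2s / 2)) / d2s) -
      pos_lt[i_base]
    out$usable <- TRUE
    out
  })
  out <- do.call(rbind, res)
  class(out) <- c("coil_components", "data.frame")
  out
}


# Noise-robust peak-time refinement: vertex of a parabola fitted to the
# velocity samples around a detected extremum (fractional index). Less
# sensitive to overlap with neighbouring velocity lobes than a half-height
# centroid.
refine_peak <- function(v, ip, half_width = 3L) {
  n <- length(v)
  a <- max(1L, ip - half_width); b <- min(n, ip + half_width)
  idx <- a:b
  seg <- v[idx]
  keep <- is.finite(seg)
  if (sum(keep) < 3) return(as.numeric(ip))
  fit <- stats::lm(seg[keep] ~ poly(idx[keep], 2, raw = TRUE))
  cf <- stats::coef(fit)
  if (!is.finite(cf[3]) || cf[3] == 0) return(as.numeric(ip))
  vertex <- -cf[2] / (2 * cf[3])
  if (vertex < a || vertex > b) as.numeric(ip) else unname(vertex)
}
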