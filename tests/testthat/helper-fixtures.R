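# Shared fixtures: small configurations and hand-constructed traces.

# Short block for fast tests: 40/60/40/60 s phases.
tiny_config <- function(...) {
  sim_config(phase_durations = c(40, 60, 40, 60), ...)
}

# Noise-free variant: all stochastic amplitudes collapsed.
noiseless_config <- function(...) {
  args <- list(...)
  defaults <- list(
    slow_phase_velocity_sd = 1e-9, slow_phase_velocity_jitter_sd = 1e-9,
    fast_phase_noise_sd = 1e-9, fast_phase_setpoint_sd = 1e-9,
    barm_noise_sd = 1e-9, torsion_wander_sd = 1e-9,
    video_white_sd = c(h = 1e-9, v = 1e-9, t = 1e-9),
    video_drift_sd = c(h = 1e-9, v = 1e-9, t = 1e-9),
    noise_sd_coil = c(h = 1e-9, v = 1e-9, t = 1e-9),
    artifact_rate = 0)
  do.call(tiny_config, utils::modifyList(defaults, args))
}

# Build a bare eye-trace block from a torsion vector (both eyes identical,
# everything valid, phase labels supplied per sample).
make_trace <- function(torsion, fs = 50, phase = NULL, stim = NULL,
                       valid_L = NULL, valid_R = NULL, h = 0, v = 0) {
  n <- length(torsion)
  if (is.null(phase)) phase <- rep("flow1", n)
  if (is.null(stim)) {
    stim <- ifelse(phase %in% c("flow1", "flow2"), "flow_cw", "off")
  }
  if (is.null(valid_L)) valid_L <- rep(TRUE, n)
  if (is.null(valid_R)) valid_R <- rep(TRUE, n)
  h <- rep_len(h, n); v <- rep_len(v, n)
  samples <- data.frame(
    time_s = (seq_len(n) - 1) / fs,
    eyeL_h = h, eyeL_v = v, eyeL_t = torsion,
    eyeR_h = h, eyeR_v = v, eyeR_t = torsion,
    valid_L = valid_L, valid_R = valid_R,
    phase = phase, stimulus_state = stim,
    stringsAsFactors = FALSE)
  pos <- c("eyeL_h", "eyeL_v", "eyeL_t")
  samples[!valid_L, pos] <- NA_real_
  pos <- c("eyeR_h", "eyeR_v", "eyeR_t")
  samples[!valid_R, pos] <- NA_real_
  eye_trace_block(samples, modality = "video", sampling_rate = fs)
}

# A trace with a dark1 stretch followed by flow1, used when referencing or
# segmentation needs both phases present.
make_two_phase_trace <- function(dark_torsion, flow_torsion, fs = 50, ...) {
  make_trace(c(dark_torsion, flow_torsion), fs = fs,
             phase = c(rep("dark1", length(dark_torsion)),
                       rep("flow1", length(flow_torsion))), ...)
}

# Closed-form dead-zoned BARM drive used as an independent oracle.
oracle_barm_drive <- function(T, c, ref) {
  T * (T^2 / (T^2 + c^2)) * ((ref^2 + c^2) / ref^2)
}
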