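#' Simulation configuration for synthetic experimental blocks
#'
#' Builds the full generative parameterization of one experimental block:
#' four phases (fixation in darkness I, optic flow I, fixation in darkness
#' II, optic flow II), torsional optokinetic nystagmus whose slow phases
#' follow the rotating stimulus and whose fast phases beat against it,
#' spontaneous blinks carrying blink-associated resetting movements (BARMs),
#' and the observation models of the video and search-coil modalities.
#'
#' Defaults reproduce the study conditions the generator emulates: 180/270 s
#' phase durations, a 30 deg/s rotary dot stimulus, slow-phase eye velocity
#' of about 2.95 deg/s, a torsional build-up plateau in the 3--8 deg range,
#' fast phases whose amplitude tracks the preceding slow-phase amplitude
#' with gain 0.33 plus a weak position feedback, BARM gains of -0.26 /
#' -0.62 / -0.28 on pre-blink torsion in the dark-I / flow / dark-II phases,
#' blinks of ~300 ms at 15--20 per minute, and a two-component coil-domain
#' blink movement (a stereotyped extorsional transient peaking ~127 ms after
#' blink onset, followed ~73 ms later by the resetting component whose
#' kinematics follow an 18.6 (deg/s)/deg main sequence; fast phases follow
#' 31.5 (deg/s)/deg).
#'
#' Blinks are generated as a bursty flurry process (gamma-distributed flurry
#' onsets, geometric flurry sizes, ~1 s within-flurry spacing). Because each
#' BARM removes most of the torsional deviation, blinks inside a flurry
#' occur at low torsion while nystagmus between flurries rides near the
#' build-up plateau; this is what lets mean BARM amplitude sit near 1.3 deg
#' while the regression gain on pre-blink torsion stays at -0.62.
#'
#' @param sampling_rate Video sampling rate in Hz; one of 50, 100, 200.
#' @param phase_durations Seconds per phase (dark1, flow1, dark2, flow2).
#' @param flow_speed Stimulus rotation speed, deg/s.
#' @param flow_direction `"cw"` or `"ccw"`; positive torsion is clockwise as
#'   seen by the camera, so CW flow builds positive torsion.
#' @param slow_phase_velocity_mean,slow_phase_velocity_sd Mean and
#'   between-block SD of the slow-phase eye velocity (deg/s).
#' @param slow_phase_velocity_jitter_sd Within-block, per-slow-phase velocity
#'   jitter SD (deg/s).
#' @param plateau_range Two numbers (deg): the range from which each block's
#'   blink-free nystagmus equilibrium (build-up plateau) is drawn.
#' @param fast_phase_slowamp_gain Gain of fast-phase amplitude on the
#'   preceding slow-phase amplitude (dimensionless).
#' @param fast_phase_position_gain Weak gain of fast-phase amplitude on the
#'   torsional position at fast-phase onset (dimensionless).
#' @param fast_phase_main_seq_slope Main-sequence slope of fast phases,
#'   (deg/s)/deg; fixes the (constant) minimum-jerk fast-phase duration.
#' @param fast_phase_interval_mean,fast_phase_interval_shape Mean (s) and
#'   gamma shape of inter-fast-phase intervals while the stimulus drives the
#'   eye.
#' @param fast_phase_noise_sd Amplitude noise SD of fast phases (deg).
#' @param fast_phase_setpoint_sd,fast_phase_setpoint_tau SD (deg, in
#'   fast-phase-amplitude units) and time constant (s) of the slow wander of
#'   the fast-phase amplitude setpoint; it makes the nystagmus equilibrium
#'   level drift over tens of seconds, as build-up plateaus do.
#' @param fast_phase_min_amplitude Smallest generated fast phase (deg).
#' @param barm_gain_by_phase Named numeric: BARM gain on pre-blink torsion
#'   for `dark1`, `flow` (both optic-flow phases), `dark2`; each in (-1, 0].
#' @param barm_noise_sd BARM amplitude noise SD (deg).
#' @param barm_deadzone Soft dead-zone scale c (deg) of the BARM drive:
#'   the latent shift is `gain * T * T^2/(T^2 + c^2)`, rescaled so the
#'   response at `barm_deadzone_ref` equals `gain * T` exactly. Small
#'   torsional deviations are under-reset, which is what shrinks
#'   restricted-range regression slopes relative to the full range.
#' @param barm_deadzone_ref Reference torsion (deg) at which the dead-zoned
#'   response is normalized to the nominal gain.
#' @param hv_barm_gain Gain of blink-associated horizontal/vertical resetting
#'   on the pre-blink h/v deviation.
#' @param blink_rate Mean blink rate, events/min.
#' @param blink_flurry_size_mean Mean number of blinks per flurry.
#' @param blink_flurry_gap_mean Mean within-flurry spacing added beyond the
#'   blink duration and safety margins (s).
#' @param blink_duration_mean,blink_duration_sd Blink duration, ms.
#' @param blink_suppression_pre,blink_suppression_post Time (s) before blink
#'   onset / after blink offset during which the optokinetic drive is
#'   suppressed (blink suppression starts before the lid closes).
#' @param comp1_amplitude_mean,comp1_amplitude_sd Torsional amplitude of the
#'   stereotyped first blink component (deg, extorsional positive).
#' @param comp1_peak_latency_mean,comp1_peak_latency_sd Latency of the first
#'   component's velocity peak after blink onset (ms).
#' @param comp1_duration Duration of the first component's outward
#'   minimum-jerk movement (ms).
#' @param comp1_return_tau Exponential time constant of the first
#'   component's return toward baseline (ms).
#' @param comp1_h_amplitude,comp1_v_amplitude Horizontal (nasal < 0) and
#'   vertical (down < 0) displacement of component 1 (deg).
#' @param comp2_latency_mean,comp2_latency_sd Latency of the second
#'   component's velocity peak after the first component's peak (ms). The
#'   `subject_s_merged` flag collapses this latency to ~0.
#' @param comp2_main_seq_slope Main-sequence slope of the resetting second
#'   component, (deg/s)/deg.
#' @param dark_drift_time_constant Exponential decay time constant of latent
#'   torsion toward zero in darkness (s).
#' @param torsion_ceiling Mechanical soft limit of ocular torsion (deg); the
#'   slow-phase drive saturates as the eye approaches it.
#' @param okan_gain,okan_tau Optokinetic afternystagmus: entering the second
#'   darkness phase, a residual slow-phase drive of `okan_gain` times the
#'   block's slow-phase velocity persists and decays with time constant
#'   `okan_tau` (s), so torsion stays deviated for a while after the flow
#'   stops.
#' @param torsion_wander_sd,torsion_wander_tau Stationary SD (deg) and
#'   correlation time (s) of the latent slow torsional wander; this is real
#'   eye state, the deviation BARMs respond to in darkness.
#' @param hv_wander_sd,hv_wander_tau Stationary SD (deg) and correlation
#'   time (s) of latent horizontal/vertical wander.
#' @param video_drift_sd Named (h, v, t): stationary SD of the slow video
#'   measurement-artifact drift per channel (deg); dominated by small head
#'   translations misread as eye movement, so large horizontally and
#'   vertically and small torsionally.
#' @param video_white_sd Named (h, v, t): white video measurement noise SD
#'   per channel (deg).
#' @param video_drift_tau Correlation time of the video artifact drift (s).
#' @param noise_sd_coil Named (h, v, t): coil observation noise SD (deg).
#' @param artifact_rate Rate of unilateral pupil-detection dropouts
#'   (events/min) used to exercise the bilateral blink rule.
#' @param include_blanks If `TRUE`, flow phases contain stimulus-blanking
#'   events (the afference-hypothesis control).
#' @param blank_durations Set of blanking durations (s).
#' @param blank_gap_peak,blank_gap_width Peak and width (s) of the half-sine
#'   density of inter-blank onset gaps (support `[0, 2 * peak]`).
#' @param subject_s_merged If `TRUE`, the two coil components merge
#'   (second-component latency ~0), reproducing the merged-component case.
#' @param slow_phase_velocity_block,plateau_block Optional fixed values for
#'   this block's slow-phase velocity (deg/s) and build-up plateau (deg),
#'   overriding the random per-block draws; [simulate_experiment()] uses
#'   them to stratify block characteristics across an experiment.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return An object of class `barm_sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 50,
                       phase_durations = c(180, 270, 180, 270),
                       flow_speed = 30,
                       flow_direction = c("cw", "ccw"),
                       slow_phase_velocity_mean = 2.95,
                       slow_phase_velocity_sd = 1.2,
                       slow_phase_velocity_jitter_sd = 1.2,
                       plateau_range = c(3, 8),
                       fast_phase_slowamp_gain = 0.52,
                       fast_phase_position_gain = 0.09,
                       fast_phase_main_seq_slope = 31.5,
                       fast_phase_interval_mean = 0.46,
                       fast_phase_interval_shape = 0.45,
                       fast_phase_noise_sd = 0.95,
                       fast_phase_setpoint_sd = 0.2,
                       fast_phase_setpoint_tau = 60,
                       fast_phase_min_amplitude = 0.25,
                       barm_gain_by_phase = c(dark1 = -0.26, flow = -0.62,
                                              dark2 = -0.28),
                       barm_noise_sd = 0.85,
                       barm_deadzone = 1.15,
                       barm_deadzone_ref = 2.8,
                       hv_barm_gain = -0.2,
                       blink_rate = 17,
                       blink_flurry_size_mean = 5.5,
                       blink_flurry_gap_mean = 0.35,
                       blink_duration_mean = 300,
                       blink_duration_sd = 50,
                       blink_suppression_pre = 0.14,
                       blink_suppression_post = 0.2,
                       comp1_amplitude_mean = 1.14,
                       comp1_amplitude_sd = 0.47,
                       comp1_peak_latency_mean = 127,
                       comp1_peak_latency_sd = 35,
                       comp1_duration = 100,
                       comp1_return_tau = 220,
                       comp1_h_amplitude = -1.0,
                       comp1_v_amplitude = -1.5,
                       comp2_latency_mean = 73,
                       comp2_latency_sd = 22,
                       comp2_main_seq_slope = 18.6,
                       dark_drift_time_constant = 30,
                       torsion_ceiling = 15,
                       okan_gain = 0.30,
                       okan_tau = 35,
                       torsion_wander_sd = 1.25,
                       torsion_wander_tau = 15,
                       hv_wander_sd = 1.0,
                       hv_wander_tau = 40,
                       video_drift_sd = c(h = 4.5, v = 6.1, t = 0.45),
                       video_white_sd = c(h = 0.5, v = 0.6, t = 0.15),
                       video_drift_tau = 40,
                       noise_sd_coil = c(h = 0.29, v = 0.29, t = 0.115),
                       artifact_rate = 2,
                       include_blanks = FALSE,
                       blank_durations = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       blank_gap_peak = 5,
                       blank_gap_width = 5,
                       subject_s_merged = FALSE,
                       slow_phase_velocity_block = NULL,
                       plateau_block = NULL,
                       seed = 1L) {
  flow_direction <- match.arg(flow_direction)
  cfg <- as.list(environment())
  class(cfg) <- "barm_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `barm_sim_config` object (or plain list) to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  chk <- function(ok, msg) if (!all(ok)) stop(msg, call. = FALSE)

  chk(config$sampling_rate %in% c(50, 100, 200),
      "sampling_rate must be one of 50, 100, 200 Hz")
  chk(length(config$phase_durations) == 4 && all(config$phase_durations > 0),
      "phase_durations must be four strictly positive durations")
  chk(config$flow_direction %in% c("cw", "ccw"),
      "flow_direction must be 'cw' or 'ccw'")
  pos <- c("torsion_ceiling", "okan_tau", "torsion_wander_tau",
           "slow_phase_velocity_sd", "slow_phase_velocity_jitter_sd",
           "fast_phase_interval_mean", "fast_phase_interval_shape",
           "fast_phase_main_seq_slope", "comp2_main_seq_slope",
           "blink_rate", "blink_flurry_size_mean", "blink_duration_mean",
           "blink_duration_sd", "comp1_peak_latency_mean", "comp1_duration",
           "comp1_return_tau", "dark_drift_time_constant", "video_drift_tau",
           "hv_wander_tau", "blank_gap_peak", "blank_gap_width",
           "barm_deadzone_ref", "fast_phase_setpoint_tau")
  for (p in pos) chk(config[[p]] > 0, sprintf("%s must be strictly positive", p))
  nneg <- c("flow_speed", "slow_phase_velocity_mean", "fast_phase_slowamp_gain",
            "fast_phase_position_gain", "fast_phase_noise_sd", "barm_noise_sd",
            "torsion_wander_sd", "hv_wander_sd", "artifact_rate",
            "blink_suppression_pre", "blink_suppression_post",
            "comp1_amplitude_sd", "comp1_peak_latency_sd", "comp2_latency_sd",
            "blink_flurry_gap_mean", "fast_phase_setpoint_sd", "okan_gain")
  for (p in nneg) chk(config[[p]] >= 0, sprintf("%s must be non-negative", p))
  chk(length(config$plateau_range) == 2 &&
        config$plateau_range[1] < config$plateau_range[2],
      "plateau_range must satisfy plateau_range[1] < plateau_range[2]")
  g <- config$barm_gain_by_phase
  chk(all(c("dark1", "flow", "dark2") %in% names(g)),
      "barm_gain_by_phase needs entries dark1, flow, dark2")
  chk(all(g > -1 & g <= 0), "barm_gain_by_phase values must lie in (-1, 0]")
  chk(config$hv_barm_gain > -1 & config$hv_barm_gain <= 0,
      "hv_barm_gain must lie in (-1, 0]")
  chk(config$barm_deadzone >= 0, "barm_deadzone must be non-negative")
  for (nm in c("video_drift_sd", "video_white_sd", "noise_sd_coil")) {
    chk(all(c("h", "v", "t") %in% names(config[[nm]])),
        sprintf("%s needs named entries h, v, t", nm))
    chk(all(config[[nm]] >= 0), sprintf("%s must be non-negative", nm))
  }
  chk(length(config$blank_durations) >= 1 && all(config$blank_durations > 0),
      "blank_durations must be a non-empty set of positive durations")
  chk(is.finite(config$seed), "seed must be a finite integer")
  config$seed <- as.integer(config$seed)
  config
}

#' @export
print.barm_sim_config <- function(x, ...) {
  cat("<barm_sim_config>\n")
  cat(sprintf("  %g Hz video, phases %s s, flow %s at %g deg/s\n",
              x$sampling_rate, paste(x$phase_durations, collapse = "/"),
              toupper(x$flow_direction), x$flow_speed))
  cat(sprintf("  slow phase %.2f deg/s, plateau %g-%g deg, blink rate %g/min\n",
              x$slow_phase_velocity_mean, x$plateau_range[1],
              x$plateau_range[2], x$blink_rate))
  cat(sprintf("  BARM gains dark1 %.2f / flow %.2f / dark2 %.2f, seed %d\n",
              x$barm_gain_by_phase[["dark1"]], x$barm_gain_by_phase[["flow"]],
              x$barm_gain_by_phase[["dark2"]], x$seed))
  invisible(x)
}

# Phase bookkeeping -----------------------------------------------------

phase_levels <- c("dark1", "flow1", "dark2", "flow2")

phase_table <- function(config) {
  d <- config$phase_durations
  data.frame(phase = phase_levels,
             start = cumsum(c(0, d[-4])),
             end = cumsum(d),
             stringsAsFactors = FALSE)
}

# Map a phase label to its BARM-gain key.
gain_key <- function(phase) ifelse(phase %in% c("flow1", "flow2"), "flow", phase)
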