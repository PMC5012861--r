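# Blink detection and slow/fast-phase segmentation of torsional nystagmus.
# All position reads around blinks respect the temporal safety margins:
# the eye position is taken 140 ms before blink onset and 200 ms after blink
# offset (7 and 10 frames at 50 Hz), because samples adjacent to the lid
# transition are unreliable.

safety_pre <- 0.140   # s before blink onset
safety_post <- 0.200  # s after blink offset

eye_cols <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (eye == "right") c(h = "eyeR_h", v = "eyeR_v", t = "eyeR_t")
  else c(h = "eyeL_h", v = "eyeL_v", t = "eyeL_t")
}

#' Reference eye position to the first fixation-in-darkness phase
#'
#' Shifts every channel of both eyes so that its mean over the valid samples
#' of the `dark1` phase is zero. The mean torsion during fixation in
#' darkness I defines zero torsion; horizontal and vertical channels are
#' referenced the same way.
#'
#' @param block An `eye_trace_block`.
#' @return The referenced `eye_trace_block`.
#' @export
reference_torsion <- function(block) {
  stopifnot(inherits(block, "eye_trace_block"))
  s <- block$samples
  for (eye in c("L", "R")) {
    valid <- s[[paste0("valid_", eye)]] & s$phase == "dark1"
    if (!any(valid))
      stop("dark1 phase has no valid samples; cannot define zero torsion",
           call. = FALSE)
    for (ch in c("h", "v", "t")) {
      col <- sprintf("eye%s_%s", eye, ch)
      s[[col]] <- s[[col]] - mean(s[[col]][valid])
    }
  }
  block$samples <- s
  block$referenced <- TRUE
  block
}

#' Detect blinks from bilateral sample dropouts
#'
#' A maximal run of samples invalid in both eyes is one blink; runs invalid
#' in only one eye are pupil-detection artifacts and are rejected. Pre- and
#' post-blink positions are read exactly 140 ms before onset and 200 ms
#' after offset (offset = reappearance of valid samples). Blinks whose
#' safety-time reads fall outside the block, on invalid samples, or inside
#' another blink's safety window are flagged unusable.
#'
#' @param block A video-modality `eye_trace_block`.
#' @param eye Which eye's channels provide the pre/post positions.
#' @return A data frame of blink events (class `blink_events`) with onset /
#'   offset indices and times, duration (ms), 3D pre/post positions, the
#'   read times, the phase label, and a `usable` flag.
#' @export
detect_blinks <- function(block, eye = c("right", "left")) {
  stopifnot(inherits(block, "eye_trace_block"))
  eye <- match.arg(eye)
  s <- block$samples
  if (is.null(s$valid_L) || is.null(s$valid_R))
    stop("block has no validity flags", call. = FALSE)
  empty <- data.frame(onset_index = integer(0), offset_index = integer(0),
                      onset_time = numeric(0), offset_time = numeric(0),
                      duration = numeric(0), phase = character(0),
                      pre_time = numeric(0), post_time = numeric(0),
                      pre_h = numeric(0), pre_v = numeric(0),
                      pre_t = numeric(0), post_h = numeric(0),
                      post_v = numeric(0), post_t = numeric(0),
                      eye = character(0), usable = logical(0))
  class(empty) <- c("blink_events", "data.frame")
  if (nrow(s) == 0) return(empty)

  fs <- block$sampling_rate
  dt <- 1 / fs
  runs <- logical_runs(!s$valid_L & !s$valid_R)
  if (nrow(runs) == 0) return(empty)

  onset_time <- s$time_s[runs$start]
  offset_time <- s$time_s[runs$end] + dt  # reappearance of valid samples
  ev <- data.frame(onset_index = runs$start, offset_index = runs$end,
                   onset_time = onset_time, offset_time = offset_time,
                   duration = (offset_time - onset_time) * 1000,
                   phase = s$phase[runs$start],
                   pre_time = onset_time - safety_pre,
                   post_time = offset_time + safety_post,
                   stringsAsFactors = FALSE)

  cols <- eye_cols(eye)
  vcol <- if (eye == "right") "valid_R" else "valid_L"
  n <- nrow(s)
  t0 <- s$time_s[1]
  read_idx <- function(tt) {
    i <- round((tt - t0) * fs) + 1L
    ifelse(i >= 1 & i <= n, i, NA_integer_)
  }
  pre_i <- read_idx(ev$pre_time)
  post_i <- read_idx(ev$post_time)

  # A read is unusable if it leaves the block, hits an invalid sample, or
  # falls strictly inside another blink's safety window.
  in_window <- function(tt, excl) {
    sapply(seq_along(tt), function(j) {
      if (is.na(tt[j])) return(TRUE)
      other <- setdiff(seq_len(nrow(ev)), excl[j])
      any(tt[j] > ev$onset_time[other] - safety_pre + dt / 2 &
            tt[j] < ev$offset_time[other] + safety_post - dt / 2)
    })
  }
  usable <- !is.na(pre_i) & !is.na(post_i)
  usable[usable] <- s[[vcol]][pre_i[usable]] & s[[vcol]][post_i[usable]]
  usable <- usable & !in_window(ev$pre_time, seq_len(nrow(ev))) &
    !in_window(ev$post_time, seq_len(nrow(ev)))

  get_pos <- function(idx, ch) ifelse(is.na(idx), NA_real_, s[[cols[ch]]][idx])
  ev$pre_h <- get_pos(pre_i, "h"); ev$pre_v <- get_pos(pre_i, "v")
  ev$pre_t <- get_pos(pre_i, "t")
  ev$post_h <- get_pos(post_i, "h"); ev$post_v <- get_pos(post_i, "v")
  ev$post_t <- get_pos(post_i, "t")
  ev$eye <- eye
  ev$usable <- usable
  class(ev) <- c("blink_events", "data.frame")
  ev
}

# Samples excluded from position reads: every blink run plus its safety
# margins.
blink_sample_mask <- function(block, blinks) {
  s <- block$samples
  masked <- rep(FALSE, nrow(s))
  if (nrow(blinks) == 0) return(masked)
  for (i in seq_len(nrow(blinks))) {
    sel <- s$time_s > blinks$onset_time[i] - safety_pre +
      1e-9 & s$time_s < blinks$offset_time[i] + safety_post - 1e-9
    masked[sel] <- TRUE
  }
  masked
}

#' Segment torsional nystagmus into slow and fast phases
#'
#' Torsional velocity is estimated with a Savitzky--Golay derivative
#' (quadratic, 100 ms window by default). Runs where the speed exceeds
#' `fast_threshold` against the flow direction (or against the local slow
#' drift in darkness) for at least `min_duration` are fast phases; the
#' unmasked intervals between them are slow phases. Blink safety windows
#' are masked out before segmentation.
#'
#' @param block A referenced `eye_trace_block`.
#' @param blinks Blink events from [detect_blinks()].
#' @param fast_threshold Fast-phase speed threshold, deg/s.
#' @param min_duration Minimum fast-phase duration, s (2 samples at 50 Hz).
#' @param sg_window Smoothing/differentiation window, s.
#' @param min_amplitude Smallest drift-corrected amplitude (deg) accepted as
#'   a fast phase; smaller threshold crossings are treated as noise.
#' @param eye Which eye's torsion channel to segment.
#' @return A data frame (class `nystagmus_phases`): `kind` (slow/fast),
#'   onset/offset indices and times, duration, torsional `amplitude`
#'   (position at offset minus onset), `peak_velocity` and
#'   `preceding_slow_amplitude` for fast phases, `mean_velocity` for slow
#'   phases, `pre_shift_position`, `direction`, and the phase label.
#' @export
segment_nystagmus <- function(block, blinks, fast_threshold = 7,
                              min_duration = 0.04, sg_window = 0.1,
                              min_amplitude = 0.3,
                              eye = c("right", "left")) {
  stopifnot(inherits(block, "eye_trace_block"))
  eye <- match.arg(eye)
  s <- block$samples
  fs <- block$sampling_rate
  cols <- eye_cols(eye)
  pos <- s[[cols["t"]]]
  masked <- blink_sample_mask(block, blinks) | is.na(pos)
  empty <- data.frame(kind = character(0), onset_index = integer(0),
                      offset_index = integer(0), onset_time = numeric(0),
                      offset_time = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      mean_velocity = numeric(0),
                      pre_shift_position = numeric(0),
                      preceding_slow_amplitude = numeric(0),
                      direction = numeric(0), phase = character(0),
                      irregular = logical(0), drift_excess = numeric(0))
  class(empty) <- c("nystagmus_phases", "data.frame")
  if (all(masked)) {
    warning("all samples masked; nothing to segment")
    return(empty)
  }

  w <- round(sg_window * fs)
  if (w %% 2 == 0) w <- w + 1L
  pos_m <- pos
  pos_m[masked] <- NA
  # bridge isolated 1-2 sample dropouts (unilateral pupil artifacts) so they
  # do not fragment slow phases; blink windows stay masked
  na_runs <- logical_runs(is.na(pos_m))
  if (nrow(na_runs) > 0) {
    short <- na_runs[na_runs$end - na_runs$start + 1L <= 2L, , drop = FALSE]
    blink_masked <- blink_sample_mask(block, blinks)
    for (i in seq_len(nrow(short))) {
      idx <- short$start[i]:short$end[i]
      if (any(blink_masked[idx])) next
      a <- short$start[i] - 1L; b <- short$end[i] + 1L
      if (a < 1L || b > length(pos_m) || is.na(pos_m[a]) || is.na(pos_m[b]))
        next
      pos_m[idx] <- pos_m[a] + (pos_m[b] - pos_m[a]) *
        (idx - a) / (b - a)
      masked[idx] <- FALSE
    }
  }
  pos[is.na(pos)] <- pos_m[is.na(pos)]
  vel <- sg_velocity(pos_m, fs, w)
  # lightly smoothed position for step/irregularity checks
  pos_sm <- as.numeric(stats::filter(pos_m, rep(1 / 5, 5), sides = 2))
  pos_sm[is.na(pos_sm)] <- pos_m[is.na(pos_sm)]

  # per-sample beat direction: opposite the flow during stimulation,
  # opposite the local slow drift (1 s scale) in darkness
  flow_dir <- rep(0, nrow(s))
  flow_dir[s$stimulus_state == "flow_cw"] <- 1
  flow_dir[s$stimulus_state == "flow_ccw"] <- -1
  in_flow <- s$phase %in% c("flow1", "flow2")
  if (any(in_flow)) {
    # blanked samples inherit the phase's flow direction
    ff <- flow_dir
    ff[in_flow & ff == 0] <- sign(sum(ff[in_flow]))
    flow_dir <- ff
  }
  drift <- sg_velocity(pos_m, fs, max(w, round(1 * fs) + (round(1 * fs) + 1) %% 2))
  beat_ok <- ifelse(in_flow, sign(vel) == -flow_dir,
                    abs(drift) < 0.5 | sign(vel) == -sign(drift))
  cand <- !masked & !is.na(vel) & abs(vel) >= fast_threshold & beat_ok

  min_len <- max(2L, round(min_duration * fs))
  runs <- logical_runs(cand)
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  # drop runs that straddle phase boundaries
  if (nrow(runs) > 0)
    runs <- runs[s$phase[runs$start] == s$phase[runs$end], , drop = FALSE]

  events <- list()
  # fast phases: read positions one sample outside the threshold run
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      i0 <- runs$start[i]; i1 <- runs$end[i]
      j0 <- if (i0 > 1 && !masked[i0 - 1]) i0 - 1L else i0
      j1 <- if (i1 < nrow(s) && !masked[i1 + 1]) i1 + 1L else i1
      pv_idx <- (i0:i1)[which.max(abs(vel[i0:i1]))]
      # the threshold window is wider than the saccade itself, so the slow
      # drift accrued inside it is subtracted from the amplitude
      near <- c(max(1L, j0 - 8L):max(1L, j0 - 1L),
                min(nrow(s), j1 + 1L):min(nrow(s), j1 + 8L))
      near <- near[!cand[near] & !masked[near] & !is.na(vel[near])]
      v_loc <- if (length(near) >= 3) stats::median(vel[near]) else 0
      amp <- (pos[j1] - pos[j0]) - v_loc * (s$time_s[j1] - s$time_s[j0])
      if (!is.finite(amp) || abs(amp) < min_amplitude) next
      # saccade duration implied by a minimum-jerk profile; the rest of the
      # threshold window is slow-phase time whose drift the window swallowed
      pv <- vel[pv_idx]
      d_est <- min(0.12, max(0.04, 1.875 * abs(amp) / max(abs(pv), 1)))
      excess <- max(0, (s$time_s[j1] - s$time_s[j0]) - d_est)
      events[[length(events) + 1L]] <- data.frame(
        kind = "fast", onset_index = j0, offset_index = j1,
        onset_time = s$time_s[j0], offset_time = s$time_s[j1],
        duration = s$time_s[j1] - s$time_s[j0],
        amplitude = amp, peak_velocity = vel[pv_idx],
        mean_velocity = NA_real_, pre_shift_position = pos[j0],
        preceding_slow_amplitude = NA_real_,
        direction = sign(amp), phase = s$phase[i0],
        irregular = FALSE, drift_excess = v_loc * excess,
        stringsAsFactors = FALSE)
    }
  }
  fast_df <- if (length(events) > 0) do.call(rbind, events) else empty

  # slow phases: unmasked, non-fast stretches within one phase label
  occupied <- masked
  if (nrow(fast_df) > 0)
    for (i in seq_len(nrow(fast_df)))
      occupied[fast_df$onset_index[i]:fast_df$offset_index[i]] <- TRUE
  phase_id <- as.integer(factor(s$phase, levels = phase_levels))
  free <- !occupied
  slow_list <- list()
  runs_s <- logical_runs(free)
  if (nrow(runs_s) > 0) {
    for (i in seq_len(nrow(runs_s))) {
      i0 <- runs_s$start[i]; i1 <- runs_s$end[i]
      # split at phase boundaries
      cuts <- which(diff(phase_id[i0:i1]) != 0)
      bounds <- unique(c(i0, i0 + cuts, i1 + 1L))
      for (j in seq_len(length(bounds) - 1L)) {
        a <- bounds[j]; b <- bounds[j + 1L] - 1L
        if (b - a + 1L < 2L) next
        dur <- s$time_s[b] - s$time_s[a]
        if (dur <= 0) next
        # endpoint positions averaged over the first/last 3 samples (inside
        # the slow phase only, so no fast-phase bleed), rescaled to the full
        # span; unbiased for a linear drift, with ~sqrt(3) less endpoint
        # noise than single samples
        if (b - a >= 5L) {
          p_a <- mean(pos_m[a:(a + 2L)], na.rm = TRUE)
          p_b <- mean(pos_m[(b - 2L):b], na.rm = TRUE)
          s_amp <- (p_b - p_a) * dur / (dur - 2 / fs)
        } else s_amp <- pos[b] - pos[a]
        # a slow phase should ride a near-straight line; a large excursion
        # from the endpoint chord signals an undetected resetting step, so
        # its amplitude must not be used as a preceding slow amplitude
        seg <- pos_sm[a:b]
        chord <- seg[1] + (seg[length(seg)] - seg[1]) *
          (seq_along(seg) - 1) / (length(seg) - 1)
        irregular <- any(abs(seg - chord) >
                           0.4 + 0.15 * sqrt(dur), na.rm = TRUE)
        slow_list[[length(slow_list) + 1L]] <- data.frame(
          kind = "slow", onset_index = a, offset_index = b,
          onset_time = s$time_s[a], offset_time = s$time_s[b],
          duration = dur, amplitude = s_amp,
          peak_velocity = NA_real_,
          mean_velocity = s_amp / dur,
          pre_shift_position = pos[a],
          preceding_slow_amplitude = NA_real_,
          direction = sign(pos[b] - pos[a]), phase = s$phase[a],
          irregular = irregular, drift_excess = 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  slow_df <- if (length(slow_list) > 0) do.call(rbind, slow_list) else empty

  out <- rbind(fast_df, slow_df)
  out <- out[order(out$onset_index), , drop = FALSE]
  rownames(out) <- NULL

  # attach each fast phase's preceding slow-phase amplitude (contiguous,
  # same experimental phase)
  if (nrow(out) > 0) {
    is_fast <- out$kind == "fast"
    for (i in which(is_fast)) {
      j <- i - 1L
      if (j >= 1 && out$kind[j] == "slow" && !out$irregular[j] &&
          out$phase[j] == out$phase[i] &&
          out$onset_index[i] - out$offset_index[j] <= 2L) {
        # restitute the slow drift swallowed by the threshold windows of
        # the flanking fast phases (half of each window's excess)
        restit <- 0.5 * out$drift_excess[i]
        if (j >= 2 && out$kind[j - 1] == "fast" &&
            out$offset_index[j - 1] >= out$onset_index[j] - 2L)
          restit <- restit + 0.5 * out$drift_excess[j - 1]
        out$preceding_slow_amplitude[i] <- out$amplitude[j] + restit
      }
    }
  }
  class(out) <- c("nystagmus_phases", "data.frame")
  out
}
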