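# Event-level measurements: torsional (and horizontal/vertical) shifts
# across blinks, fast-phase shifts, and shifts across stimulus blanks.

#' Measure blink-associated resetting movements
#'
#' One measurement per usable blink: the shift in each channel is the
#' safety-time post-blink position minus the pre-blink position; the
#' preceding slow-phase amplitude is the torsion change from the end of the
#' preceding fast phase (same experimental phase) to the pre-blink read.
#'
#' @param block A referenced `eye_trace_block`.
#' @param blinks Blink events from [detect_blinks()].
#' @param phases Segmentation from [segment_nystagmus()].
#' @return A data frame (class `barm_measurements`) with `torsional_shift`,
#'   `h_shift`, `v_shift`, pre-blink 3D position, `preceding_slow_amplitude`
#'   (NA when no fast phase precedes the blink within its phase), phase
#'   label, flow direction, and blink duration (ms).
#' @export
measure_barms <- function(block, blinks, phases) {
  stopifnot(inherits(block, "eye_trace_block"))
  flow_dir <- block_flow_direction(block)
  use <- blinks[blinks$usable, , drop = FALSE]
  out <- data.frame(
    onset_time = use$onset_time,
    torsional_shift = use$post_t - use$pre_t,
    h_shift = use$post_h - use$pre_h,
    v_shift = use$post_v - use$pre_v,
    pre_t = use$pre_t, pre_h = use$pre_h, pre_v = use$pre_v,
    preceding_slow_amplitude = rep(NA_real_, nrow(use)),
    phase = use$phase, flow_direction = rep(flow_dir, nrow(use)),
    blink_duration = use$duration,
    stringsAsFactors = FALSE)
  fast <- phases[phases$kind == "fast", , drop = FALSE]
  if (nrow(fast) > 0 && nrow(out) > 0) {
    fast_end_pos <- fast$pre_shift_position + fast$amplitude
    for (i in seq_len(nrow(out))) {
      ok <- fast$offset_time <= use$pre_time[i] & fast$phase == use$phase[i]
      if (any(ok)) {
        j <- which(ok)[which.max(fast$offset_time[ok])]
        out$preceding_slow_amplitude[i] <- use$pre_t[i] - fast_end_pos[j]
      }
    }
  }
  class(out) <- c("barm_measurements", "data.frame")
  out
}

#' Measure fast-phase torsional shifts
#'
#' Extracts the fast phases from a segmentation as shift measurements: the
#' signed torsional amplitude, the pre-shift position (torsion at fast-phase
#' onset), and the preceding slow-phase amplitude.
#'
#' @param phases Segmentation from [segment_nystagmus()].
#' @param flow_direction `"cw"` or `"ccw"` for the block the phases came
#'   from.
#' @return A data frame (class `fast_measurements`).
#' @export
measure_fast_phase_shifts <- function(phases, flow_direction) {
  fast <- phases[phases$kind == "fast", , drop = FALSE]
  out <- data.frame(
    onset_time = fast$onset_time,
    torsional_shift = fast$amplitude,
    pre_shift_position = fast$pre_shift_position,
    preceding_slow_amplitude = fast$preceding_slow_amplitude,
    peak_velocity = fast$peak_velocity,
    phase = fast$phase, flow_direction = rep(flow_direction, nrow(fast)),
    stringsAsFactors = FALSE)
  class(out) <- c("fast_measurements", "data.frame")
  out
}

#' Measure torsional shifts across stimulus blanks
#'
#' Applies the real-blink measurement convention to blanking events, which
#' involve no lid closure: positions are read 140 ms before blank onset and
#' 200 ms after blank offset. Blanks whose reads collide with a blink
#' safety window or invalid samples are excluded.
#'
#' @param block A referenced `eye_trace_block` from a blanking experiment.
#' @param blanks Data frame with `onset_time` and `duration` (s), e.g. the
#'   `blanks` table of the ground-truth log or the blank intervals recovered
#'   from `stimulus_state == "blanked"`.
#' @param blinks Optional blink events used to exclude colliding reads.
#' @param eye Which eye's channels to read.
#' @return A data frame (class `blank_measurements`) with `torsional_shift`,
#'   `pre_t`, `duration` (ms), phase label, and flow direction.
#' @export
measure_blank_shifts <- function(block, blanks, blinks = NULL,
                                 eye = c("right", "left")) {
  stopifnot(inherits(block, "eye_trace_block"))
  eye <- match.arg(eye)
  s <- block$samples
  fs <- block$sampling_rate
  cols <- eye_cols(eye)
  vcol <- if (eye == "right") "valid_R" else "valid_L"
  masked <- if (!is.null(blinks)) blink_sample_mask(block, blinks) else
    rep(FALSE, nrow(s))
  flow_dir <- block_flow_direction(block)
  t0 <- s$time_s[1]
  n <- nrow(s)

  pre_t <- blanks$onset_time - safety_pre
  post_t <- blanks$onset_time + blanks$duration + safety_post
  idx_of <- function(tt) {
    i <- round((tt - t0) * fs) + 1L
    ifelse(i >= 1 & i <= n, i, NA_integer_)
  }
  pi <- idx_of(pre_t); qi <- idx_of(post_t)
  ok <- !is.na(pi) & !is.na(qi)
  ok[ok] <- s[[vcol]][pi[ok]] & s[[vcol]][qi[ok]] &
    !masked[pi[ok]] & !masked[qi[ok]]
  out <- data.frame(
    onset_time = blanks$onset_time[ok],
    torsional_shift = s[[cols["t"]]][qi[ok]] - s[[cols["t"]]][pi[ok]],
    pre_t = s[[cols["t"]]][pi[ok]],
    duration = blanks$duration[ok] * 1000,
    phase = s$phase[pi[ok]], flow_direction = flow_dir,
    stringsAsFactors = FALSE)
  class(out) <- c("blank_measurements", "data.frame")
  out
}

# Flow direction of a block from its stimulus labels.
block_flow_direction <- function(block) {
  st <- block$samples$stimulus_state
  if (any(st == "flow_cw")) "cw" else if (any(st == "flow_ccw")) "ccw"
  else NA_character_
}

# Canonical shift table used by the statistics layer: columns shift,
# position, slow_amplitude, direction, phase.
as_shift_table <- function(x) {
  if (inherits(x, "barm_measurements")) {
    data.frame(shift = x$torsional_shift, position = x$pre_t,
               slow_amplitude = x$preceding_slow_amplitude,
               direction = x$flow_direction, phase = x$phase,
               duration = x$blink_duration, stringsAsFactors = FALSE)
  } else if (inherits(x, "fast_measurements")) {
    data.frame(shift = x$torsional_shift, position = x$pre_shift_position,
               slow_amplitude = x$preceding_slow_amplitude,
               direction = x$flow_direction, phase = x$phase,
               duration = NA_real_, stringsAsFactors = FALSE)
  } else if (inherits(x, "blank_measurements")) {
    data.frame(shift = x$torsional_shift, position = x$pre_t,
               slow_amplitude = NA_real_, direction = x$flow_direction,
               phase = x$phase, duration = x$duration,
               stringsAsFactors = FALSE)
  } else if (is.data.frame(x) &&
             all(c("shift", "position") %in% names(x))) {
    x$slow_amplitude <- x$slow_amplitude %||% NA_real_
    x$direction <- x$direction %||% NA_character_
    x$phase <- x$phase %||% NA_character_
    x$duration <- x$duration %||% NA_real_
    x
  } else {
    stop("cannot interpret measurements of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}
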