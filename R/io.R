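# Trace container and file formats. One block is one CSV file with a fixed
# column order; invalid samples carry empty position fields. Event tables and
# ground-truth logs travel as JSON.

trace_columns <- c("time_s", "eyeL_h", "eyeL_v", "eyeL_t",
                   "eyeR_h", "eyeR_v", "eyeR_t",
                   "valid_L", "valid_R", "phase", "stimulus_state")

#' Eye-trace block container
#'
#' A multichannel 3D eye-position time series (both eyes; horizontal,
#' vertical, torsional, in degrees) with per-sample validity flags,
#' experimental-phase labels and stimulus state.
#'
#' @param samples Data frame with columns `time_s`, `eyeL_h`, `eyeL_v`,
#'   `eyeL_t`, `eyeR_h`, `eyeR_v`, `eyeR_t`, `valid_L`, `valid_R`, `phase`,
#'   `stimulus_state`.
#' @param modality `"video"` or `"coil"`.
#' @param sampling_rate Sampling rate in Hz.
#' @return An `eye_trace_block` object.
#' @export
eye_trace_block <- function(samples, modality = c("video", "coil"),
                            sampling_rate) {
  modality <- match.arg(modality)
  missing_cols <- setdiff(trace_columns, names(samples))
  if (length(missing_cols) > 0)
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples)[trace_columns]
  dt <- diff(samples$time_s)
  if (length(dt) > 0 && any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("time_s must be strictly increasing (violated at row %d)",
                 bad), call. = FALSE)
  }
  if (!all(samples$phase %in% phase_levels))
    stop("phase labels must be one of: ", paste(phase_levels, collapse = ", "),
         call. = FALSE)
  structure(list(samples = samples, modality = modality,
                 sampling_rate = sampling_rate),
            class = "eye_trace_block")
}

#' @export
print.eye_trace_block <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<eye_trace_block> %s modality, %g Hz, %d samples (%.1f s)\n",
              x$modality, x$sampling_rate, n, n / x$sampling_rate))
  inval <- sum(!x$samples$valid_L | !x$samples$valid_R)
  cat(sprintf("  phases: %s; %d samples invalid in at least one eye\n",
              paste(unique(x$samples$phase), collapse = ", "), inval))
  invisible(x)
}

#' Write / read an eye-trace block
#'
#' The trace dialect is a UTF-8 CSV with a header row and the fixed column
#' order `time_s, eyeL_h, eyeL_v, eyeL_t, eyeR_h, eyeR_v, eyeR_t, valid_L,
#' valid_R, phase, stimulus_state`; angles in degrees, times in seconds,
#' validity flags 0/1, and positions of invalid samples written as empty
#' fields. A write/read round trip reproduces the block exactly.
#'
#' @param block An `eye_trace_block`.
#' @param path File path.
#' @param modality,sampling_rate Stored with the block on read; the sampling
#'   rate defaults to the reciprocal median time step.
#' @return `read_trace()` returns an `eye_trace_block`; `write_trace()`
#'   returns `path` invisibly.
#' @export
write_trace <- function(block, path) {
  stopifnot(inherits(block, "eye_trace_block"))
  out <- block$samples
  out$valid_L <- as.integer(out$valid_L)
  out$valid_R <- as.integer(out$valid_R)
  data.table::fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, modality = c("video", "coil"),
                       sampling_rate = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, trace_columns))
    stop(sprintf("malformed header in %s: expected '%s'", path,
                 paste(trace_columns, collapse = ",")), call. = FALSE)
  d <- data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                         colClasses = list(character = c("phase",
                                                         "stimulus_state")))
  d <- as.data.frame(d)
  bad_phase <- which(!d$phase %in% phase_levels)
  if (length(bad_phase) > 0)
    stop(sprintf("unknown phase label '%s' at line %d of %s",
                 d$phase[bad_phase[1]], bad_phase[1] + 1L, path),
         call. = FALSE)
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono) > 0)
    stop(sprintf("time_s not strictly increasing at line %d of %s",
                 nonmono[1] + 2L, path), call. = FALSE)
  if (!all(d$valid_L %in% c(0L, 1L)) || !all(d$valid_R %in% c(0L, 1L)))
    stop("validity flags must be 0 or 1 in ", path, call. = FALSE)
  d$valid_L <- d$valid_L == 1L
  d$valid_R <- d$valid_R == 1L
  if (is.null(sampling_rate))
    sampling_rate <- round(1 / stats::median(diff(d$time_s)))
  eye_trace_block(d, modality = modality, sampling_rate = sampling_rate)
}

#' Write / read a ground-truth event log
#'
#' Serializes the event content of a `barm_truth` log (blinks, fast phases,
#' blanks, per-phase gains, block parameters) to JSON. The per-sample latent
#' trace and render cache are not serialized; they can be regenerated from
#' the stored configuration.
#'
#' @param truth A `barm_truth` object.
#' @param path File path.
#' @return `read_truth_events()` returns the parsed list; `write_truth_events()`
#'   returns `path` invisibly.
#' @export
write_truth_events <- function(truth, path) {
  stopifnot(inherits(truth, "barm_truth"))
  payload <- list(
    blinks = truth$blinks, fast_phases = truth$fast_phases,
    blanks = truth$blanks, phase_gains = as.list(truth$phase_gains),
    flow_direction = truth$flow_direction, v_block = truth$v_block,
    plateau = truth$plateau,
    config = truth$config[setdiff(names(truth$config), character(0))])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_events
#' @export
read_truth_events <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
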