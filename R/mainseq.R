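# Main-sequence analysis: the stereotyped relationship between a saccadic
# movement's amplitude and its peak velocity, and the comparison of two
# event classes (e.g. optokinetic fast phases vs the resetting blink
# component, which rides a slower main sequence).

#' Fit a main sequence
#'
#' Ordinary least-squares fit of peak velocity on absolute amplitude for one
#' class of saccadic events.
#'
#' @param events Data frame with `amplitude` (deg, signed or absolute) and
#'   `peak_velocity` (deg/s, signed or absolute).
#' @param class_label Label stored with the fit (e.g. `"fast_phase"`,
#'   `"barm_comp2"`).
#' @return A list of class `main_sequence_fit`: `slope` ((deg/s)/deg),
#'   `intercept` (deg/s), Pearson `r`, `n`, `class_label`; or a no-fit
#'   result if fewer than 3 events or degenerate amplitude spread.
#' @export
main_sequence <- function(events, class_label = "events") {
  a <- abs(events$amplitude)
  v <- abs(events$peak_velocity)
  keep <- is.finite(a) & is.finite(v)
  a <- a[keep]; v <- v[keep]
  out <- list(class_label = class_label, slope = NA_real_,
              intercept = NA_real_, r = NA_real_, n = length(a),
              reason = NULL)
  class(out) <- "main_sequence_fit"
  if (length(a) < 3) { out$reason <- "fewer than 3 events"; return(out) }
  if (stats::var(a) == 0) { out$reason <- "degenerate amplitude spread"; return(out) }
  fit <- stats::lm(v ~ a)
  out$slope <- unname(stats::coef(fit)[2])
  out$intercept <- unname(stats::coef(fit)[1])
  out$r <- stats::cor(a, v)
  out
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<main_sequence_fit> %s: no fit (%s)\n", x$class_label,
                x$reason))
  } else {
    cat(sprintf(
      "<main_sequence_fit> %s: Vpk = %.1f + %.1f x |A| (r = %.2f, n = %d)\n",
      x$class_label, x$intercept, x$slope, x$r, x$n))
  }
  invisible(x)
}

#' Compare two main sequences
#'
#' Reports (i) the vertical offset between the two class regressions
#' evaluated at a matched amplitude (the mean absolute amplitude of the
#' combined samples) and (ii) a Wilcoxon rank-sum test on the
#' amplitude-normalized peak velocities (peak velocity divided by absolute
#' amplitude, per event).
#'
#' @param fit_a,fit_b `main_sequence_fit` objects.
#' @param events_a,events_b The event samples behind the fits (`amplitude`,
#'   `peak_velocity`).
#' @return A list of class `main_sequence_comparison`: `offset_shift`
#'   (deg/s; prediction of A minus prediction of B at the matched
#'   amplitude), `matched_amplitude`, `wilcox_p`, and the normalized-velocity
#'   medians.
#' @export
compare_main_sequences <- function(fit_a, fit_b, events_a, events_b) {
  stopifnot(inherits(fit_a, "main_sequence_fit"),
            inherits(fit_b, "main_sequence_fit"))
  if (!is.null(fit_a$reason) || !is.null(fit_b$reason))
    stop("cannot compare: at least one class has no main-sequence fit",
         call. = FALSE)
  norm_a <- abs(events_a$peak_velocity) / abs(events_a$amplitude)
  norm_b <- abs(events_b$peak_velocity) / abs(events_b$amplitude)
  norm_a <- norm_a[is.finite(norm_a)]
  norm_b <- norm_b[is.finite(norm_b)]
  a_match <- mean(c(abs(events_a$amplitude), abs(events_b$amplitude)),
                  na.rm = TRUE)
  w <- stats::wilcox.test(norm_a, norm_b)
  out <- list(
    offset_shift = (fit_a$intercept + fit_a$slope * a_match) -
      (fit_b$intercept + fit_b$slope * a_match),
    matched_amplitude = a_match,
    wilcox_p = w$p.value,
    median_norm_a = stats::median(norm_a),
    median_norm_b = stats::median(norm_b),
    class_a = fit_a$class_label, class_b = fit_b$class_label)
  class(out) <- "main_sequence_comparison"
  out
}

#' @export
print.main_sequence_comparison <- function(x, ...) {
  cat(sprintf("<main_sequence_comparison> %s vs %s\n", x$class_a, x$class_b))
  cat(sprintf("  offset at |A| = %.2f deg: %.1f deg/s; Wilcoxon p = %.3g\n",
              x$matched_amplitude, x$offset_shift, x$wilcox_p))
  cat(sprintf("  median normalized velocity: %.1f vs %.1f (deg/s)/deg\n",
              x$median_norm_a, x$median_norm_b))
  invisible(x)
}

# Re-measure an event's peak velocity from a position trace with a narrow
# Savitzky-Golay derivative (35 ms), suited to brief saccadic profiles.
peak_velocity_in <- function(pos, fs, i0, i1, window_s = 0.035) {
  w <- round(window_s * fs); if (w %% 2 == 0) w <- w + 1
  w <- max(w, 5L)
  lo <- max(1L, i0 - w); hi <- min(length(pos), i1 + w)
  v <- sg_velocity(pos[lo:hi], fs, w)
  seg <- v[(i0 - lo + 1L):(i1 - lo + 1L)]
  if (all(is.na(seg))) return(NA_real_)
  seg[which.max(abs(seg))]
}
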