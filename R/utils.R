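# Small numerical helpers shared by the simulator and the analysis layer.

#' Minimum-jerk position profile
#'
#' Smooth unit step used for saccadic displacements: `s(u) = 10u^3 - 15u^4 +
#' 6u^5` on `[0, 1]`, 0 below and 1 above. Its velocity peaks at the midpoint
#' with value `1.875 / d` for a movement of unit amplitude and duration `d`,
#' so a constant-duration family of movements obeys a linear main sequence
#' with slope `1.875 / d` in (deg/s)/deg.
#'
#' @param u Normalized time (dimensionless).
#' @return Profile values in `[0, 1]`.
#' @keywords internal
min_jerk <- function(u) {
  s <- pmin(pmax(u, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

# Duration (s) that makes a constant-duration minimum-jerk family follow a
# main-sequence slope of `slope` (deg/s)/deg: Vpk = 1.875 * A / d = slope * A.
main_seq_duration <- function(slope) 1.875 / slope

# Stationary Ornstein-Uhlenbeck sample path on a uniform grid.
# sd is the stationary standard deviation, tau the correlation time (s).
ou_path <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Savitzky-Golay derivative of a position signal (deg -> deg/s).
# Quadratic local polynomial over `window` samples (odd). NA-safe: NA runs
# propagate to the half-window around them.
sg_velocity <- function(x, fs, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (length(x) < window) return(rep(NA_real_, length(x)))
  na <- is.na(x)
  xf <- x
  if (any(na)) xf[na] <- 0
  v <- signal::sgolayfilt(xf, p = 2, n = window, m = 1, ts = 1 / fs)
  if (any(na)) {
    half <- (window - 1L) %/% 2L
    bad <- which(na)
    idx <- unique(pmin(pmax(rep(bad, each = 2L * half + 1L) +
                              seq(-half, half), 1L), length(x)))
    v[idx] <- NA_real_
  }
  v
}

# Runs of TRUE in a logical vector -> data.frame(start, end) of indices.
logical_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
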