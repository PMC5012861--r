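# Statistical layer: phase-wise shift regressions (full and restricted
# range), the pooled-versus-split cluster diagnostic, bootstrap correlation
# inference, and the 2D regression of shifts on slow-phase amplitude and
# pre-shift position.

#' Regression of torsional shift on a predictor
#'
#' Ordinary least-squares fit of the torsional shift on either the
#' pre-shift eye position or the preceding slow-phase amplitude, with the
#' Pearson correlation and its two-sided p-value. The pre-shift position
#' can be restricted to a range (e.g. -2 to 2 deg) to test whether phase
#' differences survive matched position ranges. `direction_scope`
#' `"mean_of_split"` fits the two flow directions separately and reports
#' the mean slope/intercept/correlation, the convention used for
#' fast-phase summaries.
#'
#' @param measurements A `barm_measurements`, `fast_measurements`,
#'   `blank_measurements`, or canonical shift table.
#' @param predictor `"pre_shift_position"` or `"preceding_slow_amplitude"`.
#' @param range_limits Optional length-2 numeric: keep events whose
#'   pre-shift position lies inside `[range_limits[1], range_limits[2]]`.
#' @param direction_scope `"pooled"`, `"cw"`, `"ccw"`, or `"mean_of_split"`.
#' @param phases Optional character vector of phase labels to keep.
#' @return A list of class `shift_regression`: `slope`, `intercept`, `r`,
#'   `p`, `n`, plus the scope/filters; a no-fit result (NAs and a `reason`)
#'   when fewer than 3 usable events remain.
#' @export
fit_shift_regression <- function(measurements,
                                 predictor = c("pre_shift_position",
                                               "preceding_slow_amplitude"),
                                 range_limits = NULL,
                                 direction_scope = c("pooled", "cw", "ccw",
                                                     "mean_of_split"),
                                 phases = NULL) {
  predictor <- match.arg(predictor)
  direction_scope <- match.arg(direction_scope)
  tab <- as_shift_table(measurements)
  if (!is.null(phases)) tab <- tab[tab$phase %in% phases, , drop = FALSE]
  if (!is.null(range_limits)) {
    stopifnot(length(range_limits) == 2)
    tab <- tab[!is.na(tab$position) & tab$position >= range_limits[1] &
                 tab$position <= range_limits[2], , drop = FALSE]
  }
  x <- if (predictor == "pre_shift_position") tab$position else
    tab$slow_amplitude
  keep <- is.finite(x) & is.finite(tab$shift)
  tab <- tab[keep, , drop = FALSE]
  x <- x[keep]

  base <- list(predictor = predictor, range_limits = range_limits,
               direction_scope = direction_scope, slope = NA_real_,
               intercept = NA_real_, r = NA_real_, p = NA_real_,
               n = nrow(tab), reason = NULL)
  class(base) <- "shift_regression"

  ols <- function(xx, yy) {
    if (length(xx) < 3) return(NULL)
    if (stats::var(xx) == 0) return(NULL)
    fit <- stats::lm(yy ~ xx)
    ct <- stats::cor.test(xx, yy)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = unname(ct$estimate), p = ct$p.value, n = length(xx))
  }

  if (direction_scope %in% c("pooled", "cw", "ccw")) {
    if (direction_scope != "pooled") {
      sel <- tab$direction == direction_scope
      tab <- tab[sel, , drop = FALSE]; x <- x[sel]
    }
    f <- ols(x, tab$shift)
    if (is.null(f)) {
      base$n <- nrow(tab)
      base$reason <- "insufficient n or degenerate predictor after filtering"
      return(base)
    }
    base[names(f)] <- f
    return(base)
  }

  # mean of the two direction-split fits
  fits <- lapply(c("cw", "ccw"), function(d) {
    sel <- tab$direction == d
    ols(x[sel], tab$shift[sel])
  })
  if (any(vapply(fits, is.null, logical(1)))) {
    base$reason <- "insufficient n in at least one direction"
    return(base)
  }
  base$slope <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  base$intercept <- mean(vapply(fits, `[[`, numeric(1), "intercept"))
  base$r <- mean(vapply(fits, `[[`, numeric(1), "r"))
  base$p <- max(vapply(fits, `[[`, numeric(1), "p"))
  base$n <- sum(vapply(fits, `[[`, numeric(1), "n"))
  base$split_fits <- stats::setNames(fits, c("cw", "ccw"))
  base
}

#' @export
print.shift_regression <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<shift_regression> no fit: %s (n = %d)\n", x$reason, x$n))
  } else {
    cat(sprintf(
      "<shift_regression> %s, %s: slope %.3f, intercept %.3f, r %.3f, p %.3g, n %d\n",
      x$predictor, x$direction_scope, x$slope, x$intercept, x$r, x$p, x$n))
  }
  invisible(x)
}

#' Pooled-versus-split cluster diagnostic
#'
#' Tests whether shift measurements from the two flow directions form one
#' continuum or two separated clusters: the same events are fitted once
#' pooled over directions and once per direction. Small slope and offset
#' differences indicate a continuum (BARM-like); large differences indicate
#' two direction-dependent clusters (fast-phase-like).
#'
#' The offset difference is the mean over the two directions of the
#' absolute difference between the pooled intercept and that direction's
#' intercept; the slope difference is the pooled slope minus the mean of
#' the split slopes.
#'
#' @inheritParams fit_shift_regression
#' @param event_class Label stored with the comparison.
#' @return A list of class `pooled_split_comparison` with
#'   `slope_difference`, `offset_difference` (deg), the underlying fits and
#'   the event class.
#' @export
pooled_vs_split <- function(measurements,
                            predictor = c("pre_shift_position",
                                          "preceding_slow_amplitude"),
                            phases = NULL, event_class = NULL) {
  predictor <- match.arg(predictor)
  if (is.null(event_class))
    event_class <- if (inherits(measurements, "barm_measurements")) "barm"
  else if (inherits(measurements, "fast_measurements")) "fast_phase"
  else "events"
  tab <- as_shift_table(measurements)
  if (!is.null(phases)) tab <- tab[tab$phase %in% phases, , drop = FALSE]
  dirs <- unique(tab$direction[!is.na(tab$direction)])
  if (!all(c("cw", "ccw") %in% dirs))
    stop("both flow directions must be represented", call. = FALSE)
  pooled <- fit_shift_regression(tab, predictor, direction_scope = "pooled")
  split <- fit_shift_regression(tab, predictor,
                                direction_scope = "mean_of_split")
  if (!is.null(pooled$reason) || !is.null(split$reason))
    stop("insufficient data for pooled or split fits", call. = FALSE)
  ints <- vapply(split$split_fits, `[[`, numeric(1), "intercept")
  out <- list(
    slope_difference = pooled$slope - split$slope,
    offset_difference = mean(abs(pooled$intercept - ints)),
    pooled = pooled, split = split, event_class = event_class,
    predictor = predictor)
  class(out) <- "pooled_split_comparison"
  out
}

#' @export
print.pooled_split_comparison <- function(x, ...) {
  cat(sprintf("<pooled_split_comparison> %s on %s\n", x$event_class,
              x$predictor))
  cat(sprintf("  slope difference %.3f, offset difference %.3f deg\n",
              x$slope_difference, x$offset_difference))
  invisible(x)
}

#' Bootstrap the four shift correlations
#'
#' Resamples each event pool with replacement (`sample_size` events,
#' `reps` times) and correlates (1) fast-phase shifts with their preceding
#' slow-phase amplitude and with the pre-shift eye position and (2) BARM
#' shifts with the same two predictors, giving the mean correlation and the
#' 95% percentile confidence interval per relation.
#'
#' @param barm_measurements,fast_measurements Measurement tables.
#' @param sample_size Events per resample (default 400).
#' @param reps Number of resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param phases Optional phase filter applied to both pools.
#' @return A data frame (class `bootstrap_correlations`) with one row per
#'   relation: `relation`, `mean_r`, `ci_lo`, `ci_hi`, `reps`,
#'   `sample_size`, `pool_size`.
#' @export
bootstrap_correlations <- function(barm_measurements, fast_measurements,
                                   sample_size = 400, reps = 1000,
                                   seed = 1L, phases = NULL) {
  set.seed(seed)
  pools <- list(
    fast_vs_slowamp = shift_pool(fast_measurements, "slow_amplitude", phases),
    fast_vs_position = shift_pool(fast_measurements, "position", phases),
    barm_vs_slowamp = shift_pool(barm_measurements, "slow_amplitude", phases),
    barm_vs_position = shift_pool(barm_measurements, "position", phases))
  rows <- lapply(names(pools), function(nm) {
    p <- pools[[nm]]
    if (nrow(p) == 0) stop("empty pool for relation ", nm, call. = FALSE)
    if (nrow(p) <= sample_size)
      warning(sprintf("pool %s has only %d events (<= sample_size %d)",
                      nm, nrow(p), sample_size))
    rs <- replicate(reps, {
      idx <- sample.int(nrow(p), sample_size, replace = TRUE)
      stats::cor(p$x[idx], p$shift[idx])
    })
    ci <- stats::quantile(rs, c(0.025, 0.975), names = FALSE)
    data.frame(relation = nm, mean_r = mean(rs), ci_lo = ci[1],
               ci_hi = ci[2], reps = reps, sample_size = sample_size,
               pool_size = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bootstrap_correlations", "data.frame")
  out
}

shift_pool <- function(measurements, xvar, phases = NULL) {
  tab <- as_shift_table(measurements)
  if (!is.null(phases)) tab <- tab[tab$phase %in% phases, , drop = FALSE]
  x <- if (xvar == "position") tab$position else tab$slow_amplitude
  keep <- is.finite(x) & is.finite(tab$shift)
  data.frame(x = x[keep], shift = tab$shift[keep])
}

#' 2D regression of shifts on slow-phase amplitude and position
#'
#' Least-squares fit of `shift = a * preceding slow-phase amplitude +
#' b * pre-shift eye position (+ intercept)`. BARMs are fitted with one
#' model pooled over flow directions; fast phases with two direction-split
#' models whose coefficients are averaged. 95% confidence intervals come
#' from a percentile bootstrap over events.
#'
#' @param measurements A measurement table.
#' @param event_class `"barm"` (one model) or `"fast_phase"` (two models).
#' @param reps Bootstrap replicates for the coefficient CIs.
#' @param seed Seed for the bootstrap.
#' @param phases Optional phase filter.
#' @param kappa_threshold Condition number above which the design is
#'   flagged collinear.
#' @return A list of class `regression_2d`: coefficients `a` and `b`, their
#'   CIs, `model_count`, `n`, and a `collinear` flag.
#' @export
fit_2d_regression <- function(measurements,
                              event_class = c("barm", "fast_phase"),
                              reps = 1000, seed = 1L, phases = NULL,
                              kappa_threshold = 1e4) {
  event_class <- match.arg(event_class)
  tab <- as_shift_table(measurements)
  if (!is.null(phases)) tab <- tab[tab$phase %in% phases, , drop = FALSE]
  keep <- is.finite(tab$shift) & is.finite(tab$position) &
    is.finite(tab$slow_amplitude)
  tab <- tab[keep, , drop = FALSE]

  fit_one <- function(d) {
    if (nrow(d) < 4) return(NULL)
    X <- cbind(1, d$slow_amplitude, d$position)
    kap <- kappa(X, exact = TRUE)
    fit <- stats::lm(shift ~ slow_amplitude + position, data = d)
    cf <- stats::coef(fit)
    list(a = unname(cf["slow_amplitude"]), b = unname(cf["position"]),
         kappa = kap, n = nrow(d))
  }
  coefs_of <- function(d) {
    if (event_class == "barm") {
      f <- fit_one(d)
      if (is.null(f)) return(NULL)
      f
    } else {
      fs <- lapply(c("cw", "ccw"), function(dd)
        fit_one(d[d$direction == dd, , drop = FALSE]))
      if (any(vapply(fs, is.null, logical(1)))) return(NULL)
      list(a = mean(vapply(fs, `[[`, numeric(1), "a")),
           b = mean(vapply(fs, `[[`, numeric(1), "b")),
           kappa = max(vapply(fs, `[[`, numeric(1), "kappa")),
           n = sum(vapply(fs, `[[`, numeric(1), "n")))
    }
  }

  point <- coefs_of(tab)
  if (is.null(point))
    stop("need at least 4 measurements per fitted model", call. = FALSE)
  set.seed(seed)
  boot <- replicate(reps, {
    d <- tab[sample.int(nrow(tab), nrow(tab), replace = TRUE), , drop = FALSE]
    f <- coefs_of(d)
    if (is.null(f)) c(NA_real_, NA_real_) else c(f$a, f$b)
  })
  out <- list(
    a = point$a, b = point$b,
    ci_a = stats::quantile(boot[1, ], c(0.025, 0.975), na.rm = TRUE,
                           names = FALSE),
    ci_b = stats::quantile(boot[2, ], c(0.025, 0.975), na.rm = TRUE,
                           names = FALSE),
    model_count = if (event_class == "barm") 1L else 2L,
    event_class = event_class, n = point$n,
    collinear = point$kappa > kappa_threshold)
  class(out) <- "regression_2d"
  out
}

#' @export
print.regression_2d <- function(x, ...) {
  cat(sprintf("<regression_2d> %s (%d model%s, n = %d)\n", x$event_class,
              x$model_count, if (x$model_count > 1) "s" else "", x$n))
  cat(sprintf("  a (slow amplitude) %.3f [%.3f, %.3f]\n", x$a, x$ci_a[1],
              x$ci_a[2]))
  cat(sprintf("  b (position)       %.3f [%.3f, %.3f]%s\n", x$b, x$ci_b[1],
              x$ci_b[2], if (x$collinear) "  [collinear design]" else ""))
  invisible(x)
}
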