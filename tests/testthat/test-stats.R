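# Closed-form oracles implemented independently of the fitting code.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  tt <- r * sqrt((length(x) - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), length(x) - 2)
  list(slope = slope, intercept = intercept, r = r, p = p)
}

shift_df <- function(position, shift, direction = "cw",
                     slow_amplitude = NA_real_, phase = "flow1") {
  data.frame(shift = shift, position = position,
             slow_amplitude = slow_amplitude, direction = direction,
             phase = phase, duration = NA_real_, stringsAsFactors = FALSE)
}

test_that("OLS and Pearson agree with the closed-form oracle to 1e-10", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- 0.7 * x + rnorm(n)
    f <- fit_shift_regression(shift_df(x, y), "pre_shift_position")
    o <- oracle_ols(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r, o$r, tolerance = 1e-10)
    expect_equal(f$p, o$p, tolerance = 1e-10)
  }
})

test_that("perfectly linear data recover the generating line", {
  x <- seq(-4, 4, length.out = 9)
  f <- fit_shift_regression(shift_df(x, -0.5 * x), "pre_shift_position")
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$r, -1, tolerance = 1e-12)
})

test_that("range restriction and no-fit results behave as specified", {
  x <- c(-5, -1, 0, 1, 5, 6)
  y <- -0.4 * x
  f <- fit_shift_regression(shift_df(x, y), "pre_shift_position",
                            range_limits = c(-2, 2))
  expect_identical(f$n, 3L)
  f2 <- fit_shift_regression(shift_df(x[1:2], y[1:2]), "pre_shift_position")
  expect_true(!is.null(f2$reason))
  expect_true(is.na(f2$slope))
})

test_that("mean-of-split fits average the per-direction regressions", {
  set.seed(3)
  x1 <- rnorm(30, 3); y1 <- -0.6 * x1 + rnorm(30, 0, 0.2)
  x2 <- rnorm(30, -3); y2 <- -0.4 * x2 + rnorm(30, 0, 0.2)
  tab <- rbind(shift_df(x1, y1, "cw"), shift_df(x2, y2, "ccw"))
  f <- fit_shift_regression(tab, "pre_shift_position",
                            direction_scope = "mean_of_split")
  o1 <- oracle_ols(x1, y1); o2 <- oracle_ols(x2, y2)
  expect_equal(f$slope, mean(c(o1$slope, o2$slope)), tolerance = 1e-10)
  expect_equal(f$intercept, mean(c(o1$intercept, o2$intercept)),
               tolerance = 1e-10)
})

test_that("regression is equivariant under common scaling", {
  set.seed(4)
  x <- rnorm(20, 2); y <- -0.5 * x + rnorm(20, 0.3, 0.4)
  f1 <- fit_shift_regression(shift_df(x, y), "pre_shift_position")
  f2 <- fit_shift_regression(shift_df(3 * x, 3 * y), "pre_shift_position")
  expect_equal(f1$r, f2$r, tolerance = 1e-12)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(3 * f1$intercept, f2$intercept, tolerance = 1e-10)
})

test_that("pooled-vs-split separates one-cluster from two-cluster data", {
  set.seed(5)
  # one global line: both analyses agree
  x <- rnorm(200, 0, 3)
  y <- -0.5 * x + rnorm(200, 0, 0.1)
  tab <- shift_df(x, y, ifelse(x > 0, "cw", "ccw"))
  pv <- pooled_vs_split(tab, "pre_shift_position")
  expect_lt(abs(pv$slope_difference), 0.02)
  expect_lt(pv$offset_difference, 0.05)

  # two clusters with direction-dependent offsets
  x1 <- rnorm(100, 5, 1);  y1 <- -2 + rnorm(100, 0, 0.3)
  x2 <- rnorm(100, -5, 1); y2 <- 2 + rnorm(100, 0, 0.3)
  tab2 <- rbind(shift_df(x1, y1, "cw"), shift_df(x2, y2, "ccw"))
  pv2 <- pooled_vs_split(tab2, "pre_shift_position")
  o_pool <- oracle_ols(c(x1, x2), c(y1, y2))
  o1 <- oracle_ols(x1, y1); o2 <- oracle_ols(x2, y2)
  expect_equal(pv2$slope_difference,
               o_pool$slope - mean(c(o1$slope, o2$slope)), tolerance = 1e-10)
  expect_equal(pv2$offset_difference,
               mean(abs(o_pool$intercept - c(o1$intercept, o2$intercept))),
               tolerance = 1e-10)
  expect_gt(abs(pv2$slope_difference), 5 * abs(pv$slope_difference))

  expect_error(pooled_vs_split(shift_df(x1, y1, "cw"), "pre_shift_position"),
               "both flow directions")
})

test_that("bootstrap of a degenerate linear pool gives r = 1 with zero width", {
  pool <- data.frame(
    torsional_shift = rep(c(1, 2, 3), 200) * -0.5,
    pre_t = rep(c(1, 2, 3), 200),
    preceding_slow_amplitude = rep(c(1, 2, 3), 200),
    phase = "flow1", flow_direction = "cw",
    blink_duration = 300, onset_time = 1,
    pre_h = 0, pre_v = 0, h_shift = 0, v_shift = 0)
  class(pool) <- c("barm_measurements", "data.frame")
  fast <- data.frame(
    torsional_shift = rep(c(1, 2, 3), 200) * 0.4,
    pre_shift_position = rep(c(1, 2, 3), 200),
    preceding_slow_amplitude = rep(c(1, 2, 3), 200),
    peak_velocity = 1, phase = "flow1", flow_direction = "cw",
    onset_time = 1)
  class(fast) <- c("fast_measurements", "data.frame")
  bs <- bootstrap_correlations(pool, fast, sample_size = 400, reps = 50,
                               seed = 1)
  expect_equal(bs$mean_r, c(1, 1, -1, -1), tolerance = 1e-12)
  expect_equal(bs$ci_hi - bs$ci_lo, rep(0, 4), tolerance = 1e-12)
})

test_that("bootstrap mean correlation matches the Fisher-z analytic value", {
  set.seed(6)
  n <- 2000
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.5^2) * rnorm(n)
  rho_hat <- cor(x, y)
  pool <- shift_df(x, y)
  barm <- data.frame(torsional_shift = y, pre_t = x,
                     preceding_slow_amplitude = x, phase = "flow1",
                     flow_direction = "cw", blink_duration = 300,
                     onset_time = 1, pre_h = 0, pre_v = 0,
                     h_shift = 0, v_shift = 0)
  class(barm) <- c("barm_measurements", "data.frame")
  fast <- data.frame(torsional_shift = y, pre_shift_position = x,
                     preceding_slow_amplitude = x, peak_velocity = 1,
                     phase = "flow1", flow_direction = "cw", onset_time = 1)
  class(fast) <- c("fast_measurements", "data.frame")
  bs <- bootstrap_correlations(barm, fast, sample_size = 400, reps = 400,
                               seed = 2)
  # analytic standard error of r at n = 400 via the Fisher transform
  se <- (1 - rho_hat^2) / sqrt(400 - 3)
  expect_true(all(abs(bs$mean_r - rho_hat) < 3 * se / sqrt(1)))
  expect_true(all(bs$ci_lo <= bs$mean_r & bs$mean_r <= bs$ci_hi))
  expect_identical(unique(bs$reps), 400)
})

test_that("bootstrap CI endpoints concentrate with more replicates", {
  set.seed(7)
  n <- 600
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  barm <- data.frame(torsional_shift = y, pre_t = x,
                     preceding_slow_amplitude = x, phase = "flow1",
                     flow_direction = "cw", blink_duration = 300,
                     onset_time = 1, pre_h = 0, pre_v = 0,
                     h_shift = 0, v_shift = 0)
  class(barm) <- c("barm_measurements", "data.frame")
  fast <- data.frame(torsional_shift = y, pre_shift_position = x,
                     preceding_slow_amplitude = x, peak_velocity = 1,
                     phase = "flow1", flow_direction = "cw", onset_time = 1)
  class(fast) <- c("fast_measurements", "data.frame")
  lo_at <- function(reps, seed) {
    bootstrap_correlations(barm, fast, sample_size = 400, reps = reps,
                           seed = seed)$ci_lo[1]
  }
  lo_small <- vapply(1:8, function(s) lo_at(100, s), numeric(1))
  lo_big <- vapply(1:8, function(s) lo_at(2500, s), numeric(1))
  # Monte-Carlo error of the CI endpoint should shrink about like
  # sqrt(reps ratio) = 5
  expect_gt(sd(lo_small) / sd(lo_big), 2)
})

test_that("the 2D regression matches the normal-equations oracle", {
  sa <- c(1, 2, 3, 4, 5, 6)
  pos <- c(2, 1, 4, 3, 6, 5)
  y <- c(1, 2, 2, 4, 3, 6)
  tab <- data.frame(shift = y, position = pos, slow_amplitude = sa,
                    direction = "cw", phase = "flow1", duration = NA)
  f <- fit_2d_regression(tab, "barm", reps = 50, seed = 1)
  X <- cbind(1, sa, pos)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$a, beta[2], tolerance = 1e-10)
  expect_equal(f$b, beta[3], tolerance = 1e-10)
  expect_identical(f$model_count, 1L)

  # exact dependence on the slow amplitude only
  tab2 <- data.frame(shift = 0.3 * sa, position = rep(c(1, 2), 3),
                     slow_amplitude = sa, direction = "cw",
                     phase = "flow1", duration = NA)
  f2 <- fit_2d_regression(tab2, "barm", reps = 50, seed = 1)
  expect_equal(f2$a, 0.3, tolerance = 1e-10)
  expect_equal(f2$b, 0, tolerance = 1e-10)
})

test_that("fast phases are fitted per direction with averaged coefficients", {
  set.seed(8)
  mk <- function(dirn, sgn) {
    sa <- rnorm(40, 2 * sgn); pos <- rnorm(40, 3 * sgn)
    data.frame(shift = -0.3 * sa - 0.05 * pos + rnorm(40, 0, 0.05),
               position = pos, slow_amplitude = sa, direction = dirn,
               phase = "flow1", duration = NA)
  }
  tab <- rbind(mk("cw", 1), mk("ccw", -1))
  f <- fit_2d_regression(tab, "fast_phase", reps = 50, seed = 1)
  expect_identical(f$model_count, 2L)
  expect_equal(f$a, -0.3, tolerance = 0.05)
  expect_equal(f$b, -0.05, tolerance = 0.05)
  # collinear design is flagged
  tab$position <- tab$slow_amplitude * 2
  f2 <- fit_2d_regression(tab, "fast_phase", reps = 10, seed = 1,
                          kappa_threshold = 1e2)
  expect_true(f2$collinear)
})
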