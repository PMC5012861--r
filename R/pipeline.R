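# End-to-end orchestration: simulate -> detect -> measure -> statistics,
# with file outputs and a reproducibility manifest.

#' Analyze one block: reference, detect, segment, measure
#'
#' Convenience wrapper running the full measurement chain on a video block:
#' torsion referencing, blink detection, nystagmus segmentation, and BARM /
#' fast-phase shift measurement.
#'
#' @param block A video-modality `eye_trace_block`.
#' @param fast_threshold,min_duration,sg_window Passed to
#'   [segment_nystagmus()].
#' @param eye Eye whose channels are read.
#' @return A list: the referenced `block`, `blinks`, `phases`, `barms`,
#'   `fasts`.
#' @export
analyze_block <- function(block, fast_threshold = 7, min_duration = 0.04,
                          sg_window = 0.1, eye = c("right", "left")) {
  eye <- match.arg(eye)
  ref <- reference_torsion(block)
  blinks <- detect_blinks(ref, eye = eye)
  phases <- segment_nystagmus(ref, blinks, fast_threshold = fast_threshold,
                              min_duration = min_duration,
                              sg_window = sg_window, eye = eye)
  barms <- measure_barms(ref, blinks, phases)
  fasts <- measure_fast_phase_shifts(phases, block_flow_direction(ref))
  list(block = ref, blinks = blinks, phases = phases, barms = barms,
       fasts = fasts)
}

#' Pool per-block measurement tables
#'
#' @param results A list of [analyze_block()] results.
#' @param what `"barms"`, `"fasts"`, or `"phases"`.
#' @return The row-bound table with a `block` id column.
#' @export
pool_measurements <- function(results, what = c("barms", "fasts", "phases")) {
  what <- match.arg(what)
  tabs <- lapply(seq_along(results), function(i) {
    tab <- results[[i]][[what]]
    if (nrow(tab) == 0) return(NULL)
    tab$block <- i
    tab
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (length(tabs) == 0) stop("no measurements to pool", call. = FALSE)
  out <- do.call(rbind, tabs)
  cls <- class(results[[1]][[what]])
  class(out) <- cls
  out
}

# Table-1-shaped summary: one regression row per phase/range combination.
table1_summary <- function(barms) {
  combos <- list(
    list(label = "fixation in darkness phase I", phases = "dark1",
         range = NULL),
    list(label = "optic flow phase I and II", phases = c("flow1", "flow2"),
         range = NULL),
    list(label = "fixation in darkness phase II", phases = "dark2",
         range = NULL),
    list(label = "fixation in darkness phase I (-2 to 2)", phases = "dark1",
         range = c(-2, 2)),
    list(label = "optic flow phase I and II (-2 to 2)",
         phases = c("flow1", "flow2"), range = c(-2, 2)),
    list(label = "fixation in darkness phase II (-2 to 2)", phases = "dark2",
         range = c(-2, 2)))
  rows <- lapply(combos, function(cb) {
    f <- fit_shift_regression(barms, "pre_shift_position",
                              range_limits = cb$range, phases = cb$phases)
    data.frame(phase = cb$label, slope = f$slope, intercept = f$intercept,
               correlation = f$r, p = f$p, n = f$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on a simulated experiment
#'
#' Simulates `n_blocks` balanced blocks, runs detection, segmentation and
#' measurement on each, renders and decomposes the coil modality, computes
#' the statistical reports (Table-1-shaped phase-wise regressions, the
#' pooled-vs-split diagnostics, the bootstrap correlations, the 2D
#' regressions, and -- when the configuration includes stimulus blanks --
#' the blank-control report), optionally writes everything under `out_dir`,
#' and returns the results with a reproducibility manifest.
#'
#' @param config A [sim_config()].
#' @param n_blocks Even number of blocks (half CW, half CCW).
#' @param seed Master seed.
#' @param out_dir Optional output directory; created if missing.
#' @param coil Render and decompose the coil modality (default TRUE).
#' @param bootstrap_reps,bootstrap_size Bootstrap settings.
#' @return A list of class `barm_pipeline_result`: pooled measurement
#'   tables, the statistical reports, and `manifest`.
#' @export
run_pipeline <- function(config, n_blocks = 16, seed = 1L, out_dir = NULL,
                         coil = TRUE, bootstrap_reps = 1000,
                         bootstrap_size = 400) {
  if (n_blocks < 1) stop("need at least one block", call. = FALSE)
  config <- validate_sim_config(config)
  t_start <- Sys.time()
  sims <- simulate_experiment(config, n_blocks = n_blocks, seed = seed)
  results <- lapply(sims, function(s) analyze_block(s$block))

  barms <- pool_measurements(results, "barms")
  fasts <- pool_measurements(results, "fasts")

  reports <- list(
    table1 = table1_summary(barms),
    barm_pooled_vs_split = pooled_vs_split(barms, "pre_shift_position",
                                           phases = c("flow1", "flow2")),
    fast_pooled_vs_split = pooled_vs_split(fasts, "pre_shift_position",
                                           phases = c("flow1", "flow2")),
    fast_pooled_vs_split_slowamp = pooled_vs_split(
      fasts, "preceding_slow_amplitude", phases = c("flow1", "flow2")),
    bootstrap = bootstrap_correlations(barms, fasts,
                                       sample_size = bootstrap_size,
                                       reps = bootstrap_reps,
                                       seed = seed + 1L),
    regression_2d = list(
      barm = fit_2d_regression(barms, "barm", reps = min(bootstrap_reps, 500),
                               seed = seed + 2L),
      fast_phase = fit_2d_regression(fasts, "fast_phase",
                                     reps = min(bootstrap_reps, 500),
                                     seed = seed + 3L)))

  if (config$include_blanks) {
    blank_tabs <- lapply(seq_along(sims), function(i) {
      m <- measure_blank_shifts(results[[i]]$block, sims[[i]]$truth$blanks,
                                blinks = results[[i]]$blinks)
      if (nrow(m) > 0) m$block <- i
      m
    })
    blanks <- do.call(rbind, blank_tabs)
    class(blanks) <- c("blank_measurements", "data.frame")
    reports$blank_regression <- fit_shift_regression(
      blanks, "pre_shift_position", direction_scope = "mean_of_split")
    dur_ct <- stats::cor.test(blanks$duration, abs(blanks$torsional_shift))
    reports$blank_duration_correlation <- list(r = unname(dur_ct$estimate),
                                               p = dur_ct$p.value)
  } else blanks <- NULL

  coil_components <- NULL
  if (coil) {
    comp_tabs <- lapply(seq_along(sims), function(i) {
      cb <- render_coil(sims[[i]]$block, sims[[i]]$truth,
                        sims[[i]]$truth$config)
      cc <- decompose_coil_blinks(cb, results[[i]]$blinks[
        results[[i]]$blinks$usable, , drop = FALSE])
      if (nrow(cc) > 0) cc$block <- i
      cc
    })
    coil_components <- do.call(rbind, comp_tabs)
    class(coil_components) <- c("coil_components", "data.frame")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("barmkit")),
    r_version = R.version.string,
    seed = seed, n_blocks = n_blocks,
    config = config[setdiff(names(config), character(0))],
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    thresholds = list(fast_threshold = 7, min_duration = 0.04,
                      sg_window = 0.1, safety_pre = safety_pre,
                      safety_post = safety_post))

  out <- list(measurements = list(barms = barms, fasts = fasts,
                                  blanks = blanks,
                                  coil_components = coil_components),
              reports = reports, manifest = manifest)
  class(out) <- "barm_pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(barms, file.path(out_dir, "barm_measurements.csv"))
    data.table::fwrite(fasts, file.path(out_dir, "fast_measurements.csv"))
    if (!is.null(blanks))
      data.table::fwrite(blanks, file.path(out_dir, "blank_measurements.csv"))
    if (!is.null(coil_components))
      data.table::fwrite(coil_components,
                         file.path(out_dir, "coil_components.csv"))
    data.table::fwrite(reports$table1, file.path(out_dir, "table1.csv"))
    jsonlite::write_json(serialize_reports(reports),
                         file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$file_hashes <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

serialize_reports <- function(reports) {
  strip <- function(x) {
    if (inherits(x, "shift_regression") ||
        inherits(x, "pooled_split_comparison") ||
        inherits(x, "regression_2d") ||
        inherits(x, "main_sequence_fit") ||
        inherits(x, "main_sequence_comparison"))
      return(lapply(unclass(x), strip))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(reports)
}

#' @export
print.barm_pipeline_result <- function(x, ...) {
  cat("<barm_pipeline_result>\n")
  cat(sprintf("  %d BARMs, %d fast phases pooled over %d blocks\n",
              nrow(x$measurements$barms), nrow(x$measurements$fasts),
              x$manifest$n_blocks))
  cat("  Table-1-shaped summary:\n")
  print(x$reports$table1, digits = 3)
  invisible(x)
}
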