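#!/usr/bin/env Rscript
# Re-read the simulated traces, reference torsion to the first
# fixation-in-darkness phase, detect blinks (bilateral dropouts with
# 140/200 ms safety reads), segment the torsional nystagmus, and measure
# BARM and fast-phase shifts.
#
# Input:  results/traces/block_XX.csv
# Output: results/measurements/{barms,fasts,blinks}.csv

library(barmkit)

trace_dir <- "results/traces"
out_dir <- "results/measurements"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

paths <- sort(list.files(trace_dir, pattern = "^block_[0-9]+\\.csv$",
                         full.names = TRUE))
stopifnot(length(paths) > 0)

all_barms <- list(); all_fasts <- list(); all_blinks <- list()
for (i in seq_along(paths)) {
  block <- read_trace(paths[i])
  res <- analyze_block(block)
  res$barms$block <- i; res$fasts$block <- i
  bl <- res$blinks; bl$block <- i
  all_barms[[i]] <- res$barms
  all_fasts[[i]] <- res$fasts
  all_blinks[[i]] <- bl
  cat(sprintf("block %02d: %d blinks (%d usable), %d fast phases, %d BARMs\n",
              i, nrow(bl), sum(bl$usable),
              sum(res$phases$kind == "fast"), nrow(res$barms)))
}

barms <- do.call(rbind, all_barms)
fasts <- do.call(rbind, all_fasts)
blinks <- do.call(rbind, all_blinks)
data.table::fwrite(barms, file.path(out_dir, "barms.csv"))
data.table::fwrite(fasts, file.path(out_dir, "fasts.csv"))
data.table::fwrite(blinks, file.path(out_dir, "blinks.csv"))

fl <- barms$phase %in% c("flow1", "flow2")
cat(sprintf("\npooled: %d BARMs (%d in flow, mean |shift| %.2f deg), %d fast phases\n",
            nrow(barms), sum(fl), mean(abs(barms$torsional_shift[fl])),
            nrow(fasts)))
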