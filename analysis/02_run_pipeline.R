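#!/usr/bin/env Rscript
# Run the full calling pipeline on the simulated samples written by
# 01_simulate.R: filter, input-normalized coverage, sliding-window
# enrichment against the randomized-tag null, replicate intersection,
# differential density between adjacent conditions, segmentation of the
# locus, and smoothed profiles.
#
# Reads:  results/sim/
# Writes: results/run/ (all intermediates + run_log.tsv)

library(stairstep)

sim <- "results/sim"
meta <- yaml::read_yaml(file.path(sim, "scenario.yaml"))
conditions <- unlist(meta$conditions)
reps <- paste0("rep", seq_len(meta$replicates))

chip_paths <- lapply(conditions, function(cond) {
  stats::setNames(as.list(file.path(sim, paste0(cond, "_", reps, ".bed"))),
                  reps)
})
names(chip_paths) <- conditions

config <- run_config(
  layout_path = file.path(sim, "chrom.sizes"),
  chip_paths = chip_paths,
  input_path = file.path(sim, "input.bed"),
  out_dir = "results/run",
  locus = meta$locus,
  seed = 7
)
res <- run_pipeline(config)

message("called boundaries:")
print(res$segmentation$boundary_table)
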