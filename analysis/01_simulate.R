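#!/usr/bin/env Rscript
# Generate the synthetic stairstep dataset the downstream analyses run on:
# four ordered conditions (PS4-PS7) over a 380 kb locus in a 2 Mb
# chromosome, two ChIP replicates each plus one shared input, at quarter
# scale so the whole analysis set runs in a couple of minutes.
#
# Writes: results/sim/ (BED3 per sample, chrom.sizes, scenario.yaml)

library(stairstep)

scale <- 0.25
seed <- 20140731

spec <- bxc_stairstep_scenario(scale = scale, seed = seed)
dat <- generate_tags(spec)
write_scenario(dat, "results/sim")

counts <- vapply(spec$conditions, function(cond) {
  vapply(dat$chip[[cond]], n_tags, numeric(1))
}, numeric(spec$replicates))
message("fragments per sample:")
print(counts)
message("input fragments: ", n_tags(dat$input))
message(sprintf("locus: %s:%d-%d; planted clear extents: %s bp",
                spec$locus$chrom, spec$locus$start, spec$locus$end,
                paste(vapply(spec$clear, function(cl) {
                  if (nrow(cl)) sum(cl$end - cl$start) else 0
                }, numeric(1)), collapse = ", ")))
message("wrote results/sim/")
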