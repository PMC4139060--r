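# Small in-code fixtures shared across test files.

tiny_layout <- function(L = 1000, chrom = "chrT") genome_layout(chrom, L)

tags_from <- function(..., layout) {
  df <- data.frame(...)
  tag_set(df, layout)
}

# a coverage_track built directly from per-chromosome vectors, for unit
# tests that need exact positional counts
track_from_vectors <- function(vectors, layout) {
  structure(list(cov = vectors,
                 total = sum(vapply(vectors, sum, numeric(1))),
                 layout = layout),
            class = "coverage_track")
}

# run one replicate through enrichment calling; returns merged regions
call_regions <- function(ts, input_cov, layout, w = 1000, s = 50,
                         rounds = 3, alpha = 1e-3, seed = 1,
                         condition = NA_character_,
                         replicate = NA_character_) {
  cov <- positional_coverage(ts, layout)
  trk <- normalize_coverage(cov, input_cov)
  stats <- window_sums(trk, w = w, s = s)
  null <- build_null(ts, input_cov, layout, w = w, s = s, rounds = rounds,
                     seed = seed)
  sig <- call_windows(stats, null, alpha = alpha)
  merge_windows(sig, w = w, condition = condition, replicate = replicate)
}

# enrichment-call one scenario end to end; returns per-condition
# replicate-intersected regions
scenario_regions <- function(dat, rounds = 3, alpha = 1e-3, w = 1000,
                             s = 50) {
  layout <- dat$spec$layout
  input_cov <- positional_coverage(dat$input, layout)
  regions <- list()
  i <- 0
  for (cond in dat$spec$conditions) {
    reps <- lapply(dat$chip[[cond]], function(ts) {
      i <<- i + 1
      call_regions(ts, input_cov, layout, w = w, s = s, rounds = rounds,
                   alpha = alpha, seed = 1000 + i, condition = cond)
    })
    regions[[cond]] <- Reduce(intersect_replicates, reps)
  }
  regions
}
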