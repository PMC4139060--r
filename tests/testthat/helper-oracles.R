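# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (IRanges coverage, cumulative-sum window sums,
# GRanges interval algebra) so each test compares two routes.

# per-position recount: add 1 to every position of every tag, one tag at a
# time
oracle_coverage <- function(tags, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(tags))) {
    idx <- (tags$start[i] + 1L):tags$end[i]
    v[idx] <- v[idx] + 1
  }
  v
}

# literal re-evaluation of the normalization formula at given positions
# (0-based)
oracle_norm <- function(n_vec, ni_vec, N, Ni, positions) {
  vapply(positions, function(x) {
    ((n_vec[x + 1L] + 1) / (ni_vec[x + 1L] + 1)) * (Ni / N)
  }, numeric(1))
}

# per-window re-summation with sum()
oracle_window_sums <- function(v, w, s) {
  L <- length(v)
  if (L < w) return(data.frame(start = numeric(0), sum = numeric(0)))
  starts <- seq(0, floor((L - w) / s) * s, by = s)
  data.frame(start = starts,
             sum = vapply(starts, function(a) sum(v[(a + 1L):(a + w)]),
                          numeric(1)))
}

# sweep-line union of intervals on one chromosome
oracle_union <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out_start <- df$start[1L]
  out_end <- df$end[1L]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= out_end) {
      out_end <- max(out_end, df$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- df$start[i]; out_end <- df$end[i]
    }
  }
  data.frame(start = c(starts, out_start), end = c(ends, out_end))
}

# pairwise interval intersection on one chromosome
oracle_intersect <- function(a, b) {
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (e > s) { starts <- c(starts, s); ends <- c(ends, e) }
    }
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

random_regions <- function(n, L, max_len = 2000) {
  start <- sort(sample.int(L - max_len, n)) - 1L
  len <- sample.int(max_len - 1L, n, replace = TRUE)
  data.frame(chrom = "chrT", start = start, end = start + len)
}

random_tags <- function(n, L, max_len = 400, layout = NULL, ...) {
  start <- sample.int(L - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len - 1L, n, replace = TRUE)
  df <- data.frame(chrom = "chrT", start = start, end = start + len)
  if (is.null(layout)) layout <- genome_layout("chrT", L)
  tag_set(df, layout, ...)
}
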