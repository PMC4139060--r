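# Sliding-window enrichment against a randomized-tag empirical null.
#
# Observed statistic: the sum of input-normalized coverage within windows of
# size w laid every s bp. Null: the same statistic after every ChIP tag is
# redrawn at a uniform position on its own chromosome (length preserved) and
# re-normalized against the true input track; all rounds' window sums are
# pooled into one genome-wide reference distribution.

#' @noRd
.window_starts <- function(L, w, s) {
  if (L < w) return(numeric(0))
  seq(0, floor((L - w) / s) * s, by = s)
}

#' Summed normalized coverage in sliding windows
#'
#' Windows start at 0, s, 2s, ... on each chromosome, with start + w never
#' exceeding the chromosome length; chromosomes shorter than the window get
#' no windows. Each window's statistic is the sum of normalized coverage
#' over its w positions.
#'
#' @param track A `normalized_track` (see [normalize_coverage()]).
#' @param w Window size in bp (default 1000).
#' @param s Step in bp (default 50). Requires `w >= s > 0`.
#' @return data.frame with columns `chrom`, `start` (0-based window start)
#'   and `sum`.
#' @export
window_sums <- function(track, w = 1000, s = 50) {
  stopifnot(inherits(track, "normalized_track"), w >= s, s > 0)
  rows <- lapply(names(track$norm), function(chrom) {
    v <- track$norm[[chrom]]
    starts <- .window_starts(length(v), w, s)
    if (length(starts) == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        sum = numeric(), stringsAsFactors = FALSE))
    }
    cs <- c(0, cumsum(v))
    data.frame(chrom = chrom, start = starts,
               sum = cs[starts + w + 1L] - cs[starts + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical null distribution of window sums from randomized tags
#'
#' Repeats `rounds` times: every ChIP tag's start is redrawn uniformly on its
#' own chromosome (fragment length preserved, start drawn on
#' `[0, L - length]` so the fragment stays inside), normalized coverage is
#' recomputed against the true input track, and window sums are collected.
#' All rounds are pooled and sorted into one genome-wide reference
#' distribution.
#'
#' @param x The ChIP [tag_set()] whose tags are randomized.
#' @param input The input `coverage_track` (kept fixed: the observed
#'   statistic is input-normalized, so the null must pass through the same
#'   normalization).
#' @param layout A [genome_layout()].
#' @inheritParams window_sums
#' @param rounds Number of randomization rounds (default 5).
#' @param seed Integer seed; the same seed reproduces the distribution
#'   exactly.
#' @param per_chromosome Passed to [normalize_coverage()].
#' @return A `null_distribution`: list with `sums` (sorted ascending),
#'   `rounds`, `seed`, `w`, `s`.
#' @export
build_null <- function(x, input, layout, w = 1000, s = 50, rounds = 5,
                       seed = 1, per_chromosome = FALSE) {
  stopifnot(inherits(x, "tag_set"), rounds >= 1)
  tags <- x$tags
  len <- tags$end - tags$start
  chrom_len <- .chrom_length(layout, tags$chrom)
  if (any(len > chrom_len)) {
    stop("tag longer than its chromosome cannot be randomized", call. = FALSE)
  }
  sums <- lapply(seq_len(rounds), function(r) {
    .with_seed(.fan_seed(seed, r), {
      new_start <- floor(runif(nrow(tags)) * (chrom_len - len + 1))
      rnd <- x
      rnd$tags <- data.frame(chrom = tags$chrom, start = new_start,
                             end = new_start + len,
                             stringsAsFactors = FALSE)
      cov <- positional_coverage(rnd, layout)
      trk <- normalize_coverage(cov, input, per_chromosome = per_chromosome)
      window_sums(trk, w = w, s = s)$sum
    })
  })
  sums <- sort(unlist(sums, use.names = FALSE))
  if (length(sums) == 0L) stop("empty null distribution", call. = FALSE)
  structure(list(sums = sums, rounds = rounds, seed = seed, w = w, s = s),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution: %d window sums from %d round(s), seed %d\n",
    length(x$sums), x$rounds, x$seed))
  invisible(x)
}

#' Write a null distribution as TSV (for audit)
#' @param x A `null_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null <- function(x, path) {
  data.table::fwrite(data.table::data.table(window_sum = x$sums), path,
                     sep = "\t")
  invisible(path)
}

#' Empirical p-values and significance call for windows
#'
#' Each window's p-value is the add-one empirical estimator
#' `p = (1 + #\{null sums >= observed\}) / (1 + #null sums)`, never exactly
#' zero. Windows with `p <= alpha` are returned.
#'
#' @param stats Window table from [window_sums()].
#' @param null A `null_distribution` from [build_null()].
#' @param alpha Significance cutoff in (0, 1]. The cutoff is an explicit,
#'   per-experiment choice (default 1e-3).
#' @return The significant subset of `stats` with a `p` column added.
#' @export
call_windows <- function(stats, null, alpha = 1e-3) {
  stopifnot(inherits(null, "null_distribution"), alpha > 0, alpha <= 1)
  if (length(null$sums) == 0L) stop("empty null", call. = FALSE)
  m <- length(null$sums)
  # findInterval(x, v, left.open = TRUE) = #{v < x} for sorted v
  n_ge <- m - findInterval(stats$sum, null$sums, left.open = TRUE)
  stats$p <- (1 + n_ge) / (1 + m)
  stats[stats$p <= alpha, , drop = FALSE]
}

#' Merge significant windows into enriched regions
#'
#' Overlapping windows, and windows separated by at most `max_gap` bp, merge
#' into maximal regions; each region records the minimum window p-value it
#' contains.
#'
#' @param sig Significant windows from [call_windows()] (must carry `p`).
#' @param w Window size the windows were computed with.
#' @param max_gap Maximum bp gap bridged when merging (default 0:
#'   only touching/overlapping windows merge).
#' @param condition,replicate Labels stamped on the regions.
#' @return data.frame of disjoint sorted regions: `chrom`, `start`, `end`,
#'   `min_p`, `condition`, `replicate`.
#' @export
merge_windows <- function(sig, w, max_gap = 0,
                          condition = NA_character_,
                          replicate = NA_character_) {
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), min_p = numeric(),
                      condition = character(), replicate = character(),
                      stringsAsFactors = FALSE))
  }
  win <- data.frame(chrom = sig$chrom, start = sig$start,
                    end = sig$start + w, stringsAsFactors = FALSE)
  gr <- .regions_gr(win)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  min_p <- tapply(sig$p[S4Vectors::queryHits(hit)],
                  S4Vectors::subjectHits(hit), min)
  out <- .gr_regions(GenomicRanges::sort(merged))
  # tapply keys are subject indices of the *unsorted* merged object
  ord <- order(as.character(GenomicRanges::seqnames(merged)),
               GenomicRanges::start(merged))
  out$min_p <- as.numeric(min_p[as.character(ord)])
  out$condition <- condition
  out$replicate <- replicate
  out
}

#' Intersect region calls from two replicates
#'
#' Implements the strict replicate rule: only genomic extent significant in
#' both replicates survives, as the base-level interval intersection of the
#' two region sets. A region present in only one replicate contributes
#' nothing.
#'
#' @param a,b Region data.frames (chrom/start/end, sorted disjoint).
#' @return data.frame of intersected regions (chrom/start/end), sorted;
#'   `condition` is carried over from `a` when present.
#' @export
intersect_replicates <- function(a, b) {
  .check_regions(a, "a"); .check_regions(b, "b")
  out <- .gr_regions(GenomicRanges::intersect(.regions_gr(a), .regions_gr(b)))
  if ("condition" %in% names(a) && nrow(out)) {
    out$condition <- a$condition[1L]
  }
  out
}

#' Write regions as BED5
#'
#' Score is `-10 log10(min_p)` capped at 1000; name is
#' `condition/replicate`.
#'
#' @param regions Region data.frame (from [merge_windows()] or similar).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  name <- if (all(c("condition", "replicate") %in% names(regions))) {
    paste(regions$condition, regions$replicate, sep = "/")
  } else {
    rep(".", nrow(regions))
  }
  score <- if ("min_p" %in% names(regions)) {
    pmin(1000, round(-10 * log10(regions$min_p), 1))
  } else {
    rep(0, nrow(regions))
  }
  out <- data.table::data.table(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = name, score = score)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
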