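# Internal helpers shared across modules.
#
# Genomic intervals travel between modules as plain data.frames with
# chrom/start/end columns in 0-based half-open coordinates; they are lifted
# to GRanges (1-based closed) only inside these helpers.

#' @noRd
.regions_gr <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' @noRd
.gr_regions <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @noRd
.sort_regions <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' @noRd
.check_regions <- function(df, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(what, " must have chrom/start/end columns", call. = FALSE)
  }
  if (nrow(df) && any(df$end <= df$start)) {
    stop(what, ": end must exceed start", call. = FALSE)
  }
  invisible(df)
}

# Deterministic fan-out of one root seed into per-stage / per-round seeds.
# Kept below 2^31 so the result is always a valid R integer seed.
#' @noRd
.fan_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Write one or more per-chromosome numeric tracks as bedGraph, collapsing
# runs of equal (6-decimal) values into single records.
#' @noRd
.write_bedgraph <- function(values, path) {
  stopifnot(is.list(values), !is.null(names(values)))
  rows <- lapply(names(values), function(chrom) {
    v <- sprintf("%.6f", values[[chrom]])
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.table::data.table(chrom = chrom, start = starts, end = ends,
                           value = r$values)
  })
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
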