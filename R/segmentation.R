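# Covered/clear segmentation of a locus across ordered conditions, and
# boundary calling where the state changes -- the "stairstep".
#
# Resolution is deliberately limited to the window grid (step s): the
# enrichment statistics that feed the segmentation are computed on that
# grid, so boundaries are reported as grid coordinates, not base-pair
# change-points.

#' Covered/clear state matrix over a locus
#'
#' Lays the window grid (size `w`, step `s`) across the locus and marks each
#' window, for each condition, "covered" if the window lies entirely within
#' one of that condition's enriched regions, else "clear".
#'
#' @param locus List or one-row data.frame with `chrom`, `start`, `end`.
#' @param region_sets Named list (ordered, anterior to posterior) of region
#'   data.frames, one per condition.
#' @param w,s Window size and step in bp (defaults 1000 and 50, the grid the
#'   enrichment calls were made on).
#' @return Logical matrix (windows x conditions), `TRUE` = covered, with
#'   attributes `starts` (0-based window starts), `locus`, `w`, `s`.
#' @export
state_matrix <- function(locus, region_sets, w = 1000, s = 50) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  locus <- as.list(locus)
  starts <- locus$start + .window_starts(locus$end - locus$start, w, s)
  win_gr <- .regions_gr(data.frame(chrom = locus$chrom, start = starts,
                                   end = starts + w))
  mat <- vapply(region_sets, function(r) {
    .check_regions(r)
    if (nrow(r) == 0L) return(rep(FALSE, length(starts)))
    hit <- GenomicRanges::findOverlaps(win_gr, .regions_gr(r),
                                       type = "within")
    covered <- rep(FALSE, length(starts))
    covered[unique(S4Vectors::queryHits(hit))] <- TRUE
    covered
  }, logical(length(starts)))
  mat <- matrix(mat, nrow = length(starts),
                dimnames = list(NULL, names(region_sets)))
  attr(mat, "starts") <- starts
  attr(mat, "locus") <- locus
  attr(mat, "w") <- w
  attr(mat, "s") <- s
  mat
}

# Absorb runs shorter than min_run into the flanking state. States are
# binary, so a short interior run always flips to its neighbours' shared
# state; a short edge run flips to its single neighbour. Leftmost short run
# first; repeat until stable (a whole-locus single run is kept regardless).
#' @noRd
.absorb_short_runs <- function(state, min_run) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    i <- short[1L]
    # majority of neighbours; with binary alternating states both
    # neighbours agree, so this is a flip; leftward tie-break at edges
    r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
    state <- inverse.rle(r)
  }
  state
}

#' Call domain boundaries from a state matrix
#'
#' Within each condition, runs of identical state shorter than `min_run`
#' windows are absorbed into the flanking state (they are read as noise --
#' e.g. narrow nucleosome-free gaps inside an otherwise covered domain);
#' boundaries are then the grid coordinates between the surviving runs.
#' Boundaries from different conditions that fall within one step of each
#' other are reported as a single boundary at the position from the most
#' posterior (last-ordered) condition involved.
#'
#' @param mat State matrix from [state_matrix()].
#' @param min_run Minimum run length in windows (default 5, about 1.2 kb of
#'   consistent state on the default grid).
#' @return A `domain_segmentation`: list with `locus`, `conditions`, `clear`
#'   (named list of per-condition clear-interval data.frames), `boundaries`
#'   (per-condition boundary table: condition, position, direction), and
#'   `boundary_table` (cross-condition merged report: position, conditions,
#'   directions).
#' @export
call_boundaries <- function(mat, min_run = 5) {
  stopifnot(min_run >= 1)
  starts <- attr(mat, "starts")
  locus <- attr(mat, "locus")
  s <- attr(mat, "s")
  conditions <- colnames(mat)
  n_win <- nrow(mat)
  clear <- list()
  rows <- list()
  for (cond in conditions) {
    state <- .absorb_short_runs(mat[, cond], min_run)
    r <- rle(as.logical(state))
    k <- length(r$lengths)
    run_end_idx <- cumsum(r$lengths)       # last window index of each run
    run_start_idx <- run_end_idx - r$lengths + 1L
    # clear intervals on the step grid; the last run extends to the locus end
    is_clear <- !r$values
    if (any(is_clear)) {
      cl_start <- starts[run_start_idx[is_clear]]
      cl_end_idx <- run_end_idx[is_clear]
      cl_end <- ifelse(cl_end_idx == n_win, locus$end,
                       starts[pmin(cl_end_idx + 1L, n_win)])
      clear[[cond]] <- data.frame(chrom = locus$chrom, start = cl_start,
                                  end = cl_end, stringsAsFactors = FALSE)
    } else {
      clear[[cond]] <- data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), stringsAsFactors = FALSE)
    }
    if (k > 1L) {
      pos <- starts[run_end_idx[-k] + 1L]   # grid coordinate between runs
      dir <- ifelse(r$values[-k], "covered_to_clear", "clear_to_covered")
      rows[[cond]] <- data.frame(condition = cond, position = pos,
                                 direction = dir, stringsAsFactors = FALSE)
    }
  }
  boundaries <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(condition = character(), position = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  }
  rownames(boundaries) <- NULL
  structure(
    list(locus = locus, conditions = conditions, clear = clear,
         boundaries = boundaries,
         boundary_table = .merge_boundaries(boundaries, conditions, s)),
    class = "domain_segmentation"
  )
}

# Cluster per-condition boundaries that agree to within one grid step and
# report each cluster once, at the position from the most posterior
# condition in it.
#' @noRd
.merge_boundaries <- function(boundaries, conditions, s) {
  if (nrow(boundaries) == 0L) {
    return(data.frame(position = numeric(), conditions = character(),
                      directions = character(), stringsAsFactors = FALSE))
  }
  b <- boundaries[order(boundaries$position), , drop = FALSE]
  cluster <- cumsum(c(1, diff(b$position) > s))
  out <- lapply(split(seq_len(nrow(b)), cluster), function(i) {
    rank <- match(b$condition[i], conditions)
    post <- i[which.max(rank)]
    data.frame(
      position = b$position[post],
      conditions = paste(b$condition[i][order(rank)], collapse = ","),
      directions = paste(unique(b$direction[i]), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.domain_segmentation <- function(x, ...) {
  cat(sprintf("domain_segmentation: %s:%d-%d, %d condition(s), %d boundary coordinate(s)\n",
              x$locus$chrom, x$locus$start, x$locus$end,
              length(x$conditions), nrow(x$boundary_table)))
  invisible(x)
}

#' Check that clear domains nest along the condition order
#'
#' In a stairstep locus, each successively posterior condition's clear set
#' should contain its anterior neighbour's: clear(c) is a subset of
#' clear(c+1). This check is advisory -- it reports violating intervals
#' (e.g. a local re-methylation mound inside an otherwise clear domain)
#' without failing the pipeline.
#'
#' @param seg A `domain_segmentation`.
#' @return data.frame of violations: `anterior`, `posterior`, `chrom`,
#'   `start`, `end` (intervals clear in the anterior condition but not in
#'   the posterior one). Zero rows when nesting holds.
#' @export
check_nesting <- function(seg) {
  stopifnot(inherits(seg, "domain_segmentation"))
  conds <- seg$conditions
  out <- list()
  for (i in seq_len(length(conds) - 1L)) {
    a <- seg$clear[[conds[i]]]
    b <- seg$clear[[conds[i + 1L]]]
    bad <- .gr_regions(GenomicRanges::setdiff(.regions_gr(a), .regions_gr(b)))
    if (nrow(bad)) {
      bad$anterior <- conds[i]
      bad$posterior <- conds[i + 1L]
      out[[length(out) + 1L]] <- bad[, c("anterior", "posterior", "chrom",
                                         "start", "end")]
    }
  }
  if (length(out) == 0L) {
    return(data.frame(anterior = character(), posterior = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write segmentation outputs
#'
#' Writes each condition's clear intervals as BED (one file per condition,
#' `<prefix>_<condition>_clear.bed`) and the merged boundary table as TSV
#' (`<prefix>_boundaries.tsv`).
#'
#' @param seg A `domain_segmentation`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_segmentation <- function(seg, prefix) {
  files <- character(0)
  for (cond in seg$conditions) {
    f <- paste0(prefix, "_", cond, "_clear.bed")
    cl <- seg$clear[[cond]]
    data.table::fwrite(
      data.table::data.table(
        chrom = cl$chrom,
        start = format(cl$start, scientific = FALSE, trim = TRUE),
        end = format(cl$end, scientific = FALSE, trim = TRUE)),
      f, sep = "\t", col.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- paste0(prefix, "_boundaries.tsv")
  data.table::fwrite(seg$boundary_table, f, sep = "\t")
  invisible(c(files, f))
}
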