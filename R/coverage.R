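# Positional coverage and input normalization.
#
# n(x) is the number of fragments overlapping base x. The track's total N is
# the genome-wide sum of n(x), which equals the sum of fragment lengths
# ("total genome coverage"); note this differs from the fragment count by a
# factor of the mean fragment length.

#' Per-position fragment coverage
#'
#' Computes n(x), the number of fragments whose interval contains position x,
#' for every position of every chromosome in the layout, plus the total
#' coverage N = sum over all positions of n(x) (equivalently, the summed
#' fragment lengths).
#'
#' @param x A [tag_set()].
#' @param layout A [genome_layout()].
#' @return A `coverage_track`: list with `cov` (named list of per-chromosome
#'   numeric vectors), `total` (N), and `layout`.
#' @export
positional_coverage <- function(x, layout) {
  stopifnot(inherits(x, "tag_set"), inherits(layout, "genome_layout"))
  tags <- x$tags
  cov <- lapply(seq_len(nrow(layout)), function(i) {
    chrom <- layout$chrom[i]
    L <- layout$length[i]
    sel <- tags$chrom == chrom
    if (!any(sel)) return(numeric(L))
    ir <- IRanges::IRanges(start = tags$start[sel] + 1L, end = tags$end[sel])
    as.numeric(IRanges::coverage(ir, width = L))
  })
  names(cov) <- layout$chrom
  structure(
    list(cov = cov, total = sum(vapply(cov, sum, numeric(1))),
         layout = layout),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), total coverage N = %.0f\n",
              length(x$cov), x$total))
  invisible(x)
}

#' Input-normalize a ChIP coverage track
#'
#' For each position, the normalized coverage is
#' \deqn{n_{norm}(x) = \frac{n(x) + 1}{n_i(x) + 1} \cdot \frac{N_i}{N}}
#' where n and n_i are the ChIP and input positional coverages and N and N_i
#' their genome totals. The +1 pseudocounts keep the ratio defined (and
#' strictly positive) at uncovered positions; the N_i/N factor removes the
#' overall sequencing-depth difference, so a ChIP track distributed like its
#' input normalizes to ~1 everywhere.
#'
#' @param chip,input `coverage_track`s on the same layout with positive
#'   totals.
#' @param per_chromosome If `TRUE`, the depth factor uses per-chromosome
#'   totals instead of genome-wide totals. Default `FALSE` (genome-wide).
#' @return A `normalized_track`: list with `norm` (named list of
#'   per-chromosome numeric vectors), `chip_total`, `input_total`, `layout`.
#' @export
normalize_coverage <- function(chip, input, per_chromosome = FALSE) {
  stopifnot(inherits(chip, "coverage_track"),
            inherits(input, "coverage_track"))
  if (!identical(chip$layout$chrom, input$layout$chrom) ||
      !identical(chip$layout$length, input$layout$length)) {
    stop("chip and input tracks are on different layouts", call. = FALSE)
  }
  if (chip$total <= 0 || input$total <= 0) {
    stop("zero-total coverage track cannot be normalized", call. = FALSE)
  }
  norm <- lapply(names(chip$cov), function(chrom) {
    n <- chip$cov[[chrom]]
    ni <- input$cov[[chrom]]
    ratio <- if (per_chromosome) {
      si <- sum(ni); s <- sum(n)
      if (s <= 0 || si <= 0) {
        stop("zero-total chromosome '", chrom,
             "' under per_chromosome normalization", call. = FALSE)
      }
      si / s
    } else {
      input$total / chip$total
    }
    ((n + 1) / (ni + 1)) * ratio
  })
  names(norm) <- names(chip$cov)
  structure(
    list(norm = norm, chip_total = chip$total, input_total = input$total,
         layout = chip$layout),
    class = "normalized_track"
  )
}

#' @export
print.normalized_track <- function(x, ...) {
  cat(sprintf("normalized_track: %d chromosome(s), N = %.0f, Ni = %.0f\n",
              length(x$norm), x$chip_total, x$input_total))
  invisible(x)
}

#' Write a coverage or normalized track as bedGraph
#'
#' Runs of equal value (at 6 decimals) are collapsed into single bedGraph
#' records.
#'
#' @param x A `coverage_track` or `normalized_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  values <- if (inherits(x, "coverage_track")) x$cov
            else if (inherits(x, "normalized_track")) x$norm
            else stop("not a track", call. = FALSE)
  .write_bedgraph(values, path)
}
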