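# Two-condition differential chromatin density.
#
# Densities (total normalized coverage / region length) over an aggregate
# region set are scatter-plotted between two conditions; a line of best fit
# captures the genome-wide concordance, and regions far from the line -- in
# units of the residual standard deviation (the Z-score) -- are candidate
# differing regions.

#' Union of per-condition enriched regions
#'
#' Merges the significant regions of several conditions into one aggregate
#' set of regions of interest (interval union, sorted, disjoint).
#'
#' @param region_sets List (length >= 2) of region data.frames
#'   (chrom/start/end).
#' @return data.frame of the union regions.
#' @export
aggregate_regions <- function(region_sets) {
  stopifnot(is.list(region_sets), length(region_sets) >= 2L)
  grs <- lapply(region_sets, function(r) {
    .check_regions(r)
    .regions_gr(r)
  })
  .gr_regions(GenomicRanges::reduce(do.call(c, unname(grs))))
}

#' Split long regions into equal sub-regions
#'
#' A region of length L strictly greater than `max_len` is split into
#' `ceiling(L / max_len)` contiguous sub-regions of equal length; when L is
#' not divisible, the leftmost sub-regions carry the extra bp, so sub-region
#' lengths differ by at most 1 bp and sum exactly to L. Regions of length
#' `max_len` or less pass through unchanged.
#'
#' @param regions Region data.frame (chrom/start/end).
#' @param max_len Length threshold in bp (default 50000: regions over 50 kb
#'   are split).
#' @return data.frame of (sub-)regions, sorted.
#' @export
split_large <- function(regions, max_len = 50000) {
  .check_regions(regions)
  stopifnot(max_len > 0)
  if (nrow(regions) == 0L) return(regions[, c("chrom", "start", "end")])
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    L <- regions$end[i] - regions$start[i]
    if (L <= max_len) {
      return(data.frame(chrom = regions$chrom[i], start = regions$start[i],
                        end = regions$end[i], stringsAsFactors = FALSE))
    }
    k <- ceiling(L / max_len)
    base <- L %/% k
    extra <- L %% k
    lens <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
    ends <- regions$start[i] + cumsum(lens)
    data.frame(chrom = regions$chrom[i], start = ends - lens, end = ends,
               stringsAsFactors = FALSE)
  })
  .sort_regions(do.call(rbind, pieces))
}

#' Region density: total normalized coverage over length
#'
#' @param regions Region data.frame (chrom/start/end).
#' @param track A `normalized_track`.
#' @return Numeric vector: for each region, the sum of normalized coverage
#'   over its positions divided by its length (dimensionless per bp).
#' @export
region_density <- function(regions, track) {
  .check_regions(regions)
  stopifnot(inherits(track, "normalized_track"))
  if (nrow(regions) == 0L) return(numeric(0))
  cs <- lapply(track$norm, function(v) c(0, cumsum(v)))
  vapply(seq_len(nrow(regions)), function(i) {
    v <- cs[[regions$chrom[i]]]
    if (is.null(v)) stop("region on chromosome absent from track",
                         call. = FALSE)
    a <- regions$start[i]; b <- regions$end[i]
    if (b > length(v) - 1L) stop("region beyond chromosome end",
                                 call. = FALSE)
    (v[b + 1L] - v[a + 1L]) / (b - a)
  }, numeric(1))
}

#' Average densities across replicates
#'
#' @param ... Numeric vectors of per-region densities, one per replicate
#'   (equal length, same region order), or a single list of such vectors.
#' @return Numeric vector of arithmetic means per region.
#' @export
average_replicates <- function(...) {
  reps <- list(...)
  if (length(reps) == 1L && is.list(reps[[1L]])) reps <- reps[[1L]]
  stopifnot(length(reps) >= 1L)
  lens <- vapply(reps, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("replicate density vectors differ in length", call. = FALSE)
  }
  Reduce(`+`, reps) / length(reps)
}

#' Fit the two-condition density line and score residuals
#'
#' Ordinary least squares of condition-B densities (y) on condition-A
#' densities (x) with intercept; the residual standard deviation uses the
#' (n - 2) denominator, and each region's Z-score is its residual in units
#' of that SD. Regions are ranked by |Z|. Options: `method = "orthogonal"`
#' scores signed orthogonal distances from a total-least-squares line, and
#' `robust = TRUE` replaces the residual SD with the MAD (useful when strong
#' outliers would inflate the SD they are judged against).
#'
#' @param x,y Paired per-region densities for the two conditions
#'   (length >= 3; x must not be constant).
#' @param regions Optional region data.frame carried into the result.
#' @param method `"vertical"` (default: y-on-x residuals) or
#'   `"orthogonal"`.
#' @param robust Use MAD instead of the (n-2)-denominator SD? Default
#'   `FALSE`.
#' @return A `differential_fit`: list with `slope`, `intercept`,
#'   `residual_sd`, `perfect_fit` flag, and `table` (regions, x, y,
#'   residual, z, sorted by decreasing |z|).
#' @export
fit_and_score <- function(x, y, regions = NULL,
                          method = c("vertical", "orthogonal"),
                          robust = FALSE) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("degenerate x: zero variance", call. = FALSE)
  n <- length(x)
  if (method == "vertical") {
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
    resid <- y - (intercept + slope * x)
  } else {
    # total least squares via the principal axis of the centered scatter
    pc <- prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
    d <- pc$rotation[, 1L]
    if (d[1L] == 0) stop("degenerate x: vertical principal axis",
                         call. = FALSE)
    slope <- d[2L] / d[1L]
    intercept <- mean(y) - slope * mean(x)
    resid <- (y - intercept - slope * x) / sqrt(1 + slope^2)
  }
  sd_r <- if (robust) mad(resid) else sqrt(sum(resid^2) / (n - 2))
  perfect <- sd_r == 0
  z <- if (perfect) rep(0, n) else resid / sd_r
  tab <- if (is.null(regions)) {
    data.frame(region = seq_len(n), stringsAsFactors = FALSE)
  } else {
    stopifnot(nrow(regions) == n)
    regions
  }
  tab$density_a <- x
  tab$density_b <- y
  tab$residual <- resid
  tab$z <- z
  tab <- tab[order(-abs(tab$z)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(slope = slope, intercept = intercept, residual_sd = sd_r,
         perfect_fit = perfect, method = method, robust = robust,
         table = tab),
    class = "differential_fit"
  )
}

#' @export
print.differential_fit <- function(x, ...) {
  cat(sprintf(
    "differential_fit (%s%s): y = %.4f x + %.4f, residual SD %.4g, %d regions\n",
    x$method, if (x$robust) ", robust" else "", x$slope, x$intercept,
    x$residual_sd, nrow(x$table)))
  if (x$perfect_fit) cat("  perfect fit: all Z set to 0\n")
  invisible(x)
}

#' Flag candidate differing regions by |Z|
#'
#' @param fit A `differential_fit`.
#' @param z_threshold Minimum |Z| (default 3).
#' @return The rows of `fit$table` with `|z| >= z_threshold`, ranked by
#'   decreasing |z|.
#' @export
flag_outliers <- function(fit, z_threshold = 3) {
  stopifnot(inherits(fit, "differential_fit"), z_threshold >= 0)
  fit$table[abs(fit$table$z) >= z_threshold, , drop = FALSE]
}

#' Write a differential fit table as TSV
#' @param fit A `differential_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(fit, path) {
  data.table::fwrite(fit$table, path, sep = "\t")
  invisible(path)
}
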