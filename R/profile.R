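# Gaussian-smoothed, input-subtracted tag density profiles for
# visualization. These tracks are for looking at, not for calling: all
# statistics run on windowed normalized coverage.

#' Gaussian-smoothed tag density
#'
#' Each fragment contributes a Gaussian kernel of SD `bandwidth` centred at
#' its midpoint, truncated at +/- 4 bandwidths and renormalized so every
#' fragment carries unit mass; the profile is the kernel sum, in tags per
#' bp. Midpoints (not 5' ends) anchor the kernels because paired-end inserts
#' already locate the fragment centre, so no binding-peak shift estimation
#' is needed.
#'
#' @param x A [tag_set()].
#' @param layout A [genome_layout()].
#' @param bandwidth Kernel SD in bp (default 100).
#' @return A `smoothed_profile`: list with `density` (named list of
#'   per-chromosome numeric vectors), `bandwidth`, `n_tags`, `layout`.
#' @export
smooth_density <- function(x, layout, bandwidth = 100) {
  stopifnot(inherits(x, "tag_set"), bandwidth > 0)
  h <- ceiling(4 * bandwidth)
  kern <- dnorm(seq(-h, h), sd = bandwidth)
  kern <- kern / sum(kern)   # unit mass per tag despite truncation
  tags <- x$tags
  mid <- floor((tags$start + tags$end) / 2)
  dens <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    sel <- tags$chrom == layout$chrom[i]
    if (!any(sel)) return(numeric(L))
    counts <- tabulate(mid[sel] + 1L, nbins = L)
    # FFT convolution; symmetric kernel, so orientation is irrelevant
    full <- convolve(counts, kern, type = "open")
    pmax(full[(h + 1L):(h + L)], 0)
  })
  names(dens) <- layout$chrom
  structure(
    list(density = dens, bandwidth = bandwidth, n_tags = nrow(tags),
         layout = layout),
    class = "smoothed_profile"
  )
}

#' Input-subtracted smoothed profile
#'
#' Subtracts the input profile scaled by the tag-count ratio:
#' `chip - (chip_count / input_count) * input`. The result can be negative
#' where input density locally exceeds scaled ChIP density.
#'
#' @param chip,input `smoothed_profile`s on the same layout.
#' @param chip_count,input_count Tag counts used for scaling; default to the
#'   counts recorded in the profiles.
#' @return A `smoothed_profile` with the subtracted density.
#' @export
subtract_input <- function(chip, input,
                           chip_count = chip$n_tags,
                           input_count = input$n_tags) {
  stopifnot(inherits(chip, "smoothed_profile"),
            inherits(input, "smoothed_profile"))
  if (input_count <= 0) stop("empty input", call. = FALSE)
  if (!identical(names(chip$density), names(input$density))) {
    stop("profiles are on different layouts", call. = FALSE)
  }
  scale <- chip_count / input_count
  dens <- Map(function(a, b) a - scale * b, chip$density, input$density)
  structure(
    list(density = dens, bandwidth = chip$bandwidth, n_tags = chip$n_tags,
         layout = chip$layout, subtracted = TRUE),
    class = "smoothed_profile"
  )
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf("smoothed_profile: %d chromosome(s), bandwidth %g bp, %d tags%s\n",
              length(x$density), x$bandwidth, x$n_tags,
              if (isTRUE(x$subtracted)) ", input-subtracted" else ""))
  invisible(x)
}

#' Write a smoothed profile as bedGraph
#' @param x A `smoothed_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  .write_bedgraph(x$density, path)
}
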