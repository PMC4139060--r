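# Synthetic ChIP/input fragment generator with planted nested domain
# structure.
#
# The generator emulates the geometry of a Hox-cluster locus profiled in an
# ordered series of cell populations (parasegments): a broad repressive-mark
# domain covers the locus, and successively posterior conditions lose the
# mark over successively larger proximal spans ("clear" intervals) with
# sharp boundaries. Fragment placement is Poisson with a piecewise-constant
# intensity: background rate outside enriched intervals, fold x background
# inside. Each condition's intensity can be mixed with its immediately
# anterior neighbour's at a contamination fraction, emulating imperfect
# sorting of cell populations (a residual low level of signal over a clear
# domain). Shared enriched domains away from the locus are identical across
# conditions, standing in for the genome-wide peaks that do not change.

#' Construct a scenario specification
#'
#' @param layout A [genome_layout()].
#' @param locus List with `chrom`, `start`, `end`: the stairstep locus.
#' @param conditions Character vector of condition labels, ordered anterior
#'   to posterior.
#' @param clear Named list (one entry per condition) of clear-interval
#'   data.frames (chrom/start/end) within the locus; may have zero rows.
#' @param fold Enrichment fold of covered intervals over background
#'   (>= 1; default 4).
#' @param chip_depth ChIP fragment rate inside enriched intervals, tags per
#'   bp (default 0.5); the background rate is `chip_depth / fold`.
#' @param input_rate Input fragment rate, tags per bp, uniform (default
#'   0.5).
#' @param contamination Per-condition fraction in `[0, 1)` of each
#'   condition's intensity taken from its immediately anterior neighbour
#'   (scalar recycled; the first condition is never mixed). Default 0.
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max Truncated
#'   normal fragment-length distribution in bp (defaults 200 +/- 50,
#'   truncated to \[50, 500\]).
#' @param replicates Replicates per condition (default 2).
#' @param shared_domains Optional data.frame of enriched intervals outside
#'   the locus, identical in every condition.
#' @param shared_fold Per-domain enrichment folds for `shared_domains`
#'   (recycled). Default `NULL` uses `fold` for all; varied folds give the
#'   differential scatter a spread of densities so the line of fit is
#'   identifiable.
#' @param seed Root seed; every sample's draw is a deterministic function of
#'   it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(layout, locus, conditions, clear, fold = 4,
                          chip_depth = 0.5, input_rate = 0.5,
                          contamination = 0, fragment_mean = 200,
                          fragment_sd = 50, fragment_min = 50,
                          fragment_max = 500, replicates = 2,
                          shared_domains = NULL, shared_fold = NULL,
                          seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), fold >= 1, chip_depth > 0,
            input_rate > 0, replicates >= 1,
            fragment_min >= 1, fragment_min <= fragment_max,
            all(contamination >= 0), all(contamination < 1),
            length(conditions) >= 1,
            all(conditions %in% names(clear)))
  if (fragment_max > min(layout$length)) {
    stop("fragment max exceeds a chromosome length", call. = FALSE)
  }
  contamination <- rep_len(contamination, length(conditions))
  contamination[1L] <- 0
  if (!is.null(shared_domains)) {
    .check_regions(shared_domains, "shared_domains")
    shared_fold <- if (is.null(shared_fold)) {
      rep(fold, nrow(shared_domains))
    } else {
      rep_len(shared_fold, nrow(shared_domains))
    }
    stopifnot(all(shared_fold >= 1))
  }
  locus <- as.list(locus)
  for (cond in conditions) {
    cl <- clear[[cond]]
    .check_regions(cl, paste0("clear[", cond, "]"))
    if (nrow(cl) && (any(cl$start < locus$start) ||
                     any(cl$end > locus$end))) {
      stop("clear intervals must lie within the locus", call. = FALSE)
    }
  }
  structure(
    list(layout = layout, locus = locus, conditions = conditions,
         clear = clear, fold = fold, chip_depth = chip_depth,
         input_rate = input_rate, contamination = contamination,
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         fragment_min = fragment_min, fragment_max = fragment_max,
         replicates = replicates, shared_domains = shared_domains,
         shared_fold = shared_fold, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' The stairstep reference scenario
#'
#' Four ordered conditions over a 380 kb locus embedded in a 2 Mb
#' chromosome. Clear extents grow from the locus-proximal (left) edge:
#' condition 1 is fully covered ("mesa-like"); conditions 2-4 are clear over
#' the leftmost 92 kb, 137 kb, and 173 kb (137 + 36). Twelve 15 kb enriched
#' domains shared by all conditions are planted away from the locus, with
#' enrichment strengths cycling between half and five-thirds of `fold` (all
#' collapsing to 1 when `fold = 1`) so region densities span a range. All
#' lengths scale with `scale`, so reduced-size runs keep the same geometry.
#'
#' @param scale Length multiplier (default 1.0).
#' @param conditions Condition labels, anterior to posterior.
#' @param fold Locus enrichment fold (default 4).
#' @param ... Passed to [scenario_spec()] (e.g. `contamination`, `seed`).
#' @return A `scenario_spec`.
#' @export
bxc_stairstep_scenario <- function(scale = 1.0,
                                   conditions = c("PS4", "PS5", "PS6", "PS7"),
                                   fold = 4, ...) {
  stopifnot(scale > 0, length(conditions) == 4L)
  G <- round(2e6 * scale)
  layout <- genome_layout("chrS", G)
  locus_start <- round(8e5 * scale)
  locus_len <- round(380000 * scale)
  locus <- list(chrom = "chrS", start = locus_start,
                end = locus_start + locus_len)
  extents <- round(c(0, 92000, 137000, 173000) * scale)
  clear <- lapply(extents, function(e) {
    if (e == 0) {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = "chrS", start = locus_start,
                 end = locus_start + e, stringsAsFactors = FALSE)
    }
  })
  names(clear) <- conditions
  # shared domains: 12 x 15 kb, fixed offsets clear of the locus
  dom_starts <- round(c(seq(40000, 700000, length.out = 7),
                        seq(1260000, 1900000, length.out = 5)) * scale)
  shared <- data.frame(chrom = "chrS", start = dom_starts,
                       end = dom_starts + round(15000 * scale),
                       stringsAsFactors = FALSE)
  shared_fold <- 1 + (fold - 1) * rep_len(c(1 / 2, 5 / 6, 7 / 6, 5 / 3),
                                          nrow(shared))
  scenario_spec(layout = layout, locus = locus, conditions = conditions,
                clear = clear, fold = fold, shared_domains = shared,
                shared_fold = shared_fold, ...)
}

# Enrichment geometry of one condition as intervals with a "lift": the
# multiple of the background rate applying inside. Locus covered intervals
# (locus minus clear) carry the scenario fold; shared domains carry their
# own per-domain folds.
#' @noRd
.lift_regions <- function(spec, cond) {
  locus_df <- data.frame(chrom = spec$locus$chrom, start = spec$locus$start,
                         end = spec$locus$end, stringsAsFactors = FALSE)
  covered <- .gr_regions(GenomicRanges::setdiff(
    .regions_gr(locus_df), .regions_gr(spec$clear[[cond]])))
  covered$lift <- rep(spec$fold, nrow(covered))
  if (!is.null(spec$shared_domains)) {
    shared <- spec$shared_domains[, c("chrom", "start", "end")]
    shared$lift <- spec$shared_fold
    covered <- rbind(covered, shared)
  }
  covered
}

# Evaluate the mixed intensity on the common refinement of both conditions'
# enrichment geometries: rate(x) = b * [(1-f) lift_c(x) + f lift_ant(x)],
# lift = 1 outside every enriched interval.
#' @noRd
.mixed_rates <- function(spec, cond_idx) {
  b <- spec$chip_depth / spec$fold
  f <- spec$contamination[cond_idx]
  lr_c <- .lift_regions(spec, spec$conditions[cond_idx])
  lr_a <- if (f > 0) {
    .lift_regions(spec, spec$conditions[cond_idx - 1L])
  } else {
    lr_c[0, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(spec$layout)), function(i) {
    chrom <- spec$layout$chrom[i]
    L <- spec$layout$length[i]
    cuts <- sort(unique(c(0, L,
                          lr_c$start[lr_c$chrom == chrom],
                          lr_c$end[lr_c$chrom == chrom],
                          lr_a$start[lr_a$chrom == chrom],
                          lr_a$end[lr_a$chrom == chrom])))
    piece_start <- head(cuts, -1L)
    piece_end <- tail(cuts, -1L)
    mids <- (piece_start + piece_end) / 2
    lift_at <- function(lr) {
      sel <- lr$chrom == chrom
      starts <- lr$start[sel]; ends <- lr$end[sel]; lifts <- lr$lift[sel]
      vapply(mids, function(m) {
        inside <- starts <= m & m < ends
        if (any(inside)) max(lifts[inside]) else 1
      }, numeric(1))
    }
    data.frame(chrom = chrom, start = piece_start, end = piece_end,
               rate = b * ((1 - f) * lift_at(lr_c) + f * lift_at(lr_a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Truncated-normal fragment lengths via inverse-CDF sampling.
#' @noRd
.fragment_lengths <- function(n, spec) {
  lo <- pnorm(spec$fragment_min, spec$fragment_mean, spec$fragment_sd)
  hi <- pnorm(spec$fragment_max, spec$fragment_mean, spec$fragment_sd)
  u <- runif(n, lo, hi)
  len <- round(qnorm(u, spec$fragment_mean, spec$fragment_sd))
  pmin(pmax(len, spec$fragment_min), spec$fragment_max)
}

# Draw one sample: Poisson counts per intensity piece, uniform starts
# within the piece, truncated-normal lengths, ends clamped to the
# chromosome.
#' @noRd
.draw_sample <- function(pieces, spec, layout) {
  counts <- rpois(nrow(pieces), pieces$rate * (pieces$end - pieces$start))
  total <- sum(counts)
  idx <- rep(seq_len(nrow(pieces)), counts)
  start <- floor(pieces$start[idx] +
                 runif(total) * (pieces$end[idx] - pieces$start[idx]))
  len <- .fragment_lengths(total, spec)
  chrom <- pieces$chrom[idx]
  end <- pmin(start + len, .chrom_length(layout, chrom))
  ord <- order(chrom, start, end)
  data.frame(chrom = chrom[ord], start = start[ord], end = end[ord],
             stringsAsFactors = FALSE)
}

#' Generate ChIP and input tag sets for a scenario
#'
#' Draws every condition/replicate ChIP sample from its (possibly
#' contamination-mixed) piecewise-constant intensity, and one shared input
#' sample from a uniform intensity. Fully reproducible: each sample's seed
#' is a deterministic function of the scenario seed, so regenerating the
#' scenario gives byte-identical tag sets.
#'
#' @param spec A [scenario_spec()].
#' @return List with `chip` (list by condition of lists by replicate of
#'   [tag_set()]s), `input` (a [tag_set()]), and `spec`.
#' @export
generate_tags <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  chip <- list()
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[ci]
    pieces <- .mixed_rates(spec, ci)
    reps <- list()
    for (ri in seq_len(spec$replicates)) {
      tags <- .with_seed(.fan_seed(spec$seed, ci * 100 + ri),
                         .draw_sample(pieces, spec, spec$layout))
      reps[[paste0("rep", ri)]] <- tag_set(
        tags, spec$layout, role = "experiment", condition = cond,
        replicate = paste0("rep", ri))
    }
    chip[[cond]] <- reps
  }
  input_pieces <- data.frame(chrom = spec$layout$chrom, start = 0,
                             end = spec$layout$length,
                             rate = spec$input_rate,
                             stringsAsFactors = FALSE)
  input_tags <- .with_seed(.fan_seed(spec$seed, 99999),
                           .draw_sample(input_pieces, spec, spec$layout))
  input <- tag_set(input_tags, spec$layout, role = "input",
                   condition = "input")
  list(chip = chip, input = input, spec = spec)
}

#' Write a generated scenario to disk
#'
#' Emits BED3 per sample (`<dir>/<condition>_<replicate>.bed`,
#' `<dir>/input.bed`), the chrom.sizes table, and a YAML record of the
#' scenario parameters (including the seed) for provenance.
#'
#' @param data Result of [generate_tags()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- data$spec
  write.table(spec$layout, file.path(dir, "chrom.sizes"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (cond in names(data$chip)) {
    for (rep in names(data$chip[[cond]])) {
      write_tags(data$chip[[cond]][[rep]],
                 file.path(dir, paste0(cond, "_", rep, ".bed")))
    }
  }
  write_tags(data$input, file.path(dir, "input.bed"))
  meta <- list(
    conditions = spec$conditions,
    locus = spec$locus,
    clear = lapply(spec$clear, function(cl) {
      lapply(seq_len(nrow(cl)),
             function(i) list(chrom = cl$chrom[i], start = cl$start[i],
                              end = cl$end[i]))
    }),
    fold = spec$fold, chip_depth = spec$chip_depth,
    input_rate = spec$input_rate,
    contamination = spec$contamination,
    fragment = list(mean = spec$fragment_mean, sd = spec$fragment_sd,
                    min = spec$fragment_min, max = spec$fragment_max),
    replicates = spec$replicates, seed = spec$seed)
  yaml::write_yaml(meta, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
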