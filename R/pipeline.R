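# Orchestration: one validated configuration object and one function that
# runs filter -> coverage -> normalize -> windows -> null -> call -> merge
# -> intersect -> aggregate -> split -> density -> fit -> flag -> segment,
# writing every intermediate in its standard format.

#' Build and validate a run configuration
#'
#' @param layout_path Path to a chrom.sizes file.
#' @param chip_paths Named list (by condition, ordered anterior to
#'   posterior) of named lists (by replicate) of BED3 paths.
#' @param input_path BED3 path of the input sample.
#' @param out_dir Output directory.
#' @param locus List with `chrom`, `start`, `end`: the locus to segment.
#' @param w,s Window size and step in bp.
#' @param alpha Window significance cutoff in (0, 1].
#' @param rounds Null randomization rounds.
#' @param max_insert Insert-size filter in bp.
#' @param max_len Differential region-split threshold in bp.
#' @param z_threshold |Z| cutoff for candidate differing regions.
#' @param min_run Minimum state-run length in windows for boundary calling.
#' @param bandwidth Profile smoothing bandwidth in bp.
#' @param seed Root seed; all stage/round seeds are derived from it.
#' @param write_profiles Also write smoothed profiles (slowest output;
#'   default `TRUE`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(layout_path, chip_paths, input_path, out_dir, locus,
                       w = 1000, s = 50, alpha = 1e-3, rounds = 5,
                       max_insert = 1000, max_len = 50000, z_threshold = 3,
                       min_run = 5, bandwidth = 100, seed = 1,
                       write_profiles = TRUE) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  stopifnot(w >= s, s > 0, rounds >= 1, max_insert > 0, max_len > 0,
            z_threshold >= 0, min_run >= 1, bandwidth > 0,
            is.list(chip_paths), length(chip_paths) >= 1,
            !is.null(names(chip_paths)))
  structure(
    list(layout_path = layout_path, chip_paths = chip_paths,
         input_path = input_path, out_dir = out_dir, locus = as.list(locus),
         w = w, s = s, alpha = alpha, rounds = rounds,
         max_insert = max_insert, max_len = max_len,
         z_threshold = z_threshold, min_run = min_run,
         bandwidth = bandwidth, seed = as.integer(seed),
         write_profiles = write_profiles),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Executes every stage on the configured samples and writes all
#' intermediates under `config$out_dir`: filtered tags (BED3), raw and
#' normalized tracks (bedGraph), null distributions (TSV), enriched regions
#' per replicate and per condition (BED5), the differential table for each
#' adjacent condition pair (TSV) with flagged regions (BED), the
#' segmentation (clear-interval BEDs, boundary TSV, nesting-violation TSV),
#' smoothed input-subtracted profiles (bedGraph), a tag-count log, and the
#' configuration itself (YAML). Two runs with the same configuration and
#' seed produce identical output trees.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages? Default `FALSE`.
#' @return Invisibly, a list with the per-condition regions, differential
#'   fits, segmentation, and nesting report.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config)[setdiff(names(config), "")],
                   file.path(config$out_dir, "config.yaml"))
  layout <- load_layout(config$layout_path)
  log_rows <- list()

  say("loading input: %s", config$input_path)
  input <- filter_tags(load_tags(config$input_path, layout, role = "input"),
                       max_insert = config$max_insert)
  input_cov <- positional_coverage(input, layout)
  conditions <- names(config$chip_paths)

  cond_regions <- list()
  cond_tracks <- list()
  rep_tracks <- list()
  stage_i <- 0
  for (cond in conditions) {
    rep_regions <- list()
    for (rep in names(config$chip_paths[[cond]])) {
      stage_i <- stage_i + 1
      path <- config$chip_paths[[cond]][[rep]]
      tags <- load_tags(path, layout, role = "experiment",
                        condition = cond, replicate = rep)
      n0 <- n_tags(tags)
      tags <- filter_tags(tags, max_insert = config$max_insert)
      flog <- attr(tags, "filter_log")
      say("%s/%s: %d tags, removed %d (insert > %d bp), %d duplicates",
          cond, rep, n0, flog[["removed_insert"]], config$max_insert,
          flog[["removed_duplicate"]])
      write_tags(tags, file.path(config$out_dir,
                                 paste0(cond, "_", rep, "_filtered.bed")))
      cov <- positional_coverage(tags, layout)
      trk <- normalize_coverage(cov, input_cov)
      rep_tracks[[cond]][[rep]] <- trk
      stats <- window_sums(trk, w = config$w, s = config$s)
      null <- build_null(tags, input_cov, layout, w = config$w,
                         s = config$s, rounds = config$rounds,
                         seed = .fan_seed(config$seed, stage_i))
      write_null(null, file.path(config$out_dir,
                                 paste0(cond, "_", rep, "_null.tsv")))
      sig <- call_windows(stats, null, alpha = config$alpha)
      say("%s/%s: %d of %d windows significant at alpha = %g",
          cond, rep, nrow(sig), nrow(stats), config$alpha)
      regions <- merge_windows(sig, w = config$w, condition = cond,
                               replicate = rep)
      write_regions(regions, file.path(config$out_dir,
                                       paste0(cond, "_", rep,
                                              "_regions.bed")))
      rep_regions[[rep]] <- regions
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        condition = cond, replicate = rep, tags_loaded = n0,
        removed_insert = flog[["removed_insert"]],
        removed_duplicate = flog[["removed_duplicate"]],
        windows = nrow(stats), significant_windows = nrow(sig),
        regions = nrow(regions), stringsAsFactors = FALSE)
    }
    merged <- Reduce(intersect_replicates, rep_regions)
    merged$condition <- cond
    say("%s: %d replicate-intersected regions", cond, nrow(merged))
    write_regions(merged, file.path(config$out_dir,
                                    paste0(cond, "_regions.bed")))
    cond_regions[[cond]] <- merged
    # replicate-averaged track used for densities and profiles
    cond_tracks[[cond]] <- rep_tracks[[cond]]
  }

  # differential density between adjacent condition pairs
  fits <- list()
  if (length(conditions) >= 2L) {
    agg <- aggregate_regions(cond_regions)
    sub <- split_large(agg, max_len = config$max_len)
    say("differential: %d aggregate regions -> %d sub-regions",
        nrow(agg), nrow(sub))
    dens <- lapply(conditions, function(cond) {
      average_replicates(lapply(cond_tracks[[cond]], function(trk) {
        region_density(sub, trk)
      }))
    })
    names(dens) <- conditions
    for (i in seq_len(length(conditions) - 1L)) {
      a <- conditions[i]; b <- conditions[i + 1L]
      fit <- fit_and_score(dens[[a]], dens[[b]], regions = sub)
      flag <- flag_outliers(fit, z_threshold = config$z_threshold)
      say("%s vs %s: slope %.3f, %d regions with |Z| >= %g",
          a, b, fit$slope, nrow(flag), config$z_threshold)
      pair <- paste0(a, "_vs_", b)
      write_differential(fit, file.path(config$out_dir,
                                        paste0(pair, "_density.tsv")))
      write_regions(flag, file.path(config$out_dir,
                                    paste0(pair, "_flagged.bed")))
      fits[[pair]] <- fit
    }
  }

  # segmentation over the locus
  mat <- state_matrix(config$locus, cond_regions, w = config$w,
                      s = config$s)
  seg <- call_boundaries(mat, min_run = config$min_run)
  nesting <- check_nesting(seg)
  say("segmentation: %d boundary coordinate(s), %d nesting violation(s)",
      nrow(seg$boundary_table), nrow(nesting))
  write_segmentation(seg, file.path(config$out_dir, "segmentation"))
  data.table::fwrite(nesting,
                     file.path(config$out_dir,
                               "segmentation_nesting_violations.tsv"),
                     sep = "\t")

  if (isTRUE(config$write_profiles)) {
    input_prof <- smooth_density(input, layout,
                                 bandwidth = config$bandwidth)
    for (cond in conditions) {
      reps <- names(config$chip_paths[[cond]])
      tags1 <- filter_tags(
        load_tags(config$chip_paths[[cond]][[reps[1L]]], layout,
                  role = "experiment", condition = cond),
        max_insert = config$max_insert)
      prof <- subtract_input(
        smooth_density(tags1, layout, bandwidth = config$bandwidth),
        input_prof)
      write_profile(prof, file.path(config$out_dir,
                                    paste0(cond, "_profile.bedgraph")))
    }
  }

  data.table::fwrite(data.table::rbindlist(log_rows),
                     file.path(config$out_dir, "run_log.tsv"), sep = "\t")
  invisible(list(regions = cond_regions, fits = fits, segmentation = seg,
                 nesting = nesting))
}
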