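# Fragment-interval ("tag") input, validation and filtering.
#
# A tag is one sequenced paired-end insert represented as an unstranded
# genomic interval. All coordinates are 0-based half-open, so a tag's
# length is end - start.

#' Construct a genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' anchors every coordinate in a run. The pipeline is genome-agnostic: any
#' layout (a whole fly genome, a single synthetic chromosome) works.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-like vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout`: a data.frame with columns `chrom` and `length`,
#'   row order preserved.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("no chromosomes", call. = FALSE)
  if (anyDuplicated(chrom)) {
    stop("duplicate name in genome layout: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a chromosome-sizes table
#'
#' Reads a UCSC-style chrom.sizes file: two whitespace-separated columns,
#' chromosome name and length in bp. Row order is preserved.
#'
#' @param path Path to the chrom.sizes text file.
#' @return A [genome_layout()].
#' @export
load_layout <- function(path) {
  tab <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "numeric")),
    error = function(e) stop("malformed chrom.sizes file: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) < 2L) stop("malformed chrom.sizes file: need two columns",
                           call. = FALSE)
  genome_layout(tab[[1L]], tab[[2L]])
}

#' @noRd
.chrom_length <- function(layout, chrom) {
  layout$length[match(chrom, layout$chrom)]
}

#' Construct a tag set
#'
#' @param tags data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param layout A [genome_layout()] the records are validated against.
#' @param role `"experiment"` (ChIP) or `"input"` (control).
#' @param condition,replicate Free-form labels carried through the pipeline.
#' @return A `tag_set`: list with elements `tags`, `role`, `condition`,
#'   `replicate`.
#' @export
tag_set <- function(tags, layout, role = c("experiment", "input"),
                    condition = NA_character_, replicate = NA_character_) {
  role <- match.arg(role)
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  .check_regions(tags, "tags")
  tags$chrom <- as.character(tags$chrom)
  tags$start <- as.numeric(tags$start)
  tags$end <- as.numeric(tags$end)
  if (nrow(tags)) {
    len <- .chrom_length(layout, tags$chrom)
    if (anyNA(len)) {
      bad <- unique(tags$chrom[is.na(len)])
      stop("unknown chromosome in tag file: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(tags$start < 0) || any(tags$end > len)) {
      stop("tag coordinates outside chromosome bounds", call. = FALSE)
    }
  }
  structure(
    list(tags = tags[, c("chrom", "start", "end")], role = role,
         condition = as.character(condition),
         replicate = as.character(replicate)),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d fragments (%s%s%s)\n", nrow(x$tags), x$role,
              if (is.na(x$condition)) "" else paste0(", ", x$condition),
              if (is.na(x$replicate)) "" else paste0("/", x$replicate)))
  invisible(x)
}

#' Number of fragments in a tag set
#' @param x A `tag_set`.
#' @return Integer count.
#' @export
n_tags <- function(x) nrow(x$tags)

#' Read aligned fragments from a BED-like file
#'
#' Reads the first three columns (chrom, 0-based start, exclusive end) of a
#' BED file, plain or gzip-compressed, one row per paired-end insert.
#' Records on chromosomes absent from the layout, with end <= start, or with
#' coordinates outside the chromosome are errors: the loader consumes
#' already-aligned, already-validated fragments and refuses anything else.
#'
#' @param path Path to a BED3(+) file (`.gz` accepted).
#' @param layout A [genome_layout()].
#' @inheritParams tag_set
#' @return A [tag_set()].
#' @export
load_tags <- function(path, layout, role = c("experiment", "input"),
                      condition = NA_character_, replicate = NA_character_) {
  tab <- if (isTRUE(file.size(path) == 0)) {
    data.table::data.table()
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      select = 1:3, fill = TRUE,
                      colClasses = list(character = 1, numeric = 2:3))
  }
  if (nrow(tab) == 0L) {
    tab <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  } else {
    data.table::setnames(tab, c("chrom", "start", "end"))
    if (anyNA(tab$start) || anyNA(tab$end)) {
      stop("malformed BED row (non-numeric coordinates)", call. = FALSE)
    }
  }
  tag_set(as.data.frame(tab), layout, role = role,
          condition = condition, replicate = replicate)
}

#' Write a tag set as BED3
#'
#' @param x A [tag_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(x, path) {
  out <- x$tags
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter fragments by insert size and remove duplicates
#'
#' Applies the two record-level filters used before any statistics: fragments
#' longer than `max_insert` are removed (library-prep artifacts), and, if
#' `drop_duplicates`, fragments with an exactly identical (chrom, start, end)
#' interval are collapsed to one (the standard proxy for potential PCR
#' duplicates of unstranded paired-end inserts). The insert-size filter runs
#' first, then deduplication; relative record order is preserved.
#'
#' @param x A [tag_set()].
#' @param max_insert Maximum retained insert size in bp (default 1000:
#'   fragments over 1 kb are removed).
#' @param drop_duplicates Collapse identical fragments? Default `TRUE`.
#' @return A filtered [tag_set()]; counts removed by each filter are attached
#'   as attribute `filter_log` (named integer vector).
#' @export
filter_tags <- function(x, max_insert = 1000, drop_duplicates = TRUE) {
  stopifnot(inherits(x, "tag_set"), max_insert > 0)
  tags <- x$tags
  n0 <- nrow(tags)
  keep <- (tags$end - tags$start) <= max_insert
  tags <- tags[keep, , drop = FALSE]
  n_insert <- n0 - nrow(tags)
  n_dup <- 0L
  if (drop_duplicates && nrow(tags)) {
    dup <- duplicated(tags[, c("chrom", "start", "end")])
    n_dup <- sum(dup)
    tags <- tags[!dup, , drop = FALSE]
  }
  rownames(tags) <- NULL
  out <- x
  out$tags <- tags
  attr(out, "filter_log") <- c(removed_insert = n_insert,
                               removed_duplicate = as.integer(n_dup))
  out
}
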