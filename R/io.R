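#' Read a binned strand-specific rNMP count table
#'
#' Reads per-bin rNMP counts for one \{strain, polymerase mutant, replicate\}
#' dataset.  Two on-disk dialects are accepted:
#'
#' * a combined 5-column TSV `(chrom, start, end, count_top, count_bottom)`
#'   (with or without a header line), or
#' * a pair of 4-column bedGraph-like files `(chrom, start, end, count)`,
#'   one per strand, passed as `path` (top strand) and `bottom` (bottom
#'   strand).
#'
#' Intervals must align exactly to the layout's bin grid (0-based half-open
#' bp).  Bins absent from the file are zero-filled; gzip-compressed files are
#' read transparently.
#'
#' @param path combined table, or top-strand bedGraph if `bottom` is given.
#' @param layout a [genome_layout()].
#' @param strain strain label.
#' @param polymerase one of `"delta"`, `"epsilon"`, `"alpha"`.
#' @param replicate biological replicate number (integer >= 1).
#' @param bottom optional bottom-strand bedGraph path (paired dialect).
#' @return a `binned_strand_counts` object: `layout`, `strain`, `polymerase`,
#'   `replicate`, and integer vectors `top`, `bottom` (one value per bin of
#'   the layout, in global bin order).
#' @export
read_counts <- function(path, layout, strain, polymerase, replicate = 1L,
                        bottom = NULL) {
  polymerase <- check_polymerase(polymerase)
  if (is.null(bottom)) {
    tab <- read_interval_table(path, n_value_cols = 2)
    top_counts    <- fill_bins(tab[, 1:3], tab[[4]], layout, path)
    bottom_counts <- fill_bins(tab[, 1:3], tab[[5]], layout, path)
  } else {
    tt <- read_interval_table(path,   n_value_cols = 1)
    bb <- read_interval_table(bottom, n_value_cols = 1)
    top_counts    <- fill_bins(tt[, 1:3], tt[[4]], layout, path)
    bottom_counts <- fill_bins(bb[, 1:3], bb[[4]], layout, bottom)
  }
  binned_strand_counts(layout, strain, polymerase, replicate,
                       top_counts, bottom_counts)
}

#' Construct a binned strand-count object
#'
#' @inheritParams read_counts
#' @param top,bottom non-negative integer count vectors, one value per bin.
#' @return a `binned_strand_counts` object.
#' @export
binned_strand_counts <- function(layout, strain, polymerase, replicate,
                                 top, bottom) {
  polymerase <- check_polymerase(polymerase)
  if (length(top) != layout$n_bins || length(bottom) != layout$n_bins)
    stop("counts must have exactly one value per bin of the layout")
  if (any(top < 0) || any(bottom < 0))
    stop("negative count")
  structure(
    list(layout = layout, strain = as.character(strain),
         polymerase = polymerase, replicate = as.integer(replicate),
         top = as.integer(round(top)), bottom = as.integer(round(bottom))),
    class = "binned_strand_counts"
  )
}

#' @export
print.binned_strand_counts <- function(x, ...) {
  cat(sprintf(
    "<binned_strand_counts> %s Pol%s rep%d: %d bins, %d/%d rNMPs top/bottom\n",
    x$strain, x$polymerase, x$replicate, x$layout$n_bins,
    sum(x$top), sum(x$bottom)))
  invisible(x)
}

# Read (chrom, start, end, value...) skipping comment/track lines; header
# auto-detected from a non-numeric second field.
read_interval_table <- function(path, n_value_cols) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty count file: ", path, " (all bins zero-filled)")
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      matrix(numeric(), 0, n_value_cols)))
  }
  first <- strsplit(lines[1], "\t| +")[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0) {
    warning("empty count file: ", path, " (all bins zero-filled)")
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      matrix(numeric(), 0, n_value_cols)))
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 + n_value_cols)
    stop("expected ", 3 + n_value_cols, " columns in ", path,
         ", found ", ncol(tab))
  tab[, seq_len(3 + n_value_cols)]
}

# Map interval rows onto the layout's bin grid, validating alignment.
fill_bins <- function(intervals, values, layout, path, check_negative = TRUE) {
  out <- numeric(layout$n_bins)
  if (nrow(intervals) == 0) return(out)
  chrom <- as.character(intervals[[1]])
  start <- intervals[[2]]
  end   <- intervals[[3]]
  ci <- match(chrom, layout$chrom$name)
  if (anyNA(ci))
    stop("unknown chromosome in ", path, ": ",
         paste(unique(chrom[is.na(ci)]), collapse = ", "))
  bw <- layout$bin_width
  len <- layout$chrom$length_bp[ci]
  bin <- start / bw + 1  # 1-based bin index if aligned
  exp_end <- pmin(start + bw, len)
  bad <- start %% bw != 0 | end != exp_end | start < 0 | end > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop("interval not aligned to ", bw, " bp bin grid in ", path, ": ",
         chrom[i], ":", start[i], "-", end[i])
  }
  if (check_negative && any(values < 0))
    stop("negative count in ", path)
  idx <- layout$chrom$offset[ci] + bin
  if (anyDuplicated(idx))
    stop("duplicated bin in ", path)
  out[idx] <- values
  out
}

out_connection <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Write a polymerase track to a TSV file
#'
#' Writes `(chrom, start, end, value, low_coverage)` on the bin grid,
#' 0-based half-open coordinates, tab-separated, with a header.  Flagged
#' zero-coverage bins carry value 0 and `low_coverage = 1`.  Round-trips
#' with [read_track()] to within 1e-9.
#'
#' @param track a `polymerase_track` (see [compute_track()]).
#' @param path output path (`.gz` suffix writes gzip).
#' @export
write_track <- function(track, path) {
  df <- layout_bins(track$layout)
  df$value <- format_num(track$values)
  df$low_coverage <- as.integer(track$low_coverage)
  con <- out_connection(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a polymerase track written by [write_track()]
#'
#' @param path track TSV path.
#' @param layout a [genome_layout()] matching the file's bin grid.
#' @param polymerase one of `"delta"`, `"epsilon"`, `"alpha"`.
#' @return a `polymerase_track`.
#' @export
read_track <- function(path, layout, polymerase) {
  polymerase <- check_polymerase(polymerase)
  tab <- read_interval_table(path, n_value_cols = 1)
  values <- fill_bins(tab[, 1:3], tab[[4]], layout, path,
                      check_negative = FALSE)
  full <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  low <- if ("low_coverage" %in% names(full)) {
    as.logical(fill_bins(full[, 1:3], full$low_coverage, layout, path))
  } else rep(FALSE, layout$n_bins)
  polymerase_track(layout, polymerase, values, low)
}

#' Write genomic regions as BED5
#'
#' Standard 5-column BED `(chrom, start, end, name, score)`, 0-based
#' half-open, tab-separated, no header, sorted by `(chrom, start)` with
#' chromosomes in layout order when resolvable, otherwise alphabetical.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score` (see [origins_to_regions()] / [zones_to_regions()]).
#' @param path output path.
#' @param layout optional [genome_layout()] used to order chromosomes and
#'   validate coordinates.
#' @export
write_regions <- function(regions, path, layout = NULL) {
  need <- c("chrom", "start", "end", "name", "score")
  if (!all(need %in% names(regions)))
    stop("regions must have columns ", paste(need, collapse = ", "))
  if (nrow(regions) > 0) {
    if (any(regions$start < 0) || any(regions$start >= regions$end))
      stop("invalid region: require 0 <= start < end")
    chrom_rank <- if (!is.null(layout)) {
      r <- match(regions$chrom, layout$chrom$name)
      if (anyNA(r)) stop("unknown chromosome: ",
                         paste(unique(regions$chrom[is.na(r)]), collapse = ", "))
      if (any(regions$end > layout$chrom$length_bp[r]))
        stop("region end beyond chromosome length")
      r
    } else as.integer(factor(regions$chrom))
    regions <- regions[order(chrom_rank, regions$start), , drop = FALSE]
  }
  con <- out_connection(path)
  on.exit(close(con))
  df <- regions[, need, drop = FALSE]
  df$score <- format_num(df$score)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a BED5 region file
#'
#' @param path BED5 path written by [write_regions()].
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1:5] <- c("chrom", "start", "end", "name", "score")
  tab[, 1:5]
}

# full-precision numeric formatting for TSV output (round-trip to < 1e-9)
format_num <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  else x
}

#' Convert origin calls to BED-ready region records
#'
#' @param origins origin-call data.frame from [call_origins()].
#' @param layout the [genome_layout()] the origins were called on.
#' @param score which efficiency to place in the BED score column.
#' @return data.frame `(chrom, start, end, name, score)`; each origin spans
#'   its peak-maximum bin.
#' @export
origins_to_regions <- function(origins, layout,
                               score = c("efficiency_norm", "efficiency_raw")) {
  score <- match.arg(score)
  bw <- layout$bin_width
  ci <- match(origins$chrom, layout$chrom$name)
  start <- (origins$origin_bin - 1) * bw
  data.frame(
    chrom = origins$chrom,
    start = start,
    end   = pmin(start + bw, layout$chrom$length_bp[ci]),
    name  = sprintf("ori_%d", seq_len(nrow(origins))),
    score = origins[[score]],
    stringsAsFactors = FALSE
  )
}

#' Convert termination zones to BED-ready region records
#'
#' @param zones zone data.frame from [select_termination_zones()].
#' @param layout the [genome_layout()].
#' @return data.frame `(chrom, start, end, name, score)`; score is the
#'   lesser of the two flanking origin efficiencies.
#' @export
zones_to_regions <- function(zones, layout) {
  bw <- layout$bin_width
  ci <- match(zones$chrom, layout$chrom$name)
  data.frame(
    chrom = zones$chrom,
    start = (zones$start_bin - 1) * bw,
    end   = pmin(zones$end_bin * bw, layout$chrom$length_bp[ci]),
    name  = sprintf("ter_%d", seq_len(nrow(zones))),
    score = pmin(zones$left_efficiency, zones$right_efficiency),
    stringsAsFactors = FALSE
  )
}
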