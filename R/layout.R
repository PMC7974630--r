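#' Define a binned genome layout
#'
#' A `genome_layout` fixes the bin grid that every other object in the
#' package (counts, tracks, differential signals, origin calls) is indexed
#' on.  Each chromosome is divided into fixed-width bins; the last bin of a
#' chromosome may be shorter than `bin_width`.
#'
#' Bin indices are 1-based within each chromosome throughout the R API;
#' on-disk coordinates (BED/bedGraph/TSV) are 0-based half-open base pairs,
#' so bin `i` spans `[(i-1)*bin_width, min(i*bin_width, length))`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, order is preserved).
#' @param bin_width bin width in bp (default 300, the standard Pu-Seq bin).
#' @return an object of class `genome_layout` with elements `chrom`
#'   (data.frame: `name`, `length_bp`, `n_bins`, `offset` — cumulative bin
#'   offset used for global indexing), `bin_width` and `n_bins`.
#' @examples
#' genome_layout(c(chrI = 9e5, chrII = 6e5), bin_width = 300)
#' @export
genome_layout <- function(chrom_lengths, bin_width = 300) {
  if (length(chrom_lengths) < 1)
    stop("at least one chromosome is required")
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width < 1)
    stop("bin_width must be a single integer >= 1")
  if (any(chrom_lengths < 1))
    stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  n_bins <- as.integer(ceiling(chrom_lengths / bin_width))
  chrom <- data.frame(
    name      = names(chrom_lengths),
    length_bp = as.numeric(chrom_lengths),
    n_bins    = n_bins,
    offset    = cumsum(c(0L, n_bins[-length(n_bins)])),
    stringsAsFactors = FALSE
  )
  structure(
    list(chrom = chrom, bin_width = bin_width, n_bins = sum(n_bins)),
    class = "genome_layout"
  )
}

#' Read a genome layout from a chrom-sizes file
#'
#' @param path two-column whitespace-separated file (chromosome name, length
#'   in bp), as produced by e.g. `samtools faidx` / UCSC fetchChromSizes.
#' @param bin_width bin width in bp.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_width = 300) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  lens <- stats::setNames(tab$length, tab$name)
  genome_layout(lens, bin_width = bin_width)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), bin width %d bp, %d bins\n",
              nrow(x$chrom), x$bin_width, x$n_bins))
  print(x$chrom, row.names = FALSE)
  invisible(x)
}

# list of global bin-index vectors, one per chromosome
chrom_slices <- function(layout) {
  lapply(seq_len(nrow(layout$chrom)), function(i) {
    layout$chrom$offset[i] + seq_len(layout$chrom$n_bins[i])
  })
}

# global bin index from chromosome name + 1-based within-chromosome bin
global_bin <- function(layout, chrom, bin) {
  i <- match(chrom, layout$chrom$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  bad <- bin < 1 | bin > layout$chrom$n_bins[i]
  if (any(bad)) stop("bin index out of range for chromosome ", chrom[bad][1])
  layout$chrom$offset[i] + bin
}

#' Bin coordinate table for a layout
#'
#' @param layout a [genome_layout()].
#' @return data.frame with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open bp), in layout order.
#' @export
layout_bins <- function(layout) {
  out <- lapply(seq_len(nrow(layout$chrom)), function(i) {
    nb <- layout$chrom$n_bins[i]
    start <- (seq_len(nb) - 1) * layout$bin_width
    data.frame(chrom = layout$chrom$name[i],
               start = start,
               end   = pmin(start + layout$bin_width, layout$chrom$length_bp[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

same_layout <- function(a, b) {
  identical(a$bin_width, b$bin_width) &&
    identical(a$chrom$name, b$chrom$name) &&
    identical(a$chrom$length_bp, b$chrom$length_bp)
}

POLYMERASES <- c("delta", "epsilon", "alpha")

check_polymerase <- function(polymerase) {
  match.arg(polymerase, POLYMERASES)
}
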