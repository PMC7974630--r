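#' Select efficient replication origins
#'
#' Efficient origins are those with normalised firing efficiency of at
#' least `threshold_pct` percent (40% by default).
#'
#' @param origins origin-call data.frame from [call_origins()].
#' @param threshold_pct efficiency threshold in percent.
#' @return the retained origins, input order preserved.
#' @export
select_efficient_origins <- function(origins, threshold_pct = 40) {
  origins[origins$efficiency_norm >= threshold_pct, , drop = FALSE]
}

#' Select replication termination zones
#'
#' A termination zone is the interval between two adjacent efficient
#' origins (normalised efficiency strictly above `eff_hi`, no other
#' efficient origin between them) that contains no intermediary-efficiency
#' origin, i.e. no origin with `eff_lo < efficiency_norm < eff_hi` strictly
#' between the pair.  Origins at or below `eff_lo` do not disqualify a
#' zone.  Zones never span chromosomes.
#'
#' @param origins origin-call data.frame sorted by `(chrom, origin_bin)`.
#' @param eff_hi efficient-origin threshold in percent (flanks must exceed
#'   it; default 40).
#' @param eff_lo lower edge of the open intermediary-efficiency window
#'   (default 20).
#' @return data.frame of zones: `chrom`, `left_bin`, `right_bin` (flanking
#'   origin bins), `start_bin`, `end_bin` (interior span, exclusive of the
#'   origin bins), `midpoint_bin` (floor of the bin midpoint),
#'   `left_efficiency`, `right_efficiency`.
#' @export
select_termination_zones <- function(origins, eff_hi = 40, eff_lo = 20) {
  if (nrow(origins) > 1) {
    for (cc in unique(origins$chrom)) {
      pos <- origins$origin_bin[origins$chrom == cc]
      if (is.unsorted(pos, strictly = TRUE))
        stop("origins must be sorted by position within each chromosome")
    }
  }
  zones <- list()
  for (cc in unique(origins$chrom)) {
    sub <- origins[origins$chrom == cc, , drop = FALSE]
    eff <- which(sub$efficiency_norm > eff_hi)
    if (length(eff) < 2) next
    for (k in seq_len(length(eff) - 1)) {
      i <- eff[k]; j <- eff[k + 1]
      between <- if (j > i + 1) sub[(i + 1):(j - 1), , drop = FALSE] else sub[0, ]
      intermediary <- between$efficiency_norm > eff_lo &
        between$efficiency_norm < eff_hi
      if (any(intermediary)) next
      lb <- sub$origin_bin[i]; rb <- sub$origin_bin[j]
      zones[[length(zones) + 1]] <- data.frame(
        chrom = cc, left_bin = lb, right_bin = rb,
        start_bin = lb + 1L, end_bin = rb - 1L,
        midpoint_bin = as.integer(floor((lb + rb) / 2)),
        left_efficiency = sub$efficiency_norm[i],
        right_efficiency = sub$efficiency_norm[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(zones) == 0)
    return(data.frame(chrom = character(), left_bin = integer(),
                      right_bin = integer(), start_bin = integer(),
                      end_bin = integer(), midpoint_bin = integer(),
                      left_efficiency = numeric(), right_efficiency = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, zones)
  rownames(out) <- NULL
  out
}

#' Origin-centred meta-profile of polymerase tracks
#'
#' Aligns track windows of `2 * flank_bins + 1` bins on each origin
#' (chromosomal coordinates centred relative to the origin position) and
#' averages across origins per polymerase.  Origins whose flank would
#' extend past a chromosome end are dropped (their count is reported via a
#' message and in the result).
#'
#' @param tracks named list of `polymerase_track`s (any subset of
#'   `delta`, `epsilon`, `alpha`), all on the same layout.
#' @param origins origin-call data.frame.
#' @param flank_bins half-window width in bins (default 50, i.e. 15 kb at
#'   300 bp bins).
#' @return a `puseq_metaprofile`: `offsets` (-flank..+flank), `means`
#'   (data.frame `offset` x `polymerase` x `mean`), `matrices` (per
#'   polymerase, one aligned row per origin), `n_regions`, `n_dropped`.
#' @export
origin_metaprofile <- function(tracks, origins, flank_bins = 50) {
  if (flank_bins < 1) stop("flank_bins must be >= 1")
  layout <- tracks[[1]]$layout
  ci <- match(origins$chrom, layout$chrom$name)
  if (anyNA(ci)) stop("unknown chromosome in origins")
  ok <- origins$origin_bin - flank_bins >= 1 &
    origins$origin_bin + flank_bins <= layout$chrom$n_bins[ci]
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " origin(s) dropped: flank extends past a chromosome end")
  origins <- origins[ok, , drop = FALSE]
  if (nrow(origins) == 0) stop("no origin retained for the meta-profile")
  centres <- global_bin(layout, origins$chrom, origins$origin_bin)
  offsets <- -flank_bins:flank_bins
  matrices <- lapply(tracks, function(tr) {
    m <- t(vapply(centres, function(g) tr$values[g + offsets],
                  numeric(length(offsets))))
    colnames(m) <- offsets
    m
  })
  build_metaprofile(matrices, offsets, nrow(origins), n_dropped, "origin")
}

#' Rescaled termination-zone meta-profile
#'
#' Each zone's per-bin track values are rescaled to `n_rescaled_bins`
#' equal-width bins by overlap-weighted averaging of the original bins, so
#' zones of different lengths become comparable; rescaled bins are centred
#' relative to the zone midpoint (offsets `-n/2 .. n/2 - 1`) and averaged
#' across zones per polymerase.  Zones shorter than `n_rescaled_bins / 2`
#' original bins are dropped (count reported).
#'
#' @param tracks named list of `polymerase_track`s on one layout.
#' @param zones zone data.frame from [select_termination_zones()].
#' @param n_rescaled_bins even number of rescaled bins per zone (default 20).
#' @return a `puseq_metaprofile` (see [origin_metaprofile()]).
#' @export
termination_metaprofile <- function(tracks, zones, n_rescaled_bins = 20) {
  if (n_rescaled_bins < 2 || n_rescaled_bins %% 2 != 0)
    stop("n_rescaled_bins must be a positive even integer")
  layout <- tracks[[1]]$layout
  len <- zones$end_bin - zones$start_bin + 1L
  ok <- len >= n_rescaled_bins / 2
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " zone(s) dropped: shorter than ",
            n_rescaled_bins / 2, " bins")
  zones <- zones[ok, , drop = FALSE]
  if (nrow(zones) == 0) stop("no termination zone retained for the meta-profile")
  offsets <- seq(-n_rescaled_bins / 2, n_rescaled_bins / 2 - 1)
  matrices <- lapply(tracks, function(tr) {
    m <- t(mapply(function(chrom, s, e) {
      g <- global_bin(layout, chrom, s):global_bin(layout, chrom, e)
      rescale_bins(tr$values[g], n_rescaled_bins)
    }, zones$chrom, zones$start_bin, zones$end_bin))
    colnames(m) <- offsets
    rownames(m) <- NULL
    m
  })
  build_metaprofile(matrices, offsets, nrow(zones), n_dropped, "termination")
}

# Overlap-weighted block average of v onto n equal-width bins.  Exactly
# conserves the mean of v and reduces to plain block means when length(v)
# is a multiple of n.
rescale_bins <- function(v, n) {
  L <- length(v)
  edges <- seq(0, L, length.out = n + 1)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- edges[k]; hi <- edges[k + 1]
    j <- seq(floor(lo) + 1, ceiling(hi))     # original bins touching [lo, hi)
    j <- j[j >= 1 & j <= L]
    w <- pmin(hi, j) - pmax(lo, j - 1)       # overlap of bin j with [lo, hi)
    out[k] <- sum(w * v[j]) / sum(w)
  }
  out
}

build_metaprofile <- function(matrices, offsets, n_regions, n_dropped, mode) {
  means <- do.call(rbind, lapply(names(matrices), function(nm) {
    data.frame(offset = offsets, polymerase = nm,
               mean = colMeans(matrices[[nm]]),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  structure(list(offsets = offsets, means = means, matrices = matrices,
                 n_regions = n_regions, n_dropped = n_dropped, mode = mode),
            class = "puseq_metaprofile")
}

#' @export
print.puseq_metaprofile <- function(x, ...) {
  cat(sprintf("<puseq_metaprofile> %s mode, %d region(s), offsets %d..%d, polymerases: %s\n",
              x$mode, x$n_regions, min(x$offsets), max(x$offsets),
              paste(names(x$matrices), collapse = ", ")))
  invisible(x)
}

#' Plot a meta-profile
#'
#' Mean track value per offset, one line per polymerase (base graphics).
#'
#' @param x a `puseq_metaprofile`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.puseq_metaprofile <- function(x, ...) {
  wide <- vapply(names(x$matrices),
                 function(nm) x$means$mean[x$means$polymerase == nm],
                 numeric(length(x$offsets)))
  graphics::matplot(x$offsets, wide, type = "l", lty = 1,
                    xlab = if (x$mode == "origin")
                      "bins from origin" else "rescaled bins from zone midpoint",
                    ylab = "mean polymerase track", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::legend("topleft", legend = names(x$matrices), lty = 1,
                   col = seq_along(x$matrices), bty = "n")
  invisible(x)
}

#' Histogram of normalised origin efficiencies
#'
#' Counts origins per half-open efficiency bin `[e_i, e_{i+1})`; values
#' outside the edge range are excluded.
#'
#' @param origins origin-call data.frame.
#' @param bin_edges strictly increasing numeric edges (e.g.
#'   `seq(0, 100.01, by = 10)`).
#' @return data.frame `lower`, `upper`, `count`.
#' @export
efficiency_distribution <- function(origins,
                                    bin_edges = seq(0, 100 + 1e-9, length.out = 11)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  k <- length(bin_edges) - 1
  x <- origins$efficiency_norm
  x <- x[x >= bin_edges[1] & x < bin_edges[k + 1]]
  counts <- tabulate(findInterval(x, bin_edges), nbins = k)
  data.frame(lower = bin_edges[-(k + 1)], upper = bin_edges[-1],
             count = counts)
}
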