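#' Differentiate a polymerase track
#'
#' The track is first smoothed per chromosome with a centred simple moving
#' average ([sma()], window 3 by default); the differential is then the
#' difference of neighbouring smoothed values, `Diff_i = PT_i - PT_{i-1}`,
#' computed per chromosome.  The differential of the first bin of each
#' chromosome is assigned 0 — no difference is ever taken across a
#' chromosome boundary.
#'
#' @param track a `polymerase_track`.
#' @param window SMA window applied before differencing (1 disables
#'   smoothing).
#' @return per-bin differential values (numeric vector in global bin order).
#' @export
differentiate <- function(track, window = 3) {
  v <- sma_by_chrom(track$values, track$layout, window)
  out <- numeric(length(v))
  for (idx in chrom_slices(track$layout)) {
    out[idx] <- c(0, diff(v[idx]))
  }
  out
}

#' Combine per-polymerase differentials into one origin signal
#'
#' Around an active origin the Pol epsilon track rises while the Pol delta
#' and Pol alpha tracks fall, so the epsilon differential and the
#' *opposites* of the delta and alpha differentials all peak together.  The
#' three are averaged per bin and the result smoothed once more with a
#' window-3 moving average (per chromosome).
#'
#' @param diff_epsilon,diff_delta,diff_alpha per-bin differential vectors
#'   from [differentiate()], all on `layout`'s bin grid.
#' @param layout the shared [genome_layout()].
#' @param window SMA window for the post-combination smooth.
#' @return a `differential_signal`: `layout`, per-bin `values`, and the
#'   `provenance` of contributing polymerases.
#' @export
combine_differentials <- function(diff_epsilon, diff_delta, diff_alpha,
                                  layout, window = 3) {
  n <- layout$n_bins
  if (length(diff_epsilon) != n || length(diff_delta) != n ||
      length(diff_alpha) != n)
    stop("differential length mismatch with layout")
  comb <- (diff_epsilon - diff_delta - diff_alpha) / 3
  comb <- sma_by_chrom(comb, layout, window)
  structure(list(layout = layout, values = comb,
                 provenance = c("epsilon", "delta", "alpha")),
            class = "differential_signal")
}

#' Differential origin signal from the three polymerase tracks
#'
#' Convenience wrapper: differentiates the (replicate-averaged) Pol epsilon,
#' Pol delta and Pol alpha tracks and combines them with
#' [combine_differentials()].
#'
#' @param tracks named list with elements `epsilon`, `delta`, `alpha`, each
#'   a `polymerase_track` on the same layout.
#' @param window SMA window used both before differencing and after
#'   combination.
#' @return a `differential_signal`.
#' @export
origin_signal <- function(tracks, window = 3) {
  need <- c("epsilon", "delta", "alpha")
  if (!all(need %in% names(tracks)))
    stop("tracks must be a named list with epsilon, delta and alpha")
  layout <- tracks$epsilon$layout
  for (nm in need) {
    if (!same_layout(tracks[[nm]]$layout, layout))
      stop("tracks have mismatched layouts")
  }
  combine_differentials(differentiate(tracks$epsilon, window),
                        differentiate(tracks$delta, window),
                        differentiate(tracks$alpha, window),
                        layout, window)
}

#' @export
print.differential_signal <- function(x, ...) {
  cat(sprintf("<differential_signal> %d bins, %d positive\n",
              x$layout$n_bins, sum(x$values > 0)))
  invisible(x)
}

#' Detect positive differential peaks
#'
#' Candidate peaks are maximal runs of strictly positive differential
#' values (sharp inclines in the combined track data).  Within a run, local
#' maxima are bins at least as high as both in-run neighbours, with plateaus
#' counted once at their leftmost bin; whenever two successive maxima are
#' separated by at least `min_separation` bins (index distance), the run is
#' split into independent peaks at the minimum-value bin between them, the
#' minimum bin going to the left peak.  Runs never span chromosomes.
#'
#' @param signal a `differential_signal` (or a bare numeric vector treated
#'   as one chromosome).
#' @param min_separation minimum index distance between distinct maxima for
#'   a split (default 4 bins).
#' @param positive_tol values must exceed this floor to count as positive
#'   (default 1e-9); it absorbs the sub-ulp residue that floating-point
#'   smoothing leaves on numerically constant track segments, which would
#'   otherwise surface as spurious zero-height peaks.
#' @return data.frame of peaks: `chrom`, `start_bin`, `end_bin` (1-based
#'   inclusive bin span within the chromosome), `max_bin`, `max_value`,
#'   `sum_values`.
#' @export
detect_peaks <- function(signal, min_separation = 4, positive_tol = 1e-9) {
  if (is.numeric(signal)) {
    res <- detect_peaks_chrom(signal, min_separation, positive_tol)
    res <- cbind(chrom = rep("chr", nrow(res)), res)
    return(res)
  }
  layout <- signal$layout
  slices <- chrom_slices(layout)
  out <- lapply(seq_along(slices), function(k) {
    res <- detect_peaks_chrom(signal$values[slices[[k]]], min_separation,
                              positive_tol)
    cbind(chrom = rep(layout$chrom$name[k], nrow(res)), res)
  })
  do.call(rbind, out)
}

detect_peaks_chrom <- function(v, min_separation, positive_tol = 1e-9) {
  empty <- data.frame(start_bin = integer(), end_bin = integer(),
                      max_bin = integer(), max_value = numeric(),
                      sum_values = numeric())
  pos <- v > positive_tol
  if (!any(pos)) return(empty)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  peaks <- list()
  for (k in runs) {
    s <- starts[k]; e <- ends[k]
    for (span in split_run(v, s, e, min_separation)) {
      seg <- v[span[1]:span[2]]
      mb <- span[1] + which.max(seg) - 1
      peaks[[length(peaks) + 1]] <- data.frame(
        start_bin = span[1], end_bin = span[2],
        max_bin = mb, max_value = v[mb], sum_values = sum(seg))
    }
  }
  do.call(rbind, c(list(empty), peaks))
}

# local maxima of v within [s, e]: >= both in-run neighbours, plateaus
# counted once at their leftmost bin
run_maxima <- function(v, s, e) {
  idx <- s:e
  is_max <- vapply(idx, function(i) {
    (i == s || v[i] > v[i - 1]) && (i == e || v[i] >= v[i + 1])
  }, logical(1))
  idx[is_max]
}

# split a positive run into independent peak spans: one split at the
# minimum-value bin between each pair of successive maxima >= min_sep apart
split_run <- function(v, s, e, min_sep) {
  m <- run_maxima(v, s, e)
  bounds <- s  # left edges of the child spans
  if (length(m) >= 2) {
    for (k in seq_len(length(m) - 1)) {
      if (m[k + 1] - m[k] >= min_sep) {
        between <- (m[k] + 1):(m[k + 1] - 1)
        cut <- between[which.min(v[between])]  # leftmost minimum
        bounds <- c(bounds, cut + 1)           # min bin goes to the left peak
      }
    }
  }
  ends <- c(bounds[-1] - 1, e)
  Map(c, bounds, ends)
}

#' Filter peaks by the percentile of their maxima
#'
#' Computes the given percentile of the distribution of peak maxima over
#' all candidate peaks genome-wide (linear interpolation between order
#' statistics, i.e. `stats::quantile(type = 7)`) and retains peaks whose
#' maximum is at or above that threshold.  Peaks with maxima below the 30th
#' percentile are disregarded by default.
#'
#' @param peaks peak data.frame from [detect_peaks()].
#' @param percentile threshold percentile in `[0, 100]`.
#' @return the retained peaks (same columns).
#' @export
filter_peaks <- function(peaks, percentile = 30) {
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  if (nrow(peaks) == 0) {
    warning("no candidate peaks to filter")
    return(peaks)
  }
  thr <- stats::quantile(peaks$max_value, percentile / 100, type = 7,
                         names = FALSE)
  peaks[peaks$max_value >= thr, , drop = FALSE]
}

#' Call replication origins from a differential signal
#'
#' Each independent differential peak surviving the percentile filter is an
#' origin of replication; its firing efficiency is estimated as 50% of the
#' sum of the peak's differential values (the differential telescopes the
#' polymerase-track step across the origin, which is twice the fraction of
#' cells firing there).  Efficiencies are also normalised so the most
#' efficient origin in the set is 100%.
#'
#' @param signal a `differential_signal` from [origin_signal()].
#' @param percentile peak-maximum percentile filter (default 30).
#' @param min_separation distinct-maxima separation for peak splitting
#'   (default 4 bins).
#' @return data.frame of origin calls sorted by `(chrom, origin_bin)`:
#'   `chrom`, `origin_bin` (bin of the peak maximum, 1-based),
#'   `start_bin`, `end_bin`, `max_value`, `sum_values`, `efficiency_raw`
#'   (fraction scale), `efficiency_norm` (percent of the most efficient
#'   origin).
#' @export
call_origins <- function(signal, percentile = 30, min_separation = 4) {
  peaks <- detect_peaks(signal, min_separation)
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), origin_bin = integer(),
                      start_bin = integer(), end_bin = integer(),
                      max_value = numeric(), sum_values = numeric(),
                      efficiency_raw = numeric(), efficiency_norm = numeric(),
                      stringsAsFactors = FALSE))
  }
  peaks <- filter_peaks(peaks, percentile)
  origins <- data.frame(
    chrom = peaks$chrom, origin_bin = peaks$max_bin,
    start_bin = peaks$start_bin, end_bin = peaks$end_bin,
    max_value = peaks$max_value, sum_values = peaks$sum_values,
    efficiency_raw = 0.5 * peaks$sum_values,
    stringsAsFactors = FALSE)
  chrom_rank <- match(origins$chrom, signal$layout$chrom$name)
  origins <- origins[order(chrom_rank, origins$origin_bin), , drop = FALSE]
  rownames(origins) <- NULL
  normalise_efficiencies(origins)
}

#' Normalise origin efficiencies to the most efficient origin
#'
#' For comparison across strains, efficiencies are rescaled assuming the
#' most efficient origin fires in 100% of cells:
#' `efficiency_norm = 100 * efficiency_raw / max(efficiency_raw)`.
#'
#' @param origins origin-call data.frame with an `efficiency_raw` column.
#' @return the same data.frame with `efficiency_norm` set.
#' @export
normalise_efficiencies <- function(origins) {
  if (nrow(origins) == 0) stop("cannot normalise an empty origin set")
  origins$efficiency_norm <- 100 * origins$efficiency_raw /
    max(origins$efficiency_raw)
  origins
}
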