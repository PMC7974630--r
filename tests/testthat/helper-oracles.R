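# Independent brute-force oracles used to validate the vectorised
# implementations, plus small fixture builders.

# --- peak-detection oracle -------------------------------------------------
# Direct, loop-based reading of the peak rules: maximal strictly-positive
# runs; local maxima (>= both in-run neighbours, plateaus once at their
# leftmost bin) enumerated by explicit scan; one cut at the leftmost
# minimum between every pair of successive maxima at index distance >=
# min_sep, the cut bin going to the left child.
oracle_detect_peaks <- function(v, min_sep = 4, tol = 1e-9) {
  peaks <- list()
  i <- 1
  n <- length(v)
  while (i <= n) {
    if (v[i] <= tol) { i <- i + 1; next }
    s <- i
    while (i <= n && v[i] > tol) i <- i + 1
    e <- i - 1
    # maxima by explicit scan
    maxima <- integer(0)
    for (m in s:e) {
      left_ok <- (m == s) || (v[m] > v[m - 1])
      right_ok <- (m == e) || (v[m] >= v[m + 1])
      if (left_ok && right_ok) maxima <- c(maxima, m)
    }
    # cut points between qualifying successive maxima
    cuts <- integer(0)
    if (length(maxima) >= 2) {
      for (k in 1:(length(maxima) - 1)) {
        if (maxima[k + 1] - maxima[k] >= min_sep) {
          best <- maxima[k] + 1
          for (m in (maxima[k] + 1):(maxima[k + 1] - 1)) {
            if (v[m] < v[best]) best <- m
          }
          cuts <- c(cuts, best)
        }
      }
    }
    span_starts <- c(s, cuts + 1)
    span_ends <- c(cuts, e)
    for (k in seq_along(span_starts)) {
      ss <- span_starts[k]; ee <- span_ends[k]
      mb <- ss
      for (m in ss:ee) if (v[m] > v[mb]) mb <- m
      peaks[[length(peaks) + 1]] <- data.frame(
        start_bin = ss, end_bin = ee, max_bin = mb,
        max_value = v[mb], sum_values = sum(v[ss:ee]))
    }
  }
  if (length(peaks) == 0)
    return(data.frame(start_bin = integer(), end_bin = integer(),
                      max_bin = integer(), max_value = numeric(),
                      sum_values = numeric()))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

# --- population-simulation oracle ------------------------------------------
# Event-driven single-cell simulator: replays the engine's firing-time
# draws (same seed, same stream order), then walks every cell and bin
# naively.  Tie conventions mirror the engine: right-moving arrivals scan
# origins left-to-right keeping the first minimiser, left-moving arrivals
# scan right-to-left; the same origin winning both directions means
# in-place firing (half a fork each way); any other exact tie goes to the
# leftward-moving fork.
oracle_population <- function(program, n_cells, seed) {
  layout <- program$layout
  stopifnot(nrow(layout$chrom) == 1)
  o <- program$origins$position_bin
  p <- program$origins$p
  tau <- program$origins$tau
  v <- program$fork_speed
  J <- length(o)
  n_bins <- layout$chrom$n_bins[1]
  set.seed(as.integer(seed))
  t <- puseqr:::draw_firing_times(p, tau, n_cells, program$time_model)

  right_w <- numeric(n_bins)   # accumulated rightward weight per bin
  denom <- numeric(n_bins)
  fired_active <- numeric(J)
  for (cell in seq_len(n_cells)) {
    tc <- t[cell, ]
    for (x in seq_len(n_bins)) {
      # best right-moving arrival (origins at or left of x)
      jR <- 0L; bestR <- Inf
      for (j in seq_len(J)) {
        if (o[j] > x) break
        cand <- tc[j] - o[j] / v
        if (cand < bestR) { bestR <- cand; jR <- j }
      }
      tR <- if (jR > 0) x / v + bestR else Inf
      # best left-moving arrival (origins at or right of x)
      jL <- 0L; bestL <- Inf
      for (j in rev(seq_len(J))) {
        if (o[j] < x) break
        cand <- tc[j] + o[j] / v
        if (cand < bestL) { bestL <- cand; jL <- j }
      }
      tL <- if (jL > 0) -x / v + bestL else Inf
      if (!is.finite(tR) && !is.finite(tL)) next  # unreplicated cell
      denom[x] <- denom[x] + 1
      if (jR > 0 && jR == jL) {
        right_w[x] <- right_w[x] + 0.5
      } else if (tR < tL) {
        right_w[x] <- right_w[x] + 1
      }
    }
    for (j in seq_len(J)) {
      if (!is.finite(tc[j])) next
      arr <- Inf
      for (i in seq_len(J)) {
        if (i != j) arr <- min(arr, tc[i] + abs(o[j] - o[i]) / v)
      }
      if (tc[j] < arr) fired_active[j] <- fired_active[j] + 1
    }
  }
  list(f_right = ifelse(denom > 0, right_w / denom, NA_real_),
       realized = fired_active / n_cells)
}

# Merge origin calls that came from splitting one positive run (adjacent
# spans with no gap) back into their parent run: the parent's span, summed
# efficiency and strongest-maximum bin are mirror-symmetric even though the
# split tie-break (minimum bin to the left child) is not.
merge_split_families <- function(origins) {
  if (nrow(origins) == 0) return(origins)
  fam <- cumsum(c(TRUE, !(origins$chrom[-1] == origins$chrom[-nrow(origins)] &
                            origins$start_bin[-1] ==
                              origins$end_bin[-nrow(origins)] + 1)))
  out <- lapply(split(origins, fam), function(g) {
    data.frame(chrom = g$chrom[1],
               origin_bin = g$origin_bin[which.max(g$max_value)],
               start_bin = min(g$start_bin), end_bin = max(g$end_bin),
               efficiency_raw = sum(g$efficiency_raw))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# --- fixture builders -------------------------------------------------------
make_layout <- function(n_bins, bin_width = 300, names = "chrI") {
  if (length(n_bins) != length(names)) names <- paste0("chr", seq_along(n_bins))
  genome_layout(stats::setNames(n_bins * bin_width, names), bin_width)
}

# noise-free analytic fork-direction profile for one isolated origin
analytic_f_right <- function(n_bins, origin_bin, efficiency) {
  f <- rep(0.5 - efficiency / 2, n_bins)
  f[origin_bin] <- 0.5
  if (origin_bin < n_bins)
    f[(origin_bin + 1):n_bins] <- 0.5 + efficiency / 2
  f
}

# exact expected tracks for all three polymerases from an f_right vector
analytic_tracks <- function(layout, f_right) {
  pols <- c("delta", "epsilon", "alpha")
  stats::setNames(lapply(pols, function(p)
    polymerase_track(layout, p, expected_track(f_right, p))), pols)
}

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  path
}
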