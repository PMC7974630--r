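#' Construct a polymerase track
#'
#' @param layout a [genome_layout()].
#' @param polymerase one of `"delta"`, `"epsilon"`, `"alpha"`.
#' @param values per-bin PT values in `[-1, 1]`.
#' @param low_coverage per-bin logical flag; flagged bins carry value 0.
#' @return a `polymerase_track`.
#' @export
polymerase_track <- function(layout, polymerase, values,
                             low_coverage = rep(FALSE, length(values))) {
  polymerase <- check_polymerase(polymerase)
  if (length(values) != layout$n_bins)
    stop("track must have exactly one value per bin")
  if (any(abs(values) > 1 + 1e-12))
    stop("polymerase track values must lie in [-1, 1]")
  values[low_coverage] <- 0
  structure(
    list(layout = layout, polymerase = polymerase,
         values = as.numeric(values), low_coverage = as.logical(low_coverage)),
    class = "polymerase_track"
  )
}

#' @export
print.polymerase_track <- function(x, ...) {
  cat(sprintf("<polymerase_track> Pol%s: %d bins, %d low-coverage\n",
              x$polymerase, x$layout$n_bins, sum(x$low_coverage)))
  invisible(x)
}

#' Compute a polymerase track from strand counts
#'
#' The polymerase track at each bin is the strand bias of rNMP counts,
#' `PT = (R_T - R_B) / (R_T + R_B)`, where `R_T` and `R_B` are the rNMPs
#' mapped to the top and bottom strand.  Positive values indicate
#' predominant activity of that polymerase on the top strand.  Bins with no
#' coverage (`R_T + R_B = 0`) get `PT = 0` and are flagged `low_coverage` so
#' downstream differentials stay defined while remaining auditable.
#'
#' @param counts a `binned_strand_counts` object (see [read_counts()]).
#' @return a `polymerase_track`.
#' @export
compute_track <- function(counts) {
  tot <- counts$top + counts$bottom
  low <- tot == 0
  pt <- numeric(length(tot))
  pt[!low] <- (counts$top[!low] - counts$bottom[!low]) / tot[!low]
  polymerase_track(counts$layout, counts$polymerase, pt, low)
}

#' Average polymerase tracks over biological replicates
#'
#' Tracks are computed per biological repeat and then averaged (per-bin
#' arithmetic mean).  The low-coverage flag of the average is the union of
#' the replicate flags, and flagged bins carry value 0.
#'
#' @param tracks list of `polymerase_track`s on the same layout and for the
#'   same polymerase.
#' @return a `polymerase_track`.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) < 1) stop("at least one track is required")
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (!same_layout(tr$layout, ref$layout))
      stop("tracks have mismatched layouts")
    if (tr$polymerase != ref$polymerase)
      stop("tracks have mismatched polymerases")
  }
  vals <- rowMeans(vapply(tracks, `[[`, numeric(ref$layout$n_bins), "values"))
  low <- Reduce(`|`, lapply(tracks, `[[`, "low_coverage"))
  polymerase_track(ref$layout, ref$polymerase, vals, low)
}

#' Centred simple moving average
#'
#' The smoother used throughout the pipeline (window 3 by default), applied
#' per chromosome — never across chromosome boundaries.  At chromosome edges
#' the window truncates to the available bins (e.g. the first bin of a
#' window-3 smooth is the mean of bins 1-2), which avoids manufacturing
#' artificial steps at chromosome ends.
#'
#' @param values numeric vector (one chromosome's worth of bins).
#' @param window odd positive integer window size.
#' @return smoothed vector of the same length.
#' @examples
#' sma(c(0, 3, 0))  # 1.5 1.0 1.5
#' @export
sma <- function(values, window = 3) {
  if (length(window) != 1 || window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer")
  n <- length(values)
  if (n == 0 || window == 1) return(values)
  half <- (window - 1) / 2
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  cs <- c(0, cumsum(values))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# apply sma per chromosome of a layout-indexed vector
sma_by_chrom <- function(values, layout, window = 3) {
  for (idx in chrom_slices(layout)) values[idx] <- sma(values[idx], window)
  values
}
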