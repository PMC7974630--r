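#' Run the Pu-Seq origin-calling pipeline on a set of count tables
#'
#' Convenience wrapper covering the full analysis: per-replicate polymerase
#' tracks ([compute_track()]), replicate averaging
#' ([average_replicates()]), the combined differential origin signal
#' ([origin_signal()]) and origin calling with efficiency estimation and
#' normalisation ([call_origins()]).  All three polymerase datasets
#' (delta, epsilon, alpha) must be present.
#'
#' @param counts list of `binned_strand_counts` (all replicates of all
#'   three polymerases, e.g. from [read_counts()] or [simulate_puseq()]).
#' @param percentile peak-maximum percentile filter (default 30).
#' @param min_separation distinct-maxima separation for peak splitting
#'   (default 4 bins).
#' @param window SMA window (default 3).
#' @return list with `tracks` (named list of replicate-averaged
#'   `polymerase_track`s), `signal` (the `differential_signal`) and
#'   `origins` (origin-call data.frame).
#' @export
puseq_pipeline <- function(counts, percentile = 30, min_separation = 4,
                           window = 3) {
  pols <- vapply(counts, `[[`, character(1), "polymerase")
  missing <- setdiff(POLYMERASES, unique(pols))
  if (length(missing) > 0)
    stop("missing polymerase dataset(s): ", paste(missing, collapse = ", "))
  tracks <- lapply(stats::setNames(POLYMERASES, POLYMERASES), function(pol) {
    average_replicates(lapply(counts[pols == pol], compute_track))
  })
  signal <- origin_signal(tracks, window = window)
  origins <- call_origins(signal, percentile = percentile,
                          min_separation = min_separation)
  list(tracks = tracks, signal = signal, origins = origins)
}
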