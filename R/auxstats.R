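#' RT-qPCR relative transcript level
#'
#' Relative transcript level of a target gene against a reference gene
#' (e.g. *act1*) from quantification-cycle values:
#' `RNA_target = 2^-Cq(target) / 2^-Cq(reference) = 2^(Cq(reference) - Cq(target))`.
#' Vectorised; invariant to adding a constant to both Cq values.
#'
#' @param cq_target Cq of the target gene (cycles, finite).
#' @param cq_reference Cq of the reference gene (cycles, finite).
#' @return relative transcript level(s).
#' @examples
#' relative_transcript_level(20, 21)  # 2: target one cycle earlier
#' @export
relative_transcript_level <- function(cq_target, cq_reference) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference)))
    stop("Cq values must be finite")
  2^(cq_reference - cq_target)
}

#' Culture doubling time from an OD time series
#'
#' Fits an ordinary least-squares line to log2-transformed optical density
#' against time; the doubling time is `DT = 1/k` where `k` is the slope in
#' doublings per hour.  The series must lie in the exponential growth range
#' (and be corrected for any dilutions) — the fit itself is unweighted, as
#' is standard for log-linear growth curves.
#'
#' @param times sampling times in hours, strictly increasing, length >= 3.
#' @param od optical densities (> 0).
#' @return list with `k` (slope, doublings/h) and `doubling_time` (hours).
#' @examples
#' doubling_time(0:3, c(0.1, 0.2, 0.4, 0.8))  # k = 1, DT = 1 h
#' @export
doubling_time <- function(times, od) {
  if (length(times) != length(od) || length(times) < 3)
    stop("need >= 3 paired (time, od) measurements")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(od <= 0)) stop("optical densities must be positive")
  k <- unname(stats::coef(stats::lm(log2(od) ~ times))[2])
  if (k <= 0) stop("non-growing culture: slope k = ", signif(k, 3))
  list(k = k, doubling_time = 1 / k)
}
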