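test_that("differentiation is per chromosome with first bin assigned zero", {
  lay <- make_layout(c(3, 3), names = c("chrI", "chrII"))
  tr <- polymerase_track(lay, "epsilon", c(0.1, 0.3, 0.2, 0.5, 0.5, 0.1))
  d <- differentiate(tr, window = 1)  # window 1: difference the raw values
  expect_equal(d, c(0, 0.2, -0.1, 0, 0, -0.4))
  # constant track differentiates to zero everywhere
  flat <- polymerase_track(lay, "epsilon", rep(0.4, 6))
  expect_equal(differentiate(flat), rep(0, 6))
})

test_that("differentiation smooths with SMA 3 before differencing", {
  lay <- make_layout(6)
  v <- c(0, 0, 1, 1, 0, 0)
  tr <- polymerase_track(lay, "epsilon", v)
  s <- sma(v, 3)
  expect_equal(differentiate(tr), c(0, diff(s)))
})

test_that("combining differentials averages epsilon against negated delta/alpha", {
  lay <- make_layout(5)
  de <- rep(0.3, 5); dd <- rep(-0.3, 5); da <- rep(-0.3, 5)
  sig <- combine_differentials(de, dd, da, lay)
  expect_equal(sig$values, rep(0.3, 5))  # flat neighbours: SMA is identity
  sig2 <- combine_differentials(rep(0.3, 5), rep(-0.1, 5), rep(-0.2, 5), lay)
  expect_equal(sig2$values, rep(0.2, 5))
  sig0 <- combine_differentials(rep(0, 5), rep(0, 5), rep(0, 5), lay)
  expect_equal(sig0$values, rep(0, 5))
  expect_error(combine_differentials(rep(0, 4), rep(0, 5), rep(0, 5), lay),
               "mismatch")
})

test_that("a single positive run yields one peak with span, max and sum", {
  p <- detect_peaks(c(-0.1, 0.2, 0.5, 0.1, -0.2))
  expect_equal(nrow(p), 1)
  expect_equal(p$start_bin, 2)
  expect_equal(p$end_bin, 4)
  expect_equal(p$max_bin, 3)
  expect_equal(p$max_value, 0.5)
  expect_equal(p$sum_values, 0.8)
})

test_that("distinct maxima four bins apart split a run at the minimum", {
  v <- c(0.1, 0.5, 0.1, 0.05, 0.1, 0.6, 0.1)  # maxima at 2 and 6, distance 4
  p <- detect_peaks(v)
  expect_equal(nrow(p), 2)
  expect_equal(p$start_bin, c(1, 5))  # cut at bin 4 (run minimum), left peak keeps it
  expect_equal(p$end_bin, c(4, 7))
  expect_equal(p$max_value, c(0.5, 0.6))
  expect_equal(sum(p$sum_values), sum(v))  # the split conserves the total sum
  expect_equal(p[, -1], oracle_detect_peaks(v), ignore_attr = TRUE)
})

test_that("maxima closer than four bins stay one peak", {
  v <- c(0.1, 0.5, 0.1, 0.6, 0.1)  # maxima at 2 and 4, distance 2
  p <- detect_peaks(v)
  expect_equal(nrow(p), 1)
  expect_equal(p$max_value, 0.6)
})

test_that("peaks never span chromosome boundaries", {
  lay <- make_layout(c(3, 3), names = c("chrI", "chrII"))
  sig <- structure(list(layout = lay, values = c(0.1, 0.2, 0.3, 0.3, 0.2, 0.1),
                        provenance = "test"), class = "differential_signal")
  p <- detect_peaks(sig)
  expect_equal(p$chrom, c("chrI", "chrII"))
  expect_equal(p$start_bin, c(1, 1))
  expect_equal(p$end_bin, c(3, 3))
})

test_that("peak detection matches the brute-force oracle on random vectors", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(5:30, 1)
    v <- round(rnorm(n, mean = 0.1, sd = 0.3), 3)
    expect_equal(detect_peaks(v)[, -1], oracle_detect_peaks(v),
                 ignore_attr = TRUE)
  }
})

test_that("the percentile filter interpolates between order statistics", {
  peaks <- data.frame(chrom = "chrI", start_bin = 1:10 * 10,
                      end_bin = 1:10 * 10 + 2, max_bin = 1:10 * 10 + 1,
                      max_value = 1:10, sum_values = 1:10 * 2)
  kept <- filter_peaks(peaks, 30)
  expect_equal(quantile(1:10, 0.3, type = 7, names = FALSE), 3.7)
  expect_equal(nrow(kept), 7)  # threshold 3.7 keeps maxima 4..10
  expect_equal(kept$max_value, 4:10)
  expect_equal(nrow(filter_peaks(peaks, 0)), 10)
  same <- peaks; same$max_value <- rep(2, 10)
  expect_equal(nrow(filter_peaks(same, 30)), 10)  # all equal: all retained
  expect_warning(out <- filter_peaks(peaks[0, ], 30), "no candidate")
  expect_equal(nrow(out), 0)
})

test_that("origin efficiency is half the summed peak differential", {
  lay <- make_layout(7)
  sig <- structure(list(layout = lay,
                        values = c(0, 0, 0.2, 0.4, 0.2, 0, 0),
                        provenance = "test"), class = "differential_signal")
  o <- call_origins(sig)
  expect_equal(o$efficiency_raw, 0.4)  # 0.5 * 0.8
  expect_equal(o$origin_bin, 4)
  expect_equal(o$efficiency_norm, 100)
})

test_that("an all-negative signal yields no origins", {
  lay <- make_layout(5)
  sig <- structure(list(layout = lay, values = rep(-0.2, 5),
                        provenance = "test"), class = "differential_signal")
  expect_equal(nrow(call_origins(sig)), 0)
})

test_that("the analytic pipeline identity recovers the realized efficiency", {
  lay <- make_layout(200)
  for (e in c(0.2, 0.5, 0.9)) {
    tracks <- analytic_tracks(lay, analytic_f_right(200, 100, e))
    o <- call_origins(origin_signal(tracks))
    expect_equal(nrow(o), 1)
    expect_lt(abs(o$efficiency_raw - e), 1e-6)
    expect_lt(abs(o$origin_bin - 100), 3)
  }
})

test_that("normalisation scales the most efficient origin to 100%", {
  o <- data.frame(chrom = "chrI", origin_bin = c(10, 20, 30),
                  efficiency_raw = c(0.5, 0.4, 0.25))
  n <- normalise_efficiencies(o)
  expect_equal(n$efficiency_norm, c(100, 80, 50))
  single <- normalise_efficiencies(o[1, ])
  expect_equal(single$efficiency_norm, 100)
  two <- normalise_efficiencies(data.frame(efficiency_raw = c(0.3, 0.3)))
  expect_equal(two$efficiency_norm, c(100, 100))
  expect_error(normalise_efficiencies(o[0, ]), "empty")
})

test_that("origin calls shift exactly with a translation of the program", {
  lay <- make_layout(300)
  e <- 0.7
  for (k in c(0, 17)) {
    tracks <- analytic_tracks(lay, analytic_f_right(300, 120 + k, e))
    o <- call_origins(origin_signal(tracks))
    if (k == 0) base_bin <- o$origin_bin
    else expect_equal(o$origin_bin, base_bin + k)
  }
})

test_that("mirroring the genome mirrors origin calls with equal efficiencies", {
  # the forced zero at each chromosome's first differential bin makes the
  # two chromosome ends inequivalent, so the mirror property is asserted
  # for interior origins (> 10 bins from an end); the differential at bin i
  # measures the step between bins i-1 and i, so the mirrored call sits at
  # n + 2 - origin_bin
  # peak splitting itself assigns the boundary bin to the left child, which
  # is not mirror-symmetric, so split families are merged before comparing
  # (the family span and summed efficiency are mirror-invariant); percentile
  # 0 keeps families complete
  prog <- example_program()
  sim <- simulate_puseq(prog, noise_model(80, 0.05), n_cells = 3000,
                        replicates = 2, seed = 13)
  res <- puseq_pipeline(sim$counts, percentile = 0)
  n <- prog$layout$n_bins
  mirrored <- lapply(sim$counts, function(x)
    binned_strand_counts(x$layout, x$strain, x$polymerase, x$replicate,
                         rev(x$bottom), rev(x$top)))
  res_m <- puseq_pipeline(mirrored, percentile = 0)
  fwd <- merge_split_families(res$origins)
  mir <- merge_split_families(res_m$origins)
  # the window [12, n - 10] maps onto itself under o -> n + 2 - o
  fwd <- fwd[fwd$origin_bin >= 12 & fwd$origin_bin <= n - 10, ]
  mir <- mir[mir$origin_bin >= 12 & mir$origin_bin <= n - 10, ]
  mir$mapped_bin <- n + 2 - mir$origin_bin
  expect_equal(sort(mir$mapped_bin), sort(fwd$origin_bin))
  expect_equal(mir$efficiency_raw[order(mir$mapped_bin)],
               fwd$efficiency_raw[order(fwd$origin_bin)], tolerance = 1e-9)
})

test_that("raising one origin's firing competence never lowers its efficiency", {
  # exact expected fork-direction profile by enumerating firing subsets of
  # three origins with equal fixed firing times: the winner of each bin is
  # the nearest fired origin, leftward fork on ties, own bin half each way
  lay <- make_layout(500)
  pos <- c(100, 250, 400)
  exact_f_right <- function(p) {
    f <- numeric(500); p_any <- 0
    for (S in 1:7) {  # non-empty subsets as bitmasks
      fired <- which(bitwAnd(S, c(1, 2, 4)) > 0)
      prob <- prod(ifelse(seq_len(3) %in% fired, p, 1 - p))
      if (prob == 0) next
      p_any <- p_any + prob
      fS <- vapply(seq_len(500), function(x) {
        d <- abs(x - pos[fired])
        win <- pos[fired][which(d == min(d))]
        if (length(win) == 2) return(0)          # collision tie: left fork wins
        if (win == x) return(0.5)                # in-place firing
        if (win < x) 1 else 0
      }, numeric(1))
      f <- f + prob * fS
    }
    f / p_any
  }
  eff_of <- function(p2) {
    tracks <- analytic_tracks(lay, exact_f_right(c(0.8, p2, 0.9)))
    # unfiltered calls: the invariant concerns the estimator, and with only
    # three peaks the percentile filter would always discard the weakest
    o <- call_origins(origin_signal(tracks), percentile = 0)
    o$efficiency_raw[which.min(abs(o$origin_bin - 250))]
  }
  effs <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), eff_of, numeric(1))
  expect_true(all(diff(effs) >= -1e-9))
})
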