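---
title: "Calling replication origins and termination zones from Pu-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling replication origins and termination zones from Pu-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puseqr)
```

## The measurement and the model

Polymerase usage sequencing (Pu-Seq) maps which replicative DNA polymerase
synthesised each strand of the genome. Strains carry a mutated Pol δ
(*cdc6^L591G^*), Pol ε (*cdc20^M630F^*) or Pol α (*pol1^L850F^*) that
misincorporates ribonucleotides (rNMPs) at an elevated rate, together with a
deletion of the RNase H2 catalytic subunit (*rnh201Δ*) that disables
ribonucleotide excision repair and so preserves those rNMPs as a sequencable
trace. After alkali or RNase-H2 cleavage and strand-specific library
preparation, each sequenced rNMP reports that the mutated polymerase
synthesised that strand at that position.

The analysis works on fixed-width genomic bins (300 bp by default). For one
polymerase dataset with per-bin rNMP counts $R_T$ and $R_B$ on the top and
bottom strands, the **polymerase track** is the strand bias

$$ \mathrm{PT} = \frac{R_T - R_B}{R_T + R_B} \in [-1, 1], $$

computed per biological replicate and then averaged across replicates.
Because Pol ε synthesises the leading strand and Pol δ/Pol α the lagging
strand, PT is a direct readout of local replication-fork direction: where a
fraction $f_R$ of cells replicate a bin with a rightward-moving fork,

$$ \mathrm{PT}_\varepsilon = 2 f_R - 1, \qquad
   \mathrm{PT}_\delta = \mathrm{PT}_\alpha = 1 - 2 f_R . $$

An origin of replication is a point where $f_R$ steps upward — forks diverge
— and the step height equals the fraction of cells in which that origin
fired *actively* (its efficiency). Termination zones are the intervals
between adjacent efficient origins where converging forks meet.

## The origin-calling procedure

1. **Smooth** each replicate-averaged track per chromosome with a centred
   simple moving average of window 3 (`sma()`).
2. **Differentiate**: $\mathrm{Diff}_i = \mathrm{PT}_i - \mathrm{PT}_{i-1}$
   per chromosome, with the first bin of every chromosome assigned 0
   (`differentiate()`).
3. **Combine**: average the Pol ε differential with the *opposites* of the
   Pol δ and Pol α differentials, and smooth the combination once more with
   a window-3 moving average (`combine_differentials()` /
   `origin_signal()`). All three datasets peak together at an origin, so
   averaging triples the effective signal.
4. **Detect peaks**: maximal runs of positive combined differential. A run
   containing two or more distinct local maxima at index distance ≥ 4 bins
   is split into independent peaks at the minimum-value bin between each
   such pair (`detect_peaks()`).
5. **Filter**: compute the 30th percentile of peak maxima genome-wide and
   discard peaks whose maximum falls below it (`filter_peaks()`).
6. **Estimate efficiency**: each surviving peak is an origin whose
   efficiency is 50% of the sum of its differential values
   (`call_origins()`). The differential telescopes: summed across the peak
   it equals the total PT step, which is twice the firing fraction — half
   the sum therefore recovers the efficiency itself. On exact noise-free
   tracks this identity is accurate to floating-point precision (the
   package's tests hold it to 1e-6).
7. **Normalise**: efficiencies are rescaled so the most efficient origin is
   100% (`normalise_efficiencies()`).

Efficient origins are those with normalised efficiency ≥ 40%
(`select_efficient_origins()`). A termination zone is the interval between
two adjacent origins with efficiency > 40% that contains no
intermediary-efficiency origin (the open window 20–40%); weaker origins
(≤ 20%) do not disqualify a zone (`select_termination_zones()`). The two
slightly different flank criteria (≥ 40 for the efficient-origin list,
> 40 for zone flanks) mirror how the two selections are defined; both are
arguments. Whether the thresholds apply to normalised or raw efficiencies
is genuinely open; this package applies them to *normalised* values, since
the percentages are quoted on the normalised scale, and both functions
accept any efficiency column choice via their threshold arguments.

### Meta-profiles

`origin_metaprofile()` centres track windows (default ±50 bins, i.e. ±15 kb)
on each origin and averages across origins. `termination_metaprofile()`
rescales each zone to a fixed number of equal-width bins (default 20) and
centres offsets on the zone midpoint, so zones of different lengths are
comparable. Rescaling uses overlap-weighted block averaging: each rescaled
bin is the average of the original bins it covers, weighted by fractional
overlap. This reduces to plain block means when the zone length is a
multiple of the rescaled bin count, keeps linear profiles linear, leaves no
rescaled bin empty for short zones, and conserves the zone mean exactly —
properties a centre-assignment rule does not share once zones are shorter
than the target bin count. `efficiency_distribution()` tabulates normalised
efficiencies into half-open bins for distribution comparisons across
strains.

## The replication-program simulator

The method's headline quantities (origin efficiencies, zone structure) are
population statistics of fork traffic, so the package ships a stochastic
simulator that generates Pu-Seq-like data with known ground truth
(`replication_program()`, `simulate_population()`, `simulate_puseq()`).

Per cell, each origin *fires at all* with probability $p$ and, if so, at an
exponentially distributed time with mean $\tau$ (a `"fixed"` zero-variance
variant exists for deterministic checks). Forks move outward at a constant
speed $v$ (bins per time unit). A bin is replicated by whichever fork — or
in-place origin firing — reaches it first; an origin overrun before its own
firing time is *passively replicated* and contributes no forks. This is the
minimal model that yields partial realized efficiencies, which is exactly
the quantity the differential method estimates. Replication time obeys
$T(x) = \min_j \left( t_j + |x - o_j|/v \right)$, which the engine evaluates
with running minima in $O(\text{bins} \times \text{cells})$; a brute-force
per-cell scanner in the test suite must agree exactly.

Tie conventions, chosen once for determinism: at a bin reached
simultaneously by converging forks the leftward-moving fork wins; the bin of
an origin that fired and won in place counts half to each direction (so PT
crosses zero at the origin). Cells in which no origin fired leave their bins
unreplicated; such bins are excluded from that bin's denominator rather than
resampled, which keeps realized efficiency ≤ $p$ (conditioning on
replication would violate it). Realistic programs make this astronomically
rare.

Counts are sampled Poisson per bin and strand: with background fraction $b$
(residual excision repair plus mapping noise, spread evenly over both
strands) and mean depth $\lambda$, the top strand of a dataset whose signal
fraction is $s$ gets mean $\lambda[(1-b)s + b/2]$. Defaults — 300 bp bins,
$\lambda = 50$ rNMPs per bin per strand-pair, $b = 0.05$, 2 replicates,
10,000 cells — are deliberate: depth of this order is what a Pu-Seq library
yields per 300 bp bin, two biological repeats is the standard design, and a
few-percent background matches the residual noise visible in real strand
ratios. `example_program()` fixes a 3,000-bin chromosome with 10 origins at
300-bin spacing whose competences span 0.25–1.0 in scrambled order with
$\tau = 1$, $v = 150$; under these settings neighbours compete mildly, so
realized efficiencies span roughly 0.2–1.0. All sampling is seeded;
replicate $r$ of polymerase $q$ uses an offset seed so every table is
individually reproducible.

What the simulator does *not* model, and what passing tests therefore do
not establish about real data: chromatin-driven replication-timing domains,
fork stalling and restart, rNMP-incorporation-rate differences between the
three mutant polymerases, GC or mappability bias, and library-specific end
artefacts. It validates the *pipeline arithmetic* — that the differential
method recovers known efficiencies under realistic counting noise — not the
biology of any particular genome.

## Numerical choices and edge cases

- **Zero-coverage bins** ($R_T + R_B = 0$) get PT = 0 and a `low_coverage`
  flag rather than NA, keeping differentials defined while staying
  auditable; replicate averages inherit the union of flags.
- **Chromosome edges**: the moving average truncates its window rather than
  padding, and differentials never cross chromosome boundaries (first bin
  = 0). Padding with zeros would manufacture differential peaks at every
  chromosome end.
- **Positivity floor**: peak detection treats values ≤ 1e-9 as non-positive.
  Smoothing numerically constant track segments leaves ±1e-16 floating-point
  residue which would otherwise appear as zero-height peaks; real
  differential signals live many orders of magnitude above the floor.
- **Percentile definition**: linear interpolation between order statistics
  (R's default quantile type 7), pinned for reproducibility. The percentile
  is taken over the distribution of candidate *peak maxima* genome-wide —
  filtering on the distribution of all bin values would discard nearly every
  peak. Retention uses ≥, so an all-equal peak set is kept intact.
- **Peak splitting tie-breaks**: "distinct maxima" are bins at least as high
  as both in-run neighbours with plateaus counted once at their leftmost
  bin; the split point is the leftmost minimum between a qualifying pair and
  is assigned to the left child. These choices are deterministic but chiral:
  mirroring the genome moves the boundary bin to the other child. Family
  spans and summed efficiencies are exactly mirror-symmetric, and the
  package's mirror-symmetry tests assert precisely that.
- **Separation convention**: "separated by at least four bins" is read as
  index distance ≥ 4; `min_separation` is an argument wherever it matters.
- **Origin position**: reported at the peak-maximum bin — the sharpest
  incline, hence the most likely initiation bin; the bin span is also
  returned.
- **Coordinates**: 1-based bin indices inside R, 0-based half-open base
  pairs on disk (BED/bedGraph convention); bin $i$ spans
  $[(i-1)w, \min(iw, L))$.

## Worked example

```{r example, eval = FALSE}
prog <- example_program()
sim <- simulate_puseq(prog, noise_model(50, 0.05),
                      n_cells = 10000, replicates = 2, seed = 20240601)
res <- puseq_pipeline(sim$counts)

# estimated vs realized efficiency at the true origin bins
truth <- sim$truth$origins
est <- sapply(truth$position_bin, function(pb) {
  d <- abs(res$origins$origin_bin - pb)
  res$origins$efficiency_raw[which.min(d)]
})
sqrt(mean((est - truth$realized_efficiency)^2))  # ~0.04

effs <- select_efficient_origins(res$origins)
zones <- select_termination_zones(res$origins)
mp <- termination_metaprofile(res$tracks, zones)
plot(mp)
```

The recovery error of ~0.04 on raw efficiency (with rank correlation 1)
reflects two real effects, not estimator defects: the background fraction
$b$ compresses observed strand ratios by $(1-b)$, and the percentile filter
truncates peak tails. Test-suite problem sizes (3,000-bin chromosomes,
10,000 cells, depth 50) were chosen as the smallest scales at which these
effects are measurable against Monte-Carlo noise.

## Auxiliary utilities

Two small formulas from the same experimental programme are included:
`relative_transcript_level()` computes RT-qPCR relative expression
$2^{-Cq(\text{target})} / 2^{-Cq(\text{reference})}$, and `doubling_time()`
fits an unweighted least-squares line to log2 OD measurements and returns
$DT = 1/k$. OD series must be in exponential phase and pre-corrected for
dilutions; no amplification-efficiency correction is attempted.

## Known limitations

- Efficiency estimates are relative to the fork-traffic model: a genuinely
  > 100% sum (impossible biologically) can occur on pathological noise and
  is reported as estimated, not clamped.
- The 30th-percentile filter adapts to each dataset's peak population, so
  origin *counts* are not comparable across datasets with very different
  noise floors, though efficiencies of matched origins are.
- Zones are defined purely by origin geometry; no fork-stalling or
  termination-sequence signal is used.
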