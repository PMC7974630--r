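# puseqr

Analysis of **polymerase usage sequencing (Pu-Seq)** data in R: polymerase
tracks from strand-specific ribonucleotide counts, differential-based
calling of replication origins with firing-efficiency estimation, selection
of efficient origins and replication termination zones, origin-centred and
rescaled termination-zone meta-profiles — plus a stochastic simulator of
the chromosomal replication program that generates realistic Pu-Seq count
tables with known ground truth, so every stage of the pipeline is testable
against the efficiencies it is supposed to recover.

It is intended for researchers analysing Pu-Seq (or OK-seq/GLOE-seq-style
strand-bias) data in organisms such as fission yeast, and for method work
on origin-efficiency estimation.

## The method in brief

Pu-Seq strains carry a ribonucleotide-misincorporating mutant of Pol δ,
Pol ε or Pol α together with *rnh201Δ*, so sequenced rNMPs trace which
polymerase synthesised each strand. For per-bin (300 bp) counts `R_T`, `R_B`
on the top/bottom strands, the polymerase track is

    PT = (R_T − R_B) / (R_T + R_B)

computed per replicate, then replicate-averaged. Since Pol ε is
leading-strand and Pol δ/α lagging-strand, `PT_ε = 2·f_R − 1` where `f_R`
is the local fraction of rightward-moving forks. Origins are steps in
`f_R`: tracks are smoothed (SMA 3), differentiated per chromosome
(`Diff_i = PT_i − PT_{i−1}`, first bin 0), the ε differential is averaged
with the negated δ and α differentials and smoothed again; positive peaks
of the result (split where distinct maxima are ≥ 4 bins apart, filtered at
the 30th percentile of peak maxima) are origins whose **efficiency is 50%
of the summed peak values** — the telescoped PT step across the origin is
twice the fraction of cells firing there. Efficiencies are normalised to
the most efficient origin (100%); efficient origins have `Ori_Eff ≥ 40%`,
and termination zones are intervals between adjacent `> 40%` origins
containing no origin in the open 20–40% window.

## Worked example

```r
library(puseqr)

prog <- example_program()          # 3,000-bin chromosome, 10 origins
sim  <- simulate_puseq(prog, noise_model(50, 0.05),
                       n_cells = 10000, replicates = 2, seed = 20240601)
res  <- puseq_pipeline(sim$counts) # tracks -> differential -> origin calls

head(res$origins[res$origins$efficiency_norm > 40, 
                 c("chrom", "origin_bin", "efficiency_raw", "efficiency_norm")])
#>     chrom origin_bin efficiency_raw efficiency_norm
#> 11   chrI        151      0.4279722        47.92617
#> 48   chrI        451      0.8929824       100.00000
#> 111  chrI       1051      0.6672528        74.72183
#> 180  chrI       1651      0.8344799        93.44865
#> 212  chrI       1951      0.4839853        54.19875
#> 254  chrI       2251      0.7288171        81.61607

truth <- sim$truth$origins
est <- sapply(truth$position_bin, function(pb) {
  d <- abs(res$origins$origin_bin - pb)
  res$origins$efficiency_raw[which.min(d)]
})
sqrt(mean((est - truth$realized_efficiency)^2))
#> [1] 0.04193747
cor(est, truth$realized_efficiency, method = "spearman")
#> [1] 1
```

The simulator's realized efficiencies (fraction of cells in which each
origin fired before being passively replicated) span 0.23–0.95 here; the
pipeline recovers them with RMSE ≈ 0.04 and perfect rank order. Downstream:

```r
effs  <- select_efficient_origins(res$origins)        # Ori_Eff >= 40%
zones <- select_termination_zones(res$origins)        # > 40% flanks, no 20-40% interior
mp    <- termination_metaprofile(res$tracks, zones)   # rescaled meta-profile
plot(mp)
write_regions(origins_to_regions(effs, prog$layout), "origins.bed", prog$layout)
```

Real data enter through `read_chrom_sizes()` + `read_counts()` (combined
5-column TSV or paired 4-column bedGraphs, gzip-transparent, validated
against the bin grid). A command-line wrapper for the common steps is in
`inst/scripts/puseq.R`. The methods vignette
(`vignettes/puseq-analysis.Rmd`) documents the model, parameter choices,
tie-breaks and limitations.

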