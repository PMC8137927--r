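# ribo40s

Analysis of small-subunit (40S) and conventional (80S) ribosome
profiling data from yeast, centered on translation initiation and
ribosome recycling.

After a ribosome terminates at a stop codon, the 60S subunit is
released first and the remaining post-termination 40S·tRNA·mRNA
complex must be actively disassembled. When 40S recycling factors are
absent, unrecycled 40S subunits persist on stop codons, elongating 80S
ribosomes queue behind them, and released subunits reinitiate at AUG
codons in 3'UTRs. 40S footprinting reads out these intermediates
directly: formaldehyde-stabilized 40S-protected mRNA fragments are
sequenced alongside classical 80S footprints, and their 5' ends map
the positions of scanning, initiating and post-termination small
subunits. The package is for computational biologists analyzing such
libraries (or building methods on top of them) and implements the
complete quantitative path from raw reads to codon-level statistics.

## What it computes

* **Read preprocessing** — 3'-linker trimming, 5-nt sample-barcode
  demultiplexing, PCR-duplicate collapse on the 7-nt UMI (5-nt linker
  UMI + 2-nt RT UMI), and footprint size selection (15–80 nt for 40S,
  25–34 nt for 80S).
* **Region classification** — each footprint is assigned to the 5'UTR,
  start codon, ORF, stop codon or 3'UTR; a footprint maps to a start
  codon when any part of it overlaps the 9-nt window centered on the
  codon, and to a stop codon when it overlaps the 9-nt window ending
  with the stop codon.
* **P-site quantitation** — footprint 5' ends are shifted to the P
  site (+14 nt for 40S, +13 nt for 80S); peaks are the summed shifted
  counts in a 5-nt window on the start or stop codon. Gene-level
  densities (rpkm) trim the first/last 15 nt of the ORF and extend
  3'UTRs by 25 nt; ratio analyses require ≥ 5 rpkm in the ORF and
  ≥ 0.5 rpkm in the 3'UTR.
* **Metagene and metacodon averages** — 1-D and length-resolved (2-D)
  average occupancy aligned at start/stop codons by 5' or 3' footprint
  ends, in rpm; position averages around every AUG (or any motif) in
  5'/3'UTRs, optionally normalized to ORF density.
* **Codon-level recycling statistics** — per-gene mutant/WT stop-peak
  ratios r_g = rpm_mut(g) / rpm_wt(g), grouped by the penultimate
  codon (the codon left in the post-termination P site). For each
  codon c with at least 10 transcriptome occurrences, the mean ratio
  m_c is compared against a bootstrap null: 20,000 resamples of n_c
  ratios drawn with replacement from the pooled ratio distribution,
  two-sided percentile p-value with add-one correction, significance
  at the 99th confidence level. A position sweep repeats the test for
  codons −6…−1.
* **Synthetic data** — a generator for yeast-like transcriptomes and
  footprint libraries (stalled initiation/termination complexes with
  3'-end length variability, queued 80S ribosomes 49 nt upstream of
  the 3'UTR start with ±3-nt packing satellites, 3-nt ORF periodicity
  for 80S, planted 3'UTR dORFs, linker/UMI read structure) with
  recorded ground truth, so the entire pipeline is testable without
  sequencing data.

## Worked example

A synthetic study with a planted 20-fold recycling defect, in which
AAA penultimate codons double the defect and TGT halves it:

```r
library(ribo40s)
library(dplyr)

cfg <- synthetic_config(n_genes = 610, reads_per_sample = 1e5,
                        stop_fold_change = 20,
                        codon_multipliers = c(AAA = 2, TGT = 0.5),
                        seed = 1)
tx  <- generate_transcriptome(cfg)
wt  <- simulate_footprints(tx$ann, tx$truth, cfg, "wt",     "ssu40")
mut <- simulate_footprints(tx$ann, tx$truth, cfg, "tma_dd", "ssu40")

region_fractions(wt$profile, tx$ann)
#> # A tibble: 5 × 3
#>   region count fraction
#>   <fct>  <dbl>    <dbl>
#> 1 UTR5    5826   0.0583
#> 2 START  62328   0.624
#> 3 ORF    24042   0.241
#> 4 STOP    5219   0.0523
#> 5 UTR3    2462   0.0247
```

Most wild-type 40S footprints sit on start codons, a minority in
5'UTRs (scanning) and ORFs (dissociated 80S), few at stops — the
hallmark distribution of 40S profiling. Stop-peak ratios then recover
the planted defect:

```r
rec <- peak_ratio_table(peak_height(mut$profile, tx$ann, "stop"),
                        peak_height(wt$profile,  tx$ann, "stop"),
                        tx$ann)
boot <- codon_bootstrap(rec, n_boot = 2000, seed = 2)
glance(boot)
#> # A tibble: 1 × 6
#>   transcriptome_mean n_genes n_codons n_significant n_boot alpha
#>                <dbl>   <int>    <int>         <int>  <dbl> <dbl>
#> 1               20.1     553       61             2   2000  0.01

tidy(boot) |> filter(significant)
#> # A tibble: 2 × 6
#>   codon position     n mean_ratio  p_value significant
#>   <chr>    <int> <int>      <dbl>    <dbl> <lgl>
#> 1 AAA         -1     8      40.4  0.000500 TRUE
#> 2 TGT         -1     8       9.10 0.001000 TRUE
```

The transcriptome-wide mean ratio (20.1) matches the planted 20-fold
defect, and exactly the two modifier codons are flagged — AAA on the
high side, TGT on the low side. The stalled complex is visible in the
metagene:

```r
metagene_1d(mut$profile, tx$ann, "stop")
#> <metagene> stop-anchored, five prime ends, 610 genes, offsets -300..100
#>   max 1321 rpm at offset -14 nt
```

A 40S footprint whose 5' end sits 14 nt upstream of the stop codon has
its P site on the stop codon: the unrecycled subunit. `autoplot()`
draws the trace (and the 2-D length-resolved version from
`metagene_2d()`); `plot_region_fractions()` and `autoplot(boot)` cover
the other result types.

Annotation loading from standard files is shown with the small
synthetic demo set under `inst/extdata/demo`:

```r
d <- system.file("extdata", "demo", package = "ribo40s")
ann <- load_annotation(file.path(d, "cds.gff3"),
                       file.path(d, "utr.tsv"),
                       file.path(d, "genome.fa"))
fp <- read_footprints(file.path(d, "wt_ssu40.bed"), ann, "ssu40")
```

A YAML-configured driver (`run_pipeline()`, with a thin CLI in
`inst/scripts/ribo40s`) chains the stages
`simulate → quantify → metagene → metacodon → codonstats → report`
into reproducible, file-based runs.

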