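---
title: "Models and methods behind ribo40s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribo40s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribo40s)
library(dplyr)
```

This vignette is the package's own account of the science it
implements: the coordinate model, each analysis and its assumptions,
the tunable parameters, the synthetic-data generator, and the design
choices that were genuinely open. Everything quantitative shown here
is computed by the code in this package; nothing is quoted from
elsewhere.

## The biological setting

Translation ends with two recycling steps: ABCE1/Rli1 splits the
post-termination 80S into a free 60S and a 40S still holding
deacylated tRNA and mRNA; eIF2D (Tma64) or the MCT-1/DENR heterodimer
(Tma20/Tma22) then releases tRNA and mRNA from the 40S. If the second
step fails, the transcriptome acquires a characteristic signature:

* 40S footprints pile up with their P site on stop codons;
* elongating 80S ribosomes queue one footprint length behind the
  stalled complex;
* unrecycled subunits resume scanning and reinitiate at 3'UTR AUGs,
  producing downstream-ORF (dORF) translation.

40S footprinting captures these species. Because 40S-mRNA complexes
are fragile, libraries come from formaldehyde-stabilized cells; the
protected fragments have well-defined 5' ends and variable 3' ends,
so all alignment in this package is by the 5' end.

## Coordinate model

Each transcript is a 0-based coordinate frame: position 0 is the
first nucleotide of the annotated 5'UTR, the start codon begins at
`A = utr5_len`, and — because the CDS is defined to include the stop
codon (the yeast GFF convention) — the stop codon begins at
`S = utr5_len + cds_len - 3`. All windows below are half-open unless
stated otherwise. Offsets "relative to the 3'UTR start" are
`pos - (S + 3)`.

A footprint is the interval `[five_prime, five_prime + length)`. The
P site of the complex that protected it starts at `five_prime + 14`
for 40S footprints and `five_prime + 13` for 80S footprints; mRNA-seq
style data are unshifted. These offsets are fixed constants of the
assay geometry, not calibrated per dataset (`assay_shift()`,
`ribo40s_defaults()`).

## Analyses and their assumptions

**Region classification.** A footprint maps to the start codon if any
part of it overlaps `[A - 3, A + 6)` — the codon plus 3 nt on each
side, the only symmetric reading of a "9-nt region centered" on the
codon — and otherwise to the stop codon if it overlaps
`[S - 6, S + 3)`, the 9-nt region ending with the stop codon.
Footprints touching neither window take the region of their unshifted
5' end. Start precedence over stop can only matter for CDSs of a few
codons and is logged when exercised. Classification uses whole
unshifted footprints: the overlap windows describe the physical
footprint, not the inferred P site.

**Densities.** Gene-level density is rpkm: reads per million mapped
(the per-sample denominator is all retained footprints on annotated
transcripts) divided by window length in kb. The ORF window drops its
first and last 15 nt so initiation/termination pile-ups do not
contaminate elongation density; the 3'UTR window extends 25 nt past
the annotated end so ribosomes that partially protect poly(A) are
counted. Ratio analyses (3'UTR:ORF) require ≥ 5 rpkm in the ORF and
≥ 0.5 rpkm in the 3'UTR; thresholds are inclusive because the rule is
stated as a requirement, not a strict inequality.

**Peak quantitation.** A stalled complex places its shifted 5'-end
count at the first nucleotide of the anchor codon, so the peak is the
summed shifted counts in the 5-nt window `[C - 2, C + 2]` centered
there. The window tolerates ±2 nt of digestion raggedness without
absorbing neighboring features.

**Metagenes.** The 1-D metagene is the equal-weight mean across genes
of rpm-scaled 5'-end (or 3'-end, last protected nucleotide) count
tracks, aligned at `A` or `S`. Genes enter only when their flanking
features cover the whole window — 100 nt of UTR and 300 nt of ORF for
the default 1-D windows (−100..+300 at starts, −300..+100 at stops),
±100 nt of the feature for 2-D metagenes — and genes with zero reads
in the window still contribute zeros, so the trace is an unbiased
average over the included cohort. The 2-D form computes the same
average per footprint length (15–80 nt); its column sums reproduce
the 1-D trace exactly, and 5'- versus 3'-aligned matrices are related
row-by-row by a shift of `length - 1`, which the tests assert.

**Metacodon (position-average) plots.** The same averaging anchored
at every occurrence of a motif within a UTR, one window per
occurrence (overlapping occurrences count independently). Genes with
no reads in the relevant UTR are excluded, as are occurrences whose
window leaves the transcript; windows may extend into the CDS by
default (`truncate_to_region` clips them). With ORF normalization the
track is divided by the gene's ORF rpkm and genes under 5 rpkm are
dropped — low-expression genes would otherwise dominate the
normalized average through noise.

**Codon-level recycling statistics.** For genes whose wild-type stop
peak passes a count floor, the record is
`r_g = rpm_mut(g) / rpm_wt(g)` — rpm on both sides so library depth
cancels — plus the codons at positions −1…−6 read in frame from the
CDS. For a codon `c` with `n_c` records, the bootstrap null draws
`n_c` ratios with replacement from the pooled distribution 20,000
times and records the mean; the two-sided percentile p-value with
add-one correction is

p_c = (1 + #{ |null_b − μ| ≥ |m_c − μ| }) / (B + 1),

with μ the pooled mean. Two-sided is the faithful reading of a test
that flags both slower- and faster-recycling codons; the add-one
correction keeps p > 0. Codons are eligible when they occur at least
10 times among quantified genes — the eligibility count is a property
of the transcriptome, not of how many records survive the count
floor. No multiple-testing correction is applied across the 61
codons; significance is per-codon at the 99th confidence level, and
this is deliberate and documented rather than hidden. Resampling
draws indices, so results are bit-reproducible given a seed and
invariant under a common positive rescaling of the ratios.

### The wild-type count floor

The per-gene ratio `mut/wt` is unstable when the wild-type count is
small: `E[1/X]` for a Poisson count X diverges as counts shrink, and
a handful of `wt = 1` genes can dominate both the pooled mean and the
bootstrap null's spread. The package therefore defaults
`min_wt_count = 4`. The choice is a designed compromise, fixed by a
power analysis at the package's simulation scale before any tests
were written: a floor of 1 admits outliers that swamp genuine ±2-fold
codon effects, while high floors (≥ 8) bias the mean ratio downward
through selection (keeping only genes whose wild-type count
fluctuated high deflates the ratio). At the default simulated depth
the per-gene wild-type stop peak averages ~6–7 counts, where the
1/count inflation and the ≥ 4 selection deflation approximately
cancel; the recovered transcriptome mean then sits within a few
percent of the planted fold change. The floor is exposed
(`peak_ratio_table(min_wt_count = )`) for datasets with different
depth.

## The synthetic-data generator

`generate_transcriptome()` builds random yeast-like transcripts:
5'UTRs of 50–150 nt, CDSs of 300–1500 nt assembled from random sense
codons (so no in-frame internal stops), 3'UTRs of 120–250 nt, an AUG
start and a random stop codon, and a penultimate codon assigned
either balanced (the 61 sense codons cycled across genes) or at
random. Half the genes receive a planted 9-nt dORF (AUG + one codon +
TAA) in the 3'UTR; accidental 3'UTR AUGs are scrubbed so the planted
positions are exhaustive ground truth for motif searches.

`simulate_footprints()` draws reads from a per-gene mixture of seven
occupancy components. Fixed-5'-end components encode the stalled
species: initiation complexes at `A - 14` (40S) / `A - 13` (80S),
post-termination complexes at `S - 14` / `S - 13`, reinitiation
complexes 14 nt upstream of planted 3'UTR AUGs, and queued 80S
ribosomes at `S - 46` with ±3-nt packing satellites — i.e. −49/−46/−52
relative to the 3'UTR start, the diagnostic spacing of an 80S stacked
behind a stalled 40S. Backgrounds are uniform in their regions; the
80S ORF background places 90% of shifted P sites in frame 0. Lengths
are drawn around a mode of 32 nt (40S) or 28 nt (80S) with a small
~21-nt class, and only the 3' end varies for the stalled components:
footprint length variability is 3'-end variability, which is exactly
what makes 5'-aligned 2-D metagenes show a vertical stripe and
3'-aligned ones a diagonal.

Wild-type 40S component weights are anchored to the published
wild-type footprint distribution (5'UTR 8.9%, start 59%), with one
deliberate exception: the stop-peak share defaults to 4% rather than
the published ~2.5%. At the package's simulation depth (10^5 reads
per library) the smaller share leaves ~4 expected wild-type counts
per gene — too few for any ratio statistic to be stable — while 4%
yields ~6.6 and keeps codon-level inference well-powered without
changing the qualitative picture. This is a property of the scaled
simulation, not a claim about the data.

The mutant (`tma_dd`) genotype defines `stop_fold_change` as the
planted per-gene rpm ratio at stop peaks: stop weights are multiplied
by `fold × multiplier(penultimate)` (and 3'UTR AUG peaks by their own
factor), and the non-boosted components are rescaled so the library
still sums to one. Under a naive compositional construction the
realized rpm ratio would be `fold / Z` with Z the boosted total —
never the nominal fold — so defining the parameter as the rpm-ratio
target is what makes "the planted fold is recovered" a meaningful
test. A consequence worth knowing: at fold 20 the mutant library is
dominated by stop-codon reads (~80%), which is an exaggeration of the
real mutant's ~27% stop share; the exaggeration buys per-gene counts
at desk scale.

The 80S mutant instead boosts the queued component (default 10×) and
leaves its stop weight alone: queuing, not a 20-fold 80S stop peak,
is the 80S signature of the 40S recycling defect.

`emit_fastq()` renders footprints as
`2-nt RT UMI | insert | 5-nt UMI | 5-nt barcode | linker` reads and
appends planted PCR duplicates. Its ground truth records the realized
number of distinct (insert, UMI) keys rather than the number of
template molecules: at peak positions many molecules share an
identical insert, so 7-nt UMI collisions occur at realistic depths,
and the distinct-key count is the quantity a correct deduplicator can
recover exactly.

**What the generator does not emulate** — and hence what passing
tests do not show about real data: realistic base composition and
ligation biases, RNase digestion sequence preferences, rRNA/tRNA
contamination, expression-correlated UTR lengths, uORF-regulated
genes, and alignment ambiguity (reads are planted in transcript
space; genome alignment is outside the package entirely). Tests
demonstrate that the implementations compute their definitions
correctly and recover planted structure at simulated depth; they do
not validate the biological constants, which are taken as given.

## Numerical and design choices

* **Focused length range.** Published descriptions of the
  high-precision 40S length window differ (26–45 in figure material,
  26–42 in methods text). The package defaults to 26–45 and exposes
  `length_range` wherever it applies.
* **Overlap rule for gene exclusion.** "Overlapping transcripts" is
  implemented as genomic span intersection on either strand, with
  UTR extensions included by default (`utrs_in_overlap`): same-strand
  CDS-only overlap would silently admit antisense overlaps, which are
  exactly the ones that corrupt footprint assignment.
* **rpm denominator.** All retained footprints mapped to annotated
  transcripts, per sample — the reproducible choice given that ncRNA
  contamination is removed upstream of this package.
* **Ties and degenerate inputs.** Region precedence START > STOP
  (logged when it fires); zero-length density windows yield `NA` and
  omit the gene; zero classifiable reads, empty metagene cohorts and
  fully-filtered metacodon occurrence lists are errors, not silent
  zeros; peak windows clipped by transcript ends are flagged
  (`truncated`).
* **Determinism.** Every stochastic step (generator, bootstrap,
  pipeline) takes an explicit seed; bootstrap resampling uses index
  draws so p-values are scale-invariant and bit-reproducible.
* **Simulation sizes.** The test suite and `scripts/acceptance.R` use
  610-gene balanced transcriptomes with 10^5-read libraries for the
  ratio/bootstrap analyses (~6-7 wild-type counts per stop peak),
  smaller cohorts (40–100 genes, 5×10^3–3×10^4 reads) for geometry
  and consistency checks, and 50 replicate null runs of 61 codons ×
  10 genes at 2,000 bootstrap draws for type-I calibration. These
  sizes were chosen once, as the smallest problems at which the
  statistics of interest are stable.

## Known limitations

* P-site offsets are constants; no per-dataset offset learning is
  provided, so data from other nuclease/protocol combinations may
  need the `--shift-override`/`assay = "none"` escape hatches.
* The bootstrap tests each codon against the pooled distribution that
  includes its own genes; with 61 groups of ~10 among ~600 records
  the resulting conservatism is negligible, but for very small
  transcriptomes it is not.
* `load_annotation()` handles splice-joined CDSs and strand
  orientation but not UTR introns (such genes carry a flag and are
  excluded from position-sensitive analyses, mirroring standard
  practice).
* The classifier's region fractions are properties of whole-footprint
  overlap: background reads near a start codon legitimately count as
  START. Comparisons with per-component generator weights must go
  through the classifier, not equate weights with fractions.
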