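---
title: "Methods: differential methylation from MeDIP-seq read counts"
author: "medipdiff developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation from MeDIP-seq read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdiff)
```

## The measurement model

MeDIP-seq enriches methylated DNA fragments with a 5-methylcytosine
antibody before sequencing. Read depth at a locus is therefore a proxy for
methylation density there, confounded by CpG density (more CpGs, more
epitopes) and by library size. `medipdiff` makes the minimal set of
assumptions this design supports:

* within one group, pooled replicate fragments are an i.i.d. sample from
  an enrichment-rate profile over the genome;
* between groups, the profiles are proportional except in differentially
  methylated regions;
* the comparison unit is a *region* derived from per-group enrichment
  peaks, and the statistic is the in-region fragment count.

Replicates are pooled per group before peak calling and testing. This
matches the pooled-library design the pipeline emulates; the chi-square
test consequently measures sampling noise only, not biological
between-replicate dispersion (see Limitations).

## Pipeline stages and their parameters

### Read QC (`filter_reads`)

A fragment is discarded if either mate has more than 10% undetermined
bases (N) or more than 40% of bases at Phred ≤ 20, or if it aligned with
more than five mismatches or to more than one location (when those fields
are present). All thresholds are strict inequalities on the offending
quantity: a 125 bp mate with 12 Ns (9.6%) passes, 13 Ns (10.4%) fails.
Fragment inputs from plain BED carry no sequences; `strict = FALSE`
skips the base-level checks and keeps the mapping checks.

### CpG-island scanning (`scan_cgis`)

Islands are defined by three criteria: length > 200 bp, GC fraction
> 50%, and CpG observed/expected ratio
$(n_{CpG} \cdot L)/(n_C \cdot n_G) > 0.6$. The scanner slides a 100 bp
window stepped 1 bp, averages the window GC and O/E values over all
windows covering each position, takes maximal runs of qualifying
positions longer than 200 bp, and re-checks the three criteria on the
final extent (islands failing the re-check are dropped). Windows
containing N contribute non-qualifying (zero) values. Adjacent islands
are never merged — the definition provides no merge rule, and adding one
would silently change island counts.

The window/step choice mirrors the common sliding-window island scanners'
defaults; both are parameters. The re-check on the final extent
guarantees that every reported island verifiably satisfies the defining
criteria, which the test suite asserts directly.

### Coverage profiling

* `chromosome_profile`: fragment-midpoint counts in 10 kb windows.
* `cpg_density_profile`: 1 kb windows binned by CpG count
  (0, 1–4, 5–10, 11–20, >20 by default; the edges are parameters because
  published figures rarely state them), reporting the proportion of reads
  per bin.
* `element_distribution`: fragment midpoints labelled by gene element
  with the fixed precedence `five_utr > cds > three_utr > intron >
  upstream2k > downstream2k`. A base can lie in elements of several
  genes; one proportion per element requires a deterministic
  single-label rule, and this precedence prefers the more specific,
  transcribed annotation.
* `metagene_profile`: per region, the 2 kb flanks are split into 20
  equal windows each and the body into 40; per-window mean base-level
  depth is averaged across regions and divided by 1,000. Counts use
  midpoints (a count needs one location); depth profiles use full
  per-base overlap (alignment depth is per-base by definition).

Two numerical choices matter here. First, bases are assigned to window
$\lfloor \text{offset} \times n / L \rfloor$ — deterministic and
partition-exact, with no fractional attribution. Second, minus-strand
regions reuse the plus-strand window partition and reverse the resulting
80-vector. This makes strand-flip equivariance exact for *every* region
length; assigning windows from the 5′ offset instead would differ from
the mirrored partition whenever $L$ is not a multiple of $n$ (no
pointwise-symmetric integer partition exists then, e.g. $L = 5$,
$n = 2$). The synthetic generator additionally emits gene bodies that
are multiples of 40 bp, for which the two definitions coincide.

The division by 1,000 is a display normalization applied literally, as
is conventional for windowed MeDIP read counts; it cancels in any
within-figure comparison. A per-million (library-size) scaling is
available via `normalize = "per_million"` but off by default, since
cross-group comparisons happen in the test, not in the profiles.

### Peak calling (`call_peaks_simple`)

A deliberately simple stand-in for model-based callers: midpoint counts
in 200 bp windows, a window is enriched when its count exceeds the
Poisson upper 10^-4 tail of the genome-wide mean *and* is at least 4x
that mean, and enriched windows separated by at most 200 bp merge into a
peak. It has no model shift, no local background, and no multi-scale
logic — it exists so the downstream statistics can be exercised and
validated on synthetic data; externally called peaks (BED/narrowPeak)
can be supplied instead and bypass it entirely.

### Region construction (`merge_peak_sets`)

Two peaks from different groups merge when their overlap strictly
exceeds 50% of the shorter peak's length; merged pairs chain
transitively into one region spanning the union; everything else becomes
a group-unique region. Unique regions are still tested — a region
enriched in only one group is precisely where differential methylation
is expected. Note the outputs need not be disjoint: two peaks
overlapping by less than the threshold yield two overlapping unique
regions, faithfully to the rule. Within one group, overlapping peaks
(which a well-formed caller never emits, but the simple caller could)
are unioned first with a warning; touching-but-not-overlapping peaks are
kept separate, since half-open `[a,b)` and `[b,c)` share no base.

### Testing and filtering (`test_regions`, `call_dmrs`)

The in-region counts are compared with a Pearson chi-square (df = 1) on
the 2×2 table `[[k_TC, N_TC − k_TC], [k_CH, N_CH − k_CH]]`, where `N`
are the library sizes of the pooled groups. The source description of
this analysis style says only that in-peak read numbers are compared;
the 2×2 homogeneity form was chosen because it uses library size as the
natural denominator and reduces to a direct count comparison when
libraries are equal. A goodness-of-fit variant (counts vs library-ratio
expectations) is exposed via `method = "goodness_of_fit"`. No continuity
correction is applied by default — in-peak counts are large — but
`correct = TRUE` is available. Degenerate tables (both counts zero) are
flagged with statistic 0 and p = 1 rather than propagating NaN.

p-values are Benjamini–Hochberg adjusted jointly across *all* regions of
a run, after a stable coordinate sort so ties are broken
deterministically. The DMR filter is `p < 0.01` and `q < 0.01` and
`|log2FC| ≥ 1`; the p condition is implied by the q condition under BH
but both are applied for fidelity to the stated three-part rule.

The fold change is library-normalized by default with pseudocount 0.5:
`log2(((k_TC + 0.5)/N_TC) / ((k_CH + 0.5)/N_CH))`. A raw count ratio
(the literal reading of "ratio of read counts") is available with
`normalize = FALSE`; normalization is the default because real group
libraries differ in depth, and the synthetic generator deliberately
jitters library sizes by ±10% so the choice is exercised. Pseudocount 0
gives exact ratios for strictly positive counts.

### Annotation (`annotate_dmrs`) and qPCR (`ddct_fold_change`)

A gene is a DMG when at least one DMR overlaps — by one base or more —
its gene body, 2 kb upstream, or 2 kb downstream. "Located in" phrasings
are ambiguous between overlap, midpoint and containment; ≥1 bp overlap
is the most inclusive deterministic reading, and it is what the
brute-force per-base checks in the test suite verify. A DMR spanning
several elements reports all hit labels, with the single per-DMR summary
label chosen by the profiling precedence. Genes lacking CDS annotation
get a `noncoding_exon` label in place of CDS/UTRs.

Relative expression uses the Livak 2^−ΔΔCt method with per-sample
ΔCt = Ct(target) − Ct(reference); group means are taken of per-sample
ΔCt (not of raw Ct), which respects the pairing of target and reference
within a sample and makes the result invariant to per-sample input
amounts. Concordance flags genes whose methylation and expression fold
changes have opposite signs, the repressive pattern promoter and gene
body methylation is expected to show.

## The synthetic study generator

`sim_config()` defaults encode the emulated design: 2 groups × 3
biological replicates; paired-end 125 bp mates cut from sonication
fragments drawn uniformly in 100–500 bp and size-selected to 220–320 bp;
a 2 × 1 Mb genome at 40% GC with background CpGs depleted to 25% of
random expectation (genome-wide O/E ≈ 0.25 outside implants, safely
below the island criterion); 100 genes; 40 implanted CpG islands that
provably satisfy all three criteria; 30 true differential regions
(half up, half down) at |log2FC| = 2 on the enrichment-rate track plus
30 equally-enriched null regions; ~50,000 fragments per replicate with
±10% library jitter. These scales run in seconds yet give per-region
counts in the hundreds, so the statistical machinery operates in its
intended regime. The heavier validation runs use exactly these defaults;
the unit tests use a 1 × 200 kb variant of the same generator.

Implanted enriched regions are multiplied 8× over the local baseline in
*both* groups; a true DMR additionally multiplies the TC rate by
2^±log2FC, so the implanted rate ratio is exact by construction.
Fragment midpoints are drawn proportional to the group's rate track
(100 bp resolution); sampling the midpoint rather than integrating the
rate over the fragment is an approximation that is immaterial at 100 bp
bins versus 220–320 bp fragments. Null regions exist so that null-data
runs still produce a realistic region set to test — without any
enrichment the caller correctly finds nothing and a type-I-error check
would be vacuous.

Small fractions of fragments receive N-contaminated mates (1%),
low-quality strings (1%), multi-mapping flags (0.5%) or excess
mismatches (0.2%), purely to exercise the QC filter.

What the generator does **not** emulate: sequencing errors beyond the QC
injections, GC-dependent amplification bias, copy-number variation,
fragment-level enrichment efficiency of a real antibody, and biological
replicate-to-replicate dispersion. Passing tests therefore demonstrate
the correctness of the statistical machinery under the stated sampling
model, not robustness to those real-data artefacts.

## Determinism

Every stochastic stage derives its seed deterministically from the
single configured seed, so stages are individually reproducible and a
rerun of the same configuration is byte-identical, file for file. The
qPCR simulation keeps derived seeds within the 32-bit integer range.

## Validation strategy and problem sizes

The test suite validates each optimized path against an independent
route: the island scanner against a moving-average re-implementation and
direct substring recounts (100 random 5 kb sequences); `cpg_oe` against
exhaustive hand counts for all sequences up to length 8; the merge rule
against an all-pairs scan with graph components (1,000 random two-group
sets of up to 200 peaks each); the chi-square against the closed-form
hand value 12.5 on `[[30,70],[10,90]]` and `stats::chisq.test`; BH
against `stats::p.adjust` on 1,000 random vectors. Whole-pipeline
properties use the generator: 20 null runs at the default scale must
yield zero DMRs (with near-uniform raw p-values on well-covered
regions), and one default-scale run with implanted |log2FC| = 2 must
recover ≥90% of regions with zero sign errors and median absolute
fold-change error ≤ 0.3 — the recovery thresholds were frozen after a
pilot simulation at the same scale. Observed fold changes are mildly
attenuated (median error ≈ 0.2) because called peak extents include a
window or two of non-differential shoulder around each implanted
region; this is inherent to region-based testing, not a defect of the
estimator.

## Limitations

* Pooling replicates discards biological dispersion; the chi-square
  p-values are calibrated for sampling noise only and will be
  anti-conservative on data with real replicate variability.
* The built-in peak caller is intentionally simple; for real data,
  import peaks from a dedicated caller.
* CpG-island calls depend on scanner settings; other tools' islands
  will differ at the margins.
* The DMG rule is per-gene, collapsed across transcripts; isoform-level
  effects are out of scope, as are GO/KEGG enrichment (external,
  database-versioned services) and bisulfite-resolution methylation
  levels.
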