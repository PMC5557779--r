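---
title: "Methods: bulked segregant association mapping and fine mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked segregant association mapping and fine mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The experimental design the package assumes

An F2 population from two inbred parents segregates a monogenic
dominant trait. Two DNA pools are sequenced: a *dominant bulk* of
plants showing the dominant phenotype (genotypes 1/3 homozygous
carrier : 2/3 heterozygous in expectation) and a *recessive bulk* of
homozygous-recessive plants. Away from the trait locus both pools
sample alleles at frequency 1/2; at and near the locus the recessive
bulk is fixed for the recessive parent's haplotype while the dominant
bulk carries the dominant parent's allele at expected frequency 2/3.
Association statistics contrast the pools' allele frequencies per SNP;
smoothing pools information across linked SNPs; thresholding turns the
smoothed profile into candidate regions. Fine mapping then scores
individual recessive-class plants at markers inside the region.

## Statistics

**SNP-index.** With M the dominant parent's allele and P the recessive
parent's, the SNP-index of a bulk is the M-read fraction
`M / (M + P)`; `delta` is the dominant-bulk index minus the
recessive-bulk index. If a bulk has no M or P reads at a site its index
is undefined; undefined values propagate as `NA` and are excluded from
window means — imputing 0 would fabricate evidence of absence of
association.

**Euclidean distance.** `ed = sqrt(sum_b (f_b(dom) - f_b(rec))^2)`
over the four bases. The statistic is sometimes written with raw
depths, but raw depths make it scale with coverage and unbounded,
which is incompatible with a fixed association threshold on `ed^5`
(0.15); this package therefore uses within-bulk base *frequencies*
(bounding `ed` by `sqrt(2)`), with `mode = "depth"` available for
completeness. The fifth power suppresses the many small noise-driven
values relative to the few large signal values.

**Expected peak values.** At a fully linked SNP the expectations are
`delta = 2/3 - 0 = 2/3` and
`ed = sqrt((2/3)^2 + (2/3)^2) = (2/3) sqrt(2) ≈ 0.9428` — the package
tests verify the simulator converges to both.

## Smoothing

*Sliding windows* (for `delta`): 200 consecutive SNPs per window,
advancing 1 SNP at a time. The window count, not a bp width, matches
how reduced-representation SNP sets are windowed in practice; the step
and the reported position (median SNP position) are conventions the
underlying method leaves open, chosen here for a dense, well-centred
profile and exposed as parameters. Windows never span chromosomes; a
chromosome with fewer SNPs than the window size contributes one
whole-chromosome window.

*Loess with AICc span selection* (for `ed^5`): degree-1 local
regression with tricube weights over the `span * n` nearest
neighbours, fitted per chromosome. For each candidate span the full
smoother matrix row is formed per point from the 2x2 weighted normal
equations, giving the fitted value and the diagonal element; the span
minimizing `AICc = log(sigma^2) + 1 + 2 (tr(L)+1) / (n - tr(L) - 2)`
is kept. The smoother is hand-built because the AICc needs `tr(L)`
exactly, which `stats::loess` only approximates; the test suite checks
it against an independent per-point weighted-least-squares oracle to
1e-8 and against the analytic facts that local linear regression
reproduces constants and straight lines. The span grid default
(0.05–0.95 by 0.05) brackets everything from near-interpolation to
near-global fits; spans whose local windows would hold fewer than 3
points are skipped.

## Thresholds and regions

Two threshold modes: an explicit statistic value (0.26 for windowed
`delta`, 0.15 for loess `ed^5` — the values appropriate to this design
at these depths), or `median + k * SD` of the genome-wide smoothed
values (default `k = 3`; the source method states "standard deviations
above the genome-wide median" without fixing the multiplier, so k is a
parameter). Candidate regions are maximal runs of profile points above
the threshold, bounded by the first and last observed positions of the
run — no extrapolation beyond observed SNPs — and the two methods'
regions are intersected (`[max(starts), min(ends)]`, kept when of
positive length). Interval sizes are `(end - start) / 1e6` Mb, rounded
half-up to two decimals; `end - start` rather than `end - start + 1`
is used for consistency with half-open BED arithmetic (both reproduce
published two-decimal sizes). Internally all coordinates are 1-based
inclusive; conversion to 0-based half-open happens only in the BED
writer. Sites on unplaced ("unknown") chromosomes receive per-SNP
statistics but are excluded from windows, smoothing and region calling
— they have no meaningful physical order.

## Marker screening

Rules are applied in a fixed order so the removal counters are
deterministic and each site is counted once: (1) bulk depth — both
bulks must reach `min_bulk_depth` (default 5 reads; a conjunctive
reading of the screening criterion, with an "either pool" switch);
(2) parental polymorphism — the parents must carry different known
alleles (sites with unknown parental calls are counted here, never
silently dropped); (3) multiallelic sites; (4) pool monomorphism —
both bulks fixed for the same base carry no contrast. Published
descriptions of this screening quote both a 4-read and a 5x cutoff at
different stages; the default follows the SNP-calling-stage value (5)
and the cutoff is configurable. Filtering is idempotent, and the
counters always sum to the input count.

## The synthetic generator

`simulate_f2()` draws each plant as two gametes; each gamete is a
mosaic of the two parental haplotypes with crossover count Poisson in
the chromosome's genetic length and crossover positions uniform — a
no-interference model, chosen because the design gives no information
about interference (the Kosambi function is used only for reporting
distances, not for simulation). Map positions are linear in bp.
`make_bulks()` samples plants without replacement within phenotype
class; `simulate_depths()` draws per-site total depths as Poisson and
base counts as multinomial around the bulk allele frequency, with a
sequencing error rate that redistributes reads uniformly over the
other three bases.

Defaults state the emulated experiment: 723 F2 plants (3:1 in
expectation), bulks of 50 + 50, bulk depths 45x/41x, parental depths
16x/27x, error rate 0.001, a single dominant causal locus
mid-chromosome 1. Genome defaults — 3 chromosomes of 500 Mb and 150 cM
with 200 uniformly spaced SNPs each — are not part of the emulated
experiment's published description; 500 Mb/150 cM is a realistic size
for a large cereal chromosome, three chromosomes provide two unlinked
negative controls, and 200 SNPs per chromosome keeps a 20-replicate
recovery experiment under a minute. They were fixed once, before any
acceptance measurement.

What the generator does *not* emulate: restriction-site-based locus
dropout and the resulting irregular SNP spacing, alignment and
repeat-sequence artifacts, multiallelic error modes, and
linkage-map/physical-map discordance. A green end-to-end test
therefore establishes that the statistics, smoothing and region
logic recover a clean signal at realistic depths and bulk sizes — not
that the pipeline is robust to reference-genome pathology.

## Numerical and degenerate-input choices

- Undefined statistics are `NA` end to end; writers emit literal `NA`.
- Statistic columns round-trip through the TSV writers at six decimals.
- `AICc` comparison skips spans where `n - tr(L) - 2 <= 0`; a constant
  response gives `sigma^2 = 0` and `-Inf` AICc at every span, so the
  (exactly constant) fit at the first span is returned.
- Region runs are broken by `NA` profile points and by chromosome ends.
- `delimit_interval()` aborts when two equally long zero-recombinant
  marker runs exist (a genotyping conflict that position data cannot
  resolve) rather than guessing; a run at a matrix edge yields an open
  boundary on that side.
- Recombination fractions at or above 0.5 are a domain error (unlinked
  marker), as is a Kosambi argument outside `[0, 0.5)`.

## Known limitations

- The VCF reader requires per-allele `AD` depths; records carrying
  only genotypes and total depth are flagged unusable, not guessed.
- Thresholds are not permutation-calibrated; genome-wide significance
  is out of scope.
- Multipoint linkage-map construction and dominant-marker handling in
  fine mapping are out of scope; the recombinant logic assumes
  co-dominant markers scored in the homozygous-recessive class.
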