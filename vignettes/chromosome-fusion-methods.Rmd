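---
title: "Methods: fusion mapping, pi_4D, the 50 cM model and element turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion mapping, pi_4D, the 50 cM model and element turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices behind
`karyofuse`. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` compute.

## The biological setting

In several lepidopteran lineages an ancestral karyotype of 31 small
chromosomes was reshaped by fusions: in *Heliconius*-like systems, 10 of the
ancestral chromosomes — consistently the shortest ones — each fused onto a
longer partner, leaving 21 chromosomes. Because meiosis in these clades
delivers roughly one crossover per bivalent regardless of physical length,
the genetic map of every chromosome stays near 50 cM, and a fusion therefore
halves-or-worse the per-base recombination rate of its components. Lower
per-base recombination strengthens background selection and hitchhiking,
depressing neutral diversity, and over longer timescales is expected to
shift the turnover rate of functional elements. `karyofuse` implements that
chain of inference as testable, composable stages.

## Coordinates and formats

All in-memory coordinates are 0-based half-open; conversions happen only at
format boundaries (GFF3 and VCF are 1-based on disk, BED is native, the
12-column hit table keeps its 1-based inclusive dialect inside hit records,
which are never used as genomic intervals). Soft-masked FASTA is uppercased
and masking is *not* treated as repeat evidence — repeats enter only as BED
intervals. Multiallelic VCF sites are kept whole, because the conservative
4D-site rule needs the full observed allele set of a codon.

## Fusion mapping

An anchor map lists, per derived chromosome, ordered ortholog positions and
their ancestral homolog labels. Anchors whose placement is ambiguous (a
second hit with an equal e-value or within 2 bits of bitscore) are dropped.
For each chromosome claiming two or more homologs (at least 2 anchors per
claimed homolog), blocks are ordered by median anchor position and a
minimal-misassignment changepoint partition is found (exhaustive for two
blocks, dynamic programming for more). Ties between equally good cuts go to
the cut with the largest flanking gap — the least-constrained junction. The
breakpoint is `floor` of the midpoint between the two flanking anchors, and
the flanking gap is retained as its uncertainty; no inversion-aware
segmentation is attempted, and discordant anchors are counted, not modelled.
An event whose minimal misassignment exceeds 10% of anchors is flagged
low-confidence.

Splitting maps points to the segment containing them (a point exactly at the
breakpoint goes right, position 0 of the right component); intervals are
assigned by midpoint, with a midpoint exactly at the breakpoint going left,
and spanning intervals flagged rather than clipped. Classification uses
*ancestral* (outgroup) component lengths: per fusion the shorter component is
SFC, the longer LFC, everything else NFC; length ties break lexicographically
with a warning. Sex chromosomes are not modelled by the generator; in real
data the Z should be excluded from NFC/LFC/SFC contrasts since fusions are
reported for autosomes.

## Composition

Windows are non-overlapping, 100 kb by default. The 100 kb / 500 kb choice is
genuinely underdetermined in the source material for this analysis style;
both are supported via `window_size`, and results in the package's tests use
the value stated in each call. GC is computed over non-N bases; repeat and
coding coverage use merged (union) intervals so overlaps are never double
counted; terminal windows shorter than half a window are dropped. Normalized
profiles map unfused chromosomes linearly onto [0, 1] and fused ones
piecewise-linearly so the fusion point lands at exactly 0.5; the map is
measure-preserving within each component.

Class contrasts are one-sided Wilcoxon rank-sum tests at alpha = 0.005
(exact where sample sizes permit, as in `stats::wilcox.test`). Scaling
relationships use the standardized major axis: slope = sign(r)·sd(y)/sd(x),
intercept through the means — appropriate when both variables carry error.
Group tests are permutation analogues of the likelihood-ratio machinery used
by SMA software: the common-slope statistic is the variance of group slopes
under label permutation; the elevation statistic is the difference in group
means of residual scores `y − b·x` under the pooled (within-group-centred)
common slope. With `n_permutations = 999` the smallest attainable P is
0.001.

**Known limitation.** The elevation permutation is exact when the groups
share an x distribution. When the groups occupy disjoint x ranges (intron
totals ~10 kb vs intergenic totals ~100 kb at the synthetic scale), noise in
the common slope leaks into the observed elevation difference, so elevation
P values for the intron/intergenic comparison should be read together with
the effect size (the elevation difference in log10 units, ~log10 of the
density ratio). At megabase scale, where the x–y correlation is near 1, the
leakage is negligible.

## Diversity at 4-fold degenerate sites

The caller is deliberately conservative:

1. One transcript per gene (longest total CDS, ties by id); CDS intervals
   overlapping a CDS of a different gene are removed outright.
2. Codons are read strand- and phase-aware; a trailing partial codon is
   dropped; codons containing N are discarded.
3. A codon with more than one position carrying an *observed* variant (an
   alternate allele present in at least one called genotype) is discarded.
4. Otherwise the third position is a 4D site iff it is 4-fold degenerate
   under the reference codon and under every observed allele at the single
   variant position. A first- or second-position variant can move a codon
   out of a 4-fold family (e.g. CTA is Leu-CTN, but the T allele of a C/T
   first-position variant gives TTA, whose third position is not 4-fold), so
   degeneracy is re-checked per allele.

With no variants, exactly the 32 codons of the 8 four-fold families (Leu-CTN,
Val, Ser-TCN, Pro, Thr, Ala, Arg-CGN, Gly) yield sites; the test suite pins
the caller to a brute-force substitution/translation oracle on 10,000 random
codons with planted variants.

Genotypes are kept only with DP > 10 and GQ > 30 (strict), or DP > 5 and
GQ > 20 under the low-coverage profile. Per site, pi is the mean pairwise
difference over all called alleles (two per called diploid); sites with fewer
than half their alleles callable (`min_called_fraction = 0.5`, a package
default — the genotype filter is the only missingness rule inherited from the
source analysis) are excluded from window means. Windows hold 500 consecutive
4D sites; a trailing window is kept if at least half full. Per-homolog pi is
the unweighted mean of window values (no weighting was specified for the
original per-chromosome averages; the unweighted mean is the simplest
defensible reading), normalized by the NFC mean to absorb differences in
effective population size. A pairwise mode (mean of the four between-sample
allele pairs) serves designs where within-population sampling is
compromised.

## The 50 cM recombination model

Assuming map length M = 50 cM for every chromosome in both the ancestor
proxy and the extant species (observed map lengths can override), the
per-base rate is r = M/L and the relative decrease after fusion is
`dr_rel = 1 − r_extant/r_anc`, where a fused homolog inherits the full fused
chromosome's extant length. `dr_rel` is negative when unfused chromosomes
shrank (a rate increase) — the model reproduces both signs. The relative
diversity change is defined as a ratio, `dpi_rel = (pi_norm,extant −
pi_norm,anc)/pi_norm,anc`, mirroring `dr_rel`; the exact axis formula was an
open choice and is recorded in the output metadata.

**Orientation.** The association is reported as the signed Spearman
correlation of `dpi_rel` against `dr_rel` (expected negative: the homologs
that lost the most recombination lost the most diversity).
`use_magnitude = TRUE` correlates `|dpi_rel|` with `dr_rel` (expected
positive), but that transform is not null-calibrated: under flat diversity
the shortest homologs have the noisiest pi estimates *and* the largest
`dr_rel`, which manufactures positive correlation. The signed form is
therefore the default and the one used in the acceptance checks; the
magnitude form is retained for descriptive use.

## Functional-element turnover

Reciprocal best hits use lowest e-value, then highest bitscore, then
lexicographic subject id (fully deterministic), with both directions required
to pass e ≤ 1e-10. Conservation per chromosome is the percentage of source
elements with an RBH; an ancestral-segment mode scores fused chromosomes per
homolog segment via the fusion map. Conservation is regressed on chromosome
length (Mb) and divergence time (Myr) by OLS with intercept — the
human-scaled units keep coefficients readable — and per-comparison simple
length slopes feed a paired t-test plus a ratio of mean absolute slopes when
comparing two element sources. CREs and exons are fitted separately by
default. No aligner is implemented: the analysis starts at the 12-column hit
table, and the synthetic generator fabricates hit rows from retention
indicators rather than mutating sequence — turnover is a bookkeeping model
here, which is exactly the level at which the downstream statistics operate.

## The synthetic system and what it does (not) show

`sim_config()` defaults define the study conditions: 31 ancestral
chromosomes; 10 fusions, each joining one of the 10 shortest chromosomes to a
distinct longer partner (head or tail at random; `random_pairing = TRUE`
gives the null pairing); repeat intensity `lambda0·(1 + (te−1)(2|x/L−0.5|)^2)`
with tail enrichment te = 3; GC elevated at tails and on shorter chromosomes
(`gc_size_effect = 0.04`), repeat density 20% on the longest chromosome
rising by 50% toward the shortest (`repeat_size_effect = 0.5`) — emulating
the observation that the smallest chromosomes carry the highest repeat and GC
loads; a diversity gradient `pi(L) = 0.12 − 0.018·log10 L` (floored at 1e-4)
planted only at 4D-eligible positions so recovery is exact in expectation;
6 diploid individuals with DP ~ Poisson(30) and 5% low-GQ genotypes to
exercise the filters; and logistic element retention
`plogis(4.5 − 10·L_Mb − 0.03·T_Myr)` at divergence times 26, 65 and 85 Myr.

Chromosome lengths are drawn log-uniform on [150 kb, 600 kb]. This is a
deliberate scale reduction from real lepidopteran chromosomes (5–20 Mb) so
that Monte-Carlo replication (20 fusion-recovery replicates, 2 × 50
end-to-end diversity replicates, permutation calibrations) is practical; the
retention coefficient `c_len = 10`/Mb is the megabase-scale effect
transported to this length range (same logit span across the karyotype). Structural
parameters — chromosome number, fusion count, short+long pairing, tail
enrichment, filter thresholds, divergence times, 50 cM maps — are at their
real-system values.

The generator does **not** emulate: inversion or translocation noise in
anchors (a `discordant_rate` option exists but defaults to 0, reflecting
curated orthology); sequence-level divergence behind the hit tables; indels;
linked-selection dynamics (the diversity gradient is imposed, not evolved
from a coalescent); or sex chromosomes. Passing tests therefore demonstrate
that each stage recovers what was planted under its stated model — they do
not validate the population-genetic theory itself against real data.

## Numerical choices and degenerate inputs

- Seeds: one master seed; each stage draws from a substream
  (`substream_seed`), so toggling stages does not shift other stages' draws;
  all substreams stay below 2^31.
- Breakpoint ties: equal-misassignment cuts resolve to the largest flanking
  gap; equal component lengths in classification resolve lexicographically
  with a warning.
- `detect_fusions` on a chromosome whose anchors are all one homolog emits no
  event; an empty anchor map is an error.
- Empty windows, homologs without 4D windows, and chromosomes without
  elements propagate as NA rows rather than errors.
- Spearman P values come from `stats::cor.test` (exact permutation
  distribution for small tie-free n, asymptotic otherwise; ties get average
  ranks).
- Perfectly collinear SMA input returns the exact slope and intercept;
  zero variance in either variable is an error.
- The identity `t = 0, P = 1` is returned for a paired effect-size test with
  identical slope vectors (the t statistic is otherwise undefined there).

## Problem sizes used by the test suite

Unit tests run on 2–12 chromosome systems; the planted-fusion recovery check
uses 20 replicates of the full 31-chromosome system (annotation only, no
sequence); the end-to-end diversity recovery uses 50 replicates each of the
gradient and flat-diversity configurations with sequence generated inside
gene spans only (intergenic sequence does not enter any diversity
computation); calibration and power of the elevation permutation test use
200 and 100 replicates at n = 10 per group. These sizes are the package's
validation design and are stated here so they can be scaled up knowingly.
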