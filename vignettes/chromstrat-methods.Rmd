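---
title: "Stratifying chromatin remodellers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying chromatin remodellers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromstrat asks a single integrative question of a panel of ATP-dependent
chromatin remodellers profiled by ChIP-seq: do their binding-site sets
separate into functional groups by where they sit in the epigenome —
actively marked chromatin (promoters, enhancers, transcribed regions),
repressively marked chromatin (polycomb and heterochromatin), DNA
methylation states, accessibility, and 3D-architecture features (lamina
domains, TADs, loop anchors)? This vignette documents the statistical
models, the tunable parameters, the synthetic study the package validates
itself on, and the numerical choices a maintainer would want to know about.

```{r setup, message = FALSE}
library(chromstrat)
library(dplyr)
```

## The randomization null for overlap enrichment

Every "is factor X enriched at feature Y" statement reduces to one
statistic: the total base pairs of overlap between a *segment set* (a
remodeller's peaks) and an *annotation* (a feature's intervals), compared
with what uniform placement would give.

The null model is deliberately the simplest defensible one. Each segment
is independently re-placed uniformly at random within the *workspace* (the
mappable genome, by default the whole genome), preserving its length;
placement is restricted to workspace intervals long enough to contain the
segment, and sampled segments may overlap one another. For each of
`n_iter` randomizations the total overlap with the annotation is recorded.
Then:

* **expected** = mean of the null overlaps;
* **fold** = (observed + 1) / (expected + 1). The 1 bp pseudocount on both
  sides keeps the fold finite in the near-zero-overlap regime (a real
  phenomenon: heavily methylated islands can carry a literal handful of
  peaks genome-wide);
* **p** = (1 + k) / (1 + n_iter), where k counts null overlaps at least as
  extreme as the observed one, taken in the tail of the observed direction
  (upper tail when fold ≥ 1, lower otherwise). The +1 estimator means p is
  never exactly zero and is bounded below by 1/(n_iter + 1); with
  n_iter = 10,000 the smallest reportable p is ~1e-4. The result also
  carries `p_enrich`, the upper-tail p alone, which is the exactly
  calibrated quantity for "significant enrichment" claims — the adaptive
  two-direction p rejects at roughly twice its nominal level under the
  null, as any post-hoc-direction test does.

No isochore, GC or composition matching is attempted: the null is uniform
within the workspace, and callers who need a mappability mask pass one as
the workspace.

**Oracle.** For a single segment of length $L$ on a contiguous workspace
$[0, W)$, the expected overlap has a closed form: summing per-base
inclusion probabilities over the annotation,
$\mathbb{E}[\text{overlap}] = \frac{1}{W-L+1} \sum_{b \in \text{ann}}
\big(\min(b, W-L) - \max(0, b-L+1) + 1\big)$.
`analytic_expected_overlap()` implements this independently of the
sampler, and the test suite requires the Monte-Carlo mean to sit within 3
standard errors of it across randomized geometries.

```{r oracle}
ann <- tibble(chrom = "chr1", start = 400, end = 500)
analytic_expected_overlap(L = 100, ann, W = 1000)
mean(sample_null_overlaps(tibble(chrom = "chr1", start = 0, end = 100),
                          ann, tibble(chrom = "chr1", start = 0, end = 1000),
                          n_iter = 2000, seed = 1))
```

Multiple testing uses Benjamini–Hochberg, corrected within each feature
family (one family per feature by default — the analogue of adjusting
within a figure panel). Group contrasts compare the four folds of each
remodeller group with the pooled-variance unpaired t-test (df = 6 for
4 vs 4).

## Rule-based element classification

Classification is a total, deterministic function of interval overlap
(≥ 1 bp everywhere; no reciprocal-fraction rules, since none is standard
for this design):

* **Promoters**: 2 kb windows around each TSS (`flank = 1000` on each
  side; the flank is a parameter because "a 2 kb region surrounding the
  TSS" is ambiguous between ±1 kb and ±2 kb, and ±1 kb keeps the total at
  the literal 2 kb). Labels, in precedence order: bivalent (H3K4me3 ∧
  H3K27me3) > active (H3K4me3 ∧ H3K27ac) > facultative repressed
  (H3K27me3) > constitutive repressed (H3K9me3) > unclassified. Bivalency
  outranks the active call because it is defined by exactly the
  co-occurrence the other labels would mask; windows carrying all three
  marks are additionally flagged `multi_mark` so the choice is visible in
  output.
* **Enhancers**: H3K4me1 peaks at least 2 kb from every TSS; *active* if
  they also overlap H3K27ac, p300 and a DNaseI site, otherwise *poised*.
  Any-overlap (not containment) is used for the DNaseI condition; the
  source design is silent and any-overlap is the weaker, more inclusive
  reading.
* **Chromatin states**: a 15-state segmentation collapses onto six labels
  (active promoter, transcription, active enhancer, bivalent, repressive,
  unmarked) through an editable two-column mapping
  (`default_state_collapse()`); unmapped state names are an error, never
  silently dropped.
* **CpG islands**: each island is split into 40 equal-width bins; per-bin
  means of per-site methylation ratios are taken over sites with coverage
  strictly greater than 5× (a site at exactly 5× is excluded — the filter
  is "greater than", and the same strict rule serves WGBS CpG methylation
  and NOMe-seq GCH accessibility). The island mean is the mean over
  non-empty bins; islands are *methylated* strictly above 50%, so a mean
  of exactly 0.5 is *unmethylated*; islands with no qualifying site are
  *no_data*.
* **Loop anchors**: *Type A* if the anchor overlaps at least one active
  promoter or active enhancer, else *Type B*; the two anchors of a loop
  are classified independently, and enrichment is computed over anchors,
  not loops.

## Making the two-group split algorithmic

A grouping read off enrichment panels by eye cannot be tested for
recovery. `stratify_remodellers()` therefore makes the split algorithmic: average-linkage hierarchical clustering of each remodeller's
log-fold profile (Euclidean distance), cut at k = 2; the cluster with the
higher mean log-fold over the *active* features is labelled Group 1. Each
remodeller also gets a contrast score (mean log-fold at active features
minus mean log-fold at repressive features), and the object reports a
separation statistic (between-group minus within-group mean distance) so a
degrading signal is visible before the labels flip.

Downstream integrations:

* **Expression linkage**: per expressed gene (mean TPM > 0 — the
  expression threshold is not stated in the source, and >0 is the weakest
  choice), the per-base signal mass of each group's tracks is pooled over
  the promoter window; the gene is assigned to the dominant group by the
  sign of the difference (ties labelled and excluded); a one-tailed
  Wilcoxon rank-sum test asks whether Group-1-dominant genes have higher
  log TPM. Raw pooled signal mass is used (no depth normalisation): with
  equal track counts per group the comparison is symmetric, and
  normalisation is left to the caller's tracks.
* **TPM**: counts/length rates scaled to sum to 1e6 per replicate, then
  averaged across replicates.
* **Architecture**: the genome is partitioned into TADs, boundaries and
  unorganised chromatin — boundaries take precedence where they overlap
  TADs, so the three classes are disjoint and exhaustive and their
  percentages sum to 100 exactly. Binding sites are assigned to a class by
  midpoint, so per-remodeller percentages also sum to 100. The genome size
  is always the sum of the chromosome-sizes file, never a constant.

## The synthetic epigenome

`simulate_epigenome()` generates, from one seed, a complete toy study with
the statistical structure the analysis assumes, plus a ground-truth
manifest. Its defaults *are* the validation study conditions:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 10 Mb | two chromosomes |
| remodellers | 8 (4 + 4) | BRG1/SNF2H/CHD3/CHD4 planted Group 1; BRM/INO80/SNF2L/CHD1 Group 2 |
| peaks | 2,000 each | log-normal widths, median ≈ 400 bp (>90% under 750 bp) |
| ρ1 | 5 | Group 1 odds of a peak start landing in active states vs elsewhere |
| ρ2 | 3 | Group 2 odds for the repressive state |
| lamina domains | 10% of genome | carved from unmarked chromatin; all peaks excluded |
| islands | 400 | per-site ratios Beta-distributed, means ≈ 0.05 / 0.85 |
| GCH accessibility | 0.4 vs 0.1 | mean ratio at active elements vs elsewhere |
| δ | 0.5 | log-expression shift of Group-1-dominant promoters |
| loops | 150 (300 anchors) | exactly 20% of anchors planted Type A |

States tile each chromosome as a Markov-free sequence of segments (state
drawn with probability ∝ fraction/mean-length, length
minimum + exponential), so expected genome fractions match the configured
ones; active-promoter and bivalent segments have a 2 kb minimum so a ±1 kb
promoter window around a TSS at the segment midpoint stays inside its
segment — that is what makes noise-free label recovery exact rather than
approximate. Marks are implied deterministically by state (active
promoter ⇒ H3K4me3 + H3K27ac + DNaseI; active enhancer ⇒ H3K4me1 +
H3K27ac + p300 + DNaseI, with a 30% poised subset carrying H3K4me1 only;
bivalent ⇒ H3K4me3 + H3K27me3; repressive ⇒ H3K27me3 or H3K9me3;
transcription ⇒ H3K36me3).

Peak placement is a two-component mixture over base-pair space: with odds
ρ the start falls uniformly in the preferred states, otherwise uniformly
elsewhere; lamina domains are excluded from both components and from peak
bodies; overlaps within one remodeller are resolved by rejection
resampling. Two consequences are worth knowing. First, the *density
ratio* of peak starts (preferred vs elsewhere, per bp, lamina excluded) is
the unbiased estimator of ρ — the bp-overlap enrichment fold is *not* ρ
but ρ/(ρf + 1 − f) for a feature occupying fraction f of the genome, which
is why parameter-recovery checks use `planted_density_ratio()`. Second,
the rejection step thins dense regions slightly more, biasing the realised
ratio a few percent low at default occupancy; the ±15% recovery band
absorbs this known bias.

One global seed drives a named substream per layer
(states, lamin, marks, peaks/NAME, islands, meth, gch, genes, tads, loops,
fasta), so adding or removing a layer never perturbs the others, and the
same (config, seed) emits byte-identical files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level noise and peak-calling artefacts
(peaks are exact intervals, not called from reads), mark spill-over across
state boundaries, correlated placement between remodellers beyond the
shared state preference, CpG-density structure in the i.i.d. FASTA
sequence, isochore/GC biases that a uniform null cannot absorb, and
copy-number or mappability structure. Recovery results on this synthetic
study validate the *machinery* (estimators, classifiers, tests,
determinism), not the biology of any particular cell line.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; 1-based dialects must be
  converted at the reader boundary. Chromosome names are taken verbatim —
  a `chr1`/`1` mixture is an error, not a warning.
* Region centre = floor((start + end)/2); even-width ties resolve
  leftward. Score-matrix windows clipped at chromosome ends are padded
  with zeros (the clipped part counts as signal 0 over the full bin
  width); when 2·flank is not a multiple of n_bins, bin widths differ by
  at most 1 bp.
* Merged-interval algebra (merge/intersect/subtract/overlap-bp) runs as a
  vectorized sweep in a linearized coordinate space and is
  property-tested against a per-base bitmask oracle on ≤10 kb genomes;
  overlap queries, nearest distances and coverage piling use
  GenomicRanges.
* Readers reject invariant-violating input (start ≥ end, methylated >
  total, duplicate positions, overlapping bedGraph runs, out-of-bounds
  records) with the offending line number; nothing is silently repaired.
  Empty files are empty sets, not errors.
* Degenerate statistics error loudly: zero pooled variance in the group
  contrast, all-zero counts in TPM, zero-variance vectors in correlation,
  fewer than two genes per dominance class in the expression link.
* Every stochastic function takes an explicit seed; the pipeline derives
  per-stage substreams from one config seed, and stage outputs embed the
  package version, a hash of the scientific config parameters (not paths)
  and the seed, so re-runs are byte-identical wherever they are written.

## Problem sizes used in validation

The package's own validation suite runs the headline recovery at the
default study scale (2 × 10 Mb, 8 × 2,000 peaks): 20 independent
generator seeds for group recovery (enrichment matrices at 200
randomizations each — fold estimates need the null *mean*, which is
precise long before the tail is), one full-panel matrix at 1,000
randomizations for the significance claims (p resolution 1/1001, well
below the 0.05 and 0.001 levels in use), 500 replicates for type-I
calibration, and a 2 × 1 Mb pipeline for the end-to-end determinism
check, which is a scale-free property. Single-test defaults remain
n_iter = 10,000.

## Known limitations

* The uniform-placement null ignores GC/isochore composition and
  mappability unless a workspace mask is supplied; enrichment at
  composition-confounded features will be overstated on real data.
* The two-group split assumes k = 2; a genuinely three-group panel would
  be forced into two clusters (the separation score is the tell).
* The adaptive-direction p-value is reported for compatibility with the
  observed-direction convention but is not uniform under the null; use
  `p_enrich` (or double the adaptive p) for calibrated inference.
* `analytic_expected_overlap()` enumerates per annotation base and is an
  oracle for tests, not a production path for megabase annotations.
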