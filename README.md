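# chromstrat

Integrative epigenomic stratification of chromatin remodellers.

ATP-dependent chromatin remodellers (SWI/SNF, ISWI, INO80-like and CHD
family ATPases such as BRG1, SNF2H, CHD1, ...) position nucleosomes
across the genome, but panels of them are rarely analysed together across
the layers of the epigenome. Given each remodeller's ChIP-seq binding
sites plus interval and per-position data for histone marks, chromatin
states, CpG methylation, GpC accessibility, expression and 3D
architecture (lamina domains, TADs, chromatin-loop anchors), `chromstrat`
answers: **do the remodellers stratify into functional groups by where
they bind** — one group preferring actively marked chromatin, another
repressively marked chromatin — and how does that grouping propagate into
accessibility, expression and genome architecture?

The statistical core is a Monte-Carlo randomization test for
segment–annotation overlap. For segments $S$ (peaks) and annotation $A$,
each segment is re-placed uniformly at random within the mappable
workspace (length preserved) for $n$ iterations; with observed overlap
$o$ and null mean $e$,

$$\text{fold} = \frac{o + 1}{e + 1}, \qquad
  p = \frac{1 + \#\{\text{null} \ge o\}}{1 + n}$$

(lower tail when fold < 1), with Benjamini–Hochberg correction per
feature family and pooled-variance t-contrasts between group mean folds.
Fold above one is enrichment, below one depletion. Around this sit
rule-based classifiers (promoter classes by mark co-occurrence, distal
active/poised enhancers, CpG-island methylation under a 40-bin >50% rule,
Type A/B loop anchors), signal score matrices, TPM-based expression
linkage with a one-tailed Wilcoxon rank-sum test, a TAD/boundary genome
partition, an algorithmic two-group stratification (clustering of
log-fold profiles), and a fully seeded synthetic-epigenome generator so
the entire analysis validates end-to-end without any external download.

## Worked example

Simulate a small two-chromosome study (four remodellers planted to prefer
active chromatin with odds 5, four to prefer repressive chromatin with
odds 3), test every remodeller against every chromatin state, and recover
the grouping:

```r
library(chromstrat)
library(dplyr)

sim <- simulate_epigenome(
  sim_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
             n_peaks = 500, n_genes = 150, n_islands = 120,
             n_loops = 40, seed = 42),
  out_dir = tempfile())

feats <- split(sim$states, sim$states$name) |>
  setNames(paste0("state_", sort(unique(sim$states$name))))
feats$lamin <- sim$lamin

enr <- enrichment_matrix(sim$peaks, feats, genome_workspace(sim$sizes),
                         n_iter = 1000, seed = 1)
tidy(enr) |>
  filter(segments_name %in% c("BRG1", "CHD1")) |>
  select(segments_name, feature_name, observed_bp, fold, p_empirical, q_bh)
#>    segments_name feature_name          observed_bp      fold p_empirical    q_bh
#>  1 BRG1          state_active_enhancer       38061 2.56         0.000999 2.00e-3
#>  2 BRG1          state_active_promoter       16747 2.08         0.000999 2.00e-3
#>  4 BRG1          state_repressive            23004 0.640        0.00200  2.66e-3
#>  7 BRG1          lamin                           0 0.0000452    0.000999 9.99e-4
#>  9 CHD1          state_active_promoter        6078 0.723        0.121    1.93e-1
#> 11 CHD1          state_repressive            93241 2.52         0.000999 1.60e-3
#> 14 CHD1          lamin                           0 0.0000441    0.000999 9.99e-4
```

BRG1 is ~2.1–2.6-fold enriched at active states and depleted from
repressive chromatin; CHD1 shows the mirror image; both are essentially
absent from the lamina-like domains (fold ≈ 0, the floor set by the +1 bp
pseudocount). Clustering the log-fold profiles recovers the planted
groups exactly:

```r
groups <- stratify_remodellers(
  enr,
  active_features = c("state_active_promoter", "state_active_enhancer",
                      "state_transcription"),
  repressive_features = "state_repressive")
groups
#> <chromstrat_groups>
#>   Group1: BRG1, SNF2H, CHD3, CHD4
#>   Group2: BRM, INO80, SNF2L, CHD1
#>   separation (between - within distance): 1.854

group_contrasts(enr, setNames(groups$assignments$group, groups$assignments$name)) |>
  filter(feature_name %in% c("state_active_promoter", "state_repressive"))
#>   feature_name          mean_g1 mean_g2 t_statistic    df p_two_sided
#> 1 state_active_promoter   2.46    0.806        7.05     6  0.000408
#> 2 state_repressive        0.628   2.32       -18.7      6  0.00000151
```

Group 1's mean fold at active promoters is significantly higher than
Group 2's (p = 4e-4, pooled t, df = 6), and significantly lower at
repressive chromatin — the two-group structure in one table. `tidy()`,
`glance()` and `autoplot()` methods exist for every result type, and
`run_pipeline(run_config(data_dir))` executes the whole
validate → classify → enrich → stratify → integrate sequence over a data
directory, writing one TSV per stage plus `summary.json`, byte-identical
across re-runs with the same config.

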