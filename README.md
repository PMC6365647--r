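# tcscensus

Census of two-component signal transduction systems (TCS) in bacterial
genomes, from Pfam domain annotations.

Two-component systems — a sensor histidine protein kinase (HPK) paired with a
DNA-binding response regulator (RR) via His→Asp phosphotransfer — are the most
common way bacteria sense and respond to their surroundings. How many of them
a genome carries, relative to genome size, is a readout of lifestyle:
streamlined oligotrophs keep very few sensors, copiotrophs and
particle-associated organisms keep many. `tcscensus` is for comparative
genomicists who have per-genome gene coordinate tables and gene→Pfam
assignments (e.g. warehouse annotation exports) and want reproducible
repertoire statistics and comparisons across genome cohorts.

## What it computes

* **Classification** (`classify_genome`): each gene becomes `HPK_ONLY`
  (HATPase-family domain: PF02518, PF13581, PF13589, PF14501, PF07536,
  PF07730), `RR_ONLY` (phosphoreceiver PF00072), `HYBRID` (both on one gene),
  `EXCLUDED` (gyrase/HSP90/MutL look-alikes PF00204, PF00183, PF13941;
  precedence over everything), or `NON_TCS`. Hybrids count on both sides:
  `n_hpk` and `n_rr` both include them.
* **Orphan detection** (`find_orphans`): a TCS gene is an orphan when its
  start point lies strictly more than 4 average gene lengths (configurable)
  from every other TCS gene's start on the same contig.
* **Repertoire statistics** (`summarize_genome`, `compare_cohorts`):
  HPK per 100 protein-coding genes (100·n_HPK/n_genes), RR/HPK ratio,
  % hybrid; pooled-variance Student's t, one-way ANOVA, and bootstrap
  percentile CIs. Genomes with 0 HPK and/or 0 RR are excluded from
  ratio-based analyses (carried as `NA`, never as 0).
* **Clustering** (`select_k_by_silhouette`): k-means (k-means++ seeding,
  Lloyd iterations, 10 restarts) on (HPK/100 genes, genome size) after
  min–max scaling, with k chosen by maximal mean silhouette width.
* **Power-law fit** (`fit_power_law`): spectral counts vs phosphate modeled
  as y = a·x^b by least squares in log–log space, r² reported in log space.
* **Synthetic data** (`generate_genome`, `generate_cohort`,
  `generate_transect`): annotated genomes, lifestyle cohorts and proteome
  transects with planted ground truth, so the whole pipeline is testable
  without external data.
* **Pipeline** (`run_pipeline`): one YAML/list config in, a directory of
  stamped TSV/JSON/BED reports out, byte-reproducible under a fixed seed.

## Worked example

```r
library(tcscensus)

# a synthetic genome with known content: 3 paired systems, 2 orphan kinases,
# 2 orphan regulators, 1 hybrid, 1 excluded decoy among 200 genes
g   <- generate_genome(genome_spec(genome_id = "demo", n_genes = 200,
                                   n_paired_systems = 3, n_orphan_hpk = 2,
                                   n_orphan_rr = 2, n_hybrid = 1,
                                   n_excluded_decoys = 1, seed = 42))
cls <- classify_genome(g$annotation)
cls
#> <tcs_classification> demo
#>   HPK: 6  RR: 6  hybrid: 1  excluded: 1
orph <- find_orphans(cls, g$annotation)
s    <- summarize_genome(cls, orph, g$annotation)
# hpk_per_100_genes = 3.000, rr_hpk_ratio = 1.000, pct_hybrid = 16.67
```

6 HPK = 3 paired + 2 orphan + 1 hybrid (the hybrid also makes the 6th RR);
the decoy is excluded from every count. 6/200 genes = 3.0 kinases per 100
genes; 1 hybrid among 6 kinases = 16.7% hybrid.

```r
# planted copiotroph/oligotroph contrast: 1.4 vs 0.8 HPK per 100 genes
coh <- generate_cohort(seed = 7)
d   <- split(coh$planted$hpk_per_100_genes, coh$planted$group)
two_sample_ttest(d$copiotroph, d$oligotroph, labels = c("copiotroph", "oligotroph"))
#> <cohort_result> Student t (two-tailed, pooled variance)
#>   copiotroph: n = 40, mean = 1.46
#>   oligotroph: n = 40, mean = 0.8032
#>   statistic = 13.13, df = 78, p = 1.89e-21

# abundance vs phosphate transect with planted y = 3 * x^-0.8
tr <- generate_transect(seed = 7)
fit_power_law(join_profiles(tr$abundance, tr$environment))
#> <power_law_fit> y = 3.035 * x^-0.7976
#>   r^2 (log-log) = 0.993, r^2 (linear) = 0.987, n = 50 (0 dropped)
```

The copiotrophs' higher kinase density is recovered at p ≪ 0.01, and the
fitted exponent −0.798 sits on the planted −0.8 (an inverse
abundance–nutrient relationship).

Real data enter through `read_genome_annotation()` (GFF3 or TSV gene tables +
TSV domain tables) and `read_metadata()`; see `vignettes/tcs-census-methods.Rmd`
for the model and every tunable parameter.

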