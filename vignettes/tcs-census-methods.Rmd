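---
title: "Methods: censusing two-component signal transduction systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing two-component signal transduction systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcscensus)
```

## The biological question

Two-component systems (TCS) are the dominant signal transduction machinery of
bacteria: a sensor histidine protein kinase (HPK) autophosphorylates on a
conserved histidine in response to a stimulus and passes the phosphoryl group
to the phosphoreceiver (REC) domain of a response regulator (RR), which
typically alters transcription. Counting these genes across genomes, and
normalizing for genome size, turns a genome into a quantitative readout of how
much sensing an organism invests in — oligotrophs with streamlined genomes
carry few sensors, copiotrophs and particle-associated organisms carry many.
`tcscensus` implements that census end to end: domain-based gene
classification, orphan-gene detection, normalized repertoire statistics and
cohort comparisons, repertoire/genome-size clustering, and a power-law model
linking a TCS protein's abundance to nutrient concentration.

## Gene classification from Pfam domains

Classification uses only Pfam domain content, because domain annotations are
computed uniformly across genome warehouses while gene product names are not.
The default rule set is:

* **HPK**: any HATPase-family catalytic domain — PF02518 (HATPase_c), PF13581
  (HATPase_c_2), PF13589 (HATPase_c_3), PF14501 (HATPase_c_5), PF07536
  (HWE_HK), PF07730 (HisKA_3/HWE-type). The HATPase domain is better conserved
  than the phosphoacceptor domain and identifies kinases more completely. Two
  HWE-type accessions circulate in published rule lists; the default is their
  union, and `tcs_ruleset()` makes the sets fully configurable.
* **RR**: the phosphoreceiver domain PF00072.
* **Hybrid kinase**: a single gene carrying both an HATPase and a REC domain.
  Hybrids signal through multi-step phosphorelays; they are counted on *both*
  sides of the census (`n_hpk` and `n_rr` each include hybrids).
* **Excluded**: the HATPase fold also occurs in DNA gyrase B (PF00204), HSP90
  (PF00183) and MutL (PF13941). Any gene carrying one of these is removed from
  the analysis outright — exclusion takes precedence even over a REC domain,
  a deliberately conservative choice that keeps gyrase-like false positives
  out of both counts.

Domains are counted with set semantics (multiple copies of a domain on one
gene count once); the census counts genes, not domains. Hpt phosphotransfer
proteins and RR output-domain subfamilies are out of scope.

## Orphan detection

TCS genes usually co-locate in one operon with their partner. An *orphan* is a
TCS gene whose start point lies strictly farther than `multiplier` (default 4)
average gene lengths from the start of every other TCS gene on the same
replicon. Choices fixed here:

* Distance is start-to-start, matching a number-line depiction of gene
  starting locations; the average gene length is the arithmetic mean of
  `end − start + 1` over protein-coding genes only.
* The inequality is strict at the threshold; at average length 1000 bp,
  starts {1, 4001} (distance 4000) are *not* orphans, {1, 4002} are.
* Contigs are linear, with no circular wraparound; a contig's sole TCS gene is
  an orphan by convention (infinite distance). Draft genomes therefore tend to
  slightly overcount orphans, which is noted rather than corrected.
* Excluded and non-TCS genes are neither orphan candidates nor neighbors.
* Orphan hybrids count toward both the orphan-HPK and orphan-RR tallies,
  consistent with hybrid counting in the census.

Internally the nearest neighbor is found in one pass over starts sorted per
contig; the test suite proves this equal to a quadratic all-pairs scan on
1000 random genomes.

## Repertoire statistics

Per genome: `hpk_per_100_genes = 100 · n_hpk / n_protein_coding` (genome-size
normalization), `rr_hpk_ratio = n_rr / n_hpk`, and
`pct_hybrid = 100 · n_hybrid / n_hpk`. Ratios are undefined when a genome has
zero HPK and/or zero RR; they are carried as `NA` and such genomes are
excluded from ratio-based aggregates and tests (with the dropped count
reported), but never from count-based ones.

Cohort comparisons: `two_sample_ttest()` is the classic pooled-variance
Student's t (df `n_a + n_b − 2`), two-sided by default with sidedness exposed
as a parameter; `one_way_anova()` reports the standard between/within F with
(k − 1, N − k) df. For any two-group comparison F = t² with identical
p-values, and the suite asserts this identity on random data — a useful
cross-check since the t statistic is computed from the closed form while the F
comes through `stats::lm()`. Confidence intervals for group means use the
percentile bootstrap of the resampled mean (default 10,000 replicates); a seed
is mandatory, and the interval is a deterministic function of it. No
multiple-testing correction is applied anywhere, by design.

## Clustering genomes by signaling investment

Genomes are clustered in the two-dimensional space (HPK per 100 genes, genome
size in bp). Genome size comes from metadata rather than being recomputed from
contigs, so real and synthetic inputs behave identically. Because the two
axes differ by six orders of magnitude, features are scaled first; "unit
normalization" is ambiguous between per-feature and per-sample conventions, so
the default here is per-feature min–max to [0, 1] — the variant that actually
removes the bp-versus-ratio scale mismatch — with z-score and per-sample unit
norm available for sensitivity analysis (per-sample normalization of a
2-D point collapses it onto the unit circle and discards magnitude, which is
rarely what one wants here).

K-means uses Lloyd iterations with k-means++ seeding, best of `n_init = 10`
restarts by within-cluster sum of squares, deterministic under the supplied
seed. The number of clusters is chosen by maximizing the mean silhouette
width over `k_range` (default 2–10, wide enough to bracket the 4-cluster
structure typical of marine repertoire data); ties break toward the smaller k
(parsimony). Silhouette widths follow `s(i) = (b − a)/max(a, b)` with
Euclidean distances; singleton clusters score 0 by convention. Degenerate
inputs are handled explicitly: with fewer distinct points than k the
clustering warns and returns one effective cluster per distinct point, and
such k are never selected. Each candidate k runs at derived seed `seed + k`,
making the selection invariant to the order of `k_range`.

## The abundance–phosphate power law

A response regulator involved in phosphate acquisition is expected to be more
abundant where phosphate is scarce. `fit_power_law()` models spectral counts
as `y = a·x^b` by ordinary least squares of `log y` on `log x`: the model is
linear in log-log space, multiplicative (lognormal) noise is the natural error
structure for spectral counts, and the fit is then exactly scale-equivariant
(scaling y scales a; substituting 1/x negates b — both asserted in tests).
Pairs with nonpositive counts or concentrations are dropped and counted, not
offset: a pseudo-count would bias the exponent, and the dropped tally makes
the censoring visible. The canonical r² is the log-space coefficient of
determination (an original-space r² is also reported for sensitivity); a flat
response has r² defined as 0. No sign constraint is placed on the exponent;
an inverse relationship simply fits with `b < 0`.

## What the synthetic data emulate — and what they do not

`generate_genome()` lays genes end to end per contig (lengths from a normal
around `mean_gene_length`, sd 20% of the mean, truncated to ±50%; constant
intergenic gap) and plants: paired systems as adjacent HPK+RR genes, isolated
(orphan) kinases/regulators/hybrids placed by rejection sampling so that their
nearest TCS start distance strictly exceeds the four-average-gene-length
threshold, and decoy genes carrying an HATPase plus an exclusion domain.
Placement is verified post hoc against the orphan rule itself before emission;
a spec whose spacing cannot be honored errors after 1000 attempts rather than
silently violating a constraint. Filler genes draw domains from a dummy
accession pool (PF9xxxx) disjoint from every rule-set accession, so they can
never collide with the classifier. Everything is a deterministic function of
(spec, seed), down to byte-identical output files.

`generate_cohort()` plants a lifestyle contrast in kinase density
(defaults: copiotroph 1.4 vs oligotroph 0.8 HPK per 100 genes, sd 0.2,
40 genomes per group); densities become integer kinase counts against a
sampled gene total, so realized group means differ from planted ones only by
rounding. At small gene totals this quantization is visible (a density of 0.3
on a 150-gene toy genome means 0 or 1 kinases), which is why cohort scenarios
meant to have smooth density structure should use realistic gene totals
(1200–6000). `generate_transect()` draws phosphate concentrations
log-uniformly and applies the planted power law with lognormal noise.

The generators deliberately do **not** simulate nucleotide sequence, operon
transcription, annotation error, phylogenetic covariance among genomes, or
habitat-correlated genome size. Passing round-trip tests therefore
demonstrates that the pipeline computes its definitions exactly — not that the
classifier is robust to the annotation noise, split genes or missing domains
of real draft genomes.

## Validation scale and reproducibility

The shipped validation runs at desk scale, chosen so the whole suite completes
in about two minutes: classifier invariants on dozens of random genomes;
orphan detection against the quadratic oracle on 1000 genomes; exact
ground-truth round trips for 100 seeded genome specs; cohort power and type-I
calibration over 100–200 simulated cohorts; bootstrap coverage over 1000
samples of size 100; silhouette recovery of k ∈ {2, 3, 4} over 60 seeded blob
configurations; and power-law recovery (|b̂ − b| ≤ 0.05) over 100 transects.
`scripts/acceptance.R` recomputes the headline quantities from scratch at the
same scales from a single command-line seed.

Every stochastic stage requires an explicit seed, `run_pipeline()` refuses a
stochastic configuration without one before doing any work, and reports embed
the package version, a configuration hash and the seed, so a run can be
reproduced byte for byte from its output directory alone.

## Known limitations

* Classification inherits the input annotation: genes lacking Pfam calls are
  invisible, and draft-genome fragmentation inflates orphan counts.
* Whether "protein-encoding genes" includes pseudogenes is delegated to the
  input's `is_protein_coding` flag.
* Start-to-start distance is one of several defensible orphan metrics
  (nearest-edge distance would differ near long genes); the multiplier is
  exposed for sensitivity analysis.
* Cohort tests treat genomes as independent; phylogenetic non-independence is
  not modeled.
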