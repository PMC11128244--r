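# metamobilome

Analysis toolkit for **meta-mobilomes**: populations of circularized DNA
elements (plasmids, phages, integrative and conjugative elements, and
cryptic circles) assembled from environmental shotgun metagenomes. The
package was built around the analysis of a heavy-metal-contaminated
subsurface aquifer, where samples split into a highly contaminated stratum
(`high_U`, uranium above 0.126 µM) and a low-contamination stratum
(`low_U`), and the question is whether the mobile gene pool of the
contaminated stratum is enriched in heavy-metal resistance genes (HMRGs)
and how those genes are organized and mobilized.

## What it computes

Given (i) a gene-level annotation table for each circular element, (ii) an
external-evidence table (viral-prediction category, plasmid-database mash
hit, CRISPR-spacer matches, k-mer host call), and (iii) curated COG/Pfam
vocabularies shipped with the package:

1. **Artifact screening** — removes elements that look like organellar
   fragments (≥ 50 % of genes with organelle products/lineages) or
   tandem-repeat circularization artifacts (k ≥ 2 whole copies of a unit at
   ≥ 95 % per-copy identity), then dereplicates within each stratum
   (rotation/reverse-complement-invariant identity ≥ 0.99 over ≥ 0.90 of
   the shorter sequence; annotation-fingerprint equality when sequences are
   absent).
2. **Classification cascade** — each element gets exactly one label:
   *viral* (confident viral category 1/2/4/5) → *plasmid* (database hit
   with mash distance ≤ 0.1 and p ≤ 0.1) → *unclassified MGE* (MGE Pfam,
   then extended-library domains) → *cryptic*.
3. **Host prediction** — non-viral: a phylum (or class) is called iff
   > 50 % of CDS carry the same lineage; viral: k-mer host call, plus
   CRISPR-spacer hits filtered to ≤ 1 mismatch.
4. **Resistance statistics** — HMRG/ARG/conjugation gene screening;
   densities per Mbp and per CDS; per-gene enrichment between strata by
   two-tailed Fisher exact tests on absolute gene counts
   (minimum-likelihood convention) with Benjamini–Hochberg correction;
   the probability that an HMRG lies within ± 4 ORFs of another HMRG on
   its circular element; gene co-occurrence matrices; element-level
   association between HMRG carriage and conjugative machinery; candidate
   auxiliary metabolic genes (AMGs) on viral elements; size statistics
   with Welch's two-sided t-test.

A **synthetic-mobilome generator** (`simulate_mobilome()`) produces
annotated populations with planted structure — bimodal 3 kb/70 kb length
mixture, stratum-dependent HMRG cluster rates, conjugation modules,
host-taxonomy mixtures with imperfect annotation fidelity, viral/plasmid
evidence — together with a ground-truth manifest, so every stage is
testable without external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
survey (400 elements per stratum). `Rscript analysis/01_simulate.R` through
`06_report.R` print, among other things:

```
class recovery vs ground truth: 100.0%
HMRG density (per Mbp):
  stratum  per_mbp
1  high_U 8.746377
2   low_U 2.774575
adjacency probability (+/-4 ORFs): high 0.927, low 0.762
mean length: high 39159 bp, low 18922 bp (Welch p = 7e-13)
HMRG genes on conjugative elements: 12.8% (Fisher p = 0.611)
```

Reading these numbers: the classifier recovers every planted label from
the emitted evidence; the contaminated stratum's elements carry ~3× more
HMRGs per Mbp and are on average twice as long (the low stratum is skewed
toward the 3 kb mode); planted HMRGs sit in consecutive-ORF clusters, so
most HMRG genes have another HMRG within four ORFs; and because the
generator plants conjugation modules independently of HMRG clusters, the
HMRG–conjugation association is, correctly, not significant on synthetic
data. In the field survey this association is strong; here it serves as a
negative control of the statistic.

In code, the same pipeline is one call:

```r
library(metamobilome)
sim <- simulate_mobilome(generator_config(seed = 1, n_high = 400, n_low = 400))
res <- run_pipeline(sim$elements, sim$evidence)
res$summary$hmrg_density
res$summary$adjacency
```

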