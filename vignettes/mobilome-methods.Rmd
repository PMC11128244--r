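---
title: "Methods: screening, classifying and quantifying a meta-mobilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, classifying and quantifying a meta-mobilome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamobilome)
```

## The analysis problem

Circularized DNA elements recovered from metagenome assembly graphs are a
mixture of genuine mobile genetic elements (plasmids, phages, ICEs),
cryptic circles with no recognizable mobility machinery, and assembly
artifacts. This package implements the full downstream analysis for such a
population sampled from two contamination strata of a uranium- and
heavy-metal-contaminated subsurface: artifact screening, MGE-type
classification, host prediction, and heavy-metal-resistance-gene (HMRG)
statistics. The working assumptions are that (i) every element is a closed
circle, so gene order is circular and coordinates may wrap the origin;
(ii) per-gene functional and taxonomic annotations and the external-tool
evidence (viral categories, plasmid-database distances, CRISPR-spacer
matches, k-mer host calls) are precomputed inputs, not recomputed here;
and (iii) contamination stratum (`high_U` / `low_U`, split at 0.126 µM
uranium in groundwater) is a property of the source site known upstream.

## Screening

Two rule-based filters replace what is, in practice, a manual curation
step, with explicit and conservative thresholds:

* **Organelle filter.** An element is removed when at least half of its
  genes match organelle keyword tokens (mitochondri-, chloroplast,
  plastid, eukaryotic lineages, ...) in product text or taxonomy. The 0.5
  threshold is inclusive: fragments of organellar genomes are typically
  annotated wall-to-wall with such products, so requiring a majority keeps
  bacterial elements that merely carry one organelle-like annotation.
* **Tandem-repeat filter.** A repeat region traversed k times by the
  assembler can circularize into k whole copies of one unit. For every
  divisor k ≥ 2 of the length we split the sequence into k copies and flag
  it when every copy agrees with the first at ≥ 95 % of positions. A
  rotated tandem array is still a tandem array, so no rotation search is
  needed. Elements without a sequence cannot be screened and pass with a
  logged message.

**Dereplication** is greedy and longest-first within a stratum: an element
joins an existing representative at ≥ 99 % identity over ≥ 90 % of the
shorter sequence, computed rotation- and strand-invariantly by locally
aligning the shorter sequence against the doubled longer one (both
orientations). When sequences are unavailable the fallback is exact
equality of the rotation-canonical per-gene COG/Pfam fingerprint, with the
additional guard that lengths differ by no more than the identity
tolerance (1 %) — without the guard, small fully-unannotated elements
would collapse spuriously. Processing order (length descending, then id)
makes the clustering independent of input order and idempotent. The
quadratic-cost alignment is intended for desk-scale inputs (thousands of
elements, sequences up to tens of kb).

## Classification cascade

Exactly one tier fires per element, in order: confident viral category
(1/2/4/5; the low-confidence categories 3 and 6 are discarded as
evidence), plasmid-database hit with mash distance ≤ 0.1 and p ≤ 0.1
(inclusive, since these are the search parameters of the comparison), an
MGE-associated Pfam on any gene, an extended-library (CDD / TIGRFAM /
SMART / PGAP) MGE domain, and finally *cryptic*. Viral outranks plasmid
because the plasmid-database comparison is only meaningful for non-viral
elements. Elements whose matched Pfams include a replication-initiation
family are flagged `plasmid_replication_domain`. The cascade is
deterministic and monotone in the intended sense: adding an MGE Pfam to a
cryptic element can move it only to *unclassified MGE*.

The shipped vocabularies (`inst/extdata/vocab/`) are an in-package
curation: HMRG COGs with their metal spectra and canonical gene names
(merA, merR, zntA, czcD, cusA/F, chrA/B1, copZ, pcoB, ars/acr, ter/teh
families, ...), ARG COGs, conjugal-transfer-system COGs (type IV
secretion, coupling and relaxase machinery), MGE Pfams with the
replication subset marked, extended-library domain ids, and keyword lists.
The extended-domain list in particular is a best-effort transcription — no
authoritative public list exists for that manual screen — and all files
can be overridden via `load_vocabulary(dir = ...)`.

## Host prediction

For non-viral elements, the per-gene taxonomy is tallied at phylum or
class level and a taxon is called iff its count **strictly** exceeds half
the denominator. The default denominator is *all* CDS — the conservative
reading of a ">50 % of CDS" rule, consistent with the high unassigned
rates seen in environmental surveys — with `denominator = "annotated"`
available as the permissive alternative; exact ties are unassigned. Viral
hosts come from the k-mer predictor's phylum call, and CRISPR-spacer hits
are filtered to at most one mismatch and deduplicated by taxon. Where an
element has a plasmid-database hit, the vote is cross-checked against the
database's host metadata (string-normalized, phylum level) and reported as
a consistency column rather than overriding the vote.

## Statistics

* **Fisher exact test** (two-tailed, minimum-likelihood convention): the
  p-value sums hypergeometric probabilities of all tables with the
  observed margins whose probability does not exceed the observed table's
  (relative tolerance 1e-7, the convention of mainstream implementations).
  An all-zero table returns p = 1 with a warning. The unit and acceptance
  suites verify exact agreement with the reference conditional-exact
  implementation over every 2×2 table with N ≤ 30.
* **Enrichment** between strata is computed per COG on absolute gene
  counts against the stratum CDS totals, with Benjamini–Hochberg
  correction across the COGs of one category (step-up, `stats::p.adjust`);
  rows are emitted for every vocabulary COG, including 0/0 rows at p = 1,
  so the correction denominator is the full curated list. Odds ratios are
  reported with a Haldane–Anscombe 0.5 correction for display only.
* **Neighborhood statistic**: the fraction of HMRG genes with another
  HMRG-carrying gene within ± 4 ORFs, at circular ordinal distance
  (minimum of clockwise and counterclockwise differences; `circular =
  FALSE` disables the wrap for sensitivity analysis). Genes are pooled
  across elements by default; `per_element_mean = TRUE` averages
  per-element probabilities instead. A set with no HMRG genes returns
  `NA` with a warning — deliberately distinct from an observed 0. A gene
  carrying two HMRG COGs is a single gene and never self-adjacent.
* **Welch's two-sided t-test** compares stratum length distributions;
  identical constant samples return t = 0, p = 1, and two constant
  samples with different means are rejected as a degenerate input.

## The synthetic generator

`generator_config()` defines the study conditions the package is tested
under; `simulate_mobilome()` realizes them deterministically for a seed.

| parameter | default | rationale |
|---|---|---|
| length mixture | log-normals at ln 3000 / ln 70000, shape 0.5; weights 0.5/0.5 (high), 0.8/0.2 (low) | reproduces the observed bimodal size distribution with the low stratum skewed small; only the modes are constrained by data, shape 0.5 is a free choice |
| `gene_pitch` | 1000 bp | one CDS per kb, typical prokaryotic coding density |
| `p_viral`, `p_viral_decoy` | 0.07, 0.02 | viral fraction near the observed ~7 %; decoys carry low-confidence categories 3/6 the classifier must discard |
| `p_plasmid_hit` | 0.015 | plasmid-database hits are rare (~1–2 %) |
| `p_mge_pfam`, `p_mge_domain` | 0.30, 0.05 | Pfam tier dominates the unclassified-MGE class; the extended tier is a small second pass |
| `hmrg_cluster_rate` | 0.10 (high) / 0.02 (low) | the planted stratum effect: a 5× per-element rate ratio |
| cluster size | 1 + Poisson(3), consecutive ORFs | clusters recoverable by the ± 4-ORF statistic; truncated to the element's gene count |
| `p_conj` | 0.25 on elements > 20 kb | conjugation modules (5–10 distinct conjugal COGs) occur on larger replicons; planted independently of HMRG clusters, so the HMRG–conjugation association acts as a negative control |
| host mixture | high stratum 70 % Proteobacteria | the contaminated stratum is a simplified, Proteobacteria-dominated community |
| `annotation_fidelity`, `p_unannotated_tax` | 0.7, 0.2 | realistic per-gene taxonomic noise for the majority-vote recovery tests |

Background genes draw COGs from a neutral pool disjoint from every curated
list, so planted signal is unambiguous, and cryptic elements are realized
simply by emitting no MGE-related evidence or domains. The generator
emulates annotation *tables*, not sequences: it does not model nucleotide
evolution, shared backbones between elements, correlated annotation
errors, biased database coverage, or assembly chimerism. Passing recovery
tests therefore demonstrates that the analysis logic is correct under the
declared noise model — not that real annotations satisfy that model.

## Calibration and power under the default conditions

The type-I side is clean: with no planted stratum effect (`null_config()`)
the average fraction of HMRG COGs reaching q < 0.05 is ~0 over 20 seeds,
as expected from the BH construction. The power side is instructive: the
5× *per-element* cluster-rate ratio translates into only a ~2× *per-CDS*
rate contrast, because the low stratum's much smaller elements shrink its
CDS denominator and truncate planted clusters. At 400 elements per stratum
the per-COG counts (roughly 5–15 vs 2–5) leave every individual Fisher
test non-significant even though the aggregate HMRG contrast is strong
(per-Mbp density ratio ≈ 2.6, z ≈ 3). Per-gene enrichment patterns of the
kind seen in the field survey (where HMRGs were ~6 % of CDS in the
contaminated stratum versus ~1.5 %) require a planted signal roughly an
order of magnitude stronger than these defaults produce. The acceptance
suite reports this measured power honestly rather than tuning the
generator toward significance.

## Problem sizes

The test and acceptance runs use 400 elements per stratum for survey-scale
checks (matching the scale at which calibration statements are made),
2000 elements for distributional checks on the length mixture, 20 seeds
for Monte-Carlo averages, and exhaustive enumeration for the Fisher oracle
(all 2×2 tables with N ≤ 30) — sizes chosen so each statement is tested at
the scale where its noise is well below the asserted margin.

## Known limitations

* The screening thresholds replace a manual curation step; they are
  documented defaults, not a reconstruction of any particular curator's
  decisions.
* Dereplication without sequences reduces to fingerprint equality and
  cannot detect near-identical but differently annotated elements.
* The extended-domain vocabulary is a best-effort transcription; the
  fourth cascade tier inherits its coverage.
* Viral taxonomy and lifestyle are pass-through metadata; the package
  never recomputes them from sequence.
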