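---
title: "From GWAS index SNPs to candidate regulatory variants"
author: "proxyreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS index SNPs to candidate regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyreg)
```

## The problem

A genome-wide association study reports index SNPs — the variants that
pass genome-wide significance (p < 5×10⁻⁸) at each associated locus. The
index SNP is rarely the causal variant: linkage disequilibrium (LD) makes
every variant strongly correlated with it an equally good statistical
candidate, and ~90% of association signals fall in non-coding sequence
where the plausible mechanism is regulatory. `proxyreg` implements the
standard desk workflow for turning an index-SNP list into a ranked set of
candidate regulatory variants:

1. **Proxy expansion** — compute pairwise LD from phased haplotype panels
   and expand each index SNP to every variant with r² ≥ 0.8 within a
   window;
2. **Evidence intersection** — overlap every variant with regulatory
   evidence tracks (TF ChIP-seq peaks, DNase peaks and footprints, motif
   instances, eQTL associations, histone marks);
3. **Category classification** — map each variant's evidence combination
   onto the ordered category scheme 1a–6 (1a strongest: eQTL + TF binding
   + matched TF motif + matched DNase footprint + DNase peak; 6 weakest:
   motif hit only; "ND" when no evidence record exists);
4. **Reporting** — emit the annotation table, the LD/category table and
   the category distribution, with summary counts.

The package ships a desk-scale case study from a refractive-error GWAS
follow-up (five loci — *MYO1D*, *TJP2*, *RDH5*, *CD55*, *CNDP2* — with 36
category-1 variants among 868 investigated), used throughout the test
suite.

## LD from phased haplotypes

For two biallelic sites with alternate-allele indicators $x, y$ over $2N$
haplotypes, with allele frequencies $p_A, p_B$ and joint haplotype
frequency $p_{AB}$:

$$D = p_{AB} - p_A p_B, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
D' = \frac{|D|}{D_{\max}}$$

where $D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D \ge 0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ otherwise. These are computed directly
from haplotype counts (`compute_pairwise_ld`), which keeps them exact and
makes $r^2(x,x) = 1$ an identity rather than an approximation. Only
phased input is supported: unphased-genotype EM estimation of haplotype
frequencies would introduce an estimation layer that the rest of the
pipeline cannot see or test, so it is deliberately out of scope. LD is
undefined at monomorphic sites; they are excluded from proxy search with
a warning.

`expand_proxies` applies the inclusive threshold $r^2 \ge t$ (default
0.8) within a window of 500 kb around the index SNP. The window default
is an assumption — proxy browsers do impose a distance limit but rarely
document it — and is configurable. Proxy sets from several panels (e.g. a
HapMap-like and a 1000-Genomes-like panel) are merged on the
(index, proxy) key keeping the larger r², so that thresholding after the
merge never drops a pair that either panel supported.

Reports bin r² down to the query thresholds {0.8, 0.9, 1.0} (`bin_r2`),
matching how such tables are conventionally printed.

## The evidence model

Evidence records carry a `source` tag. The *scoring* source drives
classification; a *secondary* source (a second annotation database)
enriches the report but never enters the flags. `merge_annotation_sources`
unions the two per variant: a record present in both (same kind, same
TF/mark/gene name, case-insensitive) is kept once and tagged `both`
(rendered with an asterisk); a secondary-only record stays `secondary`.
Two invariants are property-tested: a scoring record is never removed,
and a secondary-only record is never promoted. This is what lets a
variant carry motif annotations from the secondary database yet still
classify as 1f — the motifs are visible in the report but invisible to
the score.

Coordinates follow the two conventions of the field: variants are 1-based
positions, interval tracks are 0-based half-open (BED). They meet in
exactly one predicate: a variant at position $p$ overlaps $[s, e)$ iff
$s \le p-1 < e$ (`pos_in_interval`); the interval index
(`build_interval_index`, backed by `GenomicRanges`) is tested against a
linear scan on that predicate. Evidence is collapsed across cell types —
one overlapping peak in any cell type establishes the flag; cell types
are retained for reporting only. Histone marks populate the report's
"histone marked" column but never the flags, since the category scheme
does not use them.

## Flags and the decision table

Eight booleans summarize a variant's scoring-source evidence: eQTL, TF
binding, any motif, matched motif, footprint, matched footprint, DNase
peak, motif hit. "Any motif" means a motif instance at a site that also
carries a TF peak (the peak supplies the binding context); a motif
instance alone is only a "motif hit" (category 6). "Matched" means the
motif's (or footprint's) TF is one of the ChIP-seq-bound TFs, decided by
case-insensitive comparison through a small editable alias table
(`tf_aliases.tsv`, e.g. HNF3beta → FOXA2) — motif databases and ChIP-seq
metadata rarely agree on TF naming, and without aliasing "matched" flags
would be systematically undercounted. Three implications are enforced at
construction (matched motif ⇒ any motif ⇒ motif hit; matched footprint ⇒
footprint); violating combinations are an error, never silently
classified.

`classify` applies the category definitions first-match in ordinal
order; because each category's requirements are a superset of every
later category's within its block, first-match equals best-match. The
test suite proves this over all valid flag combinations against an
independently coded declarative rule table, and proves monotonicity:
adding any true flag never worsens the assigned category. Both
occurrences of "TF binding/DNase peak" (1f and 5) are read as inclusive
OR. An eQTL with neither a TF peak nor a DNase peak falls through past 1f
(to 6 or ND): the scheme simply does not define a category for it, and
inventing one would change printed counts. Score filters ("category ≤ 2")
compare the major numeral only; subletters rank within a major, and ND is
a sentinel that never passes a filter.

## Allele-differential motif scoring

`pwm_best_logodds` scans a position-probability matrix over both strands
of a sequence and returns the maximum log-odds score
$\sum_i \log_2(p_{i,b_i} / q_{b_i})$ in bits (background $q$ uniform by
default, configurable). Ties break to the smallest offset, then the
forward strand, making the scan deterministic. A pseudocount (default
0.01 per cell, renormalized) keeps scores finite. `motif_delta` scores
the reference and alternate contexts restricted to windows overlapping
the variant and reports $\Delta = s_{alt} - s_{ref}$; the motif is
"altered" when $|\Delta| \ge$ 1.0 bit. The 1-bit default is a
convention — a two-fold change in the odds of the best site — chosen
because the underlying classification scheme gives no numeric criterion;
it is exposed as a parameter. $\Delta$ is antisymmetric under swapping
ref/alt, which the suite property-tests.

## The synthetic-data generator

Real inputs for this workflow were live web databases; nothing
deposit-able remains. The generator therefore has to produce every input
the pipeline consumes, under conditions where the right answer is known
by construction:

- `simulate_panel` draws haplotypes from a founder-block model: each
  block holds founder haplotypes with given frequencies and every
  simulated haplotype picks one founder per block independently. Within a
  two-founder block LD is complete (r² = 1); between blocks it vanishes
  at rate ~1/n. Defaults (two founders at 0.5/0.5, 1 kb spacing) give the
  cleanest testable structure; the model makes no attempt at coalescent
  realism, recombination gradients, or allele-frequency spectra — so
  passing tests demonstrate correctness of the LD arithmetic, not
  robustness to realistic panel noise.
- `construct_pair_with_r2` builds a two-variant panel hitting a target r²
  through deterministic expected-count rounding of
  $p_{AB} = p_A p_B + \sqrt{r^2 p_A(1-p_A) p_B(1-p_B)}$ (positive-D
  branch), erroring with the feasible bound when the target exceeds the
  Lewontin limit. At n = 2000 the rounding error keeps the recovered r²
  within 0.01 of the target, which the acceptance tests assert.
- `plant_evidence` emits the minimal track set realizing any target
  category, such that collect → flags → classify returns exactly that
  label; the round trip is asserted for all 15 labels.

Panels serialize to phased VCF and tracks to the package's TSV formats,
so end-to-end tests exercise the real I/O paths, not in-memory shortcuts.

## Bundled case study

`load_case_study()` returns transcriptions of a published desk analysis:
the 36-variant annotation table, the LD/category table, the full category
distribution over 868 variants (662 scored, 206 no-data), per-locus proxy
totals, and two index-SNP study tables. The study tables are *synthetic*
(filenames say so): the analysis never enumerated its 40 index rsids, so
only the six printed ones are real and the rest are placeholders arranged
to reproduce the selection arithmetic — 21 + 22 entries, one rsid shared
between studies, two entries carrying bare position labels instead of
rsids (flagged "deficient" and dropped with a logged count), leaving 40.
Shape invariants are checked at load time.

## Numerical and degenerate-input choices

- Significance filtering is strict (p < 5×10⁻⁸); a p-value exactly at the
  threshold is excluded. Proxy thresholding is inclusive (r² ≥ t).
- r² and D′ are clamped into [0, 1] against floating-point overshoot.
- Duplicate index SNPs across studies keep the first study's record with
  `study_label = "both"`.
- Proxy-set merge ties on equal r² keep the first record in input order.
- Degenerate intervals (start ≥ end), non-ACGT sequence, context/allele
  mismatches, monomorphic LD queries, and profile merges across different
  variants all raise informative errors rather than propagating NAs.
- The default test and acceptance runs use panels of 20–2000 haplotypes
  and tracks of tens of intervals — sizes at which every oracle
  (enumeration, linear scan, correlation) is exact and the whole suite
  runs in well under a minute.

## Limitations

- Unphased genotypes are not accepted; phase must come from upstream.
- The classifier is exactly the printed decision table: no probabilistic
  rescoring, no learned prioritization.
- eQTL tissue specificity is carried but not scored.
- No genome-build awareness: coordinates are taken as given, and the case
  study reproduces printed positions without asserting a build.
- The block-model simulator cannot generate intermediate LD decay within
  a block; intermediate r² values come from `construct_pair_with_r2`.
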