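---
title: "Tumor-only somatic calling from FFPE lesions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic calling from FFPE lesions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmlseq)
```

## The problem

Pre-malignant lesions (e.g. ductal carcinoma in situ of the breast) are
archived as formalin-fixed, paraffin-embedded (FFPE) tissue, usually
without matched normal DNA. Calling somatic mutations from such material
faces three confounders at once:

1. **Germline contamination.** Without a matched normal, every germline
   allele looks like a candidate mutation.
2. **Fixation damage.** Formalin deaminates cytosine, producing large
   numbers of low-allelic-fraction, strand-biased C>T artifacts; frozen
   tissue instead accumulates oxidative C>A artifacts.
3. **Shallow, uneven coverage.** Microdissected regions yield nanograms
   of DNA, limiting depth and making absence-of-evidence ambiguous in
   multi-region comparisons.

`pmlseq` implements the downstream half of a tumor-only analysis: it
consumes two callers' VCFs, copy-number bins/segments, and interval
models, and applies a fixed filter cascade, copy-number summarization,
multi-region presence classification and clone-tree construction. The
upstream steps (alignment, duplicate removal, the callers themselves,
circular binary segmentation, functional annotation) are out of scope;
their outputs are this package's inputs.

## The filter cascade

The cascade order is fixed and each stage is a pure subset operation:

1. **Ensemble intersection** — only alleles called by both callers are
   retained, keyed on normalized `(chrom, pos, ref, alt)`.
2. **Initial gate** — a permissive, configurable profile
   (depth ≥ 4, ensemble quality > 0).
3. **Target mask** — calls must lie within 10 bp of a target interval
   that overlaps a gene interval.
4. **Panel of normals** — alleles observed in normal DNA are removed.
5. **Population germline** — alleles with population frequency
   above 10⁻³ are removed, unless in a tier-1 cancer gene *and* present
   in COSMIC or ClinVar (known cancer alleles can be common-looking).
6. **VAF/LOH germline** — alleles at VAF ≥ 0.9 outside LOH segments are
   homozygous-germline-like and removed; in LOH segments a somatic
   allele can legitimately reach such fractions, so it survives.
7. **Heuristic artifact profile** — the `ffpe_benchmark` profile
   (depth ≥ 5, mapping quality > 45, mean position in read > 15, mean
   mismatches < 2.5, microsatellite length < 5, tumor log-odds > 10,
   Fisher strand bias < 10 Phred, VAF > 0.14) targets exactly the FFPE
   damage signature: low VAF, one-sided strands, poor positional
   support. A stricter `gold_standard` profile (quality > 175,
   depth ≥ 25, position in read > 20) defines truth sets from frozen
   tissue.
8. **Quality floor** — ensemble quality ≥ 115, the F-optimal operating
   point found by sweeping the quality threshold against a truth set.
9. **Cross-region propagation** — an allele at VAF > 0.9 in a non-LOH
   segment of *any* region of a patient is excluded from all regions.
10. **Cross-patient recurrence** — alleles recurring in ≥ 2 patients are
    artifacts or residual germline, removed unless in a hotspot gene
    (PIK3CA, TP53, GATA3 by default).

Comparator strictness follows the stated rules verbatim: "more
than"/"greater than"/"lower than" are strict, "at least"/"greater or
equal" inclusive. The boundary tests encode each one (VAF exactly 0.14
is removed; quality exactly 115 is kept). Missing metrics default to
*keep* — a filter cannot fire on absent evidence — configurable per
metric to *drop*.

## Copy-number summaries

Bins below log2 −15 are capture dropouts and removed. Segment QC fails a
segment with fewer than 10 probes, biweight midvariance above 2, or a
log2 confidence interval containing 0. One design point deserves
explanation: the **burden** (altered length over total length, gain
log2 > 0.3, loss < −0.3) is computed over segments passing only the
probe and variance criteria. Applying the CI criterion there would drop
most copy-neutral segments (whose CIs straddle 0 by construction),
leaving an almost purely altered denominator and a meaningless fraction.
Confident **calls** — arm status, gene status — do require the CI to
exclude 0, but a CI-spanning-zero segment still counts in denominators
as neutral territory. `qc_segments(ci_check = FALSE)` produces the
segment set used for burden, arms and genes.

Arm calls use the arm length actually covered by segments as the
denominator, not the cytogenetic length: targeted segments do not tile
arms, and an uncovered arm should be neutral rather than undefined. An
arm is gained/lost when strictly more than half its covered length is.
Gene calls require ≥ 3 overlapping bins and a covering segment with
≥ 110 probes; with several covering segments the narrower-CI one wins
(ties: more probes); and a gene overlapping a segment breakpoint in any
region of a patient is excluded from all of that patient's regions,
because segmentation breakpoints are imprecise and a cross-region
comparison at such a gene would compare segmentation noise. LOH is
called from B-allele frequency outside (0.3, 0.7), strict on both sides.

## Multi-region presence model

To decide whether a mutation is present in a region we use a
two-hypothesis Bayesian classification on the alt count and depth at its
position. Under *absent*, alt reads are sequencing error:
`alt ~ Binomial(depth, e)` with `e = 0.02`. Under *present*, the allelic
fraction is unknown; with a uniform prior on [0, 1] the marginal
likelihood is `1/(depth + 1)`. With prior probability 1/2 the posterior
is `L1 / (L1 + L0)`. This is a deliberate, transparent simplification of
the published multi-region callers built on richer likelihoods and
integer programming; it preserves the testable contract (a posterior
matrix and a tree) while remaining verifiable in closed form. Cells with
depth below `min_depth` (default 10) are *unknown*, never *absent*:
shallow regions must not masquerade as wild type. Note the posterior is
not globally monotone in `alt`: the error likelihood `dbinom(alt; depth,
e)` rises to its mode near `depth·e` before falling, so for
`depth·e > 1` the posterior dips slightly at small alt counts before
increasing — a property of the model, not a bug.

Tree construction treats each mutation's present-region set as a binary
character, unknowns excluded (not imputed). A conflict-free set of
characters (every pair of region sets nested or disjoint) admits a
perfect phylogeny, which is returned with per-edge mutation counts.
Otherwise characters are admitted greedily in decreasing order of
mutation support, ties broken lexicographically for determinism;
mutations on rejected characters are reported as homoplasy. For
conflict-free matrices the greedy result equals the exhaustive-search
optimum (verified against full enumeration of rooted topologies in the
test suite).

## Benchmarking

Matching against a truth set is exact on normalized allele keys — a
documented divergence from haplotype-aware matchers like vcfeval, chosen
because it is deterministic and brute-force checkable. Indels are
left-normalized at the I/O boundary; full left-alignment through repeat
tracts requires flanking reference sequence and is applied when a genome
is supplied. The threshold sweep evaluates every distinct observed
ensemble-quality score, retains calls scoring at least the threshold,
and reports the lowest threshold achieving the maximal F-score. SNVs and
indels are reported separately as well as combined.

## What the simulator emulates — and what it does not

The generator builds a 2 × 50 Mb genome (arms split at 25 Mb, 100 genes
of 20 kb, 8 × 200 bp targets each) and, per patient: germline variants
drawn from a shared population pool with frequency-weighted sampling
(heterozygous at VAF 0.5, homozygous near 1.0, binomially resampled at
region depth ~80×); somatic mutations placed on a clone tree over
regions (40 truncal, 8 per internal edge, 10 private per region by
default, clonal VAF ~ Beta(14, 26), 5% indels); and 10,000 artifacts per
region with VAF ~ Beta(1, 60) (≈95% below 0.05), one-sided strand
counts, and a substitution spectrum with C>T weight 0.53 in FFPE mode
and C>A weight 0.52 in frozen mode — the damage signatures of formalin
fixation and of oxidation in frozen tissue. Caller concordance is drawn
independently per caller: 0.99 for real alleles, 0.2 for artifacts,
reflecting that two algorithms rarely agree on damage-driven calls.
Quality scores for real calls (Normal(200, 40)) and artifacts
(Normal(60, 30)) overlap so the threshold sweep has a non-trivial
optimum. Copy-number defaults plant an 80%-of-arm loss on chr2p
(log2 −0.5, BAF 0.25, LOH) and a 2 Mb focal gain on chr1; bins are
segment log2 + Normal(0, 0.2) noise at 50 kb resolution, and segment
CIs come from the realized bin dispersion.

One root seed drives everything through per-patient and per-region
substreams, so a region's output does not depend on the order patients
are simulated in, and identical seed + configuration produce
byte-identical files.

The simulator does **not** model read-level data (no FASTQ/BAM),
library-preparation chemistry, mappability, or position-correlated
damage; artifact metrics are drawn from parametric distributions rather
than arising mechanistically. Passing end-to-end tests therefore
demonstrates that the cascade removes variants with the *stated*
statistical signature of FFPE damage at realistic rates — not that it
would achieve the same operating point on any particular real library.
Rates not fixed by the emulation targets (artifact count per region,
concordance, metric distribution parameters) are order-of-magnitude
choices exposed in `sim_config()` and held fixed.

## Problem sizes and numerical choices

The test suite exercises the full default cohort (3 patients × 3
regions, 10⁴ artifacts per region) end to end, 100-instance brute-force
equivalence checks at ≤ 50 elements, and 50 four-region clone-tree
recoveries at 200× depth; the whole suite runs in under two minutes on
one core, and `scripts/acceptance.R` recomputes the headline quantities
in under a minute. Report TSVs serialize numerics at 10 significant
digits; VCF floats at 6 decimals. Degenerate inputs have defined
behaviour throughout: empty variant tables pass through every filter,
a zero-length segment set is an error for burden, an empty low-VAF
stratum yields flagged undefined spectrum fractions, and a
single-region patient yields a trunk-only tree.

## Known limitations

- Exact allele matching will miss truth matches that only a
  haplotype-aware comparison would resolve (complex indels).
- The presence model ignores copy number and purity; its posterior is
  qualitative support for presence, not a cancer-cell-fraction.
- The greedy character selection is optimal only on conflict-free
  matrices; with extensive homoplasy it is a heuristic and reports the
  number of conflicting mutations rather than resolving them.
- Residual rare germline variants are indistinguishable from somatic
  calls by construction in tumor-only data; multi-region sharing
  patterns mitigate but cannot remove this ambiguity.
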