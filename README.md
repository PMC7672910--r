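# pmlseq

Tumor-only somatic mutation and copy-number post-processing for targeted
sequencing of FFPE pre-malignant lesions (PMLs), such as laser-capture
microdissected regions of ductal carcinoma in situ.

Archived PML specimens are formalin-fixed, yield nanograms of degraded
DNA, and almost never come with matched normal DNA. Three problems
dominate downstream analysis: germline alleles masquerading as somatic
mutations, fixation-induced deamination artifacts (abundant low-VAF,
strand-biased C>T substitutions; frozen tissue instead shows oxidative
C>A damage), and shallow uneven coverage that makes absence calls
ambiguous across regions. `pmlseq` implements the post-calling stack
that addresses all three:

- **Ensemble calling** — intersection of two callers' call sets on
  normalized allele keys `(chrom, pos, ref, alt)`, restricted to padded
  gene-overlapping targets, minus a panel of normals.
- **Germline filtering** — remove alleles with population frequency
  above 10⁻³ (rescuing tier-1 cancer-gene alleles present in
  COSMIC/ClinVar), and alleles at VAF ≥ 0.9 outside LOH segments.
- **Heuristic artifact profiles** — named threshold sets
  (`ffpe_benchmark`: DP ≥ 5, MQ > 45, position-in-read > 15 ... VAF > 0.14;
  `gold_standard` for frozen truth sets), an ensemble-quality floor of
  115, and cross-patient recurrence removal with a hotspot-gene
  exemption (PIK3CA, TP53, GATA3).
- **Copy number** — bin cleaning, segment QC (probes ≥ 10, biweight
  midvariance ≤ 2, CI), genome burden (fraction of segment length with
  |log2| beyond ±0.3), arm calls (more than half the covered arm), gene
  calls (≥ 3 bins, ≥ 110 probes, gain > 0.4 / loss < −0.6, cross-region
  breakpoint exclusion), LOH from B-allele frequency outside (0.3, 0.7).
- **Multi-region clonality** — for each mutation and region, the
  posterior probability of presence from alt count `a` and depth `d`:

  `P(present | a, d) = π·L1 / (π·L1 + (1−π)·L0)`,
  with `L0 = Binom(a; d, e)`, `e = 0.02`, and `L1 = 1/(d+1)` (uniform
  VAF prior), plus a perfect-phylogeny / greedy-compatibility clone
  tree with per-edge mutation counts.
- **Benchmarking** — exact-key TP/FP/FN matching against a truth set,
  precision/recall/F, and an F-optimal sweep of the ensemble-quality
  threshold.
- **Simulator** — seeded generator of multi-patient multi-region
  cohorts with known truth: germline at population frequencies, clonal
  somatic mutations on a region tree, FFPE (C>T weight 0.53) or frozen
  (C>A weight 0.52) artifact spectra, two-caller concordance structure,
  and segmented copy-number profiles with LOH. Byte-identical outputs
  for identical seed and configuration.

## Worked example

```r
library(pmlseq)

sim <- simulate_cohort(sim_config(seed = 42))
res <- run_somatic_cascade(sim$cohort, sim$annotation$targets,
                           sim$annotation$genes, sim$pon)
subset(res$provenance, patient == "patient1" & region == "A")
#>    patient region         stage   n
#> 1 patient1      A      ensemble 662
#> 2 patient1      A       initial 662
#> 3 patient1      A   target_mask 662
#> 4 patient1      A           pon 492
#> 5 patient1      A    population 464
#> 6 patient1      A       vaf_loh 464
#> 7 patient1      A     heuristic  56
#> 8 patient1      A quality_floor  54
#> 9 patient1      A         final  54
```

The provenance table shows the cascade at work: 662 ensemble calls in
region A (mostly caller-concordant artifacts and germline), the panel
of normals and population filters strip the common germline, the FFPE
heuristic profile removes the low-VAF damage, and 54 candidate somatic
mutations remain. Against the generator's truth:

```r
acc <- benchmark_against_truth(res, sim$truth)
sprintf("precision %.3f recall %.3f", acc$precision, acc$recall)
#> [1] "precision 0.988 recall 0.954"
```

Copy-number summaries for the same region (the generator plants a
chr2p loss with LOH and a focal chr1 gain):

```r
r <- sim$cohort$patients$patient1$regions$A
segs <- qc_segments(r$segments, ci_check = FALSE)$passing
cna_burden(segs)
#> CNA burden: 22.0% (gain 2.0%, loss 20.0%) of 100.0 Mb
call_arms(segs, sim$annotation$arms)
#>   arm  status involved_fraction covered_bases
#> 1  1p neutral              0.00       2.5e+07
#> 2  1q neutral              0.08       2.5e+07
#> 3  2p    lost              0.80       2.5e+07
#> 4  2q neutral              0.00       2.5e+07
```

Multi-region presence classification and the clone tree for patient 3
(final calls only; branch lengths are mutation counts):

```r
p3 <- res$cohort$patients$patient3
keys <- unique(unlist(lapply(p3$regions, function(r) allele_key(r$variants))))
counts <- do.call(rbind, lapply(p3$regions, `[[`, "counts"))
pm <- build_presence_matrix(counts[counts$key %in% keys, ])
pm
#> Presence matrix: 77 mutations x 3 regions
#>   present 165, absent 66, unknown 0 (min_depth=10, e=0.02)
infer_tree(pm)
#> Clone tree over regions {A, B, C}
#>   newick: ((B:10,C:9):8,A:10):40;
```

The trunk carries the 40 truncal mutations, regions B and C share an
8-mutation branch, and each region carries its private mutations —
the generating topology, recovered from read counts alone.

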