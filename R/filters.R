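# The somatic filter cascade: population-germline removal with
# cancer-gene rescue, VAF/LOH germline removal, named heuristic artifact
# profiles, the ensemble-quality floor, cross-patient recurrence
# removal, and substitution-spectrum diagnostics. Comparator strictness
# follows the published wording exactly ("more than" strict, "at least"
# inclusive); boundary behaviour is pinned by tests.

#' Construct a filter profile
#'
#' A profile is a named set of threshold comparisons on variant-table
#' metrics. A record is kept iff every rule passes; a record missing the
#' metric is handled per `missing_policy` (default `"keep"`: a filter
#' cannot fire on absent evidence).
#'
#' @param name profile name.
#' @param rules data.frame with columns `metric`, `cmp` (one of
#'   `"<"`, `">"`, `"<="`, `">="`), `threshold`.
#' @param missing_policy `"keep"` or `"drop"`, optionally a named vector
#'   per metric.
#' @return a `filter_profile` object.
#' @export
filter_profile <- function(name, rules, missing_policy = "keep") {
  stopifnot(is.data.frame(rules),
            all(c("metric", "cmp", "threshold") %in% names(rules)))
  bad <- setdiff(rules$metric, .metric_numeric)
  if (length(bad)) {
    stop("unknown metric name(s) in profile '", name, "': ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(rules$cmp, c("<", ">", "<=", ">="))
  if (length(bad)) stop("unknown comparator(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(rules$threshold))) stop("thresholds must be finite")
  structure(list(name = name,
                 rules = rules[, c("metric", "cmp", "threshold")],
                 missing_policy = missing_policy),
            class = "filter_profile")
}

#' @export
print.filter_profile <- function(x, ...) {
  cat("Filter profile '", x$name, "':\n", sep = "")
  for (i in seq_len(nrow(x$rules))) {
    cat("  ", x$rules$metric[i], x$rules$cmp[i], x$rules$threshold[i], "\n")
  }
  invisible(x)
}

.rule_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(metric = m[, 1], cmp = m[, 2], threshold = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Built-in filter profiles
#'
#' * `gold_standard` — high-quality calls from frozen tissue: ensemble
#'   quality > 175, mean read mismatches < 2.5, depth >= 25, mean
#'   position in read > 20, microsatellite length < 5, VAF > 0.14.
#' * `ffpe_benchmark` — FFPE calls with abundant low-frequency
#'   deamination damage: depth >= 5, mapping quality > 45, mean position
#'   in read > 15, mean mismatches < 2.5, microsatellite length < 5,
#'   tumor log-odds > 10, Fisher strand-bias Phred < 10, VAF > 0.14.
#' * `initial` — permissive default gate: depth >= 4, ensemble
#'   quality > 0.
#'
#' @param name one of `"gold_standard"`, `"ffpe_benchmark"`, `"initial"`.
#' @return a [filter_profile()].
#' @export
builtin_profile <- function(name = c("gold_standard", "ffpe_benchmark", "initial")) {
  name <- match.arg(name)
  rules <- switch(name,
    gold_standard = .rule_df(
      "ensemble_quality", ">", 175,
      "mean_mismatches", "<", 2.5,
      "depth", ">=", 25,
      "mean_pos_in_read", ">", 20,
      "ms_length", "<", 5,
      "vaf", ">", 0.14),
    ffpe_benchmark = .rule_df(
      "depth", ">=", 5,
      "mapping_quality", ">", 45,
      "mean_pos_in_read", ">", 15,
      "mean_mismatches", "<", 2.5,
      "ms_length", "<", 5,
      "tlod", ">", 10,
      "fs_phred", "<", 10,
      "vaf", ">", 0.14),
    initial = .rule_df(
      "depth", ">=", 4,
      "ensemble_quality", ">", 0)
  )
  filter_profile(name, rules)
}

#' Apply a heuristic filter profile
#'
#' @param variants a variant table.
#' @param profile a [filter_profile()].
#' @return the subset passing every rule.
#' @export
apply_heuristic_profile <- function(variants, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  if (nrow(variants) == 0) return(variants)
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(profile$rules))) {
    metric <- profile$rules$metric[i]
    vals <- variants[[metric]]
    pass <- switch(profile$rules$cmp[i],
      "<" = vals < profile$rules$threshold[i],
      ">" = vals > profile$rules$threshold[i],
      "<=" = vals <= profile$rules$threshold[i],
      ">=" = vals >= profile$rules$threshold[i])
    policy <- if (length(profile$missing_policy) > 1 &&
                  metric %in% names(profile$missing_policy)) {
      profile$missing_policy[[metric]]
    } else profile$missing_policy[[1]]
    pass[is.na(pass)] <- identical(policy, "keep")
    keep <- keep & pass
  }
  variants[keep, , drop = FALSE]
}

#' Remove common population germline variants, rescuing cancer genes
#'
#' Removes a variant iff its maximum population allele frequency exceeds
#' 1e-3 and it is not rescued as a known cancer allele (tier 1 cancer
#' gene AND present in COSMIC or ClinVar). A missing `pop_af` is treated
#' as rare (kept).
#'
#' @param variants a variant table with `pop_af`, `is_cgc_tier1`,
#'   `in_cosmic`, `in_clinvar` populated.
#' @param maf_threshold population-frequency cutoff (default 1e-3).
#' @return the retained subset.
#' @export
filter_population_germline <- function(variants, maf_threshold = 1e-3) {
  if (nrow(variants) == 0) return(variants)
  common <- !is.na(variants$pop_af) & variants$pop_af > maf_threshold
  tier1 <- !is.na(variants$is_cgc_tier1) & variants$is_cgc_tier1
  known <- (!is.na(variants$in_cosmic) & variants$in_cosmic) |
    (!is.na(variants$in_clinvar) & variants$in_clinvar)
  rescued <- tier1 & known
  variants[!(common & !rescued), , drop = FALSE]
}

# TRUE where each 1-based position falls inside a 0-based half-open
# segment with the given status
.pos_in_segments <- function(chrom, pos, segments, which_segments) {
  if (nrow(segments) == 0 || !any(which_segments)) {
    return(rep(FALSE, length(pos)))
  }
  seg <- segments[which_segments, , drop = FALSE]
  sgr <- GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(start = seg$start + 1L, end = seg$end)
  )
  vgr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = pos, width = 1L)
  )
  IRanges::overlapsAny(vgr, sgr)
}

#' Remove likely germline variants by VAF in non-LOH segments
#'
#' A variant at allelic fraction >= 0.9 outside any LOH segment (or in
#' no segment at all) is most plausibly a homozygous or
#' allelically-imbalanced germline allele and is removed; in LOH
#' segments a true somatic variant can legitimately reach such
#' fractions, so it is kept.
#'
#' @param variants a variant table.
#' @param segments a segment data.frame for the same region.
#' @param loh logical vector of per-segment LOH calls, default
#'   [call_loh()] on `segments`.
#' @param vaf_threshold inclusive VAF cutoff (default 0.9).
#' @return the retained subset.
#' @export
filter_vaf_loh_germline <- function(variants, segments,
                                    loh = call_loh(segments)$loh,
                                    vaf_threshold = 0.9) {
  if (nrow(variants) == 0) return(variants)
  high <- !is.na(variants$vaf) & variants$vaf >= vaf_threshold
  in_loh <- .pos_in_segments(variants$chrom, variants$pos, segments, loh)
  variants[!(high & !in_loh), , drop = FALSE]
}

#' Ensemble-quality floor
#'
#' Excludes calls with ensemble quality lower than `floor` (the
#' F-optimal operating point for low-input blunt-end libraries is 115).
#' Missing quality is kept.
#'
#' @param variants a variant table.
#' @param floor minimum retained quality (kept iff quality >= floor).
#' @return the retained subset.
#' @export
filter_quality_floor <- function(variants, floor = 115) {
  if (nrow(variants) == 0) return(variants)
  q <- variants$ensemble_quality
  variants[is.na(q) | q >= floor, , drop = FALSE]
}

#' Remove mutations recurring across patients
#'
#' True somatic mutations essentially never recur at the same allele in
#' independent patients, so an allele key present in two or more
#' patients of a cohort is treated as a shared artifact or residual
#' germline allele and removed from every patient — except alleles in
#' well-described breast-cancer hotspot genes (PIK3CA, TP53, GATA3 by
#' default), which genuinely recur.
#'
#' @param cohort a cohort (see [cohort()]).
#' @param hotspot_genes gene symbols exempt from removal.
#' @return the cohort with recurrent alleles removed.
#' @export
filter_cross_patient_recurrent <- function(cohort,
                                           hotspot_genes = c("PIK3CA", "TP53", "GATA3")) {
  per_patient_keys <- lapply(cohort$patients, function(p) {
    unique(unlist(lapply(p$regions, function(r) allele_key(r$variants)),
                  use.names = FALSE))
  })
  tab <- table(unlist(per_patient_keys, use.names = FALSE))
  recurrent <- names(tab)[tab >= 2]
  if (length(recurrent) == 0) return(cohort)
  key_gene <- new.env(parent = emptyenv())
  for (p in cohort$patients) for (r in p$regions) {
    v <- r$variants
    k <- allele_key(v)
    for (i in seq_along(k)) {
      if (!is.na(v$gene[i])) assign(k[i], v$gene[i], envir = key_gene)
    }
  }
  drop_keys <- recurrent[vapply(recurrent, function(k) {
    g <- if (exists(k, envir = key_gene)) get(k, envir = key_gene) else NA_character_
    is.na(g) || !(g %in% hotspot_genes)
  }, logical(1))]
  for (pi in seq_along(cohort$patients)) {
    for (ri in seq_along(cohort$patients[[pi]]$regions)) {
      v <- cohort$patients[[pi]]$regions[[ri]]$variants
      cohort$patients[[pi]]$regions[[ri]]$variants <-
        v[!(allele_key(v) %in% drop_keys), , drop = FALSE]
    }
  }
  cohort
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# collapse a ref>alt SNV onto the pyrimidine-reference strand
.collapse_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  paste0(ref, ">", alt)
}

#' Substitution spectrum of a low-VAF stratum
#'
#' Counts SNVs with `vaf < vaf_max` over the six pyrimidine-context
#' substitution classes (purine-reference records are strand-collapsed,
#' e.g. G>A counts as C>T). FFPE deamination damage shows as C>T
#' dominance of the low-VAF stratum; oxidative damage in frozen tissue
#' as C>A dominance.
#'
#' @param variants a variant table (indels ignored).
#' @param vaf_max upper VAF bound of the stratum (default 0.05, strict).
#' @return a `spectrum_summary`: data.frame of class, count, fraction,
#'   with attributes `total` and `empty`.
#' @export
substitution_spectrum <- function(variants, vaf_max = 0.05) {
  snv <- variants[is_snv(variants) & !is.na(variants$vaf) &
                    variants$vaf < vaf_max, , drop = FALSE]
  cls <- .collapse_substitution(snv$ref, snv$alt)
  counts <- vapply(SPECTRUM_CLASSES, function(c) sum(cls == c), numeric(1))
  total <- sum(counts)
  out <- data.frame(class = SPECTRUM_CLASSES, count = as.integer(counts),
                    fraction = if (total > 0) counts / total else rep(NA_real_, 6),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, total = total, empty = total == 0,
            class = c("spectrum_summary", "data.frame"))
}

#' @export
as_report_table.spectrum_summary <- function(x) as.data.frame(x)
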