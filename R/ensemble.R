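# Two-caller harmonization: intersection on allele identity, target
# masking, panel-of-normals subtraction, initial quality gating. Every
# gate is a pure subset operation on the variant table.

# collapse within-caller duplicates of an allele key, keeping the
# higher-quality record
.dedupe_by_quality <- function(variants) {
  if (nrow(variants) < 2) return(variants)
  key <- allele_key(variants)
  q <- variants$ensemble_quality
  q[is.na(q)] <- -Inf
  o <- order(key, -q)
  variants <- variants[o, , drop = FALSE]
  variants[!duplicated(allele_key(variants)), , drop = FALSE]
}

#' Intersect two callers' variant sets (ensemble calling)
#'
#' Only variants reported by both callers are retained; identity is the
#' normalized (chrom, pos, ref, alt) key. The retained record carries
#' caller 1's count-type metrics, the per-allele maximum
#' `ensemble_quality` across callers, and both caller labels. If a
#' caller reports the same key twice, its higher-quality record is used.
#'
#' @param set1,set2 normalized variant tables (left-aligned,
#'   multiallelic-split), e.g. from [read_variants()].
#' @return an `ensemble_set`: list with `variants` (sorted variant
#'   table, every row carrying both caller labels) and `provenance`
#'   (input/output counts).
#' @export
intersect_callers <- function(set1, set2) {
  s1 <- .dedupe_by_quality(set1)
  s2 <- .dedupe_by_quality(set2)
  k1 <- allele_key(s1)
  k2 <- allele_key(s2)
  shared <- intersect(k1, k2)
  out <- s1[match(shared, k1), , drop = FALSE]
  if (nrow(out)) {
    q2 <- s2$ensemble_quality[match(shared, k2)]
    out$ensemble_quality <- pmax(out$ensemble_quality, q2, na.rm = TRUE)
    out$ensemble_quality[is.na(out$ensemble_quality)] <- NA_real_
    lbl1 <- if (nrow(s1)) s1$callers[1] else "caller1"
    lbl2 <- if (nrow(s2)) s2$callers[1] else "caller2"
    out$callers <- paste(lbl1, lbl2, sep = ",")
  }
  out <- sort_variants(out)
  rownames(out) <- NULL
  structure(
    list(variants = out,
         provenance = data.frame(stage = c("caller1", "caller2", "ensemble"),
                                 n = c(nrow(set1), nrow(set2), nrow(out)))),
    class = "ensemble_set"
  )
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat("Ensemble variant set:", nrow(x$variants), "variants called by both callers\n")
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' Restrict variants to padded, gene-overlapping target regions
#'
#' A variant is kept iff its position lies within a target interval
#' expanded by `pad` bases on both sides, and that target overlaps a
#' gene interval. Off-target calls and calls on targets outside the gene
#' model are both artifact-prone and are dropped.
#'
#' @param variants a variant table.
#' @param targets,genes interval sets ([interval_set()] / [read_bed()]).
#' @param pad boundary tolerance in bases (default 10).
#' @return the retained subset.
#' @export
apply_target_mask <- function(variants, targets, genes, pad = 10) {
  if (length(targets) == 0) {
    stop("empty target set: pipeline misconfiguration")
  }
  keep_targets <- targets[IRanges::overlapsAny(targets, genes)]
  if (length(keep_targets) == 0 || nrow(variants) == 0) {
    return(variants[integer(0), , drop = FALSE])
  }
  padded <- GenomicRanges::resize(keep_targets,
                                  GenomicRanges::width(keep_targets) + 2L * pad,
                                  fix = "center")
  vpos <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  variants[IRanges::overlapsAny(vpos, padded), , drop = FALSE]
}

#' Subtract panel-of-normals calls
#'
#' Removes variants whose allele key appears in the panel of normals
#' (recurrent artifacts and common germline alleles observed in normal
#' DNA).
#'
#' @param variants a variant table.
#' @param pon panel-of-normals variant table, normalized identically.
#' @return the retained subset.
#' @export
subtract_panel_of_normals <- function(variants, pon) {
  if (nrow(variants) == 0 || is.null(pon) || nrow(pon) == 0) return(variants)
  variants[!(allele_key(variants) %in% allele_key(pon)), , drop = FALSE]
}

#' Apply the initial (permissive) filter profile
#'
#' Same threshold machinery as [apply_heuristic_profile()], run with the
#' configurable `initial` profile (defaults: depth >= 4,
#' ensemble_quality > 0) that mirrors a tumor-only caller's default
#' gates.
#'
#' @param variants a variant table.
#' @param profile a [filter_profile()]; default `builtin_profile("initial")`.
#' @return the retained subset.
#' @export
apply_initial_filters <- function(variants, profile = builtin_profile("initial")) {
  apply_heuristic_profile(variants, profile)
}
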