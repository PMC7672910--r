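# Copy-number post-processing on CNVkit-style bins and segments:
# artifact-bin removal, segment QC, genome burden, chromosome-arm
# calls, gene-level calls with cross-region breakpoint exclusion, and
# LOH from B-allele frequency.

#' Remove artifact bins
#'
#' Bins with log2 copy ratio below -15 are capture dropouts and are
#' removed before any downstream use.
#'
#' @param bins a bin data.frame (chrom, start, end, log2).
#' @param floor minimum retained log2 (kept iff log2 >= floor).
#' @return the retained bins.
#' @export
clean_bins <- function(bins, floor = -15) {
  bins[!is.na(bins$log2) & bins$log2 >= floor, , drop = FALSE]
}

#' Segment quality control
#'
#' A segment fails iff it has fewer than 10 probes, biweight midvariance
#' above 2, or a log2 confidence interval containing 0. Segments with no
#' CI are evaluated on the two remaining criteria and flagged.
#'
#' @param segments a segment data.frame.
#' @param min_probes,max_bivar QC thresholds.
#' @param ci_check when `FALSE` the CI-contains-zero criterion is not
#'   applied — used where downstream calls handle CI confidence
#'   themselves and a copy-neutral segment must stay in the denominator
#'   (burden, arm and gene calls).
#' @return list with `passing`, `failing` (each a segment data.frame;
#'   `failing` gains a `reason` column) and `flagged_no_ci` (row indices
#'   evaluated without a CI).
#' @export
qc_segments <- function(segments, min_probes = 10, max_bivar = 2,
                        ci_check = TRUE) {
  n <- nrow(segments)
  few_probes <- !is.na(segments$n_probes) & segments$n_probes < min_probes
  noisy <- !is.na(segments$bivar) & segments$bivar > max_bivar
  has_ci <- !is.na(segments$ci_low) & !is.na(segments$ci_high)
  ci_zero <- ci_check & has_ci & segments$ci_low <= 0 & segments$ci_high >= 0
  fail <- few_probes | noisy | ci_zero
  reason <- character(n)
  reason[few_probes] <- "few_probes"
  reason[noisy] <- paste0(reason[noisy], ifelse(nzchar(reason[noisy]), ";", ""),
                          "high_bivar")
  reason[ci_zero] <- paste0(reason[ci_zero],
                            ifelse(nzchar(reason[ci_zero]), ";", ""),
                            "ci_contains_zero")
  failing <- segments[fail, , drop = FALSE]
  if (nrow(failing)) failing$reason <- reason[fail]
  list(passing = segments[!fail, , drop = FALSE],
       failing = failing,
       flagged_no_ci = which(!has_ci))
}

#' Genome-wide copy-number burden
#'
#' The burden is the summed length of segments in a gain
#' (log2 > `gain_threshold`) or loss (log2 < `loss_threshold`) over the
#' summed length of all segments. Segments should already pass the
#' probe-count and variance QC; the CI criterion is deliberately not
#' required here (it defines *confident* calls, not the burden
#' denominator).
#'
#' @param segments a segment data.frame.
#' @param gain_threshold,loss_threshold log2 cutoffs (default +0.3 / -0.3,
#'   both strict).
#' @return a `burden_result`: list with gain_fraction, loss_fraction,
#'   total_fraction, and base-pair denominators.
#' @export
cna_burden <- function(segments, gain_threshold = 0.3, loss_threshold = -0.3) {
  len <- as.numeric(segments$end - segments$start)
  total <- sum(len)
  if (!isTRUE(total > 0)) stop("cna_burden: zero total segment length")
  gain <- sum(len[!is.na(segments$log2) & segments$log2 > gain_threshold])
  loss <- sum(len[!is.na(segments$log2) & segments$log2 < loss_threshold])
  structure(list(gain_fraction = gain / total,
                 loss_fraction = loss / total,
                 total_fraction = (gain + loss) / total,
                 gain_bases = gain, loss_bases = loss, total_bases = total),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("CNA burden: %.1f%% (gain %.1f%%, loss %.1f%%) of %.1f Mb\n",
              100 * x$total_fraction, 100 * x$gain_fraction,
              100 * x$loss_fraction, x$total_bases / 1e6))
  invisible(x)
}

#' @export
as_report_table.burden_result <- function(x) {
  data.frame(gain_fraction = x$gain_fraction, loss_fraction = x$loss_fraction,
             total_fraction = x$total_fraction, gain_bases = x$gain_bases,
             loss_bases = x$loss_bases, total_bases = x$total_bases)
}

# TRUE where a segment's CI excludes 0 (or no CI / check disabled)
.ci_confident <- function(segments, require_ci) {
  if (!require_ci) return(rep(TRUE, nrow(segments)))
  has_ci <- !is.na(segments$ci_low) & !is.na(segments$ci_high)
  !has_ci | segments$ci_low > 0 | segments$ci_high < 0
}

.segments_granges <- function(segments) {
  GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end)
  )
}

#' Chromosome-arm gain/loss calls
#'
#' An arm is called gained (lost) when more than half of its
#' segment-covered length lies in gained (lost) segments. The
#' denominator is the arm length actually covered by segments, since
#' targeted segments do not tile whole arms; an uncovered arm is
#' neutral with involved fraction 0.
#'
#' @param segments segments passing probe-count and variance QC.
#' @param arms an interval set of chromosome arms.
#' @param gain_threshold,loss_threshold log2 cutoffs (default +/-0.3).
#' @param require_ci when `TRUE` (default) a segment whose log2
#'   confidence interval contains 0 cannot contribute gained/lost
#'   length (it still counts in the covered denominator) — confident
#'   calls demand the CI exclude 0.
#' @return data.frame with arm, status (gained/lost/neutral),
#'   involved_fraction, covered_bases.
#' @export
call_arms <- function(segments, arms, gain_threshold = 0.3,
                      loss_threshold = -0.3, require_ci = TRUE) {
  sgr <- .segments_granges(segments)
  conf <- .ci_confident(segments, require_ci)
  gained <- !is.na(segments$log2) & segments$log2 > gain_threshold & conf
  lost <- !is.na(segments$log2) & segments$log2 < loss_threshold & conf
  labels <- S4Vectors::mcols(arms)$name
  out <- data.frame(arm = labels, status = "neutral",
                    involved_fraction = 0, covered_bases = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(arms)) {
    hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, arms[i]))
    if (length(hits) == 0) next
    # overlap width of each hit segment with the arm
    ow <- GenomicRanges::width(IRanges::pintersect(sgr[hits], rep(arms[i], length(hits))))
    covered <- sum(as.numeric(ow))
    gain_frac <- sum(as.numeric(ow[gained[hits]])) / covered
    loss_frac <- sum(as.numeric(ow[lost[hits]])) / covered
    out$covered_bases[i] <- covered
    if (gain_frac > 0.5) {
      out$status[i] <- "gained"
      out$involved_fraction[i] <- gain_frac
    } else if (loss_frac > 0.5) {
      out$status[i] <- "lost"
      out$involved_fraction[i] <- loss_frac
    } else {
      out$involved_fraction[i] <- max(gain_frac, loss_frac)
    }
  }
  out
}

#' Loss-of-heterozygosity calls from B-allele frequency
#'
#' A segment is in LOH when its B-allele frequency departs from the
#' heterozygous expectation of 0.5: below 0.3 or above 0.7 (both
#' strict). Segments without BAF are not LOH and are flagged.
#'
#' @param segments a segment data.frame.
#' @param low,high BAF cutoffs.
#' @return data.frame with the segment coordinates, `loh` (logical) and
#'   `baf_missing` (logical).
#' @export
call_loh <- function(segments, low = 0.3, high = 0.7) {
  loh <- !is.na(segments$baf) & (segments$baf < low | segments$baf > high)
  data.frame(chrom = segments$chrom, start = segments$start,
             end = segments$end, baf = segments$baf, loh = loh,
             baf_missing = is.na(segments$baf), stringsAsFactors = FALSE)
}

#' Gene-level copy-number calls with cross-region breakpoint exclusion
#'
#' Per region, a gene is eligible when at least `min_bins` cleaned bins
#' overlap it and its covering segment carries at least `min_probes`
#' probes; the assigned log2 is the covering segment's. When several
#' segments cover a gene the higher-confidence one is used (narrower CI,
#' then more probes). Because segmentation breakpoints are imprecise,
#' any gene overlapping a segment breakpoint (more than one covering
#' segment) in *any* region of the patient is excluded from every
#' region. Reporting status: gain iff log2 > `gain_threshold`, loss iff
#' log2 < `loss_threshold`.
#'
#' @param region_bins named list (per region) of cleaned bin data.frames.
#' @param region_segments named list (per region) of QC-passing segment
#'   data.frames.
#' @param genes an interval set of genes.
#' @param min_bins,min_probes eligibility thresholds (default 3 bins,
#'   110 probes).
#' @param gain_threshold,loss_threshold reporting cutoffs (default +0.4,
#'   -0.6).
#' @param require_ci when `TRUE` (default) a covering segment whose log2
#'   CI contains 0 yields a neutral (not gain/loss) status.
#' @return data.frame with region, gene, log2, n_bins, segment_probes,
#'   status (gain/loss/neutral/excluded) and reason.
#' @export
call_gene_copy_number <- function(region_bins, region_segments, genes,
                                  min_bins = 3, min_probes = 110,
                                  gain_threshold = 0.4, loss_threshold = -0.6,
                                  require_ci = TRUE) {
  stopifnot(identical(names(region_bins), names(region_segments)))
  regions <- names(region_bins)
  labels <- S4Vectors::mcols(genes)$name
  per_region <- list()
  breakpoint_genes <- character(0)
  for (rg in regions) {
    bins <- region_bins[[rg]]
    segs <- region_segments[[rg]]
    bgr <- GenomicRanges::GRanges(
      seqnames = bins$chrom,
      ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end))
    sgr <- .segments_granges(segs)
    n_bins <- GenomicRanges::countOverlaps(genes, bgr)
    seg_hits <- GenomicRanges::findOverlaps(genes, sgr)
    res <- data.frame(region = rg, gene = labels, log2 = NA_real_,
                      n_bins = as.integer(n_bins),
                      segment_probes = NA_integer_,
                      status = "excluded", reason = "",
                      stringsAsFactors = FALSE)
    for (gi in seq_along(genes)) {
      si <- S4Vectors::subjectHits(seg_hits)[S4Vectors::queryHits(seg_hits) == gi]
      if (length(si) == 0) {
        res$reason[gi] <- "no_covering_segment"
        next
      }
      if (length(si) > 1) {
        breakpoint_genes <- c(breakpoint_genes, labels[gi])
        # provisional assignment from the higher-confidence segment; a
        # breakpoint anywhere in the patient overrides to excluded below
        ciw <- segs$ci_high[si] - segs$ci_low[si]
        ciw[is.na(ciw)] <- Inf
        o <- order(ciw, -segs$n_probes[si])
        si <- si[o[1]]
      }
      res$log2[gi] <- segs$log2[si]
      res$segment_probes[gi] <- segs$n_probes[si]
      if (n_bins[gi] < min_bins) {
        res$reason[gi] <- "too_few_bins"
      } else if (is.na(segs$n_probes[si]) || segs$n_probes[si] < min_probes) {
        res$reason[gi] <- "too_few_probes"
      } else {
        conf <- .ci_confident(segs[si, , drop = FALSE], require_ci)
        res$status[gi] <- if (conf && segs$log2[si] > gain_threshold) "gain"
        else if (conf && segs$log2[si] < loss_threshold) "loss" else "neutral"
      }
    }
    per_region[[rg]] <- res
  }
  out <- do.call(rbind, per_region)
  bp <- unique(breakpoint_genes)
  hit <- out$gene %in% bp
  out$status[hit] <- "excluded"
  out$reason[hit] <- "breakpoint_in_patient"
  rownames(out) <- NULL
  out
}
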