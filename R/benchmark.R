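# Accuracy of a call set against a truth set: exact allele-key matching
# after normalization (a deliberate, documented divergence from
# haplotype-aware matchers: deterministic and oracle-checkable),
# precision/recall/F, and the F-optimal ensemble-quality threshold.

#' Match calls to a truth set
#'
#' Exact matching on normalized allele keys: true positives are calls
#' whose key appears in truth, false positives the rest, false negatives
#' the unmatched truth keys.
#'
#' @param calls,truth normalized variant tables (or anything with
#'   chrom/pos/ref/alt columns).
#' @return list with `tp`, `fp`, `fn` — character vectors of allele keys.
#' @export
match_to_truth <- function(calls, truth) {
  ck <- unique(allele_key(calls))
  tk <- unique(allele_key(truth))
  list(tp = sort(intersect(ck, tk)),
       fp = sort(setdiff(ck, tk)),
       fn = sort(setdiff(tk, ck)))
}

#' Precision, recall and F-score from match counts
#'
#' @param tp,fp,fn counts (or the key vectors from [match_to_truth()]).
#' @return list with `precision`, `recall`, `f_score`; an undefined
#'   denominator yields `NA` (flagged missing), and recall is 0 when
#'   there are truth variants but no true positives.
#' @export
precision_recall <- function(tp, fp, fn) {
  n <- function(x) if (is.numeric(x)) x else length(x)
  tp <- n(tp); fp <- n(fp); fn <- n(fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (isTRUE(precision == 0) || isTRUE(recall == 0)) 0 else NA_real_
  list(precision = precision, recall = recall, f_score = f)
}

.benchmark_one <- function(calls, truth) {
  m <- match_to_truth(calls, truth)
  c(m, precision_recall(m$tp, m$fp, m$fn))
}

#' Sweep the ensemble-quality threshold for the F-optimal operating point
#'
#' At each distinct observed quality score `t`, calls with score >= `t`
#' are retained and compared with the truth set; the reported optimum is
#' the lowest threshold achieving the maximum F-score. SNVs and indels
#' are additionally reported separately.
#'
#' @param calls a scored variant table (`ensemble_quality` set on every
#'   row).
#' @param truth the truth variant table (non-empty).
#' @return a `benchmark_report`: tp/fp/fn keys and counts at the
#'   optimum, precision/recall/F overall and split by SNV/indel, the
#'   per-threshold `curve` data.frame, and `optimal_threshold`.
#' @export
optimize_threshold <- function(calls, truth) {
  if (nrow(truth) == 0) stop("optimize_threshold: empty truth set")
  if (any(is.na(calls$ensemble_quality))) {
    stop("optimize_threshold: every call must carry an ensemble_quality score")
  }
  thresholds <- sort(unique(calls$ensemble_quality))
  if (length(thresholds) == 0) thresholds <- 0
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    kept <- calls[calls$ensemble_quality >= t, , drop = FALSE]
    b <- .benchmark_one(kept, truth)
    data.frame(threshold = t, n_calls = nrow(kept),
               tp = length(b$tp), fp = length(b$fp), fn = length(b$fn),
               precision = b$precision, recall = b$recall, f_score = b$f_score)
  }))
  f <- curve$f_score
  f[is.na(f)] <- -Inf
  best <- which(f == max(f))[1]  # ties -> lowest threshold (sorted ascending)
  opt <- curve$threshold[best]
  kept <- calls[calls$ensemble_quality >= opt, , drop = FALSE]
  overall <- .benchmark_one(kept, truth)
  snv <- .benchmark_one(kept[is_snv(kept), , drop = FALSE],
                        truth[is_snv(truth), , drop = FALSE])
  indel <- .benchmark_one(kept[!is_snv(kept), , drop = FALSE],
                          truth[!is_snv(truth), , drop = FALSE])
  structure(list(tp = overall$tp, fp = overall$fp, fn = overall$fn,
                 precision = overall$precision, recall = overall$recall,
                 f_score = overall$f_score,
                 snv = snv[c("precision", "recall", "f_score")],
                 indel = indel[c("precision", "recall", "f_score")],
                 curve = curve, optimal_threshold = opt),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "Benchmark at optimal threshold %.4g: TP %d, FP %d, FN %d\n",
    x$optimal_threshold, length(x$tp), length(x$fp), length(x$fn)))
  cat(sprintf("  precision %.3f, recall %.3f, F %.3f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' @export
as_report_table.benchmark_report <- function(x) x$curve
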