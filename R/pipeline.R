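# Fixed-order filter cascade over a multi-patient cohort. The order is
# part of the contract: initial gate -> target mask -> panel of normals
# -> population germline -> VAF/LOH germline -> heuristic profile ->
# quality floor -> cross-region germline propagation -> cross-patient
# recurrence. Every stage is a subset operation.

#' Assemble a cohort
#'
#' @param patients list of patient records; each a list with `id` and
#'   `regions`, each region a list with `id`, two caller variant tables
#'   (`caller1`, `caller2`), `bins` and `segments`.
#' @return a `cohort` list.
#' @export
cohort <- function(patients) {
  ids <- vapply(patients, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  for (p in patients) {
    rids <- vapply(p$regions, `[[`, character(1), "id")
    if (anyDuplicated(rids)) stop("region ids must be unique within patient ", p$id)
  }
  names(patients) <- ids
  list(patients = patients)
}

#' Run the full somatic filter cascade on a cohort
#'
#' Harmonizes each region's two caller call sets into the ensemble
#' intersection, applies the initial gate, the padded gene-overlapping
#' target mask, panel-of-normals subtraction, population-germline
#' removal with tier-1 cancer-gene rescue, VAF>=0.9 non-LOH germline
#' removal against the region's copy-number segments, the named
#' heuristic artifact profile, the ensemble-quality floor, cross-region
#' propagation of high-VAF germline alleles within each patient, and
#' finally cross-patient recurrence removal with the hotspot-gene
#' exemption.
#'
#' @param cohort a [cohort()] (or the `cohort` element of a
#'   [simulate_cohort()] result).
#' @param targets,genes interval sets.
#' @param pon panel-of-normals variant table (`NULL` to skip).
#' @param profile heuristic [filter_profile()] (default
#'   `builtin_profile("ffpe_benchmark")`).
#' @param initial_profile the permissive initial gate.
#' @param quality_floor ensemble-quality floor (default 115; `NULL` to
#'   skip).
#' @param pad target boundary padding in bases.
#' @param hotspot_genes cross-patient exemption genes.
#' @return list with `cohort` (each region gaining `variants`, the
#'   final calls, and `ensemble`, the raw ensemble set) and `provenance`
#'   (per-region per-stage counts).
#' @export
run_somatic_cascade <- function(cohort, targets, genes, pon = NULL,
                                profile = builtin_profile("ffpe_benchmark"),
                                initial_profile = builtin_profile("initial"),
                                quality_floor = 115, pad = 10,
                                hotspot_genes = c("PIK3CA", "TP53", "GATA3")) {
  prov <- list()
  for (pid in names(cohort$patients)) {
    for (rid in names(cohort$patients[[pid]]$regions)) {
      r <- cohort$patients[[pid]]$regions[[rid]]
      ens <- intersect_callers(r$caller1, r$caller2)
      v <- ens$variants
      n <- c(ensemble = nrow(v))
      v <- apply_initial_filters(v, initial_profile)
      n <- c(n, initial = nrow(v))
      v <- apply_target_mask(v, targets, genes, pad = pad)
      n <- c(n, target_mask = nrow(v))
      v <- subtract_panel_of_normals(v, pon)
      n <- c(n, pon = nrow(v))
      v <- filter_population_germline(v)
      n <- c(n, population = nrow(v))
      v <- filter_vaf_loh_germline(v, r$segments)
      n <- c(n, vaf_loh = nrow(v))
      v <- apply_heuristic_profile(v, profile)
      n <- c(n, heuristic = nrow(v))
      if (!is.null(quality_floor)) v <- filter_quality_floor(v, quality_floor)
      n <- c(n, quality_floor = nrow(v))
      cohort$patients[[pid]]$regions[[rid]]$ensemble <- ens$variants
      cohort$patients[[pid]]$regions[[rid]]$variants <- v
      prov[[paste(pid, rid, sep = "/")]] <- data.frame(
        patient = pid, region = rid, stage = names(n), n = as.integer(n),
        stringsAsFactors = FALSE)
    }
  }
  for (pid in names(cohort$patients)) {
    cohort$patients[[pid]] <-
      propagate_germline_exclusion(cohort$patients[[pid]])
  }
  cohort <- filter_cross_patient_recurrent(cohort, hotspot_genes)
  for (pid in names(cohort$patients)) {
    for (rid in names(cohort$patients[[pid]]$regions)) {
      prov[[paste(pid, rid, sep = "/")]] <- rbind(
        prov[[paste(pid, rid, sep = "/")]],
        data.frame(patient = pid, region = rid, stage = "final",
                   n = nrow(cohort$patients[[pid]]$regions[[rid]]$variants),
                   stringsAsFactors = FALSE))
    }
  }
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  list(cohort = cohort, provenance = prov)
}

#' Pooled accuracy of a cascade result against simulation truth
#'
#' Matches each region's call set (final by default, or the raw
#' ensemble) to the true somatic keys present in that region and pools
#' TP/FP/FN counts over all regions.
#'
#' @param result a [run_somatic_cascade()] result.
#' @param truth per-patient truth bundles from [simulate_cohort()].
#' @param use `"variants"` (final calls) or `"ensemble"`.
#' @return list with pooled `tp`, `fp`, `fn` counts and `precision`,
#'   `recall`, `f_score`.
#' @export
benchmark_against_truth <- function(result, truth, use = "variants") {
  tp <- fp <- fn <- 0L
  for (pid in names(result$cohort$patients)) {
    p <- result$cohort$patients[[pid]]
    tr <- truth[[pid]]
    pat_regions <- strsplit(tr$somatic$pattern, "|", fixed = TRUE)
    for (rid in names(p$regions)) {
      truth_keys <- tr$somatic$key[vapply(pat_regions, function(s) rid %in% s,
                                          logical(1))]
      calls <- p$regions[[rid]][[use]]
      ck <- unique(allele_key(calls))
      tp <- tp + length(intersect(ck, truth_keys))
      fp <- fp + length(setdiff(ck, truth_keys))
      fn <- fn + length(setdiff(truth_keys, ck))
    }
  }
  c(list(tp = tp, fp = fp, fn = fn), precision_recall(tp, fp, fn))
}
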