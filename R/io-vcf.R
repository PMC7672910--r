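#' Default VCF field map
#'
#' Maps variant-table metric names to the INFO keys (or the `QUAL`
#' column) under which callers carry them. The defaults follow the
#' VarDict / Mutect2 naming conventions (`AF`, `DP`, `MQ`, `NM`,
#' `PMEAN`, `MSI`, `TLOD`, `FS`) plus annotation keys for population
#' frequency and cancer-gene flags; the exact keys differ between
#' pipelines, so every entry can be overridden.
#'
#' @param ... named overrides, e.g. `vaf = "VAF"`.
#' @return named list metric -> key; the sentinel `"QUAL"` means the VCF
#'   QUAL column.
#' @export
default_field_map <- function(...) {
  map <- list(
    vaf = "AF", depth = "DP",
    alt_forward = "SAF", alt_reverse = "SAR",
    ensemble_quality = "QUAL",
    mapping_quality = "MQ", mean_mismatches = "NM",
    mean_pos_in_read = "PMEAN", ms_length = "MSI",
    tlod = "TLOD", fs_phred = "FS",
    pop_af = "POPAF", gene = "GENE",
    is_cgc_tier1 = "CGC_T1", in_cosmic = "COSMIC",
    in_clinvar = "CLINVAR", is_hotspot_gene = "HOTSPOT",
    effect_class = "EFFECT"
  )
  modifyList(map, list(...))
}

# pick the allele_idx-th comma-separated entry of a per-record INFO
# string; single-valued entries apply to every allele of the record
.pick_allele <- function(values, allele_idx) {
  parts <- strsplit(as.character(values), ",", fixed = TRUE)
  vapply(seq_along(values), function(i) {
    p <- parts[[i]]
    if (length(p) == 0 || all(is.na(p))) return(NA_character_)
    if (length(p) == 1) p else p[min(allele_idx[i], length(p))]
  }, character(1))
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file into a variant table: one row per ALT allele
#' per record (multiallelic records are split), metric fields pulled
#' from INFO under the keys in `field_map`, missing metrics left `NA`
#' (never zero-filled), and indels left-normalized so allele identity is
#' comparable across callers.
#'
#' @param path VCF file.
#' @param caller_label label recorded in the `callers` column.
#' @param field_map see [default_field_map()].
#' @param genome optional named chromosome sequences for full
#'   left-alignment (see [normalize_variants()]).
#' @return a variant table sorted by allele key.
#' @export
read_variants <- function(path, caller_label, field_map = default_field_map(),
                          genome = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(variant_table())
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep(seq_len(nrow(fix)), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  pos <- suppressWarnings(as.integer(fix[rec_idx, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record ", which(is.na(as.integer(fix[, "POS"])))[1],
         " in ", path, ": non-numeric POS")
  }
  get_metric <- function(metric) {
    key <- field_map[[metric]]
    if (is.null(key)) return(rep(NA_character_, length(rec_idx)))
    if (identical(key, "QUAL")) return(fix[rec_idx, "QUAL"])
    vals <- vcfR::extract.info(vcf, element = key)
    .pick_allele(vals[rec_idx], allele_idx)
  }
  num <- function(metric) suppressWarnings(as.numeric(get_metric(metric)))
  flag <- function(metric) {
    v <- get_metric(metric)
    ifelse(is.na(v), NA, v %in% c("1", "TRUE", "T", "yes"))
  }
  gene <- get_metric("gene")
  eff <- get_metric("effect_class")
  eff[is.na(eff) | !eff %in% c("silent", "non_silent")] <- "unknown"

  out <- variant_table(
    chrom = fix[rec_idx, "CHROM"], pos = pos,
    ref = fix[rec_idx, "REF"], alt = unlist(alt_list, use.names = FALSE),
    vaf = num("vaf"), depth = num("depth"),
    alt_forward = num("alt_forward"), alt_reverse = num("alt_reverse"),
    ensemble_quality = num("ensemble_quality"),
    mapping_quality = num("mapping_quality"),
    mean_mismatches = num("mean_mismatches"),
    mean_pos_in_read = num("mean_pos_in_read"),
    ms_length = num("ms_length"), tlod = num("tlod"), fs_phred = num("fs_phred"),
    callers = caller_label, pop_af = num("pop_af"), gene = gene,
    is_cgc_tier1 = flag("is_cgc_tier1"), in_cosmic = flag("in_cosmic"),
    in_clinvar = flag("in_clinvar"), is_hotspot_gene = flag("is_hotspot_gene"),
    effect_class = eff, validate = FALSE
  )
  bad <- which(out$ref == out$alt | out$pos < 1L)
  if (length(bad)) {
    stop("malformed VCF record ", rec_idx[bad[1]], " in ", path,
         ": invalid allele or position")
  }
  sort_variants(normalize_variants(out, genome = genome))
}

.num_fmt <- function(x) {
  ifelse(is.na(x), ".", sub("\\.?0+$", "", sprintf("%.6f", x)))
}

#' Write a variant table as VCF
#'
#' Emits a minimal, deterministic VCF 4.2 representation with metrics in
#' INFO under the `field_map` keys and `ensemble_quality` in QUAL.
#' Identical tables produce byte-identical files.
#'
#' @param variants a variant table.
#' @param path output file.
#' @param field_map see [default_field_map()].
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, field_map = default_field_map()) {
  info_keys <- field_map[!vapply(field_map, identical, logical(1), "QUAL")]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pmlseq",
    vapply(names(info_keys), function(m) {
      type <- if (m %in% .metric_logical) "Integer"
      else if (m %in% c("gene", "effect_class")) "String" else "Float"
      sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
              info_keys[[m]], type, m)
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    fields <- character(0)
    for (m in names(info_keys)) {
      v <- variants[[m]][i]
      if (is.null(v) || is.na(v)) next
      val <- if (is.logical(v)) as.integer(v)
      else if (is.numeric(v)) .num_fmt(v) else as.character(v)
      fields <- c(fields, paste0(info_keys[[m]], "=", val))
    }
    if (length(fields)) paste(fields, collapse = ";") else "."
  }, character(1))
  qual <- if ("ensemble_quality" %in% names(field_map) &&
              identical(field_map$ensemble_quality, "QUAL")) {
    .num_fmt(variants$ensemble_quality)
  } else rep(".", nrow(variants))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                qual, "PASS", info, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
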