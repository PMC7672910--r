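# Canonical column set of a variant table. Metric columns may be NA
# (missing evidence); they are never zero-filled.
VARIANT_COLUMNS <- c(
  "chrom", "pos", "ref", "alt",
  "vaf", "depth", "alt_forward", "alt_reverse",
  "ensemble_quality", "mapping_quality", "mean_mismatches",
  "mean_pos_in_read", "ms_length", "tlod", "fs_phred",
  "callers", "pop_af", "gene",
  "is_cgc_tier1", "in_cosmic", "in_clinvar", "is_hotspot_gene",
  "effect_class"
)

.metric_numeric <- c(
  "vaf", "depth", "alt_forward", "alt_reverse", "ensemble_quality",
  "mapping_quality", "mean_mismatches", "mean_pos_in_read", "ms_length",
  "tlod", "fs_phred", "pop_af"
)
.metric_logical <- c("is_cgc_tier1", "in_cosmic", "in_clinvar", "is_hotspot_gene")

#' Construct a variant table
#'
#' A variant table is a plain `data.frame` with one row per normalized
#' allele observation (one ALT allele at one site). It is the unit every
#' filtering, benchmarking and multi-region operation works on. Any
#' column omitted from `...` is filled with `NA` of the right type;
#' metrics are deliberately tri-state (value / `NA` = no evidence),
#' because filters must not fire on absent evidence.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (VCF convention).
#' @param ref,alt reference and alternate allele strings; `ref != alt`.
#' @param ... further columns among [VARIANT_COLUMNS], recycled to length.
#' @param validate check invariants (`vaf` in \[0,1\],
#'   `alt_forward + alt_reverse <= depth`, `pos >= 1`, `ref != alt`).
#' @return a `data.frame` with all of [VARIANT_COLUMNS].
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(), ...,
                          validate = TRUE) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  bad <- setdiff(names(extra), VARIANT_COLUMNS)
  if (length(bad)) stop("unknown variant columns: ", paste(bad, collapse = ", "))
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  for (nm in .metric_numeric) {
    df[[nm]] <- if (is.null(df[[nm]])) rep(NA_real_, n) else as.numeric(df[[nm]])
  }
  for (nm in .metric_logical) {
    df[[nm]] <- if (is.null(df[[nm]])) rep(NA, n) else as.logical(df[[nm]])
  }
  if (is.null(df$callers)) df$callers <- rep(NA_character_, n)
  if (is.null(df$gene)) df$gene <- rep(NA_character_, n)
  if (is.null(df$effect_class)) df$effect_class <- rep("unknown", n)
  df <- df[, VARIANT_COLUMNS]
  if (validate && n > 0) validate_variants(df)
  df
}

#' Validate variant-table invariants
#'
#' @param variants a variant table.
#' @return `variants`, invisibly; errors name the first offending row.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(variants))
  if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  .first_bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop("invalid variant record ", i[1], ": ", what, call. = FALSE)
  }
  .first_bad(is.na(variants$pos) | variants$pos < 1L, "pos must be >= 1")
  .first_bad(variants$ref == variants$alt, "ref == alt")
  if (!is.null(variants$vaf)) {
    .first_bad(!is.na(variants$vaf) & (variants$vaf < 0 | variants$vaf > 1),
               "vaf outside [0, 1]")
  }
  if (!is.null(variants$alt_forward) && !is.null(variants$alt_reverse) &&
      !is.null(variants$depth)) {
    s <- variants$alt_forward + variants$alt_reverse
    .first_bad(!is.na(s) & !is.na(variants$depth) & s > variants$depth,
               "alt_forward + alt_reverse > depth")
  }
  invisible(variants)
}

#' Allele identity keys
#'
#' The identity of a call is the tuple (chrom, pos, ref, alt); every
#' intersection, subtraction and truth-matching operation keys on it.
#'
#' @param variants a variant table.
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
allele_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Sort a variant table by allele key
#' @param variants a variant table.
#' @return the table ordered by (chrom, pos, ref, alt).
#' @export
sort_variants <- function(variants) {
  o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants[o, , drop = FALSE]
}

#' Left-normalize allele representations
#'
#' Canonicalizes each (pos, ref, alt) so the same underlying event is
#' written identically by both callers. Shared trailing bases are
#' trimmed; when trimming would empty an allele and a reference genome
#' is supplied, the pair is extended leftwards with the preceding
#' reference base and trimming continues (the standard left-alignment
#' walk through a repeat). Shared leading bases are then trimmed while
#' both alleles keep at least one base. Without a genome only the
#' trimming steps run, which is exact for SNVs and for indels already
#' carrying a single anchor base.
#'
#' @param variants a variant table.
#' @param genome optional named character vector of chromosome sequences
#'   used to left-extend indels through repeats.
#' @return the table with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(variants, genome = NULL) {
  if (nrow(variants) == 0) return(variants)
  norm1 <- function(chrom, pos, ref, alt) {
    repeat {
      advanced <- FALSE
      # right-trim shared suffix; left-extend from the genome when an
      # allele would become empty
      while (nchar(ref) >= 1 && nchar(alt) >= 1 &&
             substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
             (nchar(ref) > 1 || nchar(alt) > 1)) {
        if (nchar(ref) == 1 || nchar(alt) == 1) {
          if (is.null(genome) || is.null(genome[[chrom]]) || pos <= 1) break
          prev <- substr(genome[[chrom]], pos - 1, pos - 1)
          ref <- paste0(prev, ref)
          alt <- paste0(prev, alt)
          pos <- pos - 1L
          advanced <- TRUE
        }
        ref <- substr(ref, 1, nchar(ref) - 1)
        alt <- substr(alt, 1, nchar(alt) - 1)
        advanced <- TRUE
      }
      if (!advanced) break
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    list(pos = pos, ref = ref, alt = alt)
  }
  for (i in seq_len(nrow(variants))) {
    if (nchar(variants$ref[i]) == 1 && nchar(variants$alt[i]) == 1) next
    r <- norm1(variants$chrom[i], variants$pos[i], variants$ref[i], variants$alt[i])
    variants$pos[i] <- r$pos
    variants$ref[i] <- r$ref
    variants$alt[i] <- r$alt
  }
  variants
}

#' Is each record a single-nucleotide variant?
#' @param variants a variant table.
#' @return logical vector.
#' @export
is_snv <- function(variants) {
  nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
}
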