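#' Read copy-number bins (CNVkit-style .cnr)
#'
#' Tab-delimited with header; requires columns `chromosome` (or
#' `chrom`), `start`, `end`, `log2`. Coordinates are 0-based half-open.
#'
#' @param path .cnr file.
#' @return data.frame with columns chrom, start, end, log2.
#' @export
read_bins <- function(path) {
  df <- .read_cn_table(path, c("start", "end", "log2"))
  df[, c("chrom", "start", "end", "log2")]
}

#' Read copy-number segments (CNVkit-style .cns)
#'
#' Requires `chromosome`/`chrom`, `start`, `end`, `log2`; optional
#' `probes`, `ci_lo`, `ci_hi`, `bivar`, `baf` (missing optional columns
#' yield `NA`). Coordinates are 0-based half-open; rows with
#' `end <= start` are rejected.
#'
#' @param path .cns file.
#' @return data.frame with columns chrom, start, end, log2, n_probes,
#'   ci_low, ci_high, bivar, baf.
#' @export
read_segments <- function(path) {
  df <- .read_cn_table(path, c("start", "end", "log2"))
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end, log2 = df$log2,
    n_probes = if (is.null(df$probes)) NA_integer_ else as.integer(df$probes),
    ci_low = if (is.null(df$ci_lo)) NA_real_ else as.numeric(df$ci_lo),
    ci_high = if (is.null(df$ci_hi)) NA_real_ else as.numeric(df$ci_hi),
    bivar = if (is.null(df$bivar)) NA_real_ else as.numeric(df$bivar),
    baf = if (is.null(df$baf)) NA_real_ else as.numeric(df$baf),
    stringsAsFactors = FALSE
  )
  validate_segments(out)
  out
}

.read_cn_table <- function(path, required) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if ("chromosome" %in% names(df)) names(df)[names(df) == "chromosome"] <- "chrom"
  miss <- setdiff(c("chrom", required), names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$log2 <- as.numeric(df$log2)
  df
}

#' Validate segment invariants
#' @param segments a segment data.frame.
#' @return `segments`, invisibly.
#' @export
validate_segments <- function(segments) {
  bad <- which(segments$end <= segments$start)
  if (length(bad)) {
    stop("segment row ", bad[1], ": end <= start (",
         segments$chrom[bad[1]], ":", segments$start[bad[1]], "-",
         segments$end[bad[1]], ")")
  }
  both <- !is.na(segments$ci_low) & !is.na(segments$ci_high)
  bad <- which(both & (segments$ci_low > segments$log2 |
                         segments$log2 > segments$ci_high))
  if (length(bad)) {
    stop("segment row ", bad[1], ": log2 outside its confidence interval")
  }
  invisible(segments)
}

#' Write bins / segments back to the tab-delimited dialect
#' @param x data.frame from [read_bins()] / [read_segments()] or the
#'   simulator.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bins <- function(x, path) {
  out <- data.frame(chromosome = x$chrom, start = x$start, end = x$end,
                    log2 = x$log2)
  .write_tsv(out, path)
}

#' @rdname write_bins
#' @export
write_segments <- function(x, path) {
  out <- data.frame(chromosome = x$chrom, start = x$start, end = x$end,
                    log2 = x$log2, probes = x$n_probes, ci_lo = x$ci_low,
                    ci_hi = x$ci_high, bivar = x$bivar, baf = x$baf)
  .write_tsv(out, path)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) {
        ifelse(is.na(col), "NA", sprintf("%.10g", col))
      } else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Genomic interval sets (targets, genes, chromosome arms)
#'
#' Interval sets are `GRanges` objects with a `name` column; BED input
#' is 0-based half-open and converted at the boundary.
#'
#' @param chrom,start,end 0-based half-open coordinates.
#' @param label interval labels (target id, gene symbol, arm name).
#' @return a `GRanges` with a `name` metadata column.
#' @export
interval_set <- function(chrom, start, end, label) {
  stopifnot(all(start >= 0), all(end > start))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  S4Vectors::mcols(gr)$name <- as.character(label)
  gr
}

#' Read a BED3+label file as an interval set
#' @param path BED file (3 columns, optional 4th label column).
#' @return a `GRanges` interval set.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$name)) {
    S4Vectors::mcols(gr)$name <- as.character(seq_along(gr))
  }
  gr[, "name"]
}

#' Write an interval set as BED4
#' @param gr a `GRanges` interval set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = S4Vectors::mcols(gr)$name
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) {
    writeLines(paste(df$chrom, df$start, df$end, df$name, sep = "\t"), con)
  }
  invisible(path)
}

#' Flat-table views of analysis results
#'
#' Every reportable result (benchmark report, burden, arm calls, gene
#' calls, LOH calls, presence matrix, spectrum) has a deterministic flat
#' data.frame view used by [write_report()]; `read_report()` reads it
#' back so `read_report(write_report(x))` reproduces the table exactly.
#'
#' @param x a result object.
#' @return a data.frame with a fixed column order.
#' @export
as_report_table <- function(x) UseMethod("as_report_table")

#' @export
as_report_table.data.frame <- function(x) x

#' Write a result as a TSV report
#' @param x a result object with an [as_report_table()] view.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  .write_tsv(as_report_table(x), path)
}

#' Read a TSV report back
#' @param path report file.
#' @return a data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("cannot read report: ", path)
  read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
}
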