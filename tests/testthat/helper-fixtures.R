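# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (loops, enumeration) and never
# call the implementation they check.

# a variant table whose metrics pass every built-in profile unless
# overridden
good_variants <- function(chrom = "chr1", pos = 1000, ref = "C", alt = "T", ...) {
  defaults <- list(
    vaf = 0.4, depth = 100, alt_forward = 1, alt_reverse = 1,
    ensemble_quality = 200, mapping_quality = 60, mean_mismatches = 1,
    mean_pos_in_read = 30, ms_length = 1, tlod = 30, fs_phred = 2,
    callers = "vardict", pop_af = NA_real_, gene = NA_character_,
    is_cgc_tier1 = FALSE, in_cosmic = FALSE, in_clinvar = FALSE,
    is_hotspot_gene = FALSE
  )
  args <- modifyList(defaults, list(...))
  do.call(variant_table, c(list(chrom = chrom, pos = pos, ref = ref, alt = alt),
                           args))
}

write_test_vcf <- function(body_lines, info_defs = character()) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", info_defs,
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body_lines), path)
  path
}

# ---- brute-force oracles -------------------------------------------------

bf_match <- function(call_keys, truth_keys) {
  tp <- fp <- character(0)
  for (k in unique(call_keys)) {
    if (k %in% truth_keys) tp <- c(tp, k) else fp <- c(fp, k)
  }
  fn <- character(0)
  for (k in unique(truth_keys)) if (!k %in% call_keys) fn <- c(fn, k)
  list(tp = sort(tp), fp = sort(fp), fn = sort(fn))
}

bf_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
  else if (isTRUE(p == 0) || isTRUE(r == 0)) 0 else NA_real_
  c(p, r, f)
}

bf_optimal_threshold <- function(scores, call_keys, truth_keys) {
  best_f <- -Inf
  best_t <- NA_real_
  for (t in sort(unique(scores))) {
    kept <- unique(call_keys[scores >= t])
    tp <- sum(kept %in% truth_keys)
    f <- bf_prf(tp, length(kept) - tp, sum(!truth_keys %in% kept))[3]
    if (!is.na(f) && f > best_f) {
      best_f <- f
      best_t <- t
    }
  }
  list(threshold = best_t, f = best_f)
}

bf_burden <- function(segments) {
  g <- l <- tot <- 0
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i]
    tot <- tot + len
    if (segments$log2[i] > 0.3) g <- g + len
    if (segments$log2[i] < -0.3) l <- l + len
  }
  c(gain = g / tot, loss = l / tot, total = (g + l) / tot)
}

# all set partitions of 1..n as lists of integer vectors
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out <- c(out, list(q))
    }
    out <- c(out, list(c(p, list(n))))
  }
  out
}

# all rooted trees (laminar families of leaf subsets) on a region set
all_hierarchies <- function(regions) {
  rec <- function(s) {
    if (length(s) == 1) return(list(list(s)))
    out <- list()
    for (p in set_partitions(length(s))) {
      if (length(p) < 2) next
      blocks <- lapply(p, function(ix) s[ix])
      subtree_sets <- lapply(blocks, rec)
      combos <- expand.grid(lapply(subtree_sets, seq_along))
      for (ci in seq_len(nrow(combos))) {
        fam <- list(s)
        for (bi in seq_along(blocks)) {
          fam <- c(fam, subtree_sets[[bi]][[combos[ci, bi]]])
        }
        out <- c(out, list(fam))
      }
    }
    out
  }
  rec(sort(regions))
}

# max number of characters realizable as clades over all rooted trees
bf_best_tree_score <- function(patterns, counts, regions) {
  fam_ids <- function(fam) {
    unique(vapply(fam, function(s) paste(sort(s), collapse = "|"), character(1)))
  }
  best <- 0
  for (fam in all_hierarchies(regions)) {
    ids <- fam_ids(fam)
    best <- max(best, sum(counts[patterns %in% ids]))
  }
  best
}

# random conflict-free presence matrix from a random clone tree
random_conflict_free_matrix <- function(regions, max_per_edge = 4) {
  clusters <- as.list(regions)
  patterns <- as.list(regions)
  while (length(clusters) > 1) {
    i <- sort(sample.int(length(clusters), 2))
    merged <- sort(c(clusters[[i[1]]], clusters[[i[2]]]))
    clusters <- c(clusters[-i], list(merged))
    patterns <- c(patterns, list(merged))
  }
  counts <- sample.int(max_per_edge, length(patterns), replace = TRUE)
  rows <- list()
  for (j in seq_along(patterns)) {
    for (m in seq_len(counts[j])) {
      rows[[length(rows) + 1]] <- as.integer(regions %in% patterns[[j]])
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- regions
  list(matrix = m, patterns = patterns, counts = counts)
}
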