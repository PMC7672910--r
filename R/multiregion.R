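# Multi-region analysis: cross-region germline propagation, per-region
# presence/absence classification under a binomial error model, and
# clone-tree construction from the presence matrix.

#' Propagate high-VAF germline exclusion across regions of a patient
#'
#' Any allele found at VAF > 0.9 in a non-LOH segment of *one* region is
#' almost certainly germline; it is removed from every region of the
#' same patient, including regions where it was sampled at lower VAF.
#' Idempotent.
#'
#' @param patient a patient record: list with `id` and `regions`, each
#'   region a list with `variants` (variant table) and `segments`.
#' @param vaf_threshold strict VAF cutoff (default 0.9).
#' @return the patient with the offending alleles removed everywhere.
#' @export
propagate_germline_exclusion <- function(patient, vaf_threshold = 0.9) {
  drop_keys <- character(0)
  for (r in patient$regions) {
    v <- r$variants
    if (nrow(v) == 0) next
    loh <- call_loh(r$segments)$loh
    high <- !is.na(v$vaf) & v$vaf > vaf_threshold
    in_loh <- .pos_in_segments(v$chrom, v$pos, r$segments, loh)
    drop_keys <- c(drop_keys, allele_key(v)[high & !in_loh])
  }
  drop_keys <- unique(drop_keys)
  if (length(drop_keys) == 0) return(patient)
  for (ri in seq_along(patient$regions)) {
    v <- patient$regions[[ri]]$variants
    patient$regions[[ri]]$variants <-
      v[!(allele_key(v) %in% drop_keys), , drop = FALSE]
  }
  patient
}

#' Posterior probability that a mutation is present in a region
#'
#' Two-hypothesis Bayesian classification from the alt-read count and
#' depth at a site: under "absent", alt reads arise from sequencing
#' error alone, `alt ~ Binomial(depth, e)`; under "present", the
#' allelic fraction is unknown with a uniform prior on \[0,1\], giving
#' marginal likelihood `1 / (depth + 1)`. The posterior is
#' `prior * L1 / (prior * L1 + (1 - prior) * L0)`.
#'
#' @param alt alt-supporting read counts, `0 <= alt <= depth`.
#' @param depth total read counts.
#' @param e per-read sequencing error rate, in (0, 0.5) (default 0.02).
#' @param prior prior probability of presence (default 0.5).
#' @return posterior probabilities, vectorized over `alt`/`depth`.
#' @export
presence_posterior <- function(alt, depth, e = 0.02, prior = 0.5) {
  if (any(depth < 0)) stop("depth must be >= 0")
  if (any(alt < 0 | alt > depth)) stop("alt must satisfy 0 <= alt <= depth")
  if (e <= 0 || e >= 0.5) stop("e must lie in (0, 0.5)")
  l0 <- dbinom(alt, depth, e)
  l1 <- 1 / (depth + 1)
  prior * l1 / (prior * l1 + (1 - prior) * l0)
}

#' Build the mutation-by-region presence matrix
#'
#' Re-examines every candidate mutation of a patient in every region
#' using the per-region read counts at its position, classifying each
#' cell present/absent by [presence_posterior()] against a decision
#' threshold; cells with depth below `min_depth` (or with no counts at
#' all) are `unknown` rather than absent, so shallow regions cannot
#' masquerade as wild type.
#'
#' @param counts data.frame with columns `key` (allele key), `region`,
#'   `alt`, `depth` — one row per mutation/region pair with counts.
#' @param min_depth minimum depth to classify (default 10).
#' @param e,prior see [presence_posterior()].
#' @param decision_threshold classify present iff posterior >= threshold
#'   (default 0.5).
#' @return a `presence_matrix`: list of matrices `posterior`, `alt`,
#'   `depth` (mutations x regions) and `classification`
#'   ("present"/"absent"/"unknown").
#' @export
build_presence_matrix <- function(counts, min_depth = 10, e = 0.02,
                                  prior = 0.5, decision_threshold = 0.5) {
  stopifnot(all(c("key", "region", "alt", "depth") %in% names(counts)))
  keys <- sort(unique(counts$key))
  regions <- sort(unique(counts$region))
  shape <- list(keys, regions)
  m <- function(fill) matrix(fill, length(keys), length(regions), dimnames = shape)
  alt <- m(NA_real_); depth <- m(NA_real_)
  i <- cbind(match(counts$key, keys), match(counts$region, regions))
  alt[i] <- counts$alt
  depth[i] <- counts$depth
  post <- m(NA_real_)
  known <- !is.na(depth) & depth > 0
  post[known] <- presence_posterior(alt[known], depth[known], e, prior)
  cls <- m("unknown")
  decided <- known & depth >= min_depth
  cls[decided] <- ifelse(post[decided] >= decision_threshold, "present", "absent")
  structure(list(posterior = post, alt = alt, depth = depth,
                 classification = cls,
                 min_depth = min_depth, e = e, prior = prior,
                 decision_threshold = decision_threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix:", nrow(x$posterior), "mutations x",
      ncol(x$posterior), "regions\n")
  tab <- table(factor(x$classification, c("present", "absent", "unknown")))
  cat(sprintf("  present %d, absent %d, unknown %d (min_depth=%g, e=%g)\n",
              tab[1], tab[2], tab[3], x$min_depth, x$e))
  invisible(x)
}

#' @export
as_report_table.presence_matrix <- function(x) {
  keys <- rownames(x$posterior)
  regions <- colnames(x$posterior)
  out <- expand.grid(key = keys, region = regions, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  i <- cbind(match(out$key, keys), match(out$region, regions))
  out$alt <- x$alt[i]
  out$depth <- x$depth[i]
  out$posterior <- x$posterior[i]
  out$classification <- x$classification[i]
  out[order(out$key, out$region), , drop = FALSE]
}

# region subsets of each mutation: list of character vectors, unknown
# cells excluded
.presence_patterns <- function(classification) {
  regions <- colnames(classification)
  pats <- apply(classification, 1, function(row) {
    paste(sort(regions[row == "present"]), collapse = "|")
  })
  pats[nzchar(pats)]
}

.compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

#' Infer a clone tree from a presence matrix
#'
#' Treats each mutation's present-region set as a binary character
#' (unknown cells are excluded, not imputed). When the characters form a
#' laminar family — no two region sets partially overlap — the matrix
#' admits a perfect phylogeny, which is returned with per-edge mutation
#' counts. Otherwise characters are admitted greedily in decreasing
#' order of mutation support (ties broken lexicographically), each kept
#' only if compatible with those already accepted; mutations on rejected
#' characters are reported as homoplasy.
#'
#' @param x a `presence_matrix`, or a binary/logical mutations-x-regions
#'   matrix with region column names (`NA` = unknown).
#' @return a `clone_tree`: data.frame of nodes (`pattern`, `regions`,
#'   `n_mutations`, `parent`) plus attributes `regions`, `homoplasy`,
#'   `conflict_free`.
#' @export
infer_tree <- function(x) {
  cls <- if (inherits(x, "presence_matrix")) x$classification
  else {
    m <- matrix(ifelse(is.na(x), "unknown", ifelse(x > 0, "present", "absent")),
                nrow(x), ncol(x), dimnames = dimnames(x))
    m
  }
  regions <- colnames(cls)
  pats <- .presence_patterns(cls)
  tab <- table(pats)
  pat_sets <- strsplit(names(tab), "|", fixed = TRUE)
  counts <- as.integer(tab)
  # greedy compatibility selection: most-supported characters first
  o <- order(-counts, names(tab))
  accepted <- list(); accepted_n <- integer(0); homoplasy <- 0L
  for (j in o) {
    s <- pat_sets[[j]]
    if (all(vapply(accepted, .compatible, logical(1), s))) {
      accepted <- c(accepted, list(s))
      accepted_n <- c(accepted_n, counts[j])
    } else {
      homoplasy <- homoplasy + counts[j]
    }
  }
  conflict_free <- homoplasy == 0L
  # nodes: root (all regions), every accepted pattern, every leaf
  node_sets <- c(list(regions), accepted,
                 lapply(regions, function(r) r))
  node_ids <- vapply(node_sets, function(s) paste(sort(s), collapse = "|"),
                     character(1))
  keep <- !duplicated(node_ids)
  node_sets <- node_sets[keep]
  node_ids <- node_ids[keep]
  n_mut <- setNames(rep(0L, length(node_ids)), node_ids)
  acc_ids <- vapply(accepted, function(s) paste(sort(s), collapse = "|"),
                    character(1))
  n_mut[acc_ids] <- accepted_n
  sizes <- lengths(node_sets)
  parent <- rep(NA_character_, length(node_ids))
  for (i in seq_along(node_ids)) {
    sup <- which(vapply(node_sets, function(s) {
      length(s) > sizes[i] && all(node_sets[[i]] %in% s)
    }, logical(1)))
    if (length(sup)) parent[i] <- node_ids[sup[which.min(sizes[sup])]]
  }
  nodes <- data.frame(pattern = node_ids,
                      n_regions = sizes,
                      n_mutations = as.integer(n_mut[node_ids]),
                      parent = parent, stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$n_regions, nodes$pattern), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(nodes, regions = regions, homoplasy = homoplasy,
            conflict_free = conflict_free,
            class = c("clone_tree", "data.frame"))
}

#' Internal clades of a clone tree
#'
#' Canonical topology fingerprint: the set of non-trivial clades
#' (region subsets of size > 1, excluding the full region set). Two
#' clone trees have the same topology iff these sets are equal.
#'
#' @param tree a `clone_tree`.
#' @return sorted character vector of `|`-joined region subsets.
#' @export
clone_tree_clades <- function(tree) {
  n_all <- length(attr(tree, "regions"))
  sort(tree$pattern[tree$n_regions > 1 & tree$n_regions < n_all])
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree over regions {", paste(attr(x, "regions"), collapse = ", "),
      "}\n", sep = "")
  cat("  newick:", as_newick(x), "\n")
  if (attr(x, "homoplasy") > 0) {
    cat("  homoplasy:", attr(x, "homoplasy"), "mutations on incompatible characters\n")
  }
  invisible(x)
}

#' Newick representation of a clone tree
#'
#' Branch lengths are mutation counts on the edge leading into each
#' node; the returned string parses with `ape::read.tree`.
#'
#' @param tree a `clone_tree`.
#' @return a newick string.
#' @export
as_newick <- function(tree) {
  build <- function(id) {
    kids <- tree$pattern[!is.na(tree$parent) & tree$parent == id]
    label <- if (grepl("|", id, fixed = TRUE)) "" else id
    n <- tree$n_mutations[tree$pattern == id]
    body <- if (length(kids) == 0) label
    else paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
                ")", label)
    paste0(body, ":", n)
  }
  root <- tree$pattern[is.na(tree$parent)]
  paste0(build(root), ";")
}

#' Write a clone tree as a Newick file
#' @param tree a `clone_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as_newick(tree), con)
  invisible(path)
}
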