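test_that("high-VAF non-LOH alleles propagate their exclusion patient-wide", {
  segs_neutral <- data.frame(chrom = "chr1", start = 0L, end = 1e6L, log2 = 0,
                             n_probes = 100L, ci_low = -0.05, ci_high = 0.05,
                             bivar = 0.1, baf = 0.5)
  segs_loh <- transform(segs_neutral, baf = 0.15)
  germ <- function(vaf) good_variants(pos = 500, vaf = vaf)
  somatic <- good_variants(pos = 900, vaf = 0.4)
  patient <- list(id = "p1", regions = list(
    A = list(id = "A", variants = rbind(germ(0.95), somatic),
             segments = segs_neutral),
    B = list(id = "B", variants = rbind(germ(0.45), somatic),
             segments = segs_neutral),
    C = list(id = "C", variants = somatic, segments = segs_neutral)))
  out <- propagate_germline_exclusion(patient)
  for (r in out$regions) {
    expect_false(allele_key(germ(0.5)) %in% allele_key(r$variants))
    expect_true(allele_key(somatic) %in% allele_key(r$variants))
  }
  # idempotent
  expect_identical(propagate_germline_exclusion(out), out)

  # in an LOH segment the same VAF does not propagate
  patient_loh <- patient
  patient_loh$regions$A$segments <- segs_loh
  out2 <- propagate_germline_exclusion(patient_loh)
  expect_true(allele_key(germ(0.45)) %in%
                allele_key(out2$regions$B$variants))

  # single-region patient: equivalent to the per-region rule
  single <- list(id = "s", regions = list(
    A = list(id = "A", variants = rbind(germ(0.95), somatic),
             segments = segs_neutral)))
  out3 <- propagate_germline_exclusion(single)
  expect_equal(allele_key(out3$regions$A$variants), allele_key(somatic))
})

test_that("presence posterior matches the closed form to 12 significant digits", {
  direct <- function(alt, depth, e = 0.02, prior = 0.5) {
    l1 <- 1 / (depth + 1)
    l0 <- choose(depth, alt) * e^alt * (1 - e)^(depth - alt)
    prior * l1 / (prior * l1 + (1 - prior) * l0)
  }
  cases <- list(c(0, 50), c(3, 80), c(10, 40), c(50, 50), c(1, 200))
  for (cs in cases) {
    got <- presence_posterior(cs[1], cs[2])
    want <- direct(cs[1], cs[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(signif(presence_posterior(0, 50), 3), 0.0511)
  expect_equal(presence_posterior(0, 0), 0.5)         # no evidence -> prior
  expect_equal(presence_posterior(0, 0, prior = 0.3), 0.3)
  expect_gt(presence_posterior(50, 50), 0.999)
  expect_error(presence_posterior(5, 3), "alt")
  expect_error(presence_posterior(0, -1), "depth")
  expect_error(presence_posterior(1, 10, e = 0.7), "e must")
})

test_that("posterior is monotone in alt beyond the error mode", {
  # dbinom(alt; depth, e) increases up to its mode floor((depth+1)e), so
  # the posterior is monotone non-decreasing from the mode onwards (and
  # in practice over the whole range once e*depth < 1)
  post <- presence_posterior(0:60, 60)
  mode <- floor(61 * 0.02)
  expect_true(all(diff(post[(mode + 1):61]) >= 0))
  post_small <- presence_posterior(0:20, 20)
  expect_true(all(diff(post_small) >= 0))
  expect_equal(presence_posterior(0, 0, prior = 0.77), 0.77)
})

test_that("presence matrix has union shape and depth-gated unknowns", {
  counts <- expand.grid(key = paste0("m", 1:5), region = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  counts$depth <- 100
  counts$alt <- 40
  pm <- build_presence_matrix(counts)
  expect_equal(dim(pm$posterior), c(5, 3))
  expect_true(all(pm$classification == "present"))

  counts$alt[counts$key == "m1"] <- 0
  shallow <- counts$key == "m2" & counts$region == "B"
  counts$depth[shallow] <- 2
  counts$alt[shallow] <- 1
  pm <- build_presence_matrix(counts, min_depth = 5)
  expect_true(all(pm$classification["m1", ] == "absent"))
  expect_equal(pm$classification["m2", "B"], "unknown")
  # a missing cell is unknown too
  pm2 <- build_presence_matrix(counts[-1, ], min_depth = 5)
  expect_equal(pm2$classification[counts$key[1], counts$region[1]], "unknown")

  # report table round trip
  tab <- as_report_table(pm)
  expect_equal(nrow(tab), 15)
  path <- tempfile(fileext = ".tsv")
  write_report(pm, path)
  expect_equal(read_report(path)$posterior, tab$posterior, tolerance = 1e-6)
})

test_that("the multi-region worked example yields topology ((3B,3C),3A)", {
  m <- rbind(
    matrix(1, 8, 3),                              # trunk: all three regions
    matrix(rep(c(1, 0, 0), each = 2), 2, 3),      # 2 private to 3A
    matrix(rep(c(0, 1, 1), each = 4), 4, 3),      # 4 shared by 3B,3C
    matrix(rep(c(0, 1, 0), each = 1), 1, 3),      # 1 private to 3B
    matrix(rep(c(0, 0, 1), each = 3), 3, 3))      # 3 private to 3C
  colnames(m) <- c("3A", "3B", "3C")
  tree <- infer_tree(m)
  expect_true(attr(tree, "conflict_free"))
  expect_equal(clone_tree_clades(tree), "3B|3C")
  expect_equal(tree$n_mutations[tree$pattern == "3A|3B|3C"], 8L)
  expect_equal(tree$n_mutations[tree$pattern == "3B|3C"], 4L)
  expect_equal(tree$n_mutations[tree$pattern == "3A"], 2L)
  phy <- ape::read.tree(text = as_newick(tree))
  expect_equal(sort(phy$tip.label), c("3A", "3B", "3C"))
})

test_that("fully shared mutations give a trunk-only star tree", {
  m <- matrix(1, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  tree <- infer_tree(m)
  expect_equal(clone_tree_clades(tree), character(0))
  expect_equal(tree$n_mutations[tree$pattern == "A|B|C"], 6L)
  # fewer than 2 regions: trunk only
  single <- infer_tree(matrix(1, 3, 1, dimnames = list(NULL, "A")))
  expect_equal(nrow(single), 1)
})

test_that("conflict-free 4-region matrices reach the exhaustive optimum", {
  set.seed(99)
  regions <- c("A", "B", "C", "D")
  for (i in 1:50) {
    r <- random_conflict_free_matrix(regions)
    tree <- infer_tree(r$matrix)
    expect_true(attr(tree, "conflict_free"))
    expect_equal(attr(tree, "homoplasy"), 0L)
    # every generated pattern must be a clade with the generated count
    for (j in seq_along(r$patterns)) {
      id <- paste(sort(r$patterns[[j]]), collapse = "|")
      expect_equal(tree$n_mutations[tree$pattern == id], r$counts[j])
    }
    # brute force: no rooted tree explains more characters
    pats <- vapply(r$patterns, function(s) paste(sort(s), collapse = "|"),
                   character(1))
    best <- bf_best_tree_score(pats, r$counts, regions)
    expect_equal(sum(tree$n_mutations), best)
  }
})

test_that("unknown cells are excluded from tree characters, not imputed", {
  m <- rbind(c(1, 1, NA), c(1, 0, 0), c(1, 1, NA))
  colnames(m) <- c("A", "B", "C")
  tree <- infer_tree(m)
  # the NA rows reduce to the {A,B} pattern
  expect_equal(tree$n_mutations[tree$pattern == "A|B"], 2L)
})

test_that("newick export parses and carries mutation-count branch lengths", {
  m <- rbind(matrix(1, 5, 3),
             matrix(rep(c(1, 1, 0), each = 2), 2, 3))
  colnames(m) <- c("r1", "r2", "r3")
  tree <- infer_tree(m)
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("r1", "r2", "r3"))
})
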