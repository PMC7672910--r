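mk_seg <- function(chrom = "chr1", start = 0, end = 1e6, log2 = 0,
                   n_probes = 100L, ci_low = log2 - 0.05, ci_high = log2 + 0.05,
                   bivar = 0.1, baf = NA_real_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             log2 = log2, n_probes = as.integer(n_probes), ci_low = ci_low,
             ci_high = ci_high, bivar = bivar, baf = baf)
}

test_that("artifact bins below the log2 floor are removed", {
  bins <- data.frame(chrom = "chr1", start = c(0L, 250L, 500L),
                     end = c(250L, 500L, 750L), log2 = c(-16, -14.9, 0.2))
  out <- clean_bins(bins)
  expect_equal(out$log2, c(-14.9, 0.2))
  expect_equal(nrow(clean_bins(bins[0, ])), 0)
})

test_that("segment QC fails on probes, variance or a CI containing zero", {
  segs <- rbind(mk_seg(start = 0, end = 1e5, n_probes = 9, log2 = 0.5),
                mk_seg(start = 1e5, end = 2e5, bivar = 2.5, log2 = 0.5),
                mk_seg(start = 2e5, end = 3e5, log2 = 0.25,
                       ci_low = 0.1, ci_high = 0.4, n_probes = 50, bivar = 0.5),
                mk_seg(start = 3e5, end = 4e5, log2 = 0.05,
                       ci_low = -0.1, ci_high = 0.2))
  qc <- qc_segments(segs)
  expect_equal(nrow(qc$passing), 1)
  expect_equal(qc$passing$start, 2e5)
  expect_setequal(qc$failing$reason,
                  c("few_probes", "high_bivar", "ci_contains_zero"))
  # boundary: exactly 10 probes and bivar exactly 2 pass
  ok <- qc_segments(mk_seg(n_probes = 10, bivar = 2, ci_low = 0.01,
                           ci_high = 0.09, log2 = 0.05))
  expect_equal(nrow(ok$passing), 1)
  # missing CI: evaluated on the remaining criteria and flagged
  noci <- qc_segments(mk_seg(ci_low = NA, ci_high = NA))
  expect_equal(nrow(noci$passing), 1)
  expect_equal(noci$flagged_no_ci, 1L)
})

test_that("burden is the altered fraction of total segment length", {
  expect_equal(cna_burden(mk_seg(log2 = 0))$total_fraction, 0)

  two <- rbind(mk_seg(start = 0, end = 3e7, log2 = 0.5),
               mk_seg(start = 3e7, end = 1e8, log2 = 0))
  b <- cna_burden(two)
  expect_equal(b$gain_fraction, 0.30)
  expect_equal(b$total_fraction, 0.30)

  three <- rbind(mk_seg(start = 0, end = 2e7, log2 = 0.6),
                 mk_seg(start = 2e7, end = 3e7, log2 = -0.8),
                 mk_seg(start = 3e7, end = 1e8, log2 = 0.1))
  b <- cna_burden(three)
  expect_equal(b$gain_fraction, 0.20)
  expect_equal(b$loss_fraction, 0.10)
  expect_equal(b$total_fraction, 0.30)
  # boundary: +/-0.3 itself is neutral
  expect_equal(cna_burden(mk_seg(log2 = 0.3))$total_fraction, 0)
  expect_equal(cna_burden(mk_seg(log2 = -0.3))$total_fraction, 0)
  expect_error(cna_burden(mk_seg(start = 0, end = 0)[0, ]), "zero total")
})

test_that("burden matches a brute-force length summation on random profiles", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(1:50, 1)
    starts <- cumsum(c(0, sample(1:1000, n - 1, replace = TRUE)))
    lens <- sample(1:5000, n, replace = TRUE)
    segs <- mk_seg(start = starts, end = starts + lens,
                   log2 = runif(n, -1.5, 1.5))
    b <- cna_burden(segs)
    o <- bf_burden(segs)
    expect_equal(b$gain_fraction, unname(o["gain"]))
    expect_equal(b$loss_fraction, unname(o["loss"]))
    expect_equal(b$total_fraction, unname(o["total"]))
  }
})

test_that("splitting a segment in two leaves the burden unchanged", {
  set.seed(7)
  segs <- mk_seg(start = c(0, 1e6, 3e6), end = c(1e6, 3e6, 8e6),
                 log2 = c(0.5, 0, -0.6))
  split <- rbind(mk_seg(start = 0, end = 5e5, log2 = 0.5),
                 mk_seg(start = 5e5, end = 1e6, log2 = 0.5),
                 segs[-1, ])
  expect_equal(cna_burden(split)$total_fraction, cna_burden(segs)$total_fraction)
  expect_equal(cna_burden(split)$gain_fraction, cna_burden(segs)$gain_fraction)
})

arms2 <- interval_set(c("chr1", "chr1"), c(0, 2.5e7), c(2.5e7, 5e7),
                      c("1p", "1q"))

test_that("arm calls need strictly more than half the covered length", {
  segs <- rbind(
    mk_seg(start = 0, end = 1.5e7, log2 = -0.8,
           ci_low = -0.9, ci_high = -0.7),               # 60% of covered 1p
    mk_seg(start = 1.5e7, end = 2.5e7, log2 = 0))
  out <- call_arms(segs, arms2)
  expect_equal(out$status[out$arm == "1p"], "lost")
  expect_equal(out$involved_fraction[out$arm == "1p"], 0.6)
  expect_equal(out$status[out$arm == "1q"], "neutral")
  expect_equal(out$covered_bases[out$arm == "1q"], 0)

  half <- rbind(
    mk_seg(start = 0, end = 1.25e7, log2 = -0.8, ci_low = -0.9, ci_high = -0.7),
    mk_seg(start = 1.25e7, end = 2.5e7, log2 = 0))
  expect_equal(call_arms(half, arms2)$status[1], "neutral")  # exactly 50%

  # permutation invariance
  perm <- call_arms(segs[2:1, ], arms2)
  expect_equal(perm, out)
})

test_that("segments whose CI spans zero cannot drive a confident arm call", {
  segs <- mk_seg(start = 0, end = 2e7, log2 = -0.5, ci_low = -1, ci_high = 0.1)
  expect_equal(call_arms(segs, arms2)$status[1], "neutral")
  expect_equal(call_arms(segs, arms2, require_ci = FALSE)$status[1], "lost")
})

test_that("LOH is a strict BAF departure from heterozygosity", {
  segs <- mk_seg(start = c(0, 1, 2, 3, 4) * 1e6, end = c(1, 2, 3, 4, 5) * 1e6,
                 baf = c(0.25, 0.3, 0.5, 0.75, NA))
  out <- call_loh(segs)
  expect_equal(out$loh, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$baf_missing, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("gene copy-number calls enforce eligibility and breakpoints", {
  genes <- interval_set(c("chr1", "chr1", "chr1"),
                        c(1000, 10000, 20000), c(3000, 12000, 22000),
                        c("G1", "G2", "G3"))
  mk_bins <- function(starts, width = 250) {
    data.frame(chrom = "chr1", start = as.integer(starts),
               end = as.integer(starts + width), log2 = 0.5)
  }
  # region A: G1 has 5 bins in a 200-probe gained segment; G2 only 2 bins;
  # G3 spans a segment breakpoint
  bins_a <- mk_bins(c(seq(1000, 2000, by = 250), 10000, 10300,
                      seq(20000, 21000, by = 250)))
  segs_a <- rbind(mk_seg(start = 0, end = 15000, log2 = 0.8, n_probes = 200,
                         ci_low = 0.6, ci_high = 1.0),
                  mk_seg(start = 15000, end = 21000, log2 = 0.1, n_probes = 150,
                         ci_low = 0.05, ci_high = 0.15),
                  mk_seg(start = 21000, end = 40000, log2 = -0.9, n_probes = 150,
                         ci_low = -1, ci_high = -0.8))
  # region B: one segment covers everything
  bins_b <- bins_a
  segs_b <- mk_seg(start = 0, end = 40000, log2 = -0.7, n_probes = 500,
                   ci_low = -0.8, ci_high = -0.6)
  out <- call_gene_copy_number(list(A = bins_a, B = bins_b),
                               list(A = segs_a, B = segs_b), genes)
  gA <- out[out$region == "A", ]
  gB <- out[out$region == "B", ]
  expect_equal(gA$status[gA$gene == "G1"], "gain")      # log2 0.8 > 0.4
  expect_equal(gA$log2[gA$gene == "G1"], 0.8)
  expect_equal(gA$status[gA$gene == "G2"], "excluded")  # 2 bins < 3
  expect_equal(gA$reason[gA$gene == "G2"], "too_few_bins")
  # breakpoint in region A excludes G3 in both regions
  expect_equal(gA$status[gA$gene == "G3"], "excluded")
  expect_equal(gB$status[gB$gene == "G3"], "excluded")
  expect_equal(gB$reason[gB$gene == "G3"], "breakpoint_in_patient")
  expect_equal(gB$status[gB$gene == "G1"], "loss")      # -0.7 < -0.6
})
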