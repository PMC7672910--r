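# Small configurations keep the suite fast; the full default-scale
# cohort is exercised in the acceptance tests.
small_cfg <- function(...) {
  sim_config(seed = 5, n_patients = 1, n_germline = 100, n_truncal = 8,
             n_shared_internal = 4, n_private = c(2, 1, 3), n_artifacts = 500,
             ...)
}

test_that("truth bundles conserve the configured counts", {
  cfg <- small_cfg()
  r <- simulate_patient(cfg, 1)
  expect_length(r$truth$germline, 100)
  expect_equal(nrow(r$truth$somatic), sum(r$truth$tree_spec$n))
  expect_length(r$patient$regions, 3)
  for (rg in r$patient$regions) {
    expect_length(r$truth$artifacts[[rg$id]], 500)
  }
  # truth classes are position-disjoint within each region
  pos_of <- function(k) sub("^([^:]+:[0-9]+):.*$", "\\1", k)
  base_pos <- pos_of(c(r$truth$germline, r$truth$somatic$key))
  expect_equal(anyDuplicated(base_pos), 0)
  for (rid in names(r$truth$artifacts)) {
    expect_length(intersect(pos_of(r$truth$artifacts[[rid]]), base_pos), 0)
  }
})

test_that("identical seed and config reproduce identical patients", {
  cfg <- small_cfg()
  a <- simulate_patient(cfg, 1)
  b <- simulate_patient(cfg, 1)
  expect_identical(a, b)
})

test_that("every emitted record reconciles against exactly one truth class", {
  cfg <- small_cfg()
  r <- simulate_patient(cfg, 1)
  tr <- r$truth
  for (rg in r$patient$regions) {
    in_region <- vapply(strsplit(tr$somatic$pattern, "|", fixed = TRUE),
                        function(s) rg$id %in% s, logical(1))
    classes <- list(germline = tr$germline,
                    somatic = tr$somatic$key[in_region],
                    artifact = tr$artifacts[[rg$id]])
    for (cal in c("caller1", "caller2")) {
      k <- allele_key(rg[[cal]])
      hits <- vapply(k, function(key) sum(vapply(classes, function(cl)
        key %in% cl, logical(1))), numeric(1))
      expect_true(all(hits == 1))
    }
  }
})

test_that("truth presence patterns reproduce the configured region tree", {
  cfg <- small_cfg()
  r <- simulate_patient(cfg, 1)
  pat <- table(r$truth$somatic$pattern)
  spec <- r$truth$tree_spec
  expect_setequal(names(pat), spec$pattern)
  expect_equal(as.integer(pat[spec$pattern]), spec$n)
})

test_that("perfect concordance for truth and none for artifacts recovers truth", {
  cfg <- small_cfg(concordance_true = 1, concordance_artifact = 0)
  r <- simulate_patient(cfg, 1)
  tr <- r$truth
  for (rg in r$patient$regions) {
    ens <- intersect_callers(rg$caller1, rg$caller2)
    in_region <- vapply(strsplit(tr$somatic$pattern, "|", fixed = TRUE),
                        function(s) rg$id %in% s, logical(1))
    want <- c(tr$germline, tr$somatic$key[in_region])
    expect_setequal(allele_key(ens$variants), want)
  }
})

test_that("artifacts follow the configured spectrum and low-VAF profile", {
  cfg <- sim_config(seed = 17, n_patients = 1, regions_per_patient = 1,
                    n_germline = 0, n_truncal = 0, n_shared_internal = 0,
                    n_private = 0, n_artifacts = 10000,
                    concordance_artifact = 1)
  r <- simulate_patient(cfg, 1)
  v <- r$patient$regions[[1]]$caller1
  expect_equal(nrow(v), 10000)
  sp <- substitution_spectrum(v, vaf_max = 1.01)
  ct <- sp$fraction[sp$class == "C>T"]
  # within 3 binomial standard deviations of the configured weight
  sd3 <- 3 * sqrt(0.53 * 0.47 / 10000)
  expect_lt(abs(ct - 0.53), sd3)
  # artifact VAF mass concentrates below 0.05
  expect_gt(mean(v$vaf < 0.05), 0.9)
  # strand bias: all alt reads on one strand
  expect_true(all(v$alt_forward == 0 | v$alt_reverse == 0))

  frozen <- sim_config(seed = 17, n_patients = 1, regions_per_patient = 1,
                       n_germline = 0, n_truncal = 0, n_shared_internal = 0,
                       n_private = 0, n_artifacts = 10000,
                       concordance_artifact = 1, mode = "frozen")
  vf <- simulate_patient(frozen, 1)$patient$regions[[1]]$caller1
  spf <- substitution_spectrum(vf, vaf_max = 1.01)
  ca <- spf$fraction[spf$class == "C>A"]
  expect_lt(abs(ca - 0.52), 3 * sqrt(0.52 * 0.48 / 10000))
})

test_that("simulated copy number realizes the configured events", {
  cfg <- small_cfg()
  ann <- make_genome_annotation(cfg)
  cn <- simulate_copy_number(cfg, seed = 99)
  qc <- qc_segments(cn$segments, ci_check = FALSE)
  # 80%-of-arm loss on chr2p is recovered as a lost arm
  arms <- call_arms(qc$passing, ann$arms)
  expect_equal(arms$status[arms$arm == "2p"], "lost")
  expect_equal(arms$status[arms$arm == "2q"], "neutral")
  # the LOH event is flagged from BAF
  loh <- call_loh(cn$segments)
  ev <- loh$chrom == "chr2" & loh$start == 0
  expect_true(all(loh$loh[ev] | loh$baf_missing[ev]))

  # a 40%-of-arm loss is not called
  cfg40 <- small_cfg(cna_events = list(
    list(chrom = "chr2", start = 0, end = 1e7, log2 = -0.5, baf = 0.25,
         loh = TRUE)))
  cn40 <- simulate_copy_number(cfg40, seed = 99)
  arms40 <- call_arms(qc_segments(cn40$segments, ci_check = FALSE)$passing,
                      ann$arms)
  expect_equal(arms40$status[arms40$arm == "2p"], "neutral")

  # no events, no noise: zero burden
  flat <- small_cfg(cna_events = list(), noise_sd = 0)
  cnf <- simulate_copy_number(flat, seed = 1)
  expect_equal(cna_burden(cnf$segments)$total_fraction, 0)

  # overlapping events are a configuration error
  bad <- small_cfg(cna_events = list(
    list(chrom = "chr1", start = 0, end = 2e6, log2 = 1, baf = NA, loh = FALSE),
    list(chrom = "chr1", start = 1e6, end = 3e6, log2 = -1, baf = NA,
         loh = FALSE)))
  expect_error(simulate_copy_number(bad, seed = 1), "overlapping")
})

test_that("patient substreams are independent of patient ordering", {
  cfg <- small_cfg(n_patients = 2)
  solo <- simulate_patient(cfg, 2)
  both <- simulate_cohort(cfg)
  expect_identical(both$cohort$patients$patient2$regions$A$caller1,
                   solo$patient$regions$A$caller1)
})

test_that("written cohorts are byte-identical across runs", {
  cfg <- small_cfg(n_artifacts = 200)
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})
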