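# Seeded generator of multi-patient, multi-region cohorts with known
# ground truth: germline variants at population frequencies, clonal
# somatic mutations placed on a region tree, fixation-damage artifacts
# (low-VAF, strand-biased, C>T-dominated in FFPE mode, C>A-dominated in
# frozen mode), two-caller concordance structure, and segmented
# copy-number profiles with LOH. One root seed; per-patient and
# per-region substreams keep outputs independent of iteration order.

#' Simulation configuration
#'
#' Defaults describe a desk-scale FFPE multi-region cohort: 3 patients
#' x 3 regions at ~80x mean coverage over a 2 x 50 Mb synthetic genome
#' (100 genes, 8 x 200 bp targets each, arms split at 25 Mb), 200
#' germline variants per patient drawn from a shared population pool,
#' a clonal tree with 40 truncal / 8 shared / 10 private somatic
#' mutations per edge, and 10,000 low-VAF artifacts per region with a
#' C>T weight of 0.53 (FFPE) or C>A weight of 0.52 (frozen).
#'
#' @param seed root seed; every random draw derives from it.
#' @param ... overrides of any default listed below.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = 3,
    regions_per_patient = 3,
    region_ids = NULL,              # default LETTERS[1:regions_per_patient]
    mean_depth = 80,
    # genome model
    n_chrom = 2, chrom_length = 5e7, centromere = 2.5e7,
    n_genes = 100, gene_length = 2e4, targets_per_gene = 8,
    target_length = 200,
    # germline / population model
    n_germline = 200, het_fraction = 2 / 3,
    pool_size = 3000, rare_site_fraction = 0.05,
    pon_detection = 0.85,
    # somatic model
    n_truncal = 40, n_shared_internal = 8, n_private = 10,
    tree_spec = NULL,               # data.frame(pattern, n) override
    somatic_vaf_shape = c(14, 26),  # Beta; mean 0.35
    indel_fraction = 0.05,
    # artifact model
    mode = "ffpe",                  # or "frozen"
    n_artifacts = 10000,
    artifact_vaf_shape = c(1, 60),  # Beta concentrated below 0.05
    spectrum_ffpe = c("C>A" = 0.11, "C>G" = 0.06, "C>T" = 0.53,
                      "T>A" = 0.08, "T>C" = 0.13, "T>G" = 0.09),
    spectrum_frozen = c("C>A" = 0.52, "C>G" = 0.06, "C>T" = 0.15,
                        "T>A" = 0.07, "T>C" = 0.12, "T>G" = 0.08),
    # caller concordance (independent per caller)
    concordance_true = 0.99, concordance_artifact = 0.2,
    caller_labels = c("vardict", "mutect2"),
    # quality / metric distributions (mean, sd)
    quality_true = c(200, 40), quality_artifact = c(60, 30),
    mapq_true = c(60, 3), mapq_artifact = c(50, 8),
    pmean_true = c(35, 5), pmean_artifact = c(12, 6),
    nm_true = c(1, 0.5), nm_artifact = c(2.2, 0.8),
    tlod_true = c(30, 8), tlod_artifact = c(6, 3),
    fs_true_rate = 0.5, fs_artifact = c(25, 10),
    # background error used for joint-count extraction
    error_background = 0.002,
    # copy number
    bin_size = 5e4, noise_sd = 0.2, baf_sd = 0.01, baf_missing_rate = 0.1,
    cna_events = list(
      list(chrom = "chr2", start = 0, end = 2e7, log2 = -0.5,
           baf = 0.25, loh = TRUE),
      list(chrom = "chr1", start = 3e7, end = 3.2e7, log2 = 0.8,
           baf = NA, loh = FALSE)
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  for (i in seq_along(dots)) cfg[[names(dots)[i]]] <- dots[[i]]  # last wins
  if (is.null(cfg$region_ids)) cfg$region_ids <- LETTERS[seq_len(cfg$regions_per_patient)]
  if (cfg$regions_per_patient < 1) stop("regions_per_patient must be >= 1")
  stopifnot(cfg$mode %in% c("ffpe", "frozen"),
            cfg$concordance_true >= 0, cfg$concordance_true <= 1,
            cfg$concordance_artifact >= 0, cfg$concordance_artifact <= 1,
            cfg$n_germline >= 0, cfg$n_artifacts >= 0)
  w <- if (cfg$mode == "ffpe") cfg$spectrum_ffpe else cfg$spectrum_frozen
  if (abs(sum(w) - 1) > 1e-8) stop("artifact spectrum weights must sum to 1")
  structure(cfg, class = "sim_config")
}

# deterministic substream seed below 2^31
.derive_seed <- function(root, patient, stream) {
  (abs(root) %% 100000L) * 20011L + patient * 1009L + stream * 9973L + 17L
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic genome annotation
#'
#' Builds the deterministic (seed-independent) genome model of a
#' configuration: target, gene and chromosome-arm interval sets plus the
#' flat table of targetable base positions with their gene annotations.
#' Gene 1-3 are named TP53, PIK3CA, GATA3 (the breast-cancer hotspot
#' genes); every seventh gene is flagged tier 1.
#'
#' @param config a [sim_config()].
#' @return list with `targets`, `genes`, `arms` (interval sets) and
#'   `sites` (data.frame chrom/pos/gene/tier1/hotspot, one row per
#'   targetable base).
#' @export
make_genome_annotation <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chrom))
  hot <- c("TP53", "PIK3CA", "GATA3")
  gene_names <- paste0("GENE", sprintf("%03d", seq_len(config$n_genes)))
  gene_names[seq_along(hot)] <- hot
  tier1 <- gene_names %in% hot | (seq_len(config$n_genes) %% 7L == 0L)
  gene_chrom <- chroms[((seq_len(config$n_genes) - 1L) %% config$n_chrom) + 1L]
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  slot <- ((seq_len(config$n_genes) - 1L) %/% config$n_chrom)
  usable <- config$chrom_length - 2e6
  gene_start <- as.integer(1e6 + slot * floor(usable / per_chrom))
  gene_end <- gene_start + as.integer(config$gene_length)
  genes <- interval_set(gene_chrom, gene_start, gene_end, gene_names)

  t_off <- (seq_len(config$targets_per_gene) - 1L) *
    floor(config$gene_length / config$targets_per_gene)
  tg <- expand.grid(gi = seq_len(config$n_genes),
                    ti = seq_len(config$targets_per_gene),
                    KEEP.OUT.ATTRS = FALSE)
  t_start <- gene_start[tg$gi] + t_off[tg$ti]
  targets <- interval_set(gene_chrom[tg$gi], t_start,
                          t_start + config$target_length,
                          paste0(gene_names[tg$gi], "_t", tg$ti))
  arms <- interval_set(
    rep(chroms, each = 2),
    rep(c(0, config$centromere), config$n_chrom),
    rep(c(config$centromere, config$chrom_length), config$n_chrom),
    paste0(rep(seq_len(config$n_chrom), each = 2), c("p", "q"))
  )
  pos_list <- lapply(seq_len(nrow(tg)), function(i) t_start[i] + seq_len(config$target_length))
  sites <- data.frame(
    chrom = rep(gene_chrom[tg$gi], each = config$target_length),
    pos = unlist(pos_list, use.names = FALSE),
    gene = rep(gene_names[tg$gi], each = config$target_length),
    tier1 = rep(tier1[tg$gi], each = config$target_length),
    stringsAsFactors = FALSE
  )
  sites$hotspot <- sites$gene %in% hot
  sites$ref <- c("A", "C", "G", "T")[(sites$pos %% 4L) + 1L]
  list(targets = targets, genes = genes, arms = arms, sites = sites)
}

.other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

# population pool shared by all patients of a cohort
.make_population_pool <- function(config, ann) {
  .with_seed(.derive_seed(config$seed, 0L, 1L), {
    idx <- sample.int(nrow(ann$sites), config$pool_size)
    sites <- ann$sites[idx, , drop = FALSE]
    rare <- runif(config$pool_size) < config$rare_site_fraction
    af <- ifelse(rare,
                 10^runif(config$pool_size, -5, log10(8e-4)),
                 10^runif(config$pool_size, log10(2e-3), log10(0.5)))
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
               alt = .other_base(sites$ref), gene = sites$gene,
               tier1 = sites$tier1, hotspot = sites$hotspot,
               af = af, rare = rare, stringsAsFactors = FALSE)
  })
}

# panel of normals: common pool sites observed in the normal panel
.make_panel_of_normals <- function(config, pool) {
  .with_seed(.derive_seed(config$seed, 0L, 2L), {
    seen <- !pool$rare & runif(nrow(pool)) < config$pon_detection
    variant_table(chrom = pool$chrom[seen], pos = pool$pos[seen],
                  ref = pool$ref[seen], alt = pool$alt[seen])
  })
}

# default clone-tree spec: trunk over all regions, random binary
# internal structure, private edge per leaf
.default_tree_spec <- function(config, regions) {
  k <- length(regions)
  patterns <- as.list(regions)
  n <- rep_len(config$n_private, k)
  clusters <- as.list(regions)
  while (length(clusters) > 1) {
    i <- if (length(clusters) == 2) c(1L, 2L) else sort(sample.int(length(clusters), 2))
    merged <- sort(c(clusters[[i[1]]], clusters[[i[2]]]))
    clusters <- c(clusters[-i], list(merged))
    patterns <- c(patterns, list(merged))
    n <- c(n, if (length(merged) == k) config$n_truncal else config$n_shared_internal)
  }
  data.frame(pattern = vapply(patterns, paste, character(1), collapse = "|"),
             n = n, stringsAsFactors = FALSE)
}

.draw_metrics <- function(n, class, config) {
  g <- function(par) pmax(rnorm(n, par[1], par[2]), 1)
  if (class == "true") {
    list(quality = g(config$quality_true), mapq = g(config$mapq_true),
         pmean = g(config$pmean_true), nm = abs(rnorm(n, config$nm_true[1], config$nm_true[2])),
         msi = sample(0:3, n, replace = TRUE),
         tlod = g(config$tlod_true), fs = rexp(n, config$fs_true_rate))
  } else {
    list(quality = g(config$quality_artifact), mapq = g(config$mapq_artifact),
         pmean = g(config$pmean_artifact),
         nm = abs(rnorm(n, config$nm_artifact[1], config$nm_artifact[2])),
         msi = sample(0:5, n, replace = TRUE),
         tlod = g(config$tlod_artifact),
         fs = pmax(rnorm(n, config$fs_artifact[1], config$fs_artifact[2]), 0))
  }
}

# assemble a variant table for one class of records in one region
.records_table <- function(sites, vaf_true, class, config) {
  n <- nrow(sites)
  if (n == 0) return(variant_table())
  depth <- pmax(rpois(n, config$mean_depth), 1)
  alt_n <- rbinom(n, depth, pmin(vaf_true, 1))
  fresh <- alt_n == 0
  alt_n[fresh] <- 1L  # a call implies at least one supporting read
  vaf <- alt_n / depth
  m <- .draw_metrics(n, if (class == "artifact") "artifact" else "true", config)
  if (class == "artifact") {
    side <- runif(n) < 0.5
    af <- ifelse(side, alt_n, 0L)
  } else {
    af <- rbinom(n, alt_n, 0.5)
  }
  variant_table(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    vaf = vaf, depth = depth, alt_forward = af, alt_reverse = alt_n - af,
    ensemble_quality = m$quality, mapping_quality = m$mapq,
    mean_mismatches = m$nm, mean_pos_in_read = m$pmean, ms_length = m$msi,
    tlod = m$tlod, fs_phred = m$fs,
    pop_af = sites$pop_af, gene = sites$gene,
    is_cgc_tier1 = sites$tier1, in_cosmic = sites$in_cosmic,
    in_clinvar = sites$in_clinvar, is_hotspot_gene = sites$hotspot,
    effect_class = sites$effect_class, validate = FALSE
  )
}

# artifact allele sites for one region: positions with pyrimidine or
# purine reference drawn to match the configured substitution spectrum
.artifact_sites <- function(config, ann, exclude_pos_keys) {
  n <- config$n_artifacts
  if (n == 0) {
    return(ann$sites[integer(0), c("chrom", "pos", "gene", "tier1", "hotspot", "ref")])
  }
  w <- if (config$mode == "ffpe") config$spectrum_ffpe else config$spectrum_frozen
  classes <- sample(names(w), n, replace = TRUE, prob = w)
  free <- !(paste(ann$sites$chrom, ann$sites$pos) %in% exclude_pos_keys)
  sites <- ann$sites[free, , drop = FALSE]
  is_cg <- sites$ref %in% c("C", "G")
  need_cg <- sum(startsWith(classes, "C"))
  cg_rows <- which(is_cg)
  at_rows <- which(!is_cg)
  pick_cg <- sample(cg_rows, need_cg)
  pick_at <- sample(at_rows, n - need_cg)
  out <- sites[c(pick_cg, pick_at), , drop = FALSE]
  cls <- c(classes[startsWith(classes, "C")], classes[startsWith(classes, "T")])
  pyr_alt <- substr(cls, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # the reference strand decides the written representation
  flip <- out$ref %in% c("G", "A")
  out$alt <- ifelse(flip, comp[pyr_alt], pyr_alt)
  out
}

#' Simulate one patient with ground truth
#'
#' Builds the patient's clone tree, places germline variants (shared
#' population pool, binomially sampled at region depth around VAF 0.5 or
#' 1.0), somatic mutations inherited along the tree, and per-region
#' artifact sets; emulates two callers' output per region with
#' class-specific concordance, metric distributions and a strand-biased
#' low-VAF artifact profile; and simulates the region copy-number
#' profiles.
#'
#' @param config a [sim_config()].
#' @param patient_index 1-based patient number (drives the substream).
#' @param ann genome annotation, default [make_genome_annotation()].
#' @param pool shared population pool (built internally by default).
#' @return list with `patient` (id, regions with `caller1`, `caller2`,
#'   `variants_all`, `counts`, `bins`, `segments`) and `truth`
#'   (`germline`, `somatic` with patterns, per-region `artifacts`,
#'   `tree_spec`).
#' @export
simulate_patient <- function(config, patient_index,
                             ann = make_genome_annotation(config),
                             pool = .make_population_pool(config, ann)) {
  regions <- config$region_ids
  k <- length(regions)
  p <- .with_seed(.derive_seed(config$seed, patient_index, 0L), {
    tree_spec <- config$tree_spec
    if (is.null(tree_spec)) tree_spec <- .default_tree_spec(config, regions)
    # germline sites, weighted by population frequency
    gidx <- sample.int(nrow(pool), min(config$n_germline, nrow(pool)),
                       prob = pool$af)
    germ <- pool[gidx, , drop = FALSE]
    germ$het <- runif(nrow(germ)) < config$het_fraction
    germ$pop_af <- germ$af
    germ$in_cosmic <- runif(nrow(germ)) < 0.03 | (germ$tier1 & runif(nrow(germ)) < 0.3)
    germ$in_clinvar <- runif(nrow(germ)) < 0.05
    germ$effect_class <- sample(c("silent", "non_silent", "unknown"),
                                nrow(germ), replace = TRUE, c(0.3, 0.3, 0.4))
    # somatic sites: outside the population pool, unique in the patient
    n_som <- sum(tree_spec$n)
    taken <- paste(pool$chrom, pool$pos)
    free <- which(!(paste(ann$sites$chrom, ann$sites$pos) %in% taken))
    sidx <- sample(free, n_som)
    som <- ann$sites[sidx, , drop = FALSE]
    som$pattern <- rep(tree_spec$pattern, tree_spec$n)
    som$vaf_true <- rbeta(n_som, config$somatic_vaf_shape[1],
                          config$somatic_vaf_shape[2])
    som$is_indel <- runif(n_som) < config$indel_fraction
    som$alt <- .other_base(som$ref)
    # indels: 1 bp insertion or deletion anchored on the site base
    if (any(som$is_indel)) {
      ii <- which(som$is_indel)
      del <- runif(length(ii)) < 0.5
      nxt <- c("A", "C", "G", "T")[((som$pos[ii] + 1L) %% 4L) + 1L]
      som$alt[ii][del] <- som$ref[ii][del]
      som$ref[ii][del] <- paste0(som$ref[ii][del], nxt[del])
      ins_base <- vapply(som$ref[ii][!del], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1), USE.NAMES = FALSE)
      som$alt[ii][!del] <- paste0(som$ref[ii][!del], ins_base)
    }
    som$pop_af <- rep(NA_real_, n_som)
    som$in_cosmic <- som$hotspot & runif(n_som) < 0.5
    som$in_clinvar <- rep(FALSE, n_som)
    som$effect_class <- sample(c("silent", "non_silent"), n_som,
                               replace = TRUE, c(0.3, 0.7))
    list(tree_spec = tree_spec, germ = germ, som = som)
  })
  germ <- p$germ
  som <- p$som
  germ$in_clinvar <- as.logical(germ$in_clinvar)
  som_key <- paste(som$chrom, som$pos, som$ref, som$alt, sep = ":")
  germ_key <- paste(germ$chrom, germ$pos, germ$ref, germ$alt, sep = ":")
  pos_taken <- c(paste(germ$chrom, germ$pos), paste(som$chrom, som$pos))

  region_list <- list()
  truth_artifacts <- list()
  for (ri in seq_len(k)) {
    rid <- regions[ri]
    region_list[[rid]] <- .with_seed(.derive_seed(config$seed, patient_index, ri), {
      in_region <- vapply(strsplit(som$pattern, "|", fixed = TRUE),
                          function(s) rid %in% s, logical(1))
      gsites <- data.frame(
        chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
        gene = germ$gene, tier1 = germ$tier1, hotspot = germ$hotspot,
        pop_af = germ$pop_af, in_cosmic = germ$in_cosmic,
        in_clinvar = germ$in_clinvar, effect_class = germ$effect_class,
        stringsAsFactors = FALSE)
      gvaf <- ifelse(germ$het, 0.5, 0.995)
      ssub <- som[in_region, , drop = FALSE]
      ssites <- data.frame(
        chrom = ssub$chrom, pos = ssub$pos, ref = ssub$ref, alt = ssub$alt,
        gene = ssub$gene, tier1 = ssub$tier1, hotspot = ssub$hotspot,
        pop_af = ssub$pop_af, in_cosmic = ssub$in_cosmic,
        in_clinvar = ssub$in_clinvar, effect_class = ssub$effect_class,
        stringsAsFactors = FALSE)
      asites <- .artifact_sites(config, ann, pos_taken)
      asites$pop_af <- rep(NA_real_, nrow(asites))
      asites$in_cosmic <- rep(FALSE, nrow(asites))
      asites$in_clinvar <- rep(FALSE, nrow(asites))
      asites$effect_class <- rep("unknown", nrow(asites))
      avaf <- rbeta(nrow(asites), config$artifact_vaf_shape[1],
                    config$artifact_vaf_shape[2])
      tab_g <- .records_table(gsites, gvaf, "germline", config)
      tab_s <- .records_table(ssites, ssub$vaf_true, "somatic", config)
      tab_a <- .records_table(asites, avaf, "artifact", config)
      all_tab <- rbind(tab_g, tab_s, tab_a)
      cls <- c(rep("germline", nrow(tab_g)), rep("somatic", nrow(tab_s)),
               rep("artifact", nrow(tab_a)))
      conc <- ifelse(cls == "artifact", config$concordance_artifact,
                     config$concordance_true)
      in1 <- runif(nrow(all_tab)) < conc
      in2 <- runif(nrow(all_tab)) < conc
      c1 <- all_tab[in1, , drop = FALSE]
      c1$callers <- config$caller_labels[1]
      c2 <- all_tab[in2, , drop = FALSE]
      c2$callers <- config$caller_labels[2]
      # joint-caller count extraction at every germline/somatic position
      keys <- c(germ_key, som_key)
      truevaf <- c(gvaf, ifelse(vapply(strsplit(som$pattern, "|", fixed = TRUE),
                                       function(s) rid %in% s, logical(1)),
                                som$vaf_true, config$error_background))
      cdepth <- pmax(rpois(length(keys), config$mean_depth), 1)
      counts <- data.frame(
        key = keys, region = rep(rid, length(keys)),
        alt = rbinom(length(keys), cdepth, pmin(truevaf, 1)),
        depth = cdepth, stringsAsFactors = FALSE)
      cn <- simulate_copy_number(config, .derive_seed(config$seed, patient_index,
                                                      1000L + ri))
      list(id = rid,
           caller1 = sort_variants(c1), caller2 = sort_variants(c2),
           variants_all = all_tab, truth_class = cls, counts = counts,
           bins = cn$bins, segments = cn$segments,
           artifact_keys = allele_key(tab_a))
    })
    truth_artifacts[[rid]] <- region_list[[rid]]$artifact_keys
  }
  list(
    patient = list(id = paste0("patient", patient_index), regions = region_list),
    truth = list(
      germline = germ_key,
      somatic = data.frame(key = som_key, pattern = som$pattern,
                           gene = som$gene, stringsAsFactors = FALSE),
      artifacts = truth_artifacts,
      tree_spec = p$tree_spec
    )
  )
}

#' Simulate one region's copy-number profile
#'
#' Segments realize the configured event list (log2 shift, BAF shifted
#' off 0.5 for LOH events) on a neutral backbone; bins are the segment
#' log2 plus Gaussian noise; each segment's log2 is re-estimated as its
#' bin mean, its probe count is its bin count, its CI comes from the bin
#' dispersion, and its `bivar` is a robust bin variance.
#'
#' @param config a [sim_config()].
#' @param seed substream seed.
#' @return list with `bins` and `segments` data.frames.
#' @export
simulate_copy_number <- function(config, seed) {
  ev <- config$cna_events
  chroms <- paste0("chr", seq_len(config$n_chrom))
  for (ci in seq_along(ev)) {
    for (cj in seq_along(ev)) {
      if (ci < cj && ev[[ci]]$chrom == ev[[cj]]$chrom &&
          ev[[ci]]$start < ev[[cj]]$end && ev[[cj]]$start < ev[[ci]]$end) {
        stop("overlapping configured copy-number events on ", ev[[ci]]$chrom)
      }
    }
  }
  .with_seed(seed, {
    seg_rows <- list()
    bin_rows <- list()
    for (ch in chroms) {
      evc <- Filter(function(e) e$chrom == ch, ev)
      cuts <- sort(unique(c(0, config$chrom_length,
                            unlist(lapply(evc, function(e) c(e$start, e$end))))))
      for (i in seq_len(length(cuts) - 1)) {
        s <- cuts[i]; e <- cuts[i + 1]
        hit <- Filter(function(x) x$start <= s && x$end >= e, evc)
        log2_true <- if (length(hit)) hit[[1]]$log2 else 0
        baf_true <- if (length(hit) && !is.null(hit[[1]]$baf) &&
                        !is.na(hit[[1]]$baf)) hit[[1]]$baf else 0.5
        starts <- seq(s, e - 1, by = config$bin_size)
        ends <- pmin(starts + config$bin_size, e)
        blog2 <- log2_true + rnorm(length(starts), 0, config$noise_sd)
        bin_rows[[length(bin_rows) + 1]] <- data.frame(
          chrom = ch, start = as.integer(starts), end = as.integer(ends),
          log2 = blog2, stringsAsFactors = FALSE)
        n <- length(starts)
        m <- mean(blog2)
        se <- if (n > 1) stats::sd(blog2) / sqrt(n) else config$noise_sd
        baf <- if (runif(1) < config$baf_missing_rate) NA_real_ else
          min(max(baf_true + rnorm(1, 0, config$baf_sd), 0), 1)
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = ch, start = as.integer(s), end = as.integer(e), log2 = m,
          n_probes = n, ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
          bivar = stats::mad(blog2)^2, baf = baf, stringsAsFactors = FALSE)
      }
    }
    list(bins = do.call(rbind, bin_rows), segments = do.call(rbind, seg_rows))
  })
}

#' Simulate a full cohort
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort`: list with `config`, `annotation`, `pool`,
#'   `pon`, `cohort` (the patients/regions structure the filter cascade
#'   consumes) and `truth` (per-patient truth bundles).
#' @export
simulate_cohort <- function(config = sim_config()) {
  ann <- make_genome_annotation(config)
  pool <- .make_population_pool(config, ann)
  pon <- .make_panel_of_normals(config, pool)
  patients <- list()
  truth <- list()
  for (pi in seq_len(config$n_patients)) {
    r <- simulate_patient(config, pi, ann, pool)
    patients[[r$patient$id]] <- r$patient
    truth[[r$patient$id]] <- r$truth
  }
  structure(list(config = config, annotation = ann, pool = pool, pon = pon,
                 cohort = list(patients = patients), truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$cohort$patients), "patients x",
      length(x$config$region_ids), "regions,", x$config$mode, "mode\n")
  invisible(x)
}

#' Write a caller's VCF files for one patient
#'
#' One VCF per region per caller, named
#' `<patient>_<region>_<caller>.vcf`.
#'
#' @param patient a patient record from [simulate_patient()].
#' @param dir output directory.
#' @param field_map see [default_field_map()].
#' @return character vector of written paths, invisibly.
#' @export
emit_caller_vcfs <- function(patient, dir, field_map = default_field_map()) {
  paths <- character(0)
  for (r in patient$regions) {
    for (cal in c("caller1", "caller2")) {
      lbl <- r[[cal]]$callers[1]
      if (is.na(lbl) || !length(lbl)) lbl <- cal
      f <- file.path(dir, paste0(patient$id, "_", r$id, "_", lbl, ".vcf"))
      write_variants_vcf(r[[cal]], f, field_map)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Write a simulated cohort to disk
#'
#' Per-region caller VCFs, `.cnr`/`.cns` files and count tables, plus
#' cohort-level target/gene/arm BEDs, the panel of normals and truth
#' TSVs. Identical seed and configuration produce byte-identical files.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(sim$annotation$targets, file.path(dir, "targets.bed"))
  write_bed(sim$annotation$genes, file.path(dir, "genes.bed"))
  write_bed(sim$annotation$arms, file.path(dir, "arms.bed"))
  write_variants_vcf(sim$pon, file.path(dir, "pon.vcf"))
  truth_rows <- list()
  for (pid in names(sim$cohort$patients)) {
    p <- sim$cohort$patients[[pid]]
    emit_caller_vcfs(p, dir)
    for (r in p$regions) {
      base <- file.path(dir, paste0(pid, "_", r$id))
      write_bins(r$bins, paste0(base, ".cnr"))
      write_segments(r$segments, paste0(base, ".cns"))
      .write_tsv(r$counts, paste0(base, "_counts.tsv"))
    }
    tr <- sim$truth[[pid]]
    truth_rows[[pid]] <- rbind(
      data.frame(patient = pid, key = tr$germline, class = "germline",
                 pattern = "", stringsAsFactors = FALSE),
      data.frame(patient = pid, key = tr$somatic$key, class = "somatic",
                 pattern = tr$somatic$pattern, stringsAsFactors = FALSE),
      do.call(rbind, lapply(names(tr$artifacts), function(rid) {
        if (length(tr$artifacts[[rid]]) == 0) return(NULL)
        data.frame(patient = pid, key = tr$artifacts[[rid]],
                   class = paste0("artifact_", rid), pattern = "",
                   stringsAsFactors = FALSE)
      }))
    )
  }
  .write_tsv(do.call(rbind, truth_rows), file.path(dir, "truth.tsv"))
  invisible(dir)
}
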