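test_that("configuration rejects out-of-range rates and counts", {
  expect_error(sim_config(gene_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(yan_bias = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(background_hom_snvs = -5), ">= 0")
  expect_error(simulate_genome(sim_config(genome_length = 5e3), 1),
               "10 kb")
})

test_that("genome simulation is deterministic and hits the gene fraction", {
  cfg <- sim_config(genome_length = 1e5, n_chrom = 2L)
  a <- simulate_genome(cfg, 7)
  b <- simulate_genome(cfg, 7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(region_fractions(a$annotation),
               region_fractions(b$annotation))
  # byte-identical files on re-simulation
  fa1 <- withr::local_tempfile(); fa2 <- withr::local_tempfile()
  write_fasta(a$genome, fa1); write_fasta(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  fr <- region_fractions(simulate_genome(sim_config(genome_length = 2e6),
                                         7)$annotation)
  expect_gt(fr[["genic"]], 0.25)
  expect_lt(fr[["genic"]], 0.35)
})

test_that("zero gene fraction yields an all-intergenic annotation", {
  cfg <- sim_config(genome_length = 5e4, n_chrom = 1L, gene_fraction = 0)
  ga <- simulate_genome(cfg, 3)
  expect_identical(length(ga$annotation$genes), 0L)
  expect_equal(region_fractions(ga$annotation)[["intergenic"]], 1)
})

test_that("truth bookkeeping matches the cohort structure", {
  coh <- cached_cohort()
  tr <- coh$truth
  design <- coh$design
  # shared homozygous background is identical in every plant
  bg_keys_by_plant <- lapply(split(tr[tr$origin == "background", ],
                                   tr$plant_id[tr$origin == "background"]),
                             function(d) sort(variant_key(d$chrom, d$pos,
                                                          d$ref, d$alt)))
  expect_true(all(vapply(bg_keys_by_plant, identical,
                         logical(1), bg_keys_by_plant[[1]])))
  # wild-type plants carry only background
  k1 <- tr[tr$plant_id == "K_1", ]
  expect_true(all(k1$origin == "background"))
  # control plants carry no induced origins
  tc <- tr[tr$plant_id %in% design$plant_id[design$group %in%
                                              c("tissue_culture",
                                                "agro_infection",
                                                "cas_only")], ]
  expect_false(any(tc$origin %in% c("induced_AG", "induced_other",
                                    "cluster", "on_target")))
  # induced variants are heterozygous
  expect_true(all(tr$zygosity[tr$origin %in%
                                c("induced_AG", "cluster")] == "het"))
})

test_that("induced A>G class fraction respects its boundary settings", {
  cfg <- test_config(induced_ag_fraction = 1,
                     common_stage_ag_fraction = 1,
                     unique_stage_ag_fraction = 1)
  coh <- simulate_cohort(cfg, 5)
  ind <- coh$truth[coh$truth$origin %in% c("induced_AG", "induced_other"), ]
  expect_true(all(ind$origin == "induced_AG"))
  cls <- collapse_class(ind$ref, ind$alt)
  expect_true(all(cls == "A>G"))
})

test_that("full cohort simulation is reproducible end to end", {
  cfg <- test_config()
  a <- simulate_cohort(cfg, 9)
  b <- simulate_cohort(cfg, 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$calls, b$calls)
  expect_identical(a$rna$pileups, b$rna$pileups)
  expect_identical(a$tdna$tracks, b$tdna$tracks)
})

test_that("caller emulation reaches the configured sensitivity", {
  coh <- cached_cohort()
  sens <- coh$config$caller_sensitivity[[1]]
  hits <- 0L; total <- 0L
  for (pid in c("TC_1", "rBE46b_s1", "rBE50_s2")) {
    tr <- coh$truth[coh$truth$plant_id == pid, ]
    tkeys <- variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)
    for (cid in coh$config$caller_ids) {
      calls <- coh$calls[[pid]][[cid]]
      ckeys <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
      hits <- hits + sum(tkeys %in% ckeys)
      total <- total + length(tkeys)
    }
  }
  phat <- hits / total
  expect_lt(abs(phat - sens), 3 * sqrt(sens * (1 - sens) / total))
})

test_that("caller false positives rarely survive a three-way intersection", {
  coh <- cached_cohort()
  # on a small genome with independent callers, the expected number of
  # coincident false positives is essentially zero
  pid <- "TC_3"
  cons <- intersect_callers(coh$calls[[pid]])
  tr <- coh$truth[coh$truth$plant_id == pid, ]
  tkeys <- variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)
  fp_in_consensus <- sum(!(cons$key %in% tkeys))
  expect_lte(fp_in_consensus, 1L)
})

test_that("RNA editing ratios and contexts match the generator settings", {
  coh <- cached_cohort()
  loci <- coh$rna$loci
  design <- coh$design
  high <- design$plant_id[design$rna_sequenced &
                            design$expression_tier == "high" &
                            design$generation == "T0"]
  pp <- coh$rna$pileups
  lk <- paste(loci$chrom, loci$pos)
  hp <- pp[pp$plant_id == high[1] & paste(pp$chrom, pp$pos) %in% lk, ]
  num <- ifelse(hp$ref == "A", hp$nG, hp$nC)
  den <- ifelse(hp$ref == "A", hp$nA + hp$nG, hp$nC + hp$nT)
  phat <- sum(num) / sum(den)
  r <- coh$config$rna_ratio_mean
  expect_lt(abs(phat - r), 3 * sqrt(r * (1 - r) / sum(den)))
  # Cas-only plants show only sequencing noise at the same loci
  cas <- design$plant_id[design$group == "cas_only"][1]
  cp <- pp[pp$plant_id == cas & paste(pp$chrom, pp$pos) %in% lk, ]
  cnum <- ifelse(cp$ref == "A", cp$nG, cp$nC)
  cden <- ifelse(cp$ref == "A", cp$nA + cp$nG, cp$nC + cp$nT)
  expect_lt(sum(cnum) / sum(cden), 0.01)
})

test_that("yan_bias = 1 forces a pyrimidine at every -1 context", {
  cfg <- test_config(yan_bias = 1)
  coh <- simulate_cohort(cfg, 13)
  loci <- coh$rna$loci
  chars <- lapply(names(coh$genome), function(c2)
    strsplit(as.character(coh$genome[[c2]]), "", fixed = TRUE)[[1]])
  names(chars) <- names(coh$genome)
  minus1 <- vapply(seq_len(nrow(loci)), function(i) {
    if (loci$strand[i] == "-")
      unname(c(A = "T", C = "G", G = "C", T = "A")[
        chars[[loci$chrom[i]]][loci$pos[i] + 1L]])
    else chars[[loci$chrom[i]]][loci$pos[i] - 1L]
  }, character(1))
  expect_true(all(minus1 %in% c("T", "C")))
})

test_that("T-DNA tracks encode copy number and partial insertions", {
  coh <- cached_cohort()
  tracks <- coh$tdna$tracks
  feats <- coh$tdna$features
  design <- coh$design
  carriers <- design[!is.na(design$tdna_complete) &
                       design$generation == "T0", ]
  for (i in seq_len(nrow(carriers))) {
    pl <- carriers[i, ]
    tr <- tracks[tracks$plant_id == pl$plant_id, ]
    expected <- pl$tdna_copies * coh$config$coverage_mean / 2
    if (pl$tdna_complete) {
      expect_lt(abs(mean(tr$depth) - expected), 0.1 * expected)
    } else {
      f <- feats[feats$feature == pl$tdna_missing_feature, ]
      gap <- tr$depth[tr$pos >= f$start & tr$pos <= f$end]
      rest <- tr$depth[tr$pos < f$start | tr$pos > f$end]
      expect_lt(mean(gap), 0.1 * mean(rest))
    }
  }
})
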