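test_that("caller intersection applies the 3-SNV / 2-indel support rule", {
  c1 <- rbind(make_calls(c(100, 200), caller = "gatk"),
              make_calls(300, caller = "gatk", ref = "AT", alt = "A",
                         vtype = "indel"))
  c2 <- rbind(make_calls(c(100, 200), caller = "strelka2"),
              make_calls(300, caller = "strelka2", ref = "AT", alt = "A",
                         vtype = "indel"))
  c3 <- make_calls(100, caller = "lofreq")
  cons <- intersect_callers(list(c1, c2, c3))
  # SNV at 100 in all three kept; SNV at 200 in two dropped; indel in
  # two kept
  expect_setequal(cons$pos, c(100L, 300L))
  expect_identical(cons$vtype[cons$pos == 300L], "indel")
  expect_identical(cons$n_callers[cons$pos == 100L], 3L)
})

test_that("disjoint callsets give an empty consensus", {
  cons <- intersect_callers(list(make_calls(1, caller = "a"),
                                 make_calls(2, caller = "b"),
                                 make_calls(3, caller = "c")))
  expect_identical(nrow(cons), 0L)
})

test_that("intersection is order-independent and idempotent", {
  set.seed(5)
  sets <- lapply(c("a", "b", "c"), function(cid)
    make_calls(sample(1:50, 30), caller = cid))
  cons1 <- intersect_callers(sets)
  cons2 <- intersect_callers(rev(sets))
  expect_identical(cons1[order(cons1$pos), ], cons2[order(cons2$pos), ])
})

test_that("zygosity disagreements resolve by majority with ties to het", {
  calls <- rbind(make_calls(10, caller = "a", zygosity = "hom"),
                 make_calls(10, caller = "b", zygosity = "hom"),
                 make_calls(10, caller = "c", zygosity = "het"))
  expect_identical(intersect_callers(calls)$zygosity, "hom")
  calls <- rbind(make_calls(10, caller = "a", zygosity = "hom",
                            vtype = "indel", ref = "AT", alt = "A"),
                 make_calls(10, caller = "b", zygosity = "het",
                            vtype = "indel", ref = "AT", alt = "A"))
  expect_identical(intersect_callers(calls)$zygosity, "het")
})

test_that("duplicate keys within one caller are removed with a warning", {
  calls <- rbind(make_calls(c(10, 10), caller = "a"),
                 make_calls(10, caller = "b"),
                 make_calls(10, caller = "c"))
  expect_warning(cons <- intersect_callers(calls), "duplicate")
  expect_identical(nrow(cons), 1L)
})

test_that("background subtraction pools backgrounds and matches by key only", {
  cons <- rbind(make_calls(c(10, 20, 30)),
                make_calls(40, zygosity = "hom"))
  bg1 <- make_calls(10, plant = "K1", zygosity = "hom")  # zygosity ignored
  bg2 <- make_calls(40, plant = "K2")
  out <- subtract_background(cons, list(bg1, bg2))
  expect_setequal(out$pos, c(20L, 30L))
  # self-subtraction empties; empty background warns and is identity
  expect_identical(nrow(subtract_background(cons, list(cons))), 0L)
  expect_warning(same <- subtract_background(cons, list()), "empty")
  expect_identical(same, cons)
})

test_that("homozygote removal keeps only het variants", {
  cons <- rbind(make_calls(1:2), make_calls(3, zygosity = "hom"))
  expect_identical(remove_homozygous(cons)$pos, c(1L, 2L))
  all_hom <- make_calls(1:3, zygosity = "hom")
  expect_identical(nrow(remove_homozygous(all_hom)), 0L)
})

test_that("recurrence counts plants per variant key", {
  sets <- list(A = make_calls(c(1, 2), plant = "A"),
               B = make_calls(c(1, 3), plant = "B"),
               C = make_calls(1, plant = "C"))
  rec <- recurrence_table(sets)
  expect_identical(rec$n_plants[rec$pos == 1L], 3L)
  expect_identical(rec$n_plants[rec$pos == 2L], 1L)
  uniq <- list(A = make_calls(1, plant = "A"),
               B = make_calls(2, plant = "B"))
  expect_true(all(recurrence_table(uniq)$n_plants == 1L))
})

test_that("homozygosity binomial test reproduces the allele model", {
  # p = 0.5 gives hom 0.25 / het 0.5 / wt 0.25 under the model; with
  # counts drawn exactly at those proportions p_hat recovers 0.5
  res <- homozygosity_binomial_test(n_hom = 25, n_het = 50, n_wt = 25)
  expect_equal(res$p_hat, 0.5)
  expect_equal(res$p_hom_carrier, 0.5 / 1.5)
  # hom-only shared locus: exact upper tail from direct summation
  res <- homozygosity_binomial_test(3, 0, 54)
  p_hat <- 6 / 114
  p0 <- p_hat / (2 - p_hat)
  expect_equal(res$pvalue, p0^3)
  expect_lt(res$pvalue, 0.01)
  expect_error(homozygosity_binomial_test(0, 0, 10), "carriers")
})

test_that("binomial test keeps its size under the null model", {
  set.seed(11)
  n_loci <- 2000L
  n_plants <- 57L
  rejected <- 0L
  tested <- 0L
  for (i in seq_len(n_loci)) {
    p <- runif(1, 0.05, 0.5)
    g <- sample(c("hom", "het", "wt"), n_plants, replace = TRUE,
                prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
    n_hom <- sum(g == "hom")
    if (n_hom < 1L) next
    res <- homozygosity_binomial_test(n_hom, sum(g == "het"),
                                      sum(g == "wt"), alpha = 0.05)
    tested <- tested + 1L
    rejected <- rejected + res$flagged
  }
  rate <- rejected / tested
  mc_sd <- sqrt(0.05 * 0.95 / tested)
  expect_lte(rate, 0.05 + 3 * mc_sd)
})

test_that("pairwise overlap counts shared SNVs and comparisons", {
  sets <- list(A = make_calls(c(1, 2, 3), plant = "A"),
               B = make_calls(c(3, 4), plant = "B"),
               C = make_calls(9, plant = "C"))
  m <- pairwise_overlap(sets)
  expect_identical(m["A", "B"], 1L)
  expect_identical(m["A", "C"], 0L)
  expect_identical(attr(m, "n_comparisons"), 3)
  # 57 plants -> 1596 unordered comparisons
  many <- stats::setNames(replicate(57, make_calls(1), simplify = FALSE),
                          paste0("p", 1:57))
  expect_identical(attr(pairwise_overlap(many), "n_comparisons"), 1596)
})

test_that("noise-free simulation recovers the het truth set exactly", {
  cfg <- noise_free_config()
  coh <- cached_cohort("noisefree", cfg, seed = 21L)
  bg_ids <- coh$design$plant_id[coh$design$group == "kitaake"]
  bg_sets <- lapply(coh$calls[bg_ids], intersect_callers)
  for (pid in c("TC_1", "rBE46b_s1", "rBE49b_s2")) {
    out <- consensus_chain(coh$calls[[pid]], bg_sets)
    truth <- coh$truth[coh$truth$plant_id == pid &
                         coh$truth$zygosity == "het", ]
    expect_setequal(out$key,
                    variant_key(truth$chrom, truth$pos, truth$ref,
                                truth$alt))
  }
})

test_that("recovered truth fraction matches three-caller sensitivity", {
  coh <- cached_cohort()   # sensitivity 0.95 per caller
  bg_ids <- coh$design$plant_id[coh$design$group == "kitaake"]
  bg_sets <- lapply(coh$calls[bg_ids], intersect_callers)
  hits <- 0L
  total <- 0L
  for (pid in c("TC_1", "TC_2", "rBE46b_s1", "rBE49b_s1", "rBE50_s1")) {
    out <- consensus_chain(coh$calls[[pid]], bg_sets)
    truth <- coh$truth[coh$truth$plant_id == pid &
                         coh$truth$zygosity == "het", ]
    tkeys <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
    hits <- hits + sum(tkeys %in% out$key)
    total <- total + length(tkeys)
  }
  p <- 0.95^3
  frac <- hits / total
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / total))
})

test_that("sibling plants share the planted common-stage variants", {
  coh <- cached_cohort("noisefree", noise_free_config(), seed = 21L)
  tr <- coh$truth
  common_a <- tr[tr$plant_id == "rBE46b_s2" &
                   tr$stage %in% "pre_integration", ]
  common_b <- tr[tr$plant_id == "rBE46b_s3" &
                   tr$stage %in% "pre_integration", ]
  expect_gt(nrow(common_a), 0L)
  expect_setequal(variant_key(common_a$chrom, common_a$pos, common_a$ref,
                              common_a$alt),
                  variant_key(common_b$chrom, common_b$pos, common_b$ref,
                              common_b$alt))
})
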