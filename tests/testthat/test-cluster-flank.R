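# Brute-force single-linkage oracle: connected components of the
# "within d bp" graph, found by repeated expansion.
brute_clusters <- function(pos, d) {
  pos <- sort(unique(pos))
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= d && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(pos, comp), sort))
}

test_that("DNA clusters merge by single linkage at the merge distance", {
  snvs <- make_calls(c(100, 110, 500))
  cc <- detect_dna_clusters(snvs, merge_distance = 30)
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$n_members, 2L)
  expect_identical(cc$start, 100L)
  expect_identical(cc$end, 110L)
  # 100 bp apart: no cluster
  expect_identical(nrow(detect_dna_clusters(make_calls(c(100, 200)))), 0L)
  # chained memberships merge transitively
  chain <- detect_dna_clusters(make_calls(c(100, 125, 150)))
  expect_identical(chain$n_members, 3L)
  # non-A>G SNVs are ignored
  other <- make_calls(c(100, 110), ref = "C", alt = "A")
  expect_identical(nrow(detect_dna_clusters(other)), 0L)
})

test_that("cluster detection equals the brute-force linkage oracle", {
  for (seed in c(3, 4, 5)) {
    set.seed(seed)
    pos <- sample(1:3000, 150)
    snvs <- make_calls(pos)
    cc <- detect_dna_clusters(snvs, merge_distance = 30)
    expected <- Filter(function(g) length(g) >= 2,
                       brute_clusters(pos, 30))
    got <- lapply(strsplit(cc$members, ","), as.integer)
    expect_identical(got[order(vapply(got, min, 1L))],
                     expected[order(vapply(expected, min, 1L))])
    # idempotent / order invariant
    cc2 <- detect_dna_clusters(snvs[sample(nrow(snvs)), ],
                               merge_distance = 30)
    expect_identical(cc, cc2)
  }
})

test_that("planted DNA clusters are recovered with exact member counts", {
  coh <- cached_cohort("noisefree", noise_free_config(), seed = 21L)
  tr <- coh$truth
  for (pid in unique(tr$plant_id[tr$origin == "cluster"])) {
    d <- tr[tr$plant_id == pid & tr$zygosity == "het" &
              tr$vtype == "SNV", ]
    snvs <- make_calls(d$pos, ref = d$ref, alt = d$alt, plant = pid,
                       chrom = d$chrom)
    cc <- detect_dna_clusters(snvs, merge_distance = 30)
    planted <- tr[tr$plant_id == pid & tr$origin == "cluster", ]
    for (cl in unique(planted$cluster_id)) {
      members <- planted$pos[planted$cluster_id == cl]
      hit <- cc[cc$chrom == planted$chrom[planted$cluster_id == cl][1] &
                  cc$start <= min(members) & cc$end >= max(members), ]
      expect_identical(nrow(hit), 1L)
      expect_identical(hit$n_members, length(members))
    }
  }
})

test_that("flank profile counts eligible and edited offsets", {
  # one focal A locus at 100; neighbors at +2 (edited A), +5 (clean A),
  # -3 (low coverage A), +7 (G: ineligible)
  loci <- data.frame(chrom = "c1", pos = 100L, ref = "A")
  pileups <- data.frame(
    plant_id = "p1", source = "RNA", chrom = "c1",
    pos = c(97L, 100L, 102L, 105L, 107L),
    ref = c("A", "A", "A", "A", "G"),
    nA = c(4L, 30L, 28L, 38L, 0L),
    nC = 0L,
    nG = c(0L, 10L, 12L, 1L, 40L),
    nT = 0L)
  prof <- flank_profile(loci, pileups, window = 10)
  expect_identical(prof$n_eligible[prof$offset == 2L], 1L)
  expect_identical(prof$n_edited[prof$offset == 2L], 1L)
  expect_identical(prof$n_edited[prof$offset == 5L], 0L)
  expect_identical(prof$n_eligible[prof$offset == -3L], 0L)  # cov <= 10
  expect_identical(prof$n_eligible[prof$offset == 7L], 0L)   # not A/T
  # offset 0 (the focal SNV itself) is excluded
  expect_identical(prof$n_eligible[prof$offset == 0L], 0L)
})

test_that("reference-T focal loci mirror their flanking offsets", {
  loci_a <- data.frame(chrom = "c1", pos = 100L, ref = "A")
  loci_t <- data.frame(chrom = "c1", pos = 100L, ref = "T")
  pileups <- data.frame(plant_id = "p1", source = "RNA", chrom = "c1",
                        pos = 103L, ref = "A",
                        nA = 20L, nC = 0L, nG = 10L, nT = 0L)
  pa <- flank_profile(loci_a, pileups, window = 5)
  pt <- flank_profile(loci_t, pileups, window = 5)
  expect_identical(pa$n_edited[pa$offset == 3L], 1L)
  expect_identical(pt$n_edited[pt$offset == -3L], 1L)
})

test_that("clustered plants show flanking editing and controls do not", {
  coh <- cached_cohort()
  design <- coh$design
  loci <- coh$rna$loci[, c("chrom", "pos", "ref")]
  high <- design$plant_id[design$rna_sequenced &
                            design$expression_tier == "high" &
                            design$generation == "T0"][1]
  cas <- design$plant_id[design$group == "cas_only"][1]
  pp <- coh$rna$pileups
  prof_hi <- flank_profile(loci, pp[pp$plant_id == high, ])
  prof_cas <- flank_profile(loci, pp[pp$plant_id == cas, ])
  off <- prof_hi$offset != 0
  expect_gt(mean(prof_hi$fraction[off], na.rm = TRUE), 0.01)
  # the Cas-only profile sits at the sequencing-noise floor (this
  # reduced cohort has ~40 eligible positions per offset, so a single
  # noise call reaches 1/40)
  expect_lt(mean(prof_cas$fraction[off], na.rm = TRUE), 0.005)
  better <- prof_hi$fraction[off] > prof_cas$fraction[off]
  expect_gte(mean(better, na.rm = TRUE), 0.9)
})

test_that("plants classify into cluster groups with load comparisons", {
  spectra <- rbind(spectrum_summary(make_calls(1:30), "g1a"),
                   spectrum_summary(make_calls(1:28), "g1b"),
                   spectrum_summary(make_calls(1:10, ref = "C",
                                               alt = "A"), "g2a"),
                   spectrum_summary(make_calls(1:9, ref = "C",
                                               alt = "A"), "g2b"))
  calls <- list(g1a = detect_dna_clusters(make_calls(c(1, 5))),
                g1b = detect_dna_clusters(make_calls(c(1, 9))),
                g2a = detect_dna_clusters(make_calls(c(1, 500))),
                g2b = detect_dna_clusters(make_calls(integer(0))))
  res <- classify_cluster_groups(calls, spectra)
  expect_identical(res$groups$group,
                   c("group1", "group1", "group2", "group2"))
  expect_identical(res$comparisons$metric, c("n_snvs", "n_AG", "pct_AG"))
  # no clusters anywhere: group 1 empty, no comparisons
  none <- classify_cluster_groups(
    list(g1a = calls$g2b, g1b = calls$g2b, g2a = calls$g2b,
         g2b = calls$g2b), spectra)
  expect_true(all(none$groups$group == "group2"))
  expect_null(none$comparisons)
})
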