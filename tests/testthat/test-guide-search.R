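test_that("exact protospacer with valid PAM is found as on-target", {
  spacer <- "ACGTACGTACGTACGTACGT"
  left <- "TTTTTTTTTT"
  g <- Biostrings::DNAStringSet(c(c1 = paste0(left, spacer, "TGG",
                                              "TTTTTTTTTT")))
  guide <- list(name = "g", spacer = spacer, pam_pattern = "NGG")
  sites <- find_sites_full(g, guide, max_mm = 0)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 11L)
  expect_identical(sites$end, 30L)
  expect_identical(sites$strand, "+")
  expect_true(sites$is_on_target)
  # PAM failure removes the site
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0(left, spacer, "GAT",
                                               "TTTTTTTTTT")))
  expect_identical(nrow(find_sites_full(g2, guide, max_mm = 0)), 0L)
})

test_that("reverse-strand sites are reported in forward coordinates", {
  spacer <- "ACGTACGTACGTACGTACGT"
  fwd <- paste0("TTTTTTTTTT", spacer, "TGG", "TTTTTTTTTT")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  g <- Biostrings::DNAStringSet(c(c1 = rc))
  guide <- list(name = "g", spacer = spacer, pam_pattern = "NGG")
  sites <- find_sites_full(g, guide, max_mm = 0)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$strand, "-")
  # protospacer occupies the mirrored span
  expect_identical(sites$start, nchar(fwd) - 30L + 1L)
  expect_identical(sites$end, nchar(fwd) - 11L + 1L)
})

test_that("seed search constrains only the PAM-proximal 12 nt", {
  spacer <- "ACGTACGTACGTACGTACGT"
  # mismatches only in the PAM-distal 8 nt (ACGTA vs GTACG: 5 of 5)
  proto <- paste0("GTACG", substr(spacer, 6, 20))
  g <- Biostrings::DNAStringSet(c(c1 = paste0("AAAAAAAAAA", proto, "TGG",
                                              "AAAAAAAAAA")))
  guide <- list(name = "g", spacer = spacer, pam_pattern = "NGG")
  sites <- find_sites_seed(g, guide)
  sites <- sites[sites$strand == "+" & sites$start == 11L, ]
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$n_mismatches, 5L)
  expect_identical(sites$seed_mismatches, 0L)
  # three mismatches inside the seed exceed the budget: seed spans
  # spacer positions 9-20; corrupt positions 15-17 (GTA -> TAG)
  proto2 <- paste0(substr(spacer, 1, 14), "TAG", substr(spacer, 18, 20))
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0("AAAAAAAAAA", proto2,
                                               "TGG", "AAAAAAAAAA")))
  s2 <- find_sites_seed(g2, guide)
  expect_identical(nrow(s2[s2$strand == "+" & s2$start == 11L, ]), 0L)
})

test_that("invalid guides are rejected", {
  g <- random_genome(500, 1)
  expect_error(find_sites_full(g, list(name = "g", spacer = "ACGTN",
                                       pam_pattern = "NGG"), 0), "N")
  expect_error(find_sites_full(g, random_guide(1), max_mm = 25),
               "max_mm")
})

test_that("vectorized scanner equals the naive oracle on random genomes", {
  for (seed in c(11, 12, 13)) {
    pam <- if (seed %% 2) "NGG" else "NG"
    g <- random_genome(12000, seed)
    guide <- random_guide(seed + 100, pam)
    full_fast <- find_sites_full(g, guide, max_mm = 6)
    full_naive <- find_sites_naive(g, guide, max_mm = 6, mode = "full")
    expect_identical(full_fast, full_naive)
    seed_fast <- find_sites_seed(g, guide)
    seed_naive <- find_sites_naive(g, guide, mode = "seed")
    expect_identical(seed_fast, seed_naive)
  }
})

test_that("site sets are invariant under genome reverse-complementation", {
  g <- random_genome(8000, 31)
  guide <- random_guide(131, "NG")
  fwd <- find_sites_seed(g, guide)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  rev <- find_sites_seed(grc, guide)
  L <- Biostrings::width(g)[1]
  mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         n_mismatches = rev$n_mismatches)
  ord <- function(d) d[order(d$start, d$strand), ]
  expect_identical(ord(mirrored)$start, ord(fwd[, c("start", "end",
                                                    "strand",
                                                    "n_mismatches")])$start)
  expect_identical(ord(mirrored)$n_mismatches,
                   ord(fwd[, c("start", "end", "strand",
                               "n_mismatches")])$n_mismatches)
})

test_that("zero-mismatch full sites are a subset of seed-mode sites", {
  g <- random_genome(10000, 17)
  guide <- random_guide(217, "NG")
  full0 <- find_sites_full(g, guide, max_mm = 0)
  seedm <- find_sites_seed(g, guide)
  key <- function(d) paste(d$chrom, d$start, d$strand)
  expect_true(all(key(full0) %in% key(seedm)))
})

test_that("on-target masking partitions variants by site span", {
  sites <- data.frame(chrom = "chr1", start = 100L, end = 119L,
                      strand = "+", pam_start = 120L, pam_end = 122L,
                      n_mismatches = 0L, seed_mismatches = 0L,
                      guide = "g1", is_on_target = TRUE,
                      stringsAsFactors = FALSE)
  v <- make_calls(c(105, 121, 600))
  m <- mask_on_target(v, sites)
  expect_setequal(m$on_target$pos, c(105L, 121L))  # PAM included
  expect_identical(m$off_target$pos, 600L)
  # no guides -> everything off-target
  m2 <- mask_on_target(v, sites[0, ])
  expect_identical(nrow(m2$on_target), 0L)
  expect_identical(nrow(m2$off_target), 3L)
})

test_that("planted on-target edits are recovered by masking", {
  coh <- cached_cohort("noisefree", noise_free_config(), seed = 21L)
  design <- coh$design
  guided <- design$plant_id[design$group == "abe" & nzchar(design$guides)]
  pid <- guided[1]
  gname <- design$guides[design$plant_id == pid]
  gd <- coh$guides[coh$guides$name == gname, ]
  sites <- find_sites_full(coh$genome, gd[, c("name", "spacer",
                                              "pam_pattern")],
                           max_mm = 0)
  truth <- coh$truth[coh$truth$plant_id == pid, ]
  m <- mask_on_target(truth[truth$vtype == "SNV", ], sites)
  expect_setequal(m$on_target$pos,
                  truth$pos[truth$origin == "on_target"])
})

test_that("variant counts at sites stratify by mismatch level", {
  sites <- data.frame(chrom = "chr1", start = c(10L, 200L),
                      end = c(29L, 219L), strand = "+",
                      pam_start = c(30L, 220L), pam_end = c(32L, 222L),
                      n_mismatches = c(3L, 5L), seed_mismatches = 0L,
                      guide = "g1", is_on_target = FALSE,
                      stringsAsFactors = FALSE)
  v <- make_calls(c(15, 500))
  counts <- count_variants_at_sites(v, sites)
  expect_identical(counts$n_variants[counts$n_mismatches == 3L], 1L)
  expect_identical(counts$n_variants[counts$n_mismatches == 5L], 0L)
  none <- count_variants_at_sites(make_calls(integer(0)), sites)
  expect_true(all(none$n_variants == 0L))
})
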