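# Shared fixtures: a reduced simulation configuration for fast tests
# and a cached small cohort reused across files.

test_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 2e5, n_chrom = 2L,
         background_hom_snvs = 30L, background_indels = 10L,
         residual_hom_snvs = 6L,
         tissue_culture_het_snvs = 60,
         abe_induced_snvs = 120,
         sibling_common_snvs = 50,
         rna_edit_loci = 80L,
         rna_background_snvs = 15L,
         caller_fp_per_mb = 2),
    list(...))
  do.call(sim_config, args)
}

noise_free_config <- function(...) {
  test_config(caller_sensitivity = 1, caller_fp_per_mb = 0, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name = "default", cfg = test_config(),
                          seed = 42L) {
  if (is.null(.cohort_cache[[name]]))
    .cohort_cache[[name]] <- simulate_cohort(cfg, seed)
  .cohort_cache[[name]]
}

# Minimal call data.frame constructor for consensus tests.
make_calls <- function(pos, ref = "A", alt = "G", caller = "c1",
                       plant = "p1", vtype = "SNV", zygosity = "het",
                       chrom = "chr1") {
  n <- length(pos)
  data.frame(plant_id = rep_len(plant, n), caller_id = rep_len(caller, n),
             chrom = rep_len(chrom, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             vtype = rep_len(vtype, n),
             zygosity = rep_len(zygosity, n),
             ad_ref = rep_len(20L, n), ad_alt = rep_len(20L, n),
             stringsAsFactors = FALSE)
}

random_genome <- function(len, seed, n_chrom = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

random_guide <- function(seed, pam = "NGG") {
  set.seed(seed)
  list(name = paste0("g", seed),
       spacer = paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                      collapse = ""),
       pam_pattern = pam)
}
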