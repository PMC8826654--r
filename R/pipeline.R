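# End-to-end orchestration over an on-disk cohort (as written by
# write_cohort): consensus -> background -> homozygosity screen ->
# on-target masking -> spectra/enrichment -> T-DNA -> RNA -> clusters.
# Every stage is a pure function of (inputs, parameters), so rerunning
# with identical inputs reproduces the report byte for byte.

#' Run the full off-target analysis pipeline
#'
#' Reads a cohort directory (reference FASTA, GFF3 annotation, design,
#' guides, per-plant per-caller DNA/RNA VCFs, RNA pileups and read
#' counts, T-DNA coverage) and writes every stage's table under
#' `outdir`.
#'
#' @param indir cohort directory (layout of [write_cohort()]).
#' @param outdir report directory (created if missing).
#' @param min_snv_callers,min_indel_callers caller-support thresholds.
#' @param alpha homozygosity-test flag threshold.
#' @param max_mm full-spacer mismatch budget for off-target sites.
#' @param seed_len,max_seed_mm seed-search parameters.
#' @param cov_min strict coverage threshold for editing ratios.
#' @param ratio_thr strict editing-ratio threshold for flanking counts.
#' @param merge_distance DNA cluster merge distance (bp).
#' @param snv_min RNA-mutation plant threshold ("more than" rule).
#' @param window flanking half-window (bp).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(indir, outdir,
                         min_snv_callers = 3L, min_indel_callers = 2L,
                         alpha = 0.01, max_mm = 6L, seed_len = 12L,
                         max_seed_mm = 2L, cov_min = 10L,
                         ratio_thr = 0.05, merge_distance = 30L,
                         snv_min = 5L, window = 30L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  need <- file.path(indir, c("genome.fasta", "annotation.gff3",
                             "design.tsv", "guides.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("cohort input missing: ", paste(missing, collapse = ", "))

  genome <- read_fasta(file.path(indir, "genome.fasta"))
  annotation <- read_annotation(file.path(indir, "annotation.gff3"),
                                genome)
  design <- read_design(file.path(indir, "design.tsv"))
  guides <- read_guides(file.path(indir, "guides.tsv"))

  # ---- stage 1: DNA consensus per plant -----------------------------------
  dna_calls <- read_vcf_dir(file.path(indir, "dna_vcf"))
  consensus <- lapply(dna_calls, intersect_callers,
                      min_snv_callers = min_snv_callers,
                      min_indel_callers = min_indel_callers)

  # ---- stage 2: background subtraction ------------------------------------
  bg_plants <- design$plant_id[design$group == "kitaake"]
  background <- consensus[intersect(names(consensus), bg_plants)]
  exp_plants <- setdiff(names(consensus), bg_plants)
  filtered <- lapply(consensus[exp_plants], subtract_background,
                     background_sets = background)

  # ---- stage 3: homozygosity screen and hom removal -----------------------
  homtest <- homozygosity_screen(filtered, cohort_size = length(filtered),
                                 alpha = alpha)
  het_sets <- lapply(filtered, remove_homozygous)

  # ---- stage 4: guide sites and on-target masking -------------------------
  site_list <- lapply(seq_len(nrow(guides)), function(i)
    find_sites_full(genome, guides[i, ], max_mm = max_mm,
                    seed_len = seed_len))
  names(site_list) <- guides$name
  seed_sites <- lapply(seq_len(nrow(guides)), function(i)
    find_sites_seed(genome, guides[i, ], seed_len = seed_len,
                    max_seed_mm = max_seed_mm))
  names(seed_sites) <- guides$name
  all_sites <- do.call(rbind, site_list)
  off_sets <- list()
  on_sets <- list()
  for (pid in names(het_sets)) {
    gnames <- design$guides[design$plant_id == pid]
    gnames <- if (length(gnames) && nzchar(gnames))
      strsplit(gnames, ",", fixed = TRUE)[[1]] else character(0)
    psites <- all_sites[all_sites$guide %in% gnames, , drop = FALSE]
    masked <- mask_on_target(het_sets[[pid]], psites)
    off_sets[[pid]] <- masked$off_target
    on_sets[[pid]] <- masked$on_target
  }
  site_counts <- count_variants_at_sites(
    do.call(rbind, off_sets),
    all_sites[all_sites$n_mismatches > 0L, , drop = FALSE])

  # ---- stage 5: spectra, group comparisons, enrichment --------------------
  spectra <- spectrum_table(off_sets)
  abe_ids <- design$plant_id[design$group == "abe"]
  ctrl_ids <- design$plant_id[design$group %in%
                                c("tissue_culture", "agro_infection")]
  comparisons <- compare_mutation_load(
    spectra, intersect(abe_ids, spectra$plant_id),
    intersect(ctrl_ids, spectra$plant_id), "abe", "control")
  pooled_abe <- do.call(rbind, off_sets[intersect(abe_ids,
                                                  names(off_sets))])
  enrichment <- region_enrichment(pooled_abe, annotation)
  chrom_dist <- chromosome_distribution(pooled_abe, genome)

  # ---- stage 6: recurrence and pairwise overlap ---------------------------
  recurrence <- recurrence_table(filtered)
  overlap <- pairwise_overlap(het_sets)

  # ---- stage 7: T-DNA -----------------------------------------------------
  tdna <- run_tdna_stage(indir, design, het_sets, spectra)

  # ---- stage 8: RNA -------------------------------------------------------
  rna <- run_rna_stage(indir, design, consensus, genome,
                       min_snv_callers, cov_min, snv_min)

  # ---- stage 9: clustered editing -----------------------------------------
  clusters <- lapply(off_sets[intersect(abe_ids, names(off_sets))],
                     detect_dna_clusters,
                     merge_distance = merge_distance,
                     annotation = annotation)
  abe_spectra <- spectra[spectra$plant_id %in% abe_ids, , drop = FALSE]
  cluster_groups <- classify_cluster_groups(
    clusters, abe_spectra,
    consensus_sets = off_sets[intersect(abe_ids, names(off_sets))],
    annotation = annotation)
  flanks <- run_flank_stage(indir, rna, design, window, ratio_thr,
                            cov_min)

  res <- list(consensus = consensus, filtered = filtered,
              het_sets = het_sets, off_sets = off_sets,
              on_sets = on_sets, homtest = homtest,
              sites = all_sites, seed_sites = seed_sites,
              site_counts = site_counts, spectra = spectra,
              comparisons = comparisons, enrichment = enrichment,
              chrom_dist = chrom_dist, recurrence = recurrence,
              overlap = overlap, tdna = tdna, rna = rna,
              clusters = clusters, cluster_groups = cluster_groups,
              flanks = flanks)
  write_report(res, outdir)
  invisible(res)
}

read_vcf_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  out <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.vcf$", "", basename(f)), ".",
                      fixed = TRUE)[[1]]
    pid <- parts[1]
    cid <- paste(parts[-1], collapse = ".")
    calls <- read_vcf(f, plant_id = pid, caller_id = cid)
    out[[pid]] <- c(out[[pid]], list(calls))
  }
  lapply(out, function(lst) do.call(rbind, lst))
}

# group comparison over the spectrum table (shared with the T-DNA and
# cluster stages)
compare_mutation_load <- function(spectra, group_a, group_b, label_a,
                                  label_b) {
  completeness_effect(spectra, group_a, group_b, label_a, label_b)
}

run_tdna_stage <- function(indir, design, het_sets, spectra) {
  cov_path <- file.path(indir, "tdna_coverage.tsv")
  if (!file.exists(cov_path)) return(NULL)
  tracks <- read_tsv(cov_path)
  gmeans <- read_tsv(file.path(indir, "genome_coverage.tsv"))
  features <- read_tsv(file.path(indir, "tdna_features.tsv"))
  integ <- list()
  copies <- list()
  for (pid in unique(tracks$plant_id)) {
    tr <- tracks[tracks$plant_id == pid, , drop = FALSE]
    res <- tdna_integrity(tr[, c("pos", "depth")], features)
    integ[[length(integ) + 1L]] <-
      cbind(plant_id = pid, res$features,
            plant_status = res$status)
    gm <- gmeans$genome_mean_cov[gmeans$plant_id == pid]
    cn <- tdna_copy_number(res$overall_mean, gm)
    copies[[length(copies) + 1L]] <-
      data.frame(plant_id = pid, tdna_mean_cov = res$overall_mean,
                 genome_mean_cov = gm, copies = cn$copies,
                 copies_rounded = cn$copies_rounded,
                 stringsAsFactors = FALSE)
  }
  integrity <- do.call(rbind, integ)
  copies <- do.call(rbind, copies)
  # complete vs partial, among ABE plants with spectra
  status <- stats::setNames(
    integrity$plant_status[!duplicated(integrity$plant_id)],
    integrity$plant_id[!duplicated(integrity$plant_id)])
  abe_in <- intersect(names(status), spectra$plant_id)
  comp_ids <- abe_in[status[abe_in] == "complete"]
  part_ids <- abe_in[status[abe_in] == "partial"]
  completeness <- completeness_effect(spectra, comp_ids, part_ids)
  # single vs multiple copies
  cp <- stats::setNames(copies$copies_rounded, copies$plant_id)
  one_ids <- abe_in[cp[abe_in] <= 1L]
  multi_ids <- abe_in[cp[abe_in] > 1L]
  copy_effect <- completeness_effect(spectra, multi_ids, one_ids,
                                     "multi_copy", "single_copy")
  # sibling partitions
  partitions <- list()
  calli <- unique(design$callus_id[nzchar(design$callus_id)])
  for (cal in calli) {
    sibs <- design$plant_id[design$callus_id == cal]
    sibs <- intersect(sibs, names(het_sets))
    if (length(sibs) >= 2L) {
      snv_a <- het_sets[[sibs[1]]]
      snv_b <- het_sets[[sibs[2]]]
      partitions[[cal]] <- partition_siblings(
        snv_a[snv_a$vtype == "SNV", ], snv_b[snv_b$vtype == "SNV", ],
        cal, cal)
    }
  }
  stage_test <- if (length(partitions)) stage_ag_test(partitions) else NULL
  sib_spectra <- if (length(partitions)) {
    do.call(rbind, lapply(names(partitions), function(cal)
      cbind(callus_id = cal, partitions[[cal]]$spectra)))
  } else NULL
  list(integrity = integrity, copies = copies,
       completeness = completeness, copy_effect = copy_effect,
       partitions = partitions, sibling_spectra = sib_spectra,
       stage_test = stage_test)
}

run_rna_stage <- function(indir, design, dna_consensus, genome,
                          min_snv_callers, cov_min, snv_min) {
  vcf_dir <- file.path(indir, "rna_vcf")
  if (!dir.exists(vcf_dir)) return(NULL)
  rna_calls <- read_vcf_dir(vcf_dir)
  rna_consensus <- lapply(rna_calls, intersect_callers,
                          min_snv_callers = min_snv_callers,
                          min_indel_callers = min_snv_callers)
  agro_ids <- design$plant_id[design$group == "agro_infection"]
  background_rna <- rna_consensus[intersect(names(rna_consensus),
                                            agro_ids)]
  rna_only <- list()
  for (pid in setdiff(names(rna_consensus), agro_ids)) {
    dna <- dna_consensus[[pid]]
    if (is.null(dna)) dna <- empty_consensus()
    rna_only[[pid]] <- rna_minus_dna(rna_consensus[[pid]], dna,
                                     background_rna)
  }
  # combined A>G-class loci over all transcriptomes
  pooled <- do.call(rbind, rna_only)
  loci <- NULL
  if (!is.null(pooled) && nrow(pooled)) {
    ag <- pooled[pooled$vtype == "SNV" &
                   collapse_class_safe(pooled$ref, pooled$alt) %in% "A>G", ,
                 drop = FALSE]
    loci <- ag[!duplicated(paste(ag$chrom, ag$pos)),
               c("chrom", "pos", "ref"), drop = FALSE]
    rownames(loci) <- NULL
  }
  pileups <- read_pileup(file.path(indir, "rna_pileups.tsv"))
  cas_ids <- design$plant_id[design$group == "cas_only"]
  ratio_matrix <- NULL
  tests <- NULL
  cas_pool <- numeric(0)
  if (!is.null(loci) && nrow(loci)) {
    ratio_matrix <- editing_ratio_matrix(loci, pileups,
                                         cov_min = cov_min)
    cas_cols <- intersect(cas_ids, colnames(ratio_matrix))
    cas_pool <- as.vector(ratio_matrix[, cas_cols])
    test_rows <- lapply(colnames(ratio_matrix), function(pid) {
      r <- per_plant_test(ratio_matrix[, pid], cas_pool)
      data.frame(plant_id = pid, pvalue = r$pvalue,
                 neglog10p = r$neglog10p, n_loci = r$n_plant,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, test_rows)
  }
  rc <- read_tsv(file.path(indir, "read_counts.tsv"))
  rc$rpm <- abe_rpm(rc$cas_reads, rc$tada_reads, rc$total_reads)
  # RNA-mutation grouping over T0 ABE transcriptomes
  n_ag <- vapply(rna_only, function(s) {
    if (!nrow(s)) return(0L)
    sum(s$vtype == "SNV" &
          collapse_class_safe(s$ref, s$alt) %in% "A>G")
  }, integer(1))
  t0_abe <- design$plant_id[design$group == "abe" & design$rna_sequenced]
  grouping <- NULL
  if (length(t0_abe) && !is.null(tests)) {
    pv <- stats::setNames(tests$pvalue, tests$plant_id)
    rpm <- stats::setNames(rc$rpm, rc$plant_id)
    grouping <- expression_grouping(intersect(t0_abe, names(rna_only)),
                                    n_ag, pv, rpm, snv_min = snv_min)
  }
  motif <- if (!is.null(loci) && nrow(loci))
    motif_matrix(loci, genome) else NULL
  segregation <- if (!is.null(ratio_matrix))
    segregation_check(design, ratio_matrix, cas_pool) else NULL
  list(rna_consensus = rna_consensus, rna_only = rna_only, loci = loci,
       ratio_matrix = ratio_matrix, tests = tests, cas_pool = cas_pool,
       read_counts = rc, n_ag = n_ag, grouping = grouping,
       motif = motif, segregation = segregation, pileups = pileups)
}

run_flank_stage <- function(indir, rna, design, window, ratio_thr,
                            cov_min) {
  if (is.null(rna) || is.null(rna$loci) || !nrow(rna$loci)) return(NULL)
  # focal loci: combined A>G SNVs from plants with RNA editing activity
  with_ids <- if (!is.null(rna$grouping))
    rna$grouping$groups$plant_id[rna$grouping$groups$has_rna_mutations]
  else character(0)
  focal <- rna$loci
  profiles <- list()
  for (pid in colnames(rna$ratio_matrix)) {
    pp <- rna$pileups[rna$pileups$plant_id == pid, , drop = FALSE]
    prof <- flank_profile(focal, pp, window = window,
                          ratio_thr = ratio_thr, cov_thr = cov_min)
    prof$plant_id <- pid
    profiles[[pid]] <- prof
  }
  out <- do.call(rbind, profiles)
  rownames(out) <- NULL
  attr(out, "active_plants") <- with_ids
  out
}

write_report <- function(res, outdir) {
  w <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0)
      write_tsv(df, file.path(outdir, name))
  }
  cons_all <- do.call(rbind, c(res$off_sets,
                               list(make.row.names = FALSE)))
  w(cons_all, "offtarget_consensus.tsv")
  w(res$homtest, "homozygosity_test.tsv")
  w(res$spectra, "spectrum.tsv")
  w(res$comparisons, "group_comparisons.tsv")
  w(res$enrichment, "region_enrichment.tsv")
  w(res$chrom_dist, "chromosome_distribution.tsv")
  w(res$recurrence, "recurrence.tsv")
  ov <- as.data.frame(res$overlap)
  ov <- cbind(plant_id = rownames(ov), ov)
  w(ov, "overlap_matrix.tsv")
  w(res$sites, "guide_sites.tsv")
  write_sites_bed(res$sites, file.path(outdir, "guide_sites.bed"))
  w(res$site_counts, "site_variant_counts.tsv")
  if (!is.null(res$tdna)) {
    w(res$tdna$integrity, "tdna_integrity.tsv")
    w(res$tdna$copies, "tdna_copies.tsv")
    w(res$tdna$completeness, "tdna_completeness_effect.tsv")
    w(res$tdna$copy_effect, "tdna_copy_effect.tsv")
    w(res$tdna$sibling_spectra, "sibling_spectra.tsv")
    if (!is.null(res$tdna$stage_test))
      w(res$tdna$stage_test$pairs, "sibling_stage_pairs.tsv")
  }
  if (!is.null(res$rna)) {
    rna_only_all <- do.call(rbind, c(res$rna$rna_only,
                                     list(make.row.names = FALSE)))
    w(rna_only_all, "rna_only_snvs.tsv")
    if (!is.null(res$rna$ratio_matrix)) {
      rm_df <- as.data.frame(res$rna$ratio_matrix)
      rm_df <- cbind(locus = rownames(rm_df), rm_df)
      w(rm_df, "rna_ratio_matrix.tsv")
    }
    w(res$rna$tests, "rna_plant_tests.tsv")
    w(res$rna$read_counts, "rna_rpm.tsv")
    if (!is.null(res$rna$grouping))
      w(res$rna$grouping$groups, "rna_grouping.tsv")
    if (!is.null(res$rna$motif)) {
      mm <- as.data.frame(res$rna$motif$freq)
      mm <- cbind(base = rownames(mm), mm)
      w(mm, "rna_motif_freq.tsv")
      w(data.frame(offset = names(res$rna$motif$bits),
                   bits = unname(res$rna$motif$bits)),
        "rna_motif_bits.tsv")
    }
    w(res$rna$segregation, "rna_segregation.tsv")
  }
  cl_all <- do.call(rbind, c(res$clusters, list(make.row.names = FALSE)))
  w(cl_all, "dna_clusters.tsv")
  if (!is.null(res$cluster_groups)) {
    w(res$cluster_groups$groups, "cluster_groups.tsv")
    w(res$cluster_groups$comparisons, "cluster_group_comparisons.tsv")
    w(res$cluster_groups$genic_fraction, "cluster_genic_fraction.tsv")
  }
  w(res$flanks, "flank_profiles.tsv")
  invisible(outdir)
}
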