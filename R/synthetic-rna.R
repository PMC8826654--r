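# RNA-side and T-DNA-side simulation, plus the full-cohort bundle and
# its on-disk layout.

# Candidate transcript adenines in exons: genome A on + strand genes,
# genome T on - strand genes.  The transcript -1 base decides the
# pyrimidine (YAN) context.
transcript_a_candidates <- function(genome, annotation) {
  chars <- lapply(names(genome), function(c2)
    strsplit(as.character(genome[[c2]]), "", fixed = TRUE)[[1]])
  names(chars) <- names(genome)
  lens <- genome_seqlengths(genome)
  ex <- annotation$exons
  rows <- list()
  for (i in seq_along(ex)) {
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[i]
    strand <- as.character(BiocGenerics::strand(ex))[i]
    span <- BiocGenerics::start(ex)[i]:BiocGenerics::end(ex)[i]
    cc <- chars[[chrom]][span]
    want <- if (strand == "-") "T" else "A"
    pos <- span[cc == want]
    pos <- pos[pos > 1L & pos < lens[[chrom]]]
    if (!length(pos)) next
    prev <- if (strand == "-") comp_base(chars[[chrom]][pos + 1L]) else
      chars[[chrom]][pos - 1L]
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = chrom, pos = pos, strand = strand,
                 ref = want, yan = prev %in% c("T", "C"),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chrom = character(0),
                                      pos = integer(0),
                                      strand = character(0),
                                      ref = character(0),
                                      yan = logical(0))
  out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
}

#' Simulate RNA editing: loci, pileups, emulated RNA variant calls
#'
#' Edited loci are placed on exonic transcript adenines, with
#' probability `yan_bias` of a T/C at the transcript -1 position; a
#' fraction of loci receive 2-6 satellite edits within 30 bp
#' (clustered editing).  High-expression transgenic plants edit every
#' locus at `rna_ratio_mean`; low-expression, Cas-only, infection
#' controls and transgene-segregated T1 plants do not edit.  Pileups
#' over +/-30 bp windows are drawn at the configured coverage with the
#' symmetric base-error rate, and per-caller RNA variant calls include
#' a shared RNA background (visible in the infection controls) and the
#' expressed exonic share of the DNA background.
#'
#' @param config `SimulationConfig`.
#' @param genome,annotation from [simulate_genome()].
#' @param design data.frame from [cohort_design()].
#' @param truth DNA truth table (to expose expressed background homs
#'   and avoid planting edits on background positions).
#' @param seed integer seed.
#' @return list with `loci` (edited loci incl. satellites: `chrom`,
#'   `pos`, `strand`, `ref`, `yan`, `clustered`, `is_satellite`),
#'   `background_rna`, `pileups`, `calls` (nested plant -> caller),
#'   `read_counts`.
#' @export
simulate_rna <- function(config, genome, annotation, design, truth,
                         seed) {
  if (config$yan_bias < 0 || config$yan_bias > 1)
    stop("yan_bias outside [0, 1]")
  cand <- transcript_a_candidates(genome, annotation)
  bg_truth <- truth[truth$origin == "background" & truth$vtype == "SNV", ,
                    drop = FALSE]
  bg_truth <- bg_truth[!duplicated(paste(bg_truth$chrom, bg_truth$pos)), ,
                       drop = FALSE]
  cand <- cand[!(paste(cand$chrom, cand$pos) %in%
                   paste(bg_truth$chrom, bg_truth$pos)), , drop = FALSE]
  rna <- with_seed(derive_seed(seed, "rna"), {
    n <- config$rna_edit_loci
    if (n > nrow(cand))
      stop("rna_edit_loci exceeds available exonic adenines")
    n_yan <- rbinom(1L, n, config$yan_bias)
    yan_pool <- which(cand$yan)
    other_pool <- which(!cand$yan)
    n_yan <- min(n_yan, length(yan_pool))
    pick <- c(sample(yan_pool, n_yan),
              sample(other_pool, min(n - n_yan, length(other_pool))))
    loci <- cand[pick, , drop = FALSE]
    loci$clustered <- FALSE
    loci$is_satellite <- FALSE
    k <- round(config$rna_cluster_fraction * nrow(loci))
    sats <- list()
    if (k > 0L) {
      taken <- paste(loci$chrom, loci$pos)
      for (i in seq_len(k)) {
        loci$clustered[i] <- TRUE
        s <- sample(2:6, 1L)
        near <- cand[cand$chrom == loci$chrom[i] &
                       abs(cand$pos - loci$pos[i]) <= 30L &
                       !(paste(cand$chrom, cand$pos) %in% taken), ,
                     drop = FALSE]
        if (!nrow(near)) next
        # satellites keep the deaminase context preference
        n_sat_yan <- rbinom(1L, s, config$yan_bias)
        yan_part <- near[near$yan, , drop = FALSE]
        oth_part <- near[!near$yan, , drop = FALSE]
        k_yan <- min(n_sat_yan, nrow(yan_part))
        take <- rbind(yan_part[seq_len(k_yan), , drop = FALSE],
                      oth_part[seq_len(min(s - k_yan, nrow(oth_part))), ,
                               drop = FALSE])
        if (!nrow(take)) next
        take$clustered <- TRUE
        take$is_satellite <- TRUE
        taken <- c(taken, paste(take$chrom, take$pos))
        sats[[length(sats) + 1L]] <- take
      }
    }
    loci <- rbind(loci, do.call(rbind, sats))
    rownames(loci) <- NULL
    # shared RNA background SNVs on exonic positions (any base)
    ex <- GenomicRanges::reduce(annotation$regions$exonic)
    exl <- sum(BiocGenerics::width(ex))
    bg_n <- config$rna_background_snvs
    bgi <- sample.int(exl, bg_n)
    allpos <- unlist(lapply(seq_along(ex), function(j)
      BiocGenerics::start(ex)[j]:BiocGenerics::end(ex)[j]))
    allchrom <- rep(as.character(GenomeInfoDb::seqnames(ex)),
                    BiocGenerics::width(ex))
    bg_pos <- allpos[bgi]
    bg_chrom <- allchrom[bgi]
    dup <- paste(bg_chrom, bg_pos) %in% paste(loci$chrom, loci$pos)
    bg_pos <- bg_pos[!dup]; bg_chrom <- bg_chrom[!dup]
    bg_ref <- vapply(seq_along(bg_pos), function(j)
      as.character(Biostrings::subseq(genome[[bg_chrom[j]]], bg_pos[j],
                                      bg_pos[j])), character(1))
    bg_alt <- vapply(bg_ref, function(r) sample(setdiff(BASES, r), 1L),
                     character(1), USE.NAMES = FALSE)
    list(loci = loci,
         background_rna = data.frame(chrom = bg_chrom, pos = bg_pos,
                                     ref = bg_ref, alt = bg_alt,
                                     stringsAsFactors = FALSE))
  })
  loci <- rna$loci
  # expressed DNA background (exonic homozygous SNVs)
  bg_gr <- GenomicRanges::GRanges(bg_truth$chrom,
                                  IRanges::IRanges(bg_truth$pos, width = 1L))
  expressed_bg <- bg_truth[IRanges::overlapsAny(
    bg_gr, annotation$regions$exonic, ignore.strand = TRUE), ,
    drop = FALSE]

  # pileup window positions (union of +/-30 bp around all loci)
  win <- window_positions(loci, genome, 30L)
  edited_key <- paste(loci$chrom, loci$pos)
  win$true_ratio0 <- ifelse(paste(win$chrom, win$pos) %in% edited_key,
                            config$rna_ratio_mean, 0)
  win$alt <- ifelse(win$ref == "A", "G",
                    ifelse(win$ref == "T", "C", NA_character_))

  rna_plants <- design[design$rna_sequenced, , drop = FALSE]
  pileups <- list()
  calls <- list()
  rc <- list()
  for (i in seq_len(nrow(rna_plants))) {
    pl <- rna_plants[i, ]
    active <- pl$group %in% c("abe", "abe_t1") && isTRUE(pl$transgene) &&
      identical(pl$expression_tier, "high")
    pp <- with_seed(derive_seed(seed, paste0(pl$plant_id, ":rna")), {
      r <- if (active) win$true_ratio0 else 0
      draw_pileup(win, r, config, pl$plant_id)
    })
    pileups[[pl$plant_id]] <- pp
    calls[[pl$plant_id]] <- list()
    for (cid in config$caller_ids) {
      calls[[pl$plant_id]][[cid]] <- with_seed(
        derive_seed(seed, paste(pl$plant_id, cid, "rna", sep = "|")), {
          sens <- config$caller_sensitivity[[cid]]
          det_rows <- list()
          if (active && nrow(loci)) {
            det <- runif(nrow(loci)) < sens
            ed <- loci[det, , drop = FALSE]
            if (nrow(ed))
              det_rows$edit <- data.frame(
                chrom = ed$chrom, pos = ed$pos, ref = ed$ref,
                alt = ifelse(ed$ref == "A", "G", "C"),
                stringsAsFactors = FALSE)
          }
          bgall <- rbind(rna$background_rna,
                         expressed_bg[, c("chrom", "pos", "ref", "alt")])
          if (nrow(bgall)) {
            det <- runif(nrow(bgall)) < sens
            det_rows$bg <- bgall[det, , drop = FALSE]
          }
          cr <- do.call(rbind, det_rows)
          if (is.null(cr) || !nrow(cr)) return(empty_calls())
          n <- nrow(cr)
          cov <- pmax(rpois(n, config$coverage_mean), 4L)
          ad_alt <- rbinom(n, cov,
                           ifelse(seq_len(n) <= length(det_rows$edit$pos %||% integer(0)),
                                  max(config$rna_ratio_mean, 0.1), 0.5))
          out <- data.frame(plant_id = pl$plant_id, caller_id = cid,
                            chrom = cr$chrom, pos = cr$pos, ref = cr$ref,
                            alt = cr$alt, vtype = "SNV",
                            zygosity = "het", ad_ref = cov - ad_alt,
                            ad_alt = ad_alt, stringsAsFactors = FALSE)
          out <- out[order(match(out$chrom, names(genome)), out$pos,
                           out$alt), , drop = FALSE]
          rownames(out) <- NULL
          out
        })
    }
    rpm <- if (is.na(pl$expression_rpm)) 0 else pl$expression_rpm
    reads <- round(rpm * config$total_reads / 1e6)
    rc[[length(rc) + 1L]] <-
      data.frame(plant_id = pl$plant_id, cas_reads = reads,
                 tada_reads = reads, total_reads = config$total_reads,
                 stringsAsFactors = FALSE)
  }
  list(loci = loci, background_rna = rna$background_rna,
       pileups = do.call(rbind, c(pileups, list(make.row.names = FALSE))),
       calls = calls, read_counts = do.call(rbind, rc))
}

# Unique window positions around loci with their reference base.
window_positions <- function(loci, genome, window) {
  lens <- genome_seqlengths(genome)
  rows <- list()
  for (chrom in unique(loci$chrom)) {
    centers <- loci$pos[loci$chrom == chrom]
    pos <- unique(as.vector(outer(centers, seq(-window, window), "+")))
    pos <- sort(pos[pos >= 1L & pos <= lens[[chrom]]])
    s <- as.character(genome[[chrom]])
    ref <- strsplit(s, "", fixed = TRUE)[[1]][pos]
    rows[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Multinomial pileup draw via sequential binomials: each read reports
# the alt base with probability r, the ref base otherwise, then suffers
# a symmetric error with rate e (uniform over the other three bases).
draw_pileup <- function(win, r, config, plant_id) {
  n <- nrow(win)
  e <- config$base_error
  cov <- rpois(n, config$coverage_mean)
  p <- matrix(e / 3, nrow = n, ncol = 4,
              dimnames = list(NULL, BASES))
  ri <- match(win$ref, BASES)
  ai <- match(win$alt, BASES)
  r <- rep(r, length.out = n)
  r[is.na(ai)] <- 0
  for (b in 1:4) {
    add_ref <- (1 - r) * (1 - e) * (ri == b)
    add_alt <- r * (1 - e) * (!is.na(ai) & ai == b)
    p[, b] <- p[, b] + add_ref + ifelse(is.na(add_alt), 0, add_alt)
  }
  p <- p / rowSums(p)
  nA <- rbinom(n, cov, p[, 1])
  left <- cov - nA
  pC <- p[, 2] / pmax(1 - p[, 1], 1e-12)
  nC <- rbinom(n, left, pmin(pC, 1))
  left <- left - nC
  pG <- p[, 3] / pmax(1 - p[, 1] - p[, 2], 1e-12)
  nG <- rbinom(n, left, pmin(pG, 1))
  nT <- left - nG
  data.frame(plant_id = plant_id, source = "RNA", chrom = win$chrom,
             pos = win$pos, ref = win$ref, nA = nA, nC = nC, nG = nG,
             nT = nT, stringsAsFactors = FALSE)
}

#' Simulate T-DNA coverage tracks
#'
#' Complete insertions give uniform Poisson coverage at copies x half
#' the genome coverage across LB..RB; partial insertions have their
#' missing feature near zero.  Plants without a construct get no track.
#'
#' @param design data.frame from [cohort_design()].
#' @param config `SimulationConfig`.
#' @param seed integer seed.
#' @param features T-DNA feature map (default [tdna_feature_map()]).
#' @return list with `tracks` (plant_id, pos, depth), `genome_means`
#'   (plant_id, genome_mean_cov) and `features`.
#' @export
simulate_tdna_coverage <- function(design, config, seed,
                                   features = tdna_feature_map()) {
  known <- c("LB", "promoter", "Cas", "TadA", "NLS", "terminator", "RB")
  bad <- setdiff(c(features$feature,
                   design$tdna_missing_feature[nzchar(design$tdna_missing_feature)]),
                 known)
  if (length(bad))
    stop("unknown T-DNA feature(s): ", paste(bad, collapse = ", "))
  L <- max(features$end)
  carriers <- design[!is.na(design$tdna_complete) &
                       design$generation == "T0", , drop = FALSE]
  tracks <- list()
  gm <- list()
  for (i in seq_len(nrow(carriers))) {
    pl <- carriers[i, ]
    res <- with_seed(derive_seed(seed, paste0(pl$plant_id, ":tdna")), {
      lambda <- pl$tdna_copies * config$coverage_mean / 2
      depth <- rpois(L, lambda)
      if (!pl$tdna_complete && nzchar(pl$tdna_missing_feature)) {
        f <- features[features$feature == pl$tdna_missing_feature, ]
        span <- f$start:f$end
        depth[span] <- rpois(length(span), 0.2)
      }
      list(depth = depth,
           gmean = round(rnorm(1, config$coverage_mean, 0.3), 2))
    })
    tracks[[length(tracks) + 1L]] <-
      data.frame(plant_id = pl$plant_id, pos = seq_len(L),
                 depth = res$depth, stringsAsFactors = FALSE)
    gm[[length(gm) + 1L]] <-
      data.frame(plant_id = pl$plant_id, genome_mean_cov = res$gmean,
                 stringsAsFactors = FALSE)
  }
  list(tracks = do.call(rbind, tracks),
       genome_means = do.call(rbind, gm), features = features)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates genome, design, guides, DNA truth and caller emulation,
#' RNA editing and T-DNA coverage into one bundle.
#'
#' @param config `SimulationConfig` (default [sim_config()]).
#' @param seed integer seed; the single source of randomness.
#' @return list of class `abe_cohort` with elements `genome`,
#'   `annotation`, `design`, `guides`, `truth`, `calls`, `rna`, `tdna`,
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  ga <- simulate_genome(config, seed)
  design <- cohort_design(config, seed)
  guides <- simulate_guides(ga$genome, config, seed)
  truth <- simulate_truth(config, ga$genome, ga$annotation, design,
                          guides, seed)
  calls <- emulate_callers(truth, ga$genome, config, seed)
  rna <- simulate_rna(config, ga$genome, ga$annotation, design, truth,
                      seed)
  tdna <- simulate_tdna_coverage(design, config, seed)
  structure(list(genome = ga$genome, annotation = ga$annotation,
                 design = design, guides = guides, truth = truth,
                 calls = calls, rna = rna, tdna = tdna, config = config,
                 seed = seed),
            class = "abe_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits FASTA, GFF3, design/guide/truth TSVs, per-plant per-caller
#' DNA and RNA VCFs, RNA pileup and read-count TSVs and T-DNA coverage
#' TSVs under `outdir`.
#'
#' @param cohort `abe_cohort` from [simulate_cohort()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "dna_vcf"), showWarnings = FALSE)
  dir.create(file.path(outdir, "rna_vcf"), showWarnings = FALSE)
  write_fasta(cohort$genome, file.path(outdir, "genome.fasta"))
  write_annotation(cohort$annotation, file.path(outdir, "annotation.gff3"))
  write_design(cohort$design, file.path(outdir, "design.tsv"))
  write_tsv(cohort$guides, file.path(outdir, "guides.tsv"))
  write_tsv(cohort$truth, file.path(outdir, "truth.tsv"))
  for (pid in names(cohort$calls)) {
    for (cid in names(cohort$calls[[pid]])) {
      write_vcf(cohort$calls[[pid]][[cid]],
                file.path(outdir, "dna_vcf",
                          sprintf("%s.%s.vcf", pid, cid)))
    }
  }
  for (pid in names(cohort$rna$calls)) {
    for (cid in names(cohort$rna$calls[[pid]])) {
      calls <- cohort$rna$calls[[pid]][[cid]]
      if (!nrow(calls)) {
        calls$plant_id <- character(0)
      }
      write_vcf(calls, file.path(outdir, "rna_vcf",
                                 sprintf("%s.%s.vcf", pid, cid)),
                sample = pid)
    }
  }
  write_pileup(cohort$rna$pileups, file.path(outdir, "rna_pileups.tsv"))
  write_tsv(cohort$rna$loci, file.path(outdir, "rna_loci.tsv"))
  write_tsv(cohort$rna$background_rna,
            file.path(outdir, "rna_background.tsv"))
  write_tsv(cohort$rna$read_counts, file.path(outdir, "read_counts.tsv"))
  write_tsv(cohort$tdna$tracks, file.path(outdir, "tdna_coverage.tsv"))
  write_tsv(cohort$tdna$genome_means,
            file.path(outdir, "genome_coverage.tsv"))
  write_tsv(cohort$tdna$features, file.path(outdir, "tdna_features.tsv"))
  invisible(outdir)
}
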