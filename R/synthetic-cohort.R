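# Synthetic study generator: genome + annotation, cohort design, truth
# mutations, emulated three-caller variant calls, RNA editing pileups
# and T-DNA coverage tracks, with the statistical structure the
# downstream analysis assumes.  Every plant draws from its own RNG
# stream derived from (seed, plant_id), so adding a plant never
# perturbs the others.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort with defaults chosen
#' to mirror the study design at desk scale: a 2-Mb two-chromosome
#' genome, ~30% genic fraction, a shared homozygous background, per
#' plant Poisson tissue-culture heterozygous SNVs of uniform spectrum,
#' ABE-induced heterozygous SNVs with a 60% A>G class share and 1.5x
#' genic enrichment, callus sibling pairs with common- vs unique-stage
#' A>G fractions of 0.4 vs 0.8, clustered DNA editing in a subset of
#' plants, expression-dependent RNA editing with a pyrimidine bias at
#' the -1 context position, and three independent emulated callers at
#' 0.95 sensitivity and 41x coverage.
#'
#' @param genome_length total genome size in bp (default 2e6).
#' @param n_chrom number of chromosomes (default 2).
#' @param gene_fraction target fraction of the genome covered by genes.
#' @param n_background,n_tissue_culture,n_agro,n_cas_only plants per
#'   control arm.
#' @param editors ABE editor names; the first two use an NGG PAM, the
#'   rest NG.
#' @param n_per_editor ABE plants per editor (default 3: one guided
#'   plant plus, for NGG editors, an unguided sibling pair).
#' @param background_hom_snvs,background_indels shared homozygous
#'   background variant counts (carried by every plant including the
#'   wild-type panel).
#' @param residual_hom_snvs homozygous variants segregating in the seed
#'   stock: absent from the wild-type background panel, carried
#'   homozygously by each experimental plant with probability
#'   `residual_hom_carrier` -- the substrate of the binomial
#'   homozygosity screen.
#' @param tissue_culture_het_snvs mean per-plant heterozygous SNVs from
#'   tissue culture / infection (uniform spectrum).
#' @param abe_induced_snvs mean per-plant ABE-induced heterozygous SNVs.
#' @param induced_ag_fraction fraction of induced SNVs in the
#'   strand-collapsed A>G class.
#' @param genic_enrichment length-normalized genic enrichment of
#'   induced A>G SNVs.
#' @param sibling_common_snvs mean common-stage SNVs shared by a callus
#'   sibling pair.
#' @param common_stage_ag_fraction,unique_stage_ag_fraction A>G class
#'   fraction for common-stage and unique-stage sibling SNVs.
#' @param partial_induced_scale induced-count multiplier for plants
#'   with a partial T-DNA insertion.
#' @param cluster_induced_scale induced-count multiplier for plants
#'   carrying clustered editing.
#' @param clusters_per_plant DNA clusters planted in each
#'   cluster-carrying plant (the first plant of each editor).
#' @param cluster_span bp span within which cluster members are placed.
#' @param cluster_members inclusive range of members per cluster.
#' @param rna_edit_loci edited adenine loci planted in exons (default
#'   300, enough that per-offset flanking denominators sit well above
#'   the sequencing-noise floor).
#' @param rna_ratio_mean per-locus editing ratio in high-expression
#'   plants.
#' @param rna_cluster_fraction fraction of RNA loci seeded with 2-6
#'   satellite edits within 30 bp.
#' @param rna_background_snvs shared RNA background SNVs (seen in all
#'   transcriptomes including infection controls).
#' @param yan_bias probability that an edited adenine has T or C at the
#'   transcript -1 position.
#' @param base_error symmetric per-base sequencing error rate in
#'   pileups.
#' @param caller_ids names of the emulated callers.
#' @param caller_sensitivity per-variant detection probability, scalar
#'   or named per caller.
#' @param caller_fp_per_mb caller-private false positives per Mb.
#' @param coverage_mean mean sequencing depth.
#' @param expression_rpm_high,expression_rpm_low design ABE RPM for
#'   high/low expression tiers.
#' @param n_high_expression number of T0 ABE transcriptomes in the
#'   high-expression tier.
#' @param total_reads RNA library size.
#' @param n_t1 T1 offspring of the first high-expression plant (half
#'   transgenic, half segregated away).
#' @param tdna_copy_probs probabilities for 1, 2, 3 T-DNA copies.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(genome_length = 2e6, n_chrom = 2L,
                       gene_fraction = 0.3,
                       n_background = 3L, n_tissue_culture = 3L,
                       n_agro = 3L, n_cas_only = 3L,
                       editors = c("rBE46b", "rBE49b", "rBE50", "rBE53"),
                       n_per_editor = 3L,
                       background_hom_snvs = 80L, background_indels = 30L,
                       residual_hom_snvs = 10L,
                       residual_hom_carrier = 0.5,
                       tissue_culture_het_snvs = 150,
                       abe_induced_snvs = 250,
                       induced_ag_fraction = 0.6,
                       genic_enrichment = 1.5,
                       sibling_common_snvs = 100,
                       common_stage_ag_fraction = 0.4,
                       unique_stage_ag_fraction = 0.8,
                       partial_induced_scale = 0.3,
                       cluster_induced_scale = 1.5,
                       clusters_per_plant = 2L,
                       cluster_span = 60L,
                       cluster_members = c(2L, 10L),
                       rna_edit_loci = 300L,
                       rna_ratio_mean = 0.3,
                       rna_cluster_fraction = 0.1,
                       rna_background_snvs = 30L,
                       yan_bias = 0.9,
                       base_error = 0.002,
                       caller_ids = c("gatk", "strelka2", "lofreq"),
                       caller_sensitivity = 0.95,
                       caller_fp_per_mb = 5,
                       coverage_mean = 41,
                       expression_rpm_high = 100,
                       expression_rpm_low = 5,
                       n_high_expression = 2L,
                       total_reads = 2e7,
                       n_t1 = 4L,
                       tdna_copy_probs = c(0.7, 0.25, 0.05)) {
  cfg <- as.list(environment())
  rates <- c(gene_fraction = gene_fraction,
             induced_ag_fraction = induced_ag_fraction,
             common_stage_ag_fraction = common_stage_ag_fraction,
             unique_stage_ag_fraction = unique_stage_ag_fraction,
             rna_cluster_fraction = rna_cluster_fraction,
             yan_bias = yan_bias, base_error = base_error,
             rna_ratio_mean = rna_ratio_mean)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop("rate(s) outside [0, 1]: ", paste(names(rates)[bad],
                                           collapse = ", "))
  if (gene_fraction >= 1) stop("gene_fraction must be < 1")
  counts <- c(background_hom_snvs, background_indels, rna_edit_loci,
              clusters_per_plant, rna_background_snvs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(cfg$caller_sensitivity) == 1L)
    cfg$caller_sensitivity <- stats::setNames(
      rep(cfg$caller_sensitivity, length(caller_ids)), caller_ids)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a genome and gene annotation
#'
#' Chromosomes are i.i.d. uniform ACGT; non-overlapping genes with 1-3
#' exons are laid down to cover approximately `gene_fraction` of the
#' genome.  Deterministic given the seed.
#'
#' @param config `SimulationConfig`.
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`) and `annotation`
#'   (`AnnotationSet`).
#' @export
simulate_genome <- function(config, seed) {
  if (config$genome_length < 1e4)
    stop("genome_length must be at least 10 kb")
  with_seed(derive_seed(seed, "genome"), {
    chrom_len <- rep(floor(config$genome_length / config$n_chrom),
                     config$n_chrom)
    names(chrom_len) <- paste0("chr", seq_len(config$n_chrom))
    seqs <- vapply(chrom_len, function(L) {
      paste(sample(BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(chrom_len)
    genes <- list()
    exons <- list()
    f <- config$gene_fraction
    if (f > 0) {
      mean_gene <- 2000
      mean_gap <- mean_gene * (1 - f) / f
      for (chrom in names(chrom_len)) {
        L <- chrom_len[[chrom]]
        pos <- 1L
        gi <- 0L
        repeat {
          gap <- ceiling(runif(1, 0.5, 1.5) * mean_gap)
          glen <- ceiling(runif(1, 0.5, 1.5) * mean_gene)
          start <- pos + gap
          end <- start + glen - 1L
          if (end > L - 10L) break
          gi <- gi + 1L
          strand <- sample(c("+", "-"), 1L)
          gid <- sprintf("%s.g%03d", chrom, gi)
          genes[[length(genes) + 1L]] <-
            data.frame(chrom = chrom, start = start, end = end,
                       strand = strand, ID = gid)
          n_ex <- sample(1:3, 1L)
          ex <- split_exons(start, end, n_ex)
          exons[[length(exons) + 1L]] <-
            data.frame(chrom = chrom, start = ex$start, end = ex$end,
                       strand = strand, Parent = gid)
          pos <- end + 1L
        }
      }
    }
    gene_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 ID = character(0))
    exon_df <- if (length(exons)) do.call(rbind, exons) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 Parent = character(0))
    ggr <- GenomicRanges::GRanges(gene_df$chrom,
                                  IRanges::IRanges(gene_df$start,
                                                   gene_df$end),
                                  strand = gene_df$strand)
    ggr$ID <- gene_df$ID
    egr <- GenomicRanges::GRanges(exon_df$chrom,
                                  IRanges::IRanges(exon_df$start,
                                                   exon_df$end),
                                  strand = exon_df$strand)
    egr$Parent <- exon_df$Parent
    list(genome = genome, annotation = annotation_set(ggr, egr, genome))
  })
}

# Split a gene span into n_ex exons separated by introns; falls back to
# a single exon for short genes.
split_exons <- function(start, end, n_ex) {
  len <- end - start + 1L
  min_part <- 80L
  n_parts <- 2L * n_ex - 1L
  if (len < n_parts * min_part) {
    return(list(start = start, end = end))
  }
  cuts <- sort(sample(seq_len(len - 1L), n_parts - 1L))
  while (any(diff(c(0L, cuts, len)) < min_part)) {
    cuts <- sort(sample(seq_len(len - 1L), n_parts - 1L))
  }
  bounds <- c(0L, cuts, len)
  part_start <- start + bounds[-length(bounds)]
  part_end <- start + bounds[-1L] - 1L
  keep <- seq(1L, n_parts, by = 2L)
  list(start = part_start[keep], end = part_end[keep])
}

#' Lay out the cohort design
#'
#' Builds the plant table: wild-type background plants, tissue-culture
#' and Agrobacterium-infection controls, Cas-only plants, ABE plants
#' per editor (one guided plant plus an unguided sibling pair for NGG
#' editors), and T1 offspring with segregating transgenes.  T-DNA copy
#' numbers and expression tiers are drawn from the design RNG stream.
#'
#' @param config `SimulationConfig`.
#' @param seed integer seed.
#' @return data.frame with one row per plant.
#' @export
cohort_design <- function(config, seed) {
  with_seed(derive_seed(seed, "design"), {
    rows <- list()
    add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
    blank <- list(guides = "", callus_id = "", tdna_complete = NA,
                  tdna_missing_feature = "", tdna_copies = NA_integer_,
                  expression_rpm = NA_real_, rna_sequenced = FALSE,
                  generation = "T0", transgene = FALSE,
                  expression_tier = "")
    for (i in seq_len(config$n_background))
      add(plant_id = sprintf("K_%d", i), group = "kitaake",
          editor = "none", blank)
    for (i in seq_len(config$n_tissue_culture))
      add(plant_id = sprintf("TC_%d", i), group = "tissue_culture",
          editor = "none", blank)
    for (i in seq_len(config$n_agro)) {
      b <- blank; b$rna_sequenced <- TRUE
      add(plant_id = sprintf("AG_%d", i), group = "agro_infection",
          editor = "none", b)
    }
    for (i in seq_len(config$n_cas_only)) {
      b <- blank
      b$rna_sequenced <- TRUE
      b$tdna_complete <- TRUE
      b$tdna_copies <- sample(seq_along(config$tdna_copy_probs), 1L,
                              prob = config$tdna_copy_probs)
      b$expression_rpm <- config$expression_rpm_low
      b$transgene <- TRUE
      b$expression_tier <- "low"
      add(plant_id = sprintf("Cas_%d", i), group = "cas_only",
          editor = "SpCas9", b)
    }
    ngg <- config$editors[seq_len(min(2L, length(config$editors)))]
    for (ed in config$editors) {
      for (i in seq_len(config$n_per_editor)) {
        b <- blank
        b$transgene <- TRUE
        b$tdna_copies <- sample(seq_along(config$tdna_copy_probs), 1L,
                                prob = config$tdna_copy_probs)
        sibling <- ed %in% ngg && i >= 2L && config$n_per_editor >= 3L
        b$callus_id <- if (sibling) paste0(ed, "_cal1") else
          sprintf("%s_cal%d", ed, i + 10L)
        guided <- if (sibling) FALSE else TRUE
        b$guides <- if (guided) paste0(ed, "_g1") else ""
        # partial insertions arise in the relaxed-PAM constructs; the
        # third plant of each NG editor carries one
        partial <- !(ed %in% ngg) && i == config$n_per_editor
        b$tdna_complete <- !partial
        b$tdna_missing_feature <- if (partial)
          c("TadA", "Cas")[1L + (match(ed, config$editors) %% 2L)] else ""
        b$rna_sequenced <- ed %in% ngg
        add(plant_id = sprintf("%s_s%d", ed, i), group = "abe",
            editor = ed, b)
      }
    }
    df <- do.call(rbind, rows)
    # expression tiers for T0 ABE transcriptomes
    rna_abe <- which(df$group == "abe" & df$rna_sequenced)
    hi <- sample(rna_abe, min(config$n_high_expression, length(rna_abe)))
    df$expression_tier[rna_abe] <- "low"
    df$expression_tier[hi] <- "high"
    df$expression_rpm[rna_abe] <- ifelse(
      seq_len(nrow(df))[rna_abe] %in% hi,
      config$expression_rpm_high, config$expression_rpm_low)
    # T1 offspring of the first high-expression plant
    if (config$n_t1 > 0L && length(hi)) {
      parent <- df$plant_id[hi[1]]
      for (i in seq_len(config$n_t1)) {
        carrier <- i <= ceiling(config$n_t1 / 2)
        b <- blank
        b$rna_sequenced <- TRUE
        b$generation <- "T1"
        b$transgene <- carrier
        b$expression_tier <- if (carrier) "high" else "none"
        b$expression_rpm <- if (carrier) config$expression_rpm_high else 0
        b$callus_id <- ""
        add(plant_id = sprintf("%s_T1_%d", parent, i), group = "abe_t1",
            editor = df$editor[hi[1]], b)
      }
      df <- do.call(rbind, rows)
      df$expression_tier[rna_abe] <- "low"
      df$expression_tier[hi] <- "high"
      df$expression_rpm[rna_abe] <- ifelse(
        seq_len(nrow(df))[rna_abe] %in% hi,
        config$expression_rpm_high, config$expression_rpm_low)
    }
    rownames(df) <- NULL
    df
  })
}

#' Derive guides with exact protospacers in the simulated genome
#'
#' Picks, for each editor, a 20-nt genomic spacer followed by a valid
#' PAM (NGG for the first two editors, NG otherwise) and containing at
#' least one adenine in the editing window (protospacer positions 4-8),
#' so that on-target edits exist.
#'
#' @param genome named `DNAStringSet`.
#' @param config `SimulationConfig`.
#' @param seed integer seed.
#' @return data.frame with `name`, `spacer`, `pam_pattern`, `editor_id`.
#' @export
simulate_guides <- function(genome, config, seed) {
  with_seed(derive_seed(seed, "guides"), {
    ngg <- config$editors[seq_len(min(2L, length(config$editors)))]
    chroms <- names(genome)
    rows <- lapply(config$editors, function(ed) {
      pam <- if (ed %in% ngg) "NGG" else "NG"
      repeat {
        chrom <- sample(chroms, 1L)
        s <- as.character(genome[[chrom]])
        L <- nchar(s)
        i <- sample(seq(100L, L - 120L), 1L)
        spacer <- substr(s, i, i + 19L)
        pam_seq <- substr(s, i + 20L, i + 19L + nchar(pam))
        ok_pam <- all(mapply(function(b, p) b %in% IUPAC[[p]],
                             strsplit(pam_seq, "")[[1]],
                             strsplit(pam, "")[[1]]))
        window <- substr(spacer, 4L, 8L)
        if (ok_pam && grepl("A", window, fixed = TRUE))
          return(data.frame(name = paste0(ed, "_g1"), spacer = spacer,
                            pam_pattern = pam, editor_id = ed,
                            chrom = chrom, start = i,
                            stringsAsFactors = FALSE))
      }
    })
    do.call(rbind, rows)
  })
}

# Cached per-chromosome character data and A/T position indices.
pos_index <- function(genome, annotation) {
  lens <- genome_seqlengths(genome)
  idx <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    at <- which(chars == "A" | chars == "T")
    genic_mask <- logical(lens[[chrom]])
    gr <- annotation$regions$genic
    gr <- gr[GenomeInfoDb::seqnames(gr) == chrom]
    for (j in seq_along(gr)) {
      genic_mask[BiocGenerics::start(gr)[j]:BiocGenerics::end(gr)[j]] <- TRUE
    }
    idx[[chrom]] <- list(seq = s, chars = chars, at = at,
                         at_genic = at[genic_mask[at]],
                         at_intergenic = at[!genic_mask[at]],
                         len = lens[[chrom]])
  }
  idx
}

ref_at <- function(idx, chrom, pos) {
  vapply(seq_along(chrom),
         function(i) idx[[chrom[i]]]$chars[pos[i]], character(1))
}

# Sample n positions uniformly over the genome.
sample_uniform_pos <- function(idx, n) {
  lens <- vapply(idx, `[[`, numeric(1), "len")
  chrom <- sample(names(idx), n, replace = TRUE, prob = lens)
  pos <- vapply(chrom, function(c2) sample.int(idx[[c2]]$len, 1L),
                integer(1))
  data.frame(chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Sample n A/T positions with genic enrichment.
sample_at_pos <- function(idx, n, genic_enrichment) {
  n_gen_at <- sum(vapply(idx, function(x) length(x$at_genic), numeric(1)))
  n_at <- sum(vapply(idx, function(x) length(x$at), numeric(1)))
  if (n > n_at) stop("requested more variants than available A/T positions")
  p_genic <- min(1, genic_enrichment * n_gen_at / n_at)
  n_gen <- rbinom(1L, n, p_genic)
  pick <- function(field, k) {
    if (k == 0L) return(NULL)
    avail <- vapply(idx, function(x) length(x[[field]]), numeric(1))
    chrom <- sample(names(idx), k, replace = TRUE, prob = avail)
    pos <- vapply(chrom, function(c2) {
      v <- idx[[c2]][[field]]
      v[sample.int(length(v), 1L)]
    }, integer(1))
    data.frame(chrom = chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(pick("at_genic", n_gen), pick("at_intergenic", n - n_gen))
  out[sample.int(nrow(out)), , drop = FALSE]
}

# A>G-class SNV rows at given A/T positions.
ag_rows <- function(idx, pos_df, zygosity, origin, stage) {
  if (is.null(pos_df) || !nrow(pos_df)) return(NULL)
  ref <- ref_at(idx, pos_df$chrom, pos_df$pos)
  alt <- ifelse(ref == "A", "G", "C")
  data.frame(chrom = pos_df$chrom, pos = pos_df$pos, ref = ref,
             alt = alt, vtype = "SNV", zygosity = zygosity,
             origin = origin, stage = stage, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Uniform-spectrum SNV rows (all 12 ordered substitutions equally
# likely); when exclude_ag, the alt creating an A>G/T>C event is
# excluded.
uniform_rows <- function(idx, n, zygosity, origin, stage,
                         exclude_ag = FALSE) {
  if (n == 0L) return(NULL)
  pos_df <- sample_uniform_pos(idx, n)
  ref <- ref_at(idx, pos_df$chrom, pos_df$pos)
  alt <- vapply(ref, function(r) {
    choices <- setdiff(BASES, r)
    if (exclude_ag) {
      if (r == "A") choices <- setdiff(choices, "G")
      if (r == "T") choices <- setdiff(choices, "C")
    }
    sample(choices, 1L)
  }, character(1), USE.NAMES = FALSE)
  data.frame(chrom = pos_df$chrom, pos = pos_df$pos, ref = ref,
             alt = alt, vtype = "SNV", zygosity = zygosity,
             origin = origin, stage = stage, stringsAsFactors = FALSE,
             row.names = NULL)
}

indel_rows <- function(idx, n, zygosity, origin, stage) {
  if (n == 0L) return(NULL)
  pos_df <- sample_uniform_pos(idx, n)
  rows <- lapply(seq_len(n), function(i) {
    chrom <- pos_df$chrom[i]
    pos <- min(pos_df$pos[i], idx[[chrom]]$len - 5L)
    len <- sample(1:3, 1L)
    if (runif(1) < 0.5) {  # deletion
      ref <- substr(idx[[chrom]]$seq, pos, pos + len)
      alt <- substr(ref, 1L, 1L)
    } else {               # insertion
      ref <- substr(idx[[chrom]]$seq, pos, pos)
      alt <- paste0(ref, paste(sample(BASES, len, replace = TRUE),
                               collapse = ""))
    }
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               vtype = "indel", zygosity = zygosity, origin = origin,
               stage = stage, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Clustered A>G rows: m members taken from consecutive A/T positions
# within `span` bp of an anchor; anchors carry the same genic
# enrichment as scattered induced A>G SNVs.
cluster_rows <- function(idx, n_clusters, span, members_range, origin,
                         genic_enrichment) {
  rows <- list()
  for (k in seq_len(n_clusters)) {
    m <- sample(seq(members_range[1], members_range[2]), 1L)
    repeat {
      a <- sample_at_pos(idx, 1L, genic_enrichment)
      chrom <- a$chrom[1]
      anchor <- min(a$pos[1], idx[[chrom]]$len - span - 10L)
      at <- idx[[chrom]]$at
      cand <- at[at >= anchor & at <= anchor + span]
      if (length(cand) >= m && all(diff(cand[seq_len(m)]) <= 30L)) {
        pos <- cand[seq_len(m)]
        break
      }
    }
    ref <- idx[[chrom]]$chars[pos]
    rows[[k]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                            alt = ifelse(ref == "A", "G", "C"),
                            vtype = "SNV", zygosity = "het",
                            origin = origin, stage = "post_integration",
                            cluster_id = sprintf("cl%d", k),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate the truth table of DNA mutations for the cohort
#'
#' Every plant carries the shared homozygous background; regenerated
#' plants add Poisson heterozygous tissue-culture SNVs of uniform
#' spectrum; ABE plants add induced heterozygous SNVs with the
#' configured A>G fraction and genic enrichment, scaled down for
#' partial T-DNA insertions and up for cluster-carrying plants (the
#' first plant of each editor, which also receives planted A>G
#' clusters); callus sibling pairs share an identical common-stage set
#' with a lower A>G fraction while their unique sets use a higher one;
#' guided plants get on-target A>G edits inside their protospacer.
#'
#' @param config `SimulationConfig`.
#' @param genome,annotation from [simulate_genome()].
#' @param design data.frame from [cohort_design()].
#' @param guides data.frame from [simulate_guides()].
#' @param seed integer seed.
#' @return data.frame (the truth table): `plant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vtype`, `zygosity`, `origin` (background /
#'   tissue_culture / induced_AG / induced_other / cluster /
#'   on_target), `stage` (pre_integration / post_integration / NA) and
#'   `cluster_id`.
#' @export
simulate_truth <- function(config, genome, annotation, design, guides,
                           seed) {
  idx <- pos_index(genome, annotation)
  bg <- with_seed(derive_seed(seed, "background"), {
    rbind(uniform_rows(idx, config$background_hom_snvs, "hom",
                       "background", NA_character_),
          indel_rows(idx, config$background_indels, "hom", "background",
                     NA_character_))
  })
  bg$cluster_id <- NA_character_
  residual <- with_seed(derive_seed(seed, "residual"), {
    out <- uniform_rows(idx, config$residual_hom_snvs, "hom",
                        "residual_background", NA_character_)
    if (!is.null(out)) out$cluster_id <- NA_character_
    out
  })
  # common-stage sets per callus (shared within a sibling pair)
  calli <- unique(design$callus_id[design$group == "abe" &
                                     design$callus_id != ""])
  common_sets <- list()
  for (cal in calli) {
    n_sib <- sum(design$callus_id == cal)
    if (n_sib < 2L) next
    common_sets[[cal]] <- with_seed(derive_seed(seed, cal), {
      n <- rpois(1L, config$sibling_common_snvs)
      n_ag <- rbinom(1L, n, config$common_stage_ag_fraction)
      out <- rbind(ag_rows(idx, sample_at_pos(idx, n_ag,
                                              config$genic_enrichment),
                           "het", "induced_AG", "pre_integration"),
                   uniform_rows(idx, n - n_ag, "het", "induced_other",
                                "pre_integration", exclude_ag = TRUE))
      if (!is.null(out)) out$cluster_id <- NA_character_
      out
    })
  }
  cluster_plants <- cluster_plant_ids(config, design)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    pl <- design[i, ]
    if (pl$group == "abe_t1") next  # transcriptome-only offspring
    plant_rows <- list(cbind(plant_id = pl$plant_id, bg))
    plant_seed <- derive_seed(seed, pl$plant_id)
    if (pl$group != "kitaake" && !is.null(residual) && nrow(residual)) {
      carry <- with_seed(derive_seed(seed, paste0(pl$plant_id, ":residual")),
                         runif(nrow(residual)) < config$residual_hom_carrier)
      if (any(carry))
        plant_rows <- c(plant_rows,
                        list(cbind(plant_id = pl$plant_id,
                                   residual[carry, , drop = FALSE])))
    }
    if (pl$group != "kitaake") {
      tc <- with_seed(plant_seed, {
        out <- uniform_rows(idx, rpois(1L, config$tissue_culture_het_snvs),
                            "het", "tissue_culture", NA_character_)
        if (!is.null(out)) out$cluster_id <- NA_character_
        out
      })
      if (!is.null(tc))
        plant_rows <- c(plant_rows, list(cbind(plant_id = pl$plant_id, tc)))
    }
    if (pl$group == "abe") {
      sibling <- pl$callus_id %in% names(common_sets)
      if (sibling) {
        cs <- common_sets[[pl$callus_id]]
        if (!is.null(cs))
          plant_rows <- c(plant_rows,
                          list(cbind(plant_id = pl$plant_id, cs)))
      }
      ind <- with_seed(derive_seed(seed, paste0(pl$plant_id, ":induced")), {
        scale <- 1
        if (isFALSE(pl$tdna_complete)) scale <- config$partial_induced_scale
        if (pl$plant_id %in% cluster_plants)
          scale <- scale * config$cluster_induced_scale
        n <- rpois(1L, config$abe_induced_snvs * scale)
        f <- if (sibling) config$unique_stage_ag_fraction else
          config$induced_ag_fraction
        n_ag <- rbinom(1L, n, f)
        out <- rbind(ag_rows(idx, sample_at_pos(idx, n_ag,
                                                config$genic_enrichment),
                             "het", "induced_AG", "post_integration"),
                     uniform_rows(idx, n - n_ag, "het", "induced_other",
                                  "post_integration", exclude_ag = TRUE))
        cl <- NULL
        if (pl$plant_id %in% cluster_plants && config$clusters_per_plant > 0)
          cl <- cluster_rows(idx, config$clusters_per_plant,
                             config$cluster_span, config$cluster_members,
                             "cluster", config$genic_enrichment)
        if (!is.null(out)) out$cluster_id <- NA_character_
        # keep planted clusters isolated from scattered induced SNVs
        if (!is.null(cl) && !is.null(out)) {
          near <- rep(FALSE, nrow(out))
          for (j in seq_len(nrow(cl))) {
            near <- near | (out$chrom == cl$chrom[j] &
                              abs(out$pos - cl$pos[j]) <= 100L)
          }
          out <- out[!near, , drop = FALSE]
        }
        rbind(out, cl)
      })
      if (!is.null(ind))
        plant_rows <- c(plant_rows, list(cbind(plant_id = pl$plant_id, ind)))
      if (nzchar(pl$guides)) {
        ot <- with_seed(derive_seed(seed, paste0(pl$plant_id, ":ontarget")),
                        on_target_rows(genome, guides, pl$guides))
        if (!is.null(ot)) {
          ot$cluster_id <- NA_character_
          plant_rows <- c(plant_rows, list(cbind(plant_id = pl$plant_id, ot)))
        }
      }
    }
    all_rows <- do.call(rbind, plant_rows)
    all_rows <- all_rows[!duplicated(variant_key(all_rows$chrom,
                                                 all_rows$pos,
                                                 all_rows$ref,
                                                 all_rows$alt)), ,
                         drop = FALSE]
    rows[[length(rows) + 1L]] <- all_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# A>G edits inside the protospacer editing window (positions 4-8).
on_target_rows <- function(genome, guides, guide_names) {
  gn <- strsplit(guide_names, ",", fixed = TRUE)[[1]]
  rows <- list()
  for (g in gn) {
    gd <- guides[guides$name == g, ]
    if (!nrow(gd)) next
    s <- as.character(genome[[gd$chrom]])
    window_pos <- gd$start + 3:7
    refs <- strsplit(substr(s, gd$start + 3L, gd$start + 7L), "")[[1]]
    a_pos <- window_pos[refs == "A"]
    if (!length(a_pos)) next
    take <- a_pos[seq_len(min(length(a_pos), sample(1:2, 1L)))]
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = gd$chrom, pos = take, ref = "A", alt = "G",
                 vtype = "SNV", zygosity = "het", origin = "on_target",
                 stage = "post_integration", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

cluster_plant_ids <- function(config, design) {
  abe <- design[design$group == "abe", , drop = FALSE]
  out <- character(0)
  for (ed in unique(abe$editor)) {
    ids <- abe$plant_id[abe$editor == ed]
    if (length(ids)) out <- c(out, ids[1])
  }
  out
}

#' Emulate three independent variant callers
#'
#' Each true variant enters each caller's callset independently with
#' the caller's sensitivity; caller-private false positives are added
#' as Poisson(rate x Mb) uniform het SNVs.  Allele depths are drawn at
#' the configured coverage with alt fraction ~0.5 for het and ~1 for
#' hom calls.
#'
#' @param truth truth table from [simulate_truth()].
#' @param genome named `DNAStringSet`.
#' @param config `SimulationConfig`.
#' @param seed integer seed.
#' @return nested named list: `calls[[plant_id]][[caller_id]]` is a
#'   calls data.frame as returned by [read_vcf()].
#' @export
emulate_callers <- function(truth, genome, config, seed) {
  lens <- genome_seqlengths(genome)
  genome_mb <- sum(as.numeric(lens)) / 1e6
  chars <- lapply(names(genome),
                  function(c2) as.character(genome[[c2]]))
  names(chars) <- names(genome)
  plants <- unique(truth$plant_id)
  out <- list()
  for (pid in plants) {
    tv <- truth[truth$plant_id == pid, , drop = FALSE]
    out[[pid]] <- list()
    for (cid in config$caller_ids) {
      out[[pid]][[cid]] <- with_seed(
        derive_seed(seed, paste(pid, cid, sep = "|")), {
          sens <- config$caller_sensitivity[[cid]]
          det <- runif(nrow(tv)) < sens
          calls <- tv[det, c("chrom", "pos", "ref", "alt", "vtype",
                             "zygosity"), drop = FALSE]
          n_fp <- rpois(1L, config$caller_fp_per_mb * genome_mb)
          if (n_fp > 0L) {
            fchrom <- sample(names(lens), n_fp, replace = TRUE,
                             prob = lens)
            fpos <- vapply(fchrom,
                           function(c2) sample.int(lens[[c2]], 1L),
                           integer(1))
            fref <- vapply(seq_len(n_fp), function(i)
              substr(chars[[fchrom[i]]], fpos[i], fpos[i]), character(1))
            falt <- vapply(fref, function(r)
              sample(setdiff(BASES, r), 1L), character(1),
              USE.NAMES = FALSE)
            calls <- rbind(calls,
                           data.frame(chrom = fchrom, pos = as.integer(fpos),
                                      ref = fref, alt = falt,
                                      vtype = "SNV", zygosity = "het",
                                      stringsAsFactors = FALSE))
          }
          n <- nrow(calls)
          cov <- rpois(n, config$coverage_mean)
          cov <- pmax(cov, 4L)
          p_alt <- ifelse(calls$zygosity == "hom", 1 - config$base_error,
                          0.5)
          ad_alt <- rbinom(n, cov, p_alt)
          calls$ad_ref <- cov - ad_alt
          calls$ad_alt <- ad_alt
          calls$plant_id <- pid
          calls$caller_id <- cid
          ord <- order(match(calls$chrom, names(lens)), calls$pos,
                       calls$ref, calls$alt)
          calls <- calls[ord, c("plant_id", "caller_id", "chrom", "pos",
                                "ref", "alt", "vtype", "zygosity",
                                "ad_ref", "ad_alt")]
          rownames(calls) <- NULL
          calls
        })
    }
  }
  out
}
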