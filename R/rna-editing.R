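# RNA off-target analysis: RNA-only SNV detection, per-locus A>G
# editing ratios, per-plant significance against the Cas-only pool,
# ABE expression (RPM), motif matrices and transgene segregation.

#' RNA-only SNVs for one plant
#'
#' Keeps RNA consensus keys that are absent from the plant's own DNA
#' consensus and from the pooled RNA background (the union of calls in
#' the Agrobacterium-infection transcriptomes).
#'
#' @param rna_consensus RNA consensus data.frame for the plant.
#' @param dna_consensus matching DNA consensus data.frame (required;
#'   pass a zero-row frame for plants without genome data only if the
#'   design says so).
#' @param background_rna list of RNA consensus data.frames from the
#'   background (Agrobacterium-infection) plants.
#' @return filtered RNA consensus data.frame.
#' @export
rna_minus_dna <- function(rna_consensus, dna_consensus, background_rna) {
  if (is.null(dna_consensus))
    stop("missing DNA consensus partner for plant ",
         if (nrow(rna_consensus)) rna_consensus$plant_id[1] else "?")
  rna <- with_keys(rna_consensus)
  dna_keys <- with_keys(dna_consensus)$key
  bg_keys <- unique(unlist(lapply(background_rna,
                                  function(b) with_keys(b)$key)))
  out <- rna[!(rna$key %in% dna_keys) & !(rna$key %in% bg_keys), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A>G editing ratio at one position
#'
#' At a reference-A position the ratio is G/(A+G); at a reference-T
#' position (edited strand is the complement) it is C/(C+T).  Positions
#' with total coverage of 10 or fewer reads are reported missing
#' ("higher than 10" is strict).
#'
#' @param nA,nC,nG,nT read counts (vectorized).
#' @param ref_base reference base, `"A"` or `"T"` (vectorized).
#' @param cov_min strict coverage threshold (default 10).
#' @return numeric vector of ratios in [0, 1], NA where coverage is
#'   insufficient or the denominator is empty.
#' @export
editing_ratio <- function(nA, nC, nG, nT, ref_base, cov_min = 10L) {
  if (any(!ref_base %in% c("A", "T")))
    stop("editing_ratio requires reference base A or T")
  cov <- nA + nC + nG + nT
  num <- ifelse(ref_base == "A", nG, nC)
  den <- ifelse(ref_base == "A", nA + nG, nC + nT)
  out <- ifelse(cov > cov_min & den > 0, num / den, NA_real_)
  as.numeric(out)
}

#' Editing-ratio matrix over combined loci
#'
#' Builds the loci x plants matrix of A>G editing ratios from pileup
#' counts; cells with coverage <= `cov_min` are NA.
#'
#' @param loci data.frame with `chrom`, `pos`, `ref` (A or T).
#' @param pileups pileup data.frame (see [read_pileup()]).
#' @param plants plant ids to include (default: all in `pileups`).
#' @param cov_min strict coverage threshold.
#' @return numeric matrix; rows named `chrom:pos`, columns plant ids.
#' @export
editing_ratio_matrix <- function(loci, pileups, plants = NULL,
                                 cov_min = 10L) {
  if (is.null(plants)) plants <- sort(unique(pileups$plant_id))
  key <- paste(loci$chrom, loci$pos, sep = ":")
  m <- matrix(NA_real_, nrow = nrow(loci), ncol = length(plants),
              dimnames = list(key, plants))
  pk <- paste(pileups$plant_id, pileups$chrom, pileups$pos, sep = ":")
  idx <- stats::setNames(seq_len(nrow(pileups)), pk)
  for (j in seq_along(plants)) {
    want <- paste(plants[j], loci$chrom, loci$pos, sep = ":")
    rows <- idx[want]
    ok <- !is.na(rows)
    if (any(ok)) {
      p <- pileups[rows[ok], , drop = FALSE]
      m[ok, j] <- editing_ratio(p$nA, p$nC, p$nG, p$nT, loci$ref[ok],
                                cov_min)
    }
  }
  m
}

#' Per-plant Wilcoxon test of editing ratios against the Cas-only pool
#'
#' One-tailed (greater) rank-sum test of a plant's per-locus editing
#' ratios against the concatenated ratios of the Cas-only plants.
#'
#' @param ratios_plant numeric vector of the plant's ratios (NA cells
#'   dropped).
#' @param ratios_cas_pool concatenated Cas-only ratios (NAs dropped).
#' @param min_n minimum non-missing values per side (default 3).
#' @return list with `pvalue`, `neglog10p`, `n_plant`, `n_cas`; values
#'   NA when either side has fewer than `min_n` ratios.
#' @export
per_plant_test <- function(ratios_plant, ratios_cas_pool, min_n = 3L) {
  a <- ratios_plant[!is.na(ratios_plant)]
  b <- ratios_cas_pool[!is.na(ratios_cas_pool)]
  if (length(a) < min_n || length(b) < min_n) {
    return(list(pvalue = NA_real_, neglog10p = NA_real_,
                n_plant = length(a), n_cas = length(b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  list(pvalue = wt$p.value, neglog10p = -log10(wt$p.value),
       n_plant = length(a), n_cas = length(b))
}

#' ABE expression in reads per million
#'
#' Average of the Cas-module and TadA-module read counts, normalized by
#' the library size in millions.
#'
#' @param cas_reads,tada_reads raw read counts over the two modules.
#' @param total_reads total library read count (> 0).
#' @return RPM value.
#' @export
abe_rpm <- function(cas_reads, tada_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  ((cas_reads + tada_reads) / 2) / (total_reads / 1e6)
}

#' Group plants by presence of RNA mutations and compare ABE expression
#'
#' A plant "has RNA mutations" when it carries more than a threshold
#' number of RNA-only A>G SNVs and its per-plant editing-ratio test is
#' significant; ABE RPM is then compared between the two groups by a
#' one-tailed Wilcoxon test (with > without).
#'
#' @param plant_ids character vector of ABE plants considered.
#' @param n_ag_snvs named vector: RNA-only A>G SNV count per plant.
#' @param pvalues named vector: per-plant test p-value.
#' @param rpm named vector: ABE RPM per plant.
#' @param snv_min SNV-count threshold (default 5: "more than 5").
#' @param alpha significance threshold for the per-plant test.
#' @return list: `groups` data.frame (`plant_id`, `n_ag_snvs`,
#'   `pvalue`, `rpm`, `has_rna_mutations`) and `rpm_test`
#'   ([group_compare()] result or NULL when a group is empty).
#' @export
expression_grouping <- function(plant_ids, n_ag_snvs, pvalues, rpm,
                                snv_min = 5L, alpha = 0.05) {
  df <- data.frame(plant_id = plant_ids,
                   n_ag_snvs = as.integer(n_ag_snvs[plant_ids]),
                   pvalue = as.numeric(pvalues[plant_ids]),
                   rpm = as.numeric(rpm[plant_ids]),
                   stringsAsFactors = FALSE)
  df$n_ag_snvs[is.na(df$n_ag_snvs)] <- 0L
  df$has_rna_mutations <- df$n_ag_snvs > snv_min &
    !is.na(df$pvalue) & df$pvalue < alpha
  with_m <- df$rpm[df$has_rna_mutations]
  without <- df$rpm[!df$has_rna_mutations]
  test <- if (length(with_m) && length(without))
    group_compare(with_m, without, "greater") else NULL
  list(groups = df, rpm_test = test)
}

#' Position frequency matrix and information content around edit loci
#'
#' Extracts the +/- `flank` bp reference context around each edited
#' adenine (reverse-complemented for reference-T loci so the center is
#' always A on the edited strand) and reports per-position base counts,
#' frequencies, and information content in bits
#' (2 - Shannon entropy, log2; no small-sample correction).  Windows
#' truncated at a chromosome edge contribute only to the columns they
#' cover.
#'
#' @param loci data.frame with `chrom`, `pos`, `ref` (A or T).
#' @param genome named `DNAStringSet`.
#' @param flank window half-width in bp (default 3).
#' @return list with `counts` (4 x (2*flank+1) matrix), `freq`, `bits`
#'   (per-column numeric) and `n_loci`.
#' @export
motif_matrix <- function(loci, genome, flank = 3L) {
  if (!nrow(loci)) stop("motif_matrix requires at least one locus")
  genome <- as_genome(genome)
  lens <- genome_seqlengths(genome)
  w <- 2L * flank + 1L
  counts <- matrix(0, nrow = 4L, ncol = w,
                   dimnames = list(BASES, as.character(seq(-flank, flank))))
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    pos <- loci$pos[i]
    lo <- max(1L, pos - flank)
    hi <- min(lens[[chrom]], pos + flank)
    ctx <- strsplit(as.character(
      Biostrings::subseq(genome[[chrom]], lo, hi)), "", fixed = TRUE)[[1]]
    offs <- seq(lo, hi) - pos
    if (identical(loci$ref[i], "T")) {
      ctx <- rev(unname(COMPLEMENT[ctx]))
      offs <- rev(-offs)
    }
    cols <- offs + flank + 1L
    for (j in seq_along(ctx)) {
      b <- ctx[j]
      if (b %in% BASES) counts[b, cols[j]] <- counts[b, cols[j]] + 1
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1), "/")
  bits <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  bits[tot == 0] <- NA_real_
  list(counts = counts, freq = freq, bits = bits, n_loci = nrow(loci))
}

#' Transgene segregation check in the T1 generation
#'
#' Runs the per-plant editing-ratio test for T1 plants; plants that
#' segregated away the transgene are expected non-significant while
#' transgene carriers remain active.
#'
#' @param design cohort design data.frame with `generation` and
#'   `transgene` columns.
#' @param ratio_matrix loci x plants editing-ratio matrix.
#' @param cas_pool concatenated Cas-only ratios.
#' @return data.frame per T1 plant: `plant_id`, `transgene`, `pvalue`,
#'   `neglog10p`; zero rows (with a message) when the design has no T1
#'   plants.
#' @export
segregation_check <- function(design, ratio_matrix, cas_pool) {
  t1 <- design[!is.na(design$generation) & design$generation == "T1", ,
               drop = FALSE]
  if (!nrow(t1)) {
    message("no T1 plants in design; segregation check skipped")
    return(data.frame(plant_id = character(0), transgene = logical(0),
                      pvalue = numeric(0), neglog10p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(t1)), function(i) {
    pid <- t1$plant_id[i]
    res <- if (pid %in% colnames(ratio_matrix))
      per_plant_test(ratio_matrix[, pid], cas_pool)
    else list(pvalue = NA_real_, neglog10p = NA_real_)
    data.frame(plant_id = pid, transgene = isTRUE(t1$transgene[i]),
               pvalue = res$pvalue, neglog10p = res$neglog10p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
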