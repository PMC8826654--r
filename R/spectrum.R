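# Strand-collapsed mutation spectra, region enrichment, chromosome
# distribution and the one-tailed Wilcoxon group comparison used for
# every between-group contrast in the analysis.

SPECTRUM_CLASSES <- c("A>G", "C>T", "A>T", "A>C", "C>A", "C>G")

#' Collapse an SNV to one of the six strand-collapsed classes
#'
#' Substitutions are reported from the A/C reference strand, so e.g.
#' T>C collapses onto A>G and G>A onto C>T.  The A>G class therefore
#' counts both A>G and T>C events.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector of class labels among A>G, C>T, A>T, A>C,
#'   C>A, C>G.
#' @export
collapse_class <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L | ref == alt))
    stop("collapse_class expects single-base ref != alt")
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  paste0(r, ">", a)
}

#' Per-plant mutation spectrum summary
#'
#' Counts the six strand-collapsed SNV classes plus indels, and derives
#' per-class percentages.  The headline "A>G percentage" is the A>G
#' (plus T>C) count over all six classes.  Percentages are NA when a
#' plant has no SNVs.
#'
#' @param consensus consensus data.frame (het SNVs expected; indel rows
#'   are counted, not classified).
#' @param plant_id optional plant identifier for the output row.
#' @return one-row data.frame: `plant_id`, `n_snvs`, `n_indels`, one
#'   count and one `pct_` column per class.
#' @export
spectrum_summary <- function(consensus, plant_id = NULL) {
  if (is.null(plant_id))
    plant_id <- if (nrow(consensus)) consensus$plant_id[1] else NA_character_
  snvs <- consensus[consensus$vtype == "SNV", , drop = FALSE]
  n_snvs <- nrow(snvs)
  counts <- stats::setNames(integer(length(SPECTRUM_CLASSES)),
                            SPECTRUM_CLASSES)
  if (n_snvs) {
    tab <- table(collapse_class(snvs$ref, snvs$alt))
    counts[names(tab)] <- as.integer(tab)
  }
  pct <- if (n_snvs > 0) 100 * counts / n_snvs else
    stats::setNames(rep(NA_real_, length(counts)), names(counts))
  out <- data.frame(plant_id = plant_id, n_snvs = n_snvs,
                    n_indels = sum(consensus$vtype == "indel"),
                    stringsAsFactors = FALSE)
  for (cl in SPECTRUM_CLASSES) {
    out[[paste0("n_", gsub(">", "", cl))]] <- counts[[cl]]
    out[[paste0("pct_", gsub(">", "", cl))]] <- unname(pct[[cl]])
  }
  out
}

#' Spectrum table for a cohort
#'
#' @param consensus_sets named list of per-plant consensus data.frames.
#' @return data.frame with one [spectrum_summary()] row per plant.
#' @export
spectrum_table <- function(consensus_sets) {
  rows <- Map(spectrum_summary, consensus_sets, names(consensus_sets))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic-region enrichment of SNVs
#'
#' Assigns every SNV to genic or intergenic (and exonic/intronic within
#' genic) and reports, per region, the SNV fraction, the genome length
#' fraction, and their ratio (1 = proportional to length).  The
#' per-region A>G percentage is also emitted.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `vtype`.
#' @param annotation `AnnotationSet` covering all variant chromosomes.
#' @return data.frame with one row per region class: `region`,
#'   `n_snvs`, `snv_fraction`, `genome_fraction`, `ratio`, `pct_AG`.
#' @export
region_enrichment <- function(variants, annotation) {
  snvs <- variants[variants$vtype == "SNV", , drop = FALSE]
  bad <- setdiff(unique(snvs$chrom), names(annotation$seqlengths))
  if (length(bad))
    stop("variants on unannotated chromosome(s): ",
         paste(bad, collapse = ", "))
  fracs <- region_fractions(annotation)
  gr <- GenomicRanges::GRanges(snvs$chrom,
                               IRanges::IRanges(snvs$pos, width = 1L))
  assign_region <- function(region) {
    IRanges::overlapsAny(gr, annotation$regions[[region]],
                         ignore.strand = TRUE)
  }
  n <- nrow(snvs)
  rows <- lapply(names(annotation$regions), function(region) {
    inr <- assign_region(region)
    k <- sum(inr)
    pct_ag <- if (k > 0) {
      cls <- collapse_class(snvs$ref[inr], snvs$alt[inr])
      100 * mean(cls == "A>G")
    } else NA_real_
    data.frame(region = region, n_snvs = k,
               snv_fraction = if (n > 0) k / n else NA_real_,
               genome_fraction = unname(fracs[region]),
               ratio = if (n > 0) (k / n) / fracs[region] else NA_real_,
               pct_AG = pct_ag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chromosome variant counts and densities
#'
#' @param variants data.frame with `chrom`.
#' @param genome named `DNAStringSet`.
#' @return data.frame: `chrom`, `length_bp`, `n_variants`,
#'   `per_mb` density.
#' @export
chromosome_distribution <- function(variants, genome) {
  lens <- genome_seqlengths(genome)
  counts <- table(factor(variants$chrom, levels = names(lens)))
  data.frame(chrom = names(lens), length_bp = unname(lens),
             n_variants = as.integer(counts),
             per_mb = as.numeric(counts) / (unname(lens) / 1e6),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-tailed Wilcoxon rank-sum comparison with significance stars
#'
#' Exact null distribution when both groups have at most 10 values and
#' no ties are present; otherwise the normal approximation with tie
#' correction and continuity correction.  Star categories follow the
#' reporting convention: `***` p < 0.001, `**` p < 0.01, `*` p < 0.1,
#' `ns` otherwise.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @param alternative `"greater"` or `"less"` (a vs b).
#' @return list with `W`, `pvalue`, `stars`, `n_a`, `n_b`.
#' @export
group_compare <- function(values_a, values_b,
                          alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 10L && length(b) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(W = unname(wt$statistic), pvalue = wt$p.value,
       stars = p_stars(wt$p.value), n_a = length(a), n_b = length(b))
}

#' Significance star category
#'
#' @param p p-value(s).
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.1) or
#'   `"ns"`.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.1, "*", "ns")))
}
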