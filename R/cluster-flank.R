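# Clustered-editing statistics: per-offset flanking A>G profiles around
# focal SNV loci, DNA cluster detection by single-linkage merging, and
# the group-1/group-2 plant classification.

#' Flanking A>G editing profile around focal loci
#'
#' For one plant, aggregates over all focal A>G loci: at every offset in
#' -window..window (0 = the focal SNV, excluded from the summary), the
#' number of positions whose A>G editing ratio exceeds `ratio_thr`
#' (numerator) and the number of A/T reference positions with coverage
#' strictly above `cov_thr` (denominator).  Offsets are reported in the
#' edited-strand orientation, so reference-T focal loci contribute with
#' mirrored offsets.
#'
#' @param loci data.frame of focal loci: `chrom`, `pos`, `ref` (A/T).
#' @param pileups pileup data.frame for the plant (single plant); its
#'   `ref` column provides the reference base at each covered position.
#' @param window half-window in bp (default 30).
#' @param ratio_thr strict editing-ratio threshold (default 0.05).
#' @param cov_thr strict coverage threshold (default 10).
#' @return data.frame per offset: `offset`, `n_edited`, `n_eligible`,
#'   `fraction` (NA when no eligible positions).
#' @export
flank_profile <- function(loci, pileups, window = 30L,
                          ratio_thr = 0.05, cov_thr = 10L) {
  offsets <- seq(-window, window)
  out <- data.frame(offset = offsets, n_edited = 0L, n_eligible = 0L,
                    fraction = NA_real_, row.names = NULL)
  if (!nrow(loci) || !nrow(pileups)) return(out)
  no <- length(offsets)
  nl <- nrow(loci)
  # all (locus, offset) pairs; reference-T loci mirror their offsets so
  # profiles are reported in edited-strand orientation
  off <- rep(offsets, times = nl)
  li <- rep(seq_len(nl), each = no)
  flip <- loci$ref[li] == "T"
  pos <- loci$pos[li] + ifelse(flip, -off, off)
  chrom <- loci$chrom[li]
  keep <- off != 0L & pos >= 1L
  row <- match(paste(chrom, pos, sep = ":"),
               paste(pileups$chrom, pileups$pos, sep = ":"))
  keep <- keep & !is.na(row)
  off <- off[keep]; row <- row[keep]
  p <- pileups[row, , drop = FALSE]
  at <- p$ref %in% c("A", "T")
  cov <- p$nA + p$nC + p$nG + p$nT
  eligible <- at & cov > cov_thr
  off <- off[eligible]
  p <- p[eligible, , drop = FALSE]
  if (nrow(p)) {
    ratio <- editing_ratio(p$nA, p$nC, p$nG, p$nT, p$ref,
                           cov_min = cov_thr)
    edited <- !is.na(ratio) & ratio > ratio_thr
    tab_el <- table(factor(off, levels = offsets))
    tab_ed <- table(factor(off[edited], levels = offsets))
    out$n_eligible <- as.integer(tab_el)
    out$n_edited <- as.integer(tab_ed)
  }
  out$fraction <- ifelse(out$n_eligible > 0,
                         out$n_edited / out$n_eligible, NA_real_)
  out$fraction[out$offset == 0L & out$n_eligible == 0L] <- NA_real_
  out
}

#' Detect clustered A>G DNA SNVs by single-linkage merging
#'
#' Merges a plant's strand-collapsed A>G SNVs that lie within
#' `merge_distance` bp of a neighbor; merged groups with at least two
#' members are reported as cluster calls.
#'
#' @param snvs consensus data.frame of off-target het SNVs for one
#'   plant (non-A>G classes are ignored).
#' @param merge_distance single-linkage distance in bp (default 30).
#' @param annotation optional `AnnotationSet`; when given, each call is
#'   labelled genic/intergenic.
#' @return data.frame of cluster calls: `chrom`, `start`, `end`,
#'   `n_members`, `members` (comma-joined positions), `plant_id`,
#'   and `region` when annotation is supplied.
#' @export
detect_dna_clusters <- function(snvs, merge_distance = 30L,
                                annotation = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      members = character(0), plant_id = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(snvs)) return(empty)
  ag <- snvs[snvs$vtype == "SNV" &
               collapse_class_safe(snvs$ref, snvs$alt) == "A>G", ,
             drop = FALSE]
  if (nrow(ag) < 2L) return(empty)
  calls <- list()
  for (chrom in unique(ag$chrom)) {
    pos <- sort(unique(ag$pos[ag$chrom == chrom]))
    grp <- cumsum(c(1L, as.integer(diff(pos) > merge_distance)))
    for (g in unique(grp)) {
      members <- pos[grp == g]
      if (length(members) >= 2L) {
        calls[[length(calls) + 1L]] <-
          data.frame(chrom = chrom, start = min(members),
                     end = max(members), n_members = length(members),
                     members = paste(members, collapse = ","),
                     plant_id = ag$plant_id[1],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(match(out$chrom, unique(ag$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotation)) {
    gr <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$start, out$end))
    genic <- IRanges::overlapsAny(gr, annotation$regions$genic,
                                  ignore.strand = TRUE)
    out$region <- ifelse(genic, "genic", "intergenic")
  }
  out
}

# vectorized collapse that tolerates indel rows (returns NA for them)
collapse_class_safe <- function(ref, alt) {
  ok <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  out <- rep(NA_character_, length(ref))
  if (any(ok)) out[ok] <- collapse_class(ref[ok], alt[ok])
  out
}

#' Classify plants by clustered-SNV presence and compare mutation load
#'
#' Plants with at least one cluster call form group 1, the remaining
#' ABE plants group 2.  Three one-tailed Wilcoxon comparisons
#' (group 1 > group 2) are run on SNV count, A>G count and A>G
#' percentage, and the genic fraction of clustered SNVs is contrasted
#' with the genic fraction of all A>G SNVs.
#'
#' @param cluster_calls named list (by plant) of cluster-call
#'   data.frames from [detect_dna_clusters()].
#' @param spectra cohort spectrum table ([spectrum_table()]) restricted
#'   to ABE plants.
#' @param consensus_sets named list of the same plants' consensus sets
#'   (for the genic-fraction contrast); optional.
#' @param annotation optional `AnnotationSet` for genic fractions.
#' @return list: `groups` (plant_id, group), `comparisons`
#'   (metric/W/pvalue/stars data.frame or NULL when a group is empty),
#'   `genic_fraction` (two-column table, NULL without annotation).
#' @export
classify_cluster_groups <- function(cluster_calls, spectra,
                                    consensus_sets = NULL,
                                    annotation = NULL) {
  plants <- spectra$plant_id
  has_cluster <- vapply(plants, function(p) {
    cc <- cluster_calls[[p]]
    !is.null(cc) && nrow(cc) > 0L
  }, logical(1))
  groups <- data.frame(plant_id = plants,
                       group = ifelse(has_cluster, "group1", "group2"),
                       stringsAsFactors = FALSE)
  comparisons <- NULL
  if (any(has_cluster) && any(!has_cluster)) {
    comparisons <- completeness_effect(spectra, plants[has_cluster],
                                       plants[!has_cluster],
                                       "group1", "group2")
  }
  genic_fraction <- NULL
  if (!is.null(annotation) && !is.null(consensus_sets)) {
    all_ag <- do.call(rbind, lapply(consensus_sets, function(s) {
      s <- s[s$vtype == "SNV", , drop = FALSE]
      s[collapse_class_safe(s$ref, s$alt) %in% "A>G", , drop = FALSE]
    }))
    clustered <- do.call(rbind, lapply(names(cluster_calls), function(p) {
      cc <- cluster_calls[[p]]
      if (is.null(cc) || !nrow(cc)) return(NULL)
      pos <- as.integer(unlist(strsplit(cc$members, ",")))
      data.frame(chrom = rep(cc$chrom, cc$n_members), pos = pos,
                 stringsAsFactors = FALSE)
    }))
    frac_genic <- function(df) {
      if (is.null(df) || !nrow(df)) return(NA_real_)
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$pos, width = 1L))
      mean(IRanges::overlapsAny(gr, annotation$regions$genic,
                                ignore.strand = TRUE))
    }
    genic_fraction <- data.frame(
      set = c("clustered_AG", "all_AG"),
      genic_fraction = c(frac_genic(clustered), frac_genic(all_ag)),
      stringsAsFactors = FALSE)
  }
  list(groups = groups, comparisons = comparisons,
       genic_fraction = genic_fraction)
}
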