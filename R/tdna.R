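# T-DNA integrity and copy number from coverage tracks, and the
# sibling-plant shared/unique SNV partition with temporal stage
# attribution.

#' Default T-DNA feature map
#'
#' Synthetic construct layout used by the simulator: left border,
#' promoter, Cas module, TadA module, NLS, terminator, right border
#' (1-based bp over the T-DNA sequence).
#'
#' @return data.frame with `feature`, `start`, `end`.
#' @export
tdna_feature_map <- function() {
  data.frame(
    feature = c("LB", "promoter", "Cas", "TadA", "NLS", "terminator", "RB"),
    start = c(1L, 201L, 2201L, 6301L, 6801L, 6901L, 7201L),
    end = c(200L, 2200L, 6300L, 6800L, 6900L, 7200L, 7400L),
    stringsAsFactors = FALSE)
}

#' T-DNA fragment integrity from a coverage track
#'
#' A feature is called missing when its mean coverage falls below
#' `min_frac` of the mean coverage over the whole LB..RB span.  A plant
#' with zero overall coverage is flagged "no insertion".
#'
#' @param coverage data.frame with `pos`, `depth` over the T-DNA.
#' @param features feature map data.frame (see [tdna_feature_map()]).
#' @param min_frac presence threshold (default 0.1).
#' @return list with `features` (data.frame: `feature`, `mean_cov`,
#'   `status`), `status` ("complete", "partial" or "no_insertion") and
#'   `overall_mean`.
#' @export
tdna_integrity <- function(coverage, features = tdna_feature_map(),
                           min_frac = 0.1) {
  bad <- setdiff(features$feature,
                 c("LB", "promoter", "Cas", "TadA", "NLS", "terminator",
                   "RB"))
  if (length(bad))
    stop("unknown T-DNA feature(s): ", paste(bad, collapse = ", "))
  lb <- min(features$start)
  rb <- max(features$end)
  span <- coverage[coverage$pos >= lb & coverage$pos <= rb, , drop = FALSE]
  overall <- mean(span$depth)
  per_feat <- vapply(seq_len(nrow(features)), function(i) {
    sel <- span$pos >= features$start[i] & span$pos <= features$end[i]
    mean(span$depth[sel])
  }, numeric(1))
  if (!is.finite(overall) || overall == 0) {
    return(list(features = data.frame(feature = features$feature,
                                      mean_cov = per_feat,
                                      status = "missing",
                                      stringsAsFactors = FALSE),
                status = "no_insertion", overall_mean = 0))
  }
  status <- ifelse(per_feat < min_frac * overall, "missing", "present")
  list(features = data.frame(feature = features$feature,
                             mean_cov = per_feat, status = status,
                             stringsAsFactors = FALSE),
       status = if (any(status == "missing")) "partial" else "complete",
       overall_mean = overall)
}

#' T-DNA copy number from relative coverage
#'
#' For primary transformants (T0, hemizygous insertions) the copy
#' number is the mean T-DNA coverage divided by half the genome mean
#' coverage.
#'
#' @param tdna_mean_cov mean coverage over LB..RB.
#' @param genome_mean_cov genome-wide mean coverage (> 0).
#' @return list with `copies` (real) and `copies_rounded`.
#' @export
tdna_copy_number <- function(tdna_mean_cov, genome_mean_cov) {
  if (genome_mean_cov <= 0) stop("genome_mean_cov must be > 0")
  copies <- tdna_mean_cov / (genome_mean_cov / 2)
  list(copies = copies, copies_rounded = as.integer(round(copies)))
}

#' Partition SNVs of two sibling plants into unique/common sets
#'
#' Plants regenerated from the same callus share the mutations that
#' arose before their progenitor cell divided; the partition separates
#' those common variants from each plant's unique ones and attaches a
#' spectrum summary per set.
#'
#' @param snvs_a,snvs_b consensus data.frames for the two plants.
#' @param callus_a,callus_b callus identifiers; must match unless
#'   `force = TRUE`.
#' @param force allow partitioning plants from different calli.
#' @return list of class `SiblingPartition`: `unique_a`, `unique_b`,
#'   `common` (data.frames), `spectra` (3-row spectrum table labelled
#'   set1/set2/overlap), `plant_a`, `plant_b`.
#' @export
partition_siblings <- function(snvs_a, snvs_b, callus_a = NULL,
                               callus_b = NULL, force = FALSE) {
  if (!force && !is.null(callus_a) && !is.null(callus_b) &&
      (is.na(callus_a) || is.na(callus_b) || callus_a != callus_b))
    stop("plants are not from the same callus (use force = TRUE to override)")
  a <- with_keys(snvs_a)
  b <- with_keys(snvs_b)
  common_keys <- intersect(a$key, b$key)
  unique_a <- a[!(a$key %in% common_keys), , drop = FALSE]
  unique_b <- b[!(b$key %in% common_keys), , drop = FALSE]
  common <- a[a$key %in% common_keys, , drop = FALSE]
  stopifnot(length(intersect(unique_a$key, common$key)) == 0L,
            length(intersect(unique_b$key, common$key)) == 0L)
  spectra <- rbind(spectrum_summary(unique_a, "set1"),
                   spectrum_summary(unique_b, "set2"),
                   spectrum_summary(common, "overlap"))
  names(spectra)[1] <- "set"
  structure(list(unique_a = unique_a, unique_b = unique_b,
                 common = common, spectra = spectra,
                 plant_a = if (nrow(a)) a$plant_id[1] else NA_character_,
                 plant_b = if (nrow(b)) b$plant_id[1] else NA_character_),
            class = "SiblingPartition")
}

#' Temporal stage attribution for a sibling partition
#'
#' Common SNVs predate the first division of the transformed callus
#' cell (stages 1-2, before/at T-DNA integration); unique SNVs arise
#' after (stage 3).  Reports the A>G percentage per set; across a list
#' of partitions, [stage_ag_test()] contrasts unique vs common.
#'
#' @param partition `SiblingPartition` from [partition_siblings()].
#' @return data.frame with `set`, `stage`, `n_snvs`, `pct_AG`.
#' @export
stage_attribution <- function(partition) {
  sp <- partition$spectra
  data.frame(set = sp$set,
             stage = c("stage3", "stage3", "stage1_2"),
             n_snvs = sp$n_snvs, pct_AG = sp$pct_AG,
             stringsAsFactors = FALSE)
}

#' One-tailed test that unique-set A>G percentage exceeds the common set
#'
#' @param partitions list of `SiblingPartition` objects.
#' @return list: per-pair table `pairs` and, when at least two
#'   non-missing values per side exist, the [group_compare()] result.
#' @export
stage_ag_test <- function(partitions) {
  rows <- lapply(partitions, function(p) {
    st <- stage_attribution(p)
    data.frame(plant_a = p$plant_a, plant_b = p$plant_b,
               pct_AG_unique = mean(st$pct_AG[st$stage == "stage3"],
                                    na.rm = TRUE),
               pct_AG_common = st$pct_AG[st$stage == "stage1_2"],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  test <- NULL
  ua <- pairs$pct_AG_unique[!is.na(pairs$pct_AG_unique)]
  co <- pairs$pct_AG_common[!is.na(pairs$pct_AG_common)]
  if (length(ua) >= 1L && length(co) >= 1L)
    test <- group_compare(ua, co, "greater")
  list(pairs = pairs, test = test)
}

#' Compare mutation load between plants grouped by a T-DNA property
#'
#' Runs three one-tailed Wilcoxon comparisons (group A > group B) on
#' the number of SNVs, the number of A>G SNVs and the A>G percentage —
#' used both for complete-vs-partial insertions and for single-vs-multi
#' copy grouping.
#'
#' @param spectra spectrum table ([spectrum_table()]).
#' @param group_a,group_b character vectors of plant ids.
#' @param label_a,label_b group labels for the output.
#' @return data.frame with one row per metric: group means, `W`,
#'   `pvalue`, `stars`; NULL rows are NA when a group is empty.
#' @export
completeness_effect <- function(spectra, group_a, group_b,
                                label_a = "complete",
                                label_b = "partial") {
  metrics <- c(n_snvs = "n_snvs", n_AG = "n_AG", pct_AG = "pct_AG")
  a <- spectra[spectra$plant_id %in% group_a, , drop = FALSE]
  b <- spectra[spectra$plant_id %in% group_b, , drop = FALSE]
  rows <- lapply(names(metrics), function(m) {
    va <- a[[metrics[[m]]]]
    vb <- b[[metrics[[m]]]]
    if (!nrow(a) || !nrow(b)) {
      return(data.frame(metric = m, group_a = label_a, group_b = label_b,
                        mean_a = NA_real_, mean_b = NA_real_, W = NA_real_,
                        pvalue = NA_real_, stars = NA_character_,
                        stringsAsFactors = FALSE))
    }
    gc <- group_compare(va, vb, "greater")
    data.frame(metric = m, group_a = label_a, group_b = label_b,
               mean_a = mean(va, na.rm = TRUE),
               mean_b = mean(vb, na.rm = TRUE),
               W = gc$W, pvalue = gc$pvalue, stars = gc$stars,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
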