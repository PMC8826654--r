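# Variant-confidence pipeline: multi-caller intersection, background
# subtraction, the binomial homozygosity test, recurrence analysis and
# pairwise plant overlap.

#' Intersect variant calls across callers
#'
#' Keeps a variant when its normalized key is reported by at least
#' `min_snv_callers` callers (SNVs) or `min_indel_callers` callers
#' (indels), mirroring the rule "SNVs identified by all three callers
#' and indels identified by two".  Zygosity is decided by majority vote
#' among the supporting callers, with ties resolved to heterozygous.
#'
#' @param callsets either a single data.frame of calls for one plant
#'   carrying a `caller_id` column, or a list of per-caller data.frames.
#' @param min_snv_callers,min_indel_callers minimum number of supporting
#'   callers per variant type.
#' @return data.frame (the consensus set): one row per variant with
#'   columns `plant_id`, `chrom`, `pos`, `ref`, `alt`, `vtype`,
#'   `zygosity`, `n_callers`, `callers`, `key`.
#' @export
intersect_callers <- function(callsets, min_snv_callers = 3L,
                              min_indel_callers = 2L) {
  if (is.data.frame(callsets)) calls <- callsets
  else calls <- do.call(rbind, callsets)
  if (is.null(calls) || nrow(calls) == 0L) return(empty_consensus())
  stopifnot_cols(calls, c("plant_id", "caller_id", "chrom", "pos", "ref",
                          "alt", "vtype", "zygosity"), "callset")
  if (length(unique(calls$plant_id)) > 1L)
    stop("intersect_callers expects calls from a single plant")
  calls <- with_keys(calls)
  # de-duplicate within caller (warn once if needed)
  dup <- duplicated(paste(calls$caller_id, calls$key))
  if (any(dup)) {
    warning(sum(dup), " duplicate key(s) within a caller removed",
            call. = FALSE)
    calls <- calls[!dup, , drop = FALSE]
  }
  supp <- split(seq_len(nrow(calls)), calls$key)
  keep <- vapply(supp, function(idx) {
    need <- if (calls$vtype[idx[1]] == "SNV") min_snv_callers
            else min_indel_callers
    length(idx) >= need
  }, logical(1))
  supp <- supp[keep]
  if (!length(supp)) return(empty_consensus())
  rows <- lapply(supp, function(idx) {
    first <- calls[idx[1], , drop = FALSE]
    n_hom <- sum(calls$zygosity[idx] == "hom")
    n_het <- sum(calls$zygosity[idx] == "het")
    first$zygosity <- if (n_hom > n_het) "hom" else "het"
    first$n_callers <- length(idx)
    first$callers <- paste(sort(calls$caller_id[idx]), collapse = ",")
    first
  })
  out <- do.call(rbind, rows)
  out$caller_id <- NULL
  out <- out[order(match(out$chrom, unique(calls$chrom)), out$pos,
                   out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_consensus <- function() {
  df <- empty_calls()
  df$caller_id <- NULL
  df$ad_ref <- NULL
  df$ad_alt <- NULL
  df$n_callers <- integer(0)
  df$callers <- character(0)
  df$key <- character(0)
  df
}

#' Remove background variants from a consensus set
#'
#' All variants observed in any of the designated background plants
#' (e.g. the wild-type Kitaake panel) are pooled into one union and
#' removed by key, regardless of zygosity.
#'
#' @param consensus consensus data.frame for one plant.
#' @param background_sets list of consensus data.frames (one per
#'   background plant), or a single pooled data.frame.
#' @return the filtered consensus data.frame.
#' @export
subtract_background <- function(consensus, background_sets) {
  if (is.data.frame(background_sets)) background_sets <- list(background_sets)
  if (!length(background_sets)) {
    warning("empty background list; returning consensus unchanged",
            call. = FALSE)
    return(consensus)
  }
  bg_keys <- unique(unlist(lapply(background_sets,
                                  function(b) with_keys(b)$key)))
  consensus <- with_keys(consensus)
  out <- consensus[!(consensus$key %in% bg_keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep heterozygous variants only
#'
#' @param consensus consensus data.frame.
#' @return data.frame restricted to `zygosity == "het"`.
#' @export
remove_homozygous <- function(consensus) {
  out <- consensus[consensus$zygosity == "het", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant recurrence across plants
#'
#' Counts, for every variant key, in how many plants it was observed and
#' the zygosity breakdown — the basis of the observation that homozygous
#' mutations tend to recur across plants while heterozygous ones are
#' mostly private.
#'
#' @param consensus_sets named list of per-plant consensus data.frames.
#' @return data.frame with `key`, `chrom`, `pos`, `ref`, `alt`, `vtype`,
#'   `n_plants`, `n_hom`, `n_het`, `plants`.
#' @export
recurrence_table <- function(consensus_sets) {
  if (length(consensus_sets) < 2L)
    stop("recurrence requires at least two plants")
  all <- do.call(rbind, lapply(consensus_sets, with_keys))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(key = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vtype = character(0),
                      n_plants = integer(0), n_hom = integer(0),
                      n_het = integer(0), plants = character(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(all)), all$key)
  rows <- lapply(sp, function(idx) {
    data.frame(key = all$key[idx[1]], chrom = all$chrom[idx[1]],
               pos = all$pos[idx[1]], ref = all$ref[idx[1]],
               alt = all$alt[idx[1]], vtype = all$vtype[idx[1]],
               n_plants = length(unique(all$plant_id[idx])),
               n_hom = sum(all$zygosity[idx] == "hom"),
               n_het = sum(all$zygosity[idx] == "het"),
               plants = paste(sort(unique(all$plant_id[idx])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$n_plants, out$key), , drop = FALSE]
}

#' Exact binomial test for a shared homozygous locus
#'
#' Under the model that the two alleles of a plant mutate independently
#' with per-allele probability p, genotype probabilities at a locus are
#' hom = p^2, het = 2p(1-p), wild type = (1-p)^2.  The per-allele rate
#' is estimated as `p_hat = (2*n_hom + n_het) / (2*n_total)` and the
#' observed number of homozygotes among carriers is compared with the
#' carrier-conditional expectation `P(hom | carrier) = p_hat/(2-p_hat)`
#' by an exact upper-tail binomial test.  Small p-values flag loci whose
#' homozygote excess is incompatible with independent allele mutation,
#' i.e. residual background.
#'
#' @param n_hom,n_het,n_wt genotype counts across the cohort at one
#'   locus; `n_hom >= 1` and `n_hom + n_het >= 1` required.
#' @param alpha flag threshold (default 0.01).
#' @return list with `p_hat`, `p_hom_carrier`, `pvalue` and `flagged`.
#' @export
homozygosity_binomial_test <- function(n_hom, n_het, n_wt, alpha = 0.01) {
  n <- n_hom + n_het + n_wt
  if (n_hom + n_het == 0L) stop("no carriers: test undefined")
  if (n_hom < 1L) stop("n_hom must be >= 1")
  p_hat <- (2 * n_hom + n_het) / (2 * n)
  p0 <- p_hat / (2 - p_hat)
  pv <- stats::binom.test(n_hom, n_hom + n_het, p = p0,
                          alternative = "greater")$p.value
  list(p_hat = p_hat, p_hom_carrier = p0, pvalue = pv,
       flagged = pv < alpha)
}

#' Binomial homozygosity screen over all recurrent homozygous loci
#'
#' @param consensus_sets named list of per-plant consensus data.frames.
#' @param cohort_size number of plants in the cohort (defaults to
#'   `length(consensus_sets)`).
#' @param alpha flag threshold.
#' @return data.frame with one row per locus carrying at least one
#'   homozygous call: genotype counts, `p_hat`, `pvalue`, `flagged`.
#' @export
homozygosity_screen <- function(consensus_sets,
                                cohort_size = length(consensus_sets),
                                alpha = 0.01) {
  rec <- recurrence_table(consensus_sets)
  rec <- rec[rec$n_hom >= 1L, , drop = FALSE]
  if (!nrow(rec)) {
    rec$n_wt <- integer(0); rec$p_hat <- numeric(0)
    rec$pvalue <- numeric(0); rec$flagged <- logical(0)
    return(rec)
  }
  rec$n_wt <- cohort_size - rec$n_hom - rec$n_het
  res <- Map(homozygosity_binomial_test, rec$n_hom, rec$n_het, rec$n_wt,
             alpha = alpha)
  rec$p_hat <- vapply(res, `[[`, numeric(1), "p_hat")
  rec$pvalue <- vapply(res, `[[`, numeric(1), "pvalue")
  rec$flagged <- vapply(res, `[[`, logical(1), "flagged")
  rownames(rec) <- NULL
  rec
}

#' Pairwise shared-SNV counts between plants
#'
#' Entry (i, j) is the number of SNV keys shared by plants i and j after
#' background and homozygote removal.  With n plants there are
#' n(n-1)/2 unordered comparisons (57 plants give 1596).
#'
#' @param consensus_sets named list of per-plant consensus data.frames.
#' @param snv_only count SNVs only (default TRUE).
#' @return symmetric integer matrix with the per-plant SNV counts on the
#'   diagonal; attribute `n_comparisons` holds n(n-1)/2.
#' @export
pairwise_overlap <- function(consensus_sets, snv_only = TRUE) {
  n <- length(consensus_sets)
  if (n < 2L) stop("pairwise overlap requires at least two plants")
  ids <- names(consensus_sets)
  if (is.null(ids)) ids <- paste0("plant", seq_len(n))
  keysets <- lapply(consensus_sets, function(s) {
    s <- with_keys(s)
    if (snv_only) s <- s[s$vtype == "SNV", , drop = FALSE]
    unique(s$key)
  })
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(keysets[[i]])
    if (i < n) for (j in seq((i + 1L), n)) {
      ov <- length(intersect(keysets[[i]], keysets[[j]]))
      m[i, j] <- ov
      m[j, i] <- ov
    }
  }
  attr(m, "n_comparisons") <- n * (n - 1L) / 2L
  m
}

#' Full variant-confidence chain for one plant
#'
#' Convenience wrapper: caller intersection, background subtraction and
#' homozygote removal in the order used throughout the analysis.
#'
#' @param callsets per-caller calls for one plant (list or data.frame).
#' @param background_sets background consensus sets (see
#'   [subtract_background()]); NULL to skip.
#' @param drop_hom remove homozygous variants (default TRUE).
#' @inheritParams intersect_callers
#' @return filtered consensus data.frame.
#' @export
consensus_chain <- function(callsets, background_sets = NULL,
                            drop_hom = TRUE, min_snv_callers = 3L,
                            min_indel_callers = 2L) {
  cons <- intersect_callers(callsets, min_snv_callers, min_indel_callers)
  if (!is.null(background_sets) && length(background_sets))
    cons <- subtract_background(cons, background_sets)
  if (drop_hom) cons <- remove_homozygous(cons)
  cons
}
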