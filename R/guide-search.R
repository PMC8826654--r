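# sgRNA target-site search: full-spacer and seed-constrained mismatch
# scans over both strands, on-target masking, and variant-at-site
# counting.  The vectorized scanner examines every genomic position, so
# it is exhaustive by construction; a deliberately naive per-position
# oracle ships alongside for testing.

spacer_len <- function(guide) nchar(guide$spacer)

# Scan one strand of one chromosome.  `seq_int` is the chromosome as a
# vector of utf8 codes.  Returns a data.frame of window starts with full
# and seed mismatch counts for windows whose PAM matches.
scan_strand <- function(seq_int, spacer, pam_pattern, seed_len) {
  k <- nchar(spacer)
  pl <- nchar(pam_pattern)
  L <- length(seq_int)
  n <- L - (k + pl) + 1L
  if (n < 1L) {
    return(data.frame(start = integer(0), mm = integer(0),
                      seed_mm = integer(0)))
  }
  sp <- utf8ToInt(spacer)
  nint <- utf8ToInt("N")
  mm <- integer(n)
  seed_mm <- integer(n)
  seed_from <- k - seed_len + 1L
  for (j in seq_len(k)) {
    xs <- seq_int[j:(j + n - 1L)]
    d <- (xs != sp[j]) | (xs == nint)
    mm <- mm + d
    if (j >= seed_from) seed_mm <- seed_mm + d
  }
  pam_ok <- rep(TRUE, n)
  pam_chars <- strsplit(pam_pattern, "", fixed = TRUE)[[1]]
  for (j in seq_len(pl)) {
    allowed <- utf8ToInt(paste(IUPAC[[pam_chars[j]]], collapse = ""))
    xs <- seq_int[(k + j):(k + j + n - 1L)]
    pam_ok <- pam_ok & (xs %in% allowed)
  }
  data.frame(start = which(pam_ok), mm = mm[pam_ok],
             seed_mm = seed_mm[pam_ok])
}

scan_genome <- function(genome, guide, seed_len) {
  k <- spacer_len(guide)
  pl <- nchar(guide$pam_pattern)
  out <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    fwd_int <- utf8ToInt(s)
    L <- length(fwd_int)
    f <- scan_strand(fwd_int, guide$spacer, guide$pam_pattern, seed_len)
    if (nrow(f)) {
      f$chrom <- chrom; f$strand <- "+"
      f$end <- f$start + k - 1L
      f$pam_start <- f$end + 1L
      f$pam_end <- f$end + pl
      out[[length(out) + 1L]] <- f
    }
    rev_int <- utf8ToInt(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
    r <- scan_strand(rev_int, guide$spacer, guide$pam_pattern, seed_len)
    if (nrow(r)) {
      # window start i on the reverse complement: protospacer occupies
      # forward positions (L-i-k+2)..(L-i+1); PAM lies 5' of it.
      r$chrom <- chrom; r$strand <- "-"
      start_fwd <- L - (r$start + k - 1L) + 1L
      r$end <- L - r$start + 1L
      r$pam_start <- start_fwd - pl
      r$pam_end <- start_fwd - 1L
      r$start <- start_fwd
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      pam_start = integer(0), pam_end = integer(0),
                      mm = integer(0), seed_mm = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(match(res$chrom, names(genome)), res$start,
            res$strand), , drop = FALSE]
}

format_sites <- function(res, guide) {
  data.frame(chrom = res$chrom, start = res$start, end = res$end,
             strand = res$strand, pam_start = res$pam_start,
             pam_end = res$pam_end,
             n_mismatches = res$mm, seed_mismatches = res$seed_mm,
             guide = rep(guide$name, nrow(res)),
             is_on_target = res$mm == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find guide target sites under a full-spacer mismatch budget
#'
#' Reports every position, on either strand, where the PAM matches the
#' guide's IUPAC PAM pattern and the protospacer is within `max_mm`
#' Hamming mismatches of the 20-nt spacer.  A genome N never matches.
#'
#' @param genome named `DNAStringSet` (or character vector of
#'   chromosome sequences).
#' @param guide list or one-row data.frame with `name`, `spacer`,
#'   `pam_pattern`.
#' @param max_mm maximum full-spacer mismatches (0..spacer length).
#' @param seed_len seed length used for the reported
#'   `seed_mismatches` column (PAM-proximal 3' end of the spacer).
#' @return data.frame of target sites sorted by (chrom, start):
#'   `chrom`, `start`, `end` (1-based inclusive protospacer span),
#'   `strand`, `pam_start`, `n_mismatches`, `seed_mismatches`, `guide`,
#'   `is_on_target`.
#' @export
find_sites_full <- function(genome, guide, max_mm = 6L, seed_len = 12L) {
  guide <- as.list(guide)
  check_guide(guide, max_mm)
  res <- scan_genome(as_genome(genome), guide, seed_len)
  format_sites(res[res$mm <= max_mm, , drop = FALSE], guide)
}

#' Find guide target sites under a seed-constrained mismatch budget
#'
#' Requires the PAM to match and the PAM-proximal seed (the `seed_len`
#' 3'-most spacer bases) to match with at most `max_seed_mm`
#' mismatches; positions outside the seed are unconstrained.  Full
#' spacer mismatch counts are still reported.
#'
#' @inheritParams find_sites_full
#' @param max_seed_mm maximum mismatches inside the seed.
#' @return data.frame of target sites (see [find_sites_full()]).
#' @export
find_sites_seed <- function(genome, guide, seed_len = 12L,
                            max_seed_mm = 2L) {
  guide <- as.list(guide)
  check_guide(guide, 0L)
  if (seed_len > spacer_len(guide))
    stop("seed_len exceeds spacer length")
  res <- scan_genome(as_genome(genome), guide, seed_len)
  format_sites(res[res$seed_mm <= max_seed_mm, , drop = FALSE], guide)
}

check_guide <- function(guide, max_mm) {
  if (grepl("N", guide$spacer, fixed = TRUE))
    stop("spacer must not contain N")
  if (grepl("[^ACGT]", guide$spacer))
    stop("spacer alphabet must be ACGT")
  if (max_mm < 0L || max_mm > spacer_len(guide))
    stop("max_mm outside 0..spacer length")
  invisible(guide)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(unlist(genome))
}

#' Naive reference scanner for guide sites
#'
#' Character-by-character scan of every window on both strands; slow but
#' transparently correct.  Used as the oracle against which the
#' vectorized scanner is verified.
#'
#' @inheritParams find_sites_full
#' @param mode `"full"` or `"seed"`.
#' @param max_seed_mm seed budget in seed mode.
#' @return data.frame of target sites (see [find_sites_full()]).
#' @export
find_sites_naive <- function(genome, guide, max_mm = 6L, mode = "full",
                             seed_len = 12L, max_seed_mm = 2L) {
  guide <- as.list(guide)
  genome <- as_genome(genome)
  k <- spacer_len(guide)
  pam <- strsplit(guide$pam_pattern, "", fixed = TRUE)[[1]]
  pl <- length(pam)
  sp <- strsplit(guide$spacer, "", fixed = TRUE)[[1]]
  seed_from <- k - seed_len + 1L
  hits <- list()
  for (chrom in names(genome)) {
    fwd <- as.character(genome[[chrom]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      i <- 1L
      while (i + k + pl - 1L <= L) {
        ok_pam <- TRUE
        for (j in seq_len(pl)) {
          b <- sc[i + k + j - 1L]
          if (!(b %in% IUPAC[[pam[j]]])) { ok_pam <- FALSE; break }
        }
        if (ok_pam) {
          mm <- 0L; seed_mm <- 0L
          for (j in seq_len(k)) {
            b <- sc[i + j - 1L]
            if (b != sp[j] || b == "N") {
              mm <- mm + 1L
              if (j >= seed_from) seed_mm <- seed_mm + 1L
            }
          }
          keep <- if (mode == "full") mm <= max_mm else seed_mm <= max_seed_mm
          if (keep) {
            if (strand == "+") {
              hits[[length(hits) + 1L]] <-
                data.frame(chrom = chrom, start = i, end = i + k - 1L,
                           strand = strand, pam_start = i + k,
                           pam_end = i + k + pl - 1L,
                           mm = mm, seed_mm = seed_mm)
            } else {
              st <- L - (i + k - 1L) + 1L
              hits[[length(hits) + 1L]] <-
                data.frame(chrom = chrom, start = st, end = L - i + 1L,
                           strand = strand, pam_start = st - pl,
                           pam_end = st - 1L,
                           mm = mm, seed_mm = seed_mm)
            }
          }
        }
        i <- i + 1L
      }
    }
  }
  if (!length(hits)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      pam_start = integer(0), pam_end = integer(0),
                      mm = integer(0), seed_mm = integer(0))
  } else {
    res <- do.call(rbind, hits)
    res <- res[order(match(res$chrom, names(genome)), res$start,
                     res$strand), , drop = FALSE]
  }
  format_sites(res, guide)
}

#' Partition variants into on-target and off-target sets
#'
#' A variant is on-target when its position falls within the
#' protospacer-plus-PAM span (extended by `flank`) of any zero-mismatch
#' site of the plant's own guides.
#'
#' @param variants consensus data.frame with `chrom` and `pos`.
#' @param sites site data.frame from [find_sites_full()] (any mismatch
#'   budget; only zero-mismatch sites are used for masking).
#' @param flank extra bases on each side of the site span (default 0).
#' @return list with elements `on_target` and `off_target`.
#' @export
mask_on_target <- function(variants, sites, flank = 0L) {
  if (is.null(sites) || nrow(sites) == 0L)
    return(list(on_target = variants[0, , drop = FALSE],
                off_target = variants))
  on <- sites[sites$n_mismatches == 0L, , drop = FALSE]
  if (!nrow(on) || !nrow(variants))
    return(list(on_target = variants[0, , drop = FALSE],
                off_target = variants))
  # span covers protospacer plus full PAM on either strand
  span_start <- pmin(on$start, on$pam_start) - flank
  span_end <- pmax(on$end, on$pam_end) + flank
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(on))) {
    hit <- hit | (variants$chrom == on$chrom[i] &
                    variants$pos >= span_start[i] &
                    variants$pos <= span_end[i])
  }
  list(on_target = variants[hit, , drop = FALSE],
       off_target = variants[!hit, , drop = FALSE])
}

#' Count variants falling inside guide sites, by mismatch stratum
#'
#' @param variants data.frame with `chrom`, `pos` (SNVs expected).
#' @param sites site data.frame (typically off-target sites).
#' @return data.frame with one row per mismatch level: `n_mismatches`,
#'   `n_sites`, `n_variants`.
#' @export
count_variants_at_sites <- function(variants, sites) {
  levs <- sort(unique(sites$n_mismatches))
  rows <- lapply(levs, function(m) {
    ss <- sites[sites$n_mismatches == m, , drop = FALSE]
    cnt <- 0L
    if (nrow(variants)) {
      inside <- rep(FALSE, nrow(variants))
      for (i in seq_len(nrow(ss))) {
        inside <- inside | (variants$chrom == ss$chrom[i] &
                              variants$pos >= ss$start[i] &
                              variants$pos <= ss$end[i])
      }
      cnt <- sum(inside)
    }
    data.frame(n_mismatches = m, n_sites = nrow(ss), n_variants = cnt)
  })
  if (!length(rows)) {
    return(data.frame(n_mismatches = integer(0), n_sites = integer(0),
                      n_variants = integer(0)))
  }
  do.call(rbind, rows)
}

#' Write target sites as BED6
#'
#' Name is `guide:mismatches`, score the mismatch count.
#'
#' @param sites site data.frame.
#' @param path output BED file.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- character(0)
  if (nrow(sites)) {
    lines <- paste(sites$chrom, sites$start - 1L, sites$end,
                   paste0(sites$guide, ":", sites$n_mismatches),
                   sites$n_mismatches, sites$strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
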