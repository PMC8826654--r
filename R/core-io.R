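# Readers and writers for the standard formats consumed by the pipeline:
# VCF (via VariantAnnotation), FASTA (via Biostrings), GFF3/GTF (via
# rtracklayer), and the plain TSV formats used for pileups, cohort
# designs and coverage tracks.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with upper-case sequences; the
#'   per-chromosome lengths are available via `width()`.
#' @export
read_fasta <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(names(gs)))
    stop("duplicate chromosome names in ", path)
  Biostrings::DNAStringSet(toupper(gs))
}

#' Write a genome to FASTA
#'
#' @param genome named `DNAStringSet` (or named character vector).
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

genome_seqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file with `VariantAnnotation::readVcf`, splits
#' multi-allelic records so that each returned row carries one ALT
#' allele, and derives zygosity from the GT field (`0/1` -> het,
#' `1/1` -> hom).  When GT is absent or uninformative for an allele the
#' alt-read fraction is used instead: >= 0.8 hom, 0.2-0.8 het, < 0.2
#' dropped with a warning.
#'
#' @param path VCF file (single-sample).
#' @param plant_id,caller_id identifiers stored on every returned row;
#'   default to values parsed from `##mutscape_plant` / caller header
#'   lines when present, else the sample name and file name.
#' @return data.frame with columns `plant_id`, `caller_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `vtype`, `zygosity`, `ad_ref`, `ad_alt`.
#' @export
read_vcf <- function(path, plant_id = NULL, caller_id = NULL) {
  v <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  # provenance meta lines (written by write_vcf); readVcf does not keep
  # arbitrary ##key=value pairs, so scan the raw header
  hdr_lines <- grep("^##", readLines(path, n = 200L), value = TRUE)
  meta_val <- function(name) {
    hit <- grep(paste0("^##", name, "="), hdr_lines, value = TRUE)
    if (length(hit)) sub(paste0("^##", name, "="), "", hit[1]) else NULL
  }
  if (is.null(plant_id))
    plant_id <- meta_val("mutscape_plant") %||%
      colnames(v)[1] %||% basename(path)
  if (is.null(caller_id))
    caller_id <- meta_val("mutscape_caller") %||% basename(path)
  if (length(v) == 0L) {
    out <- empty_calls()
    return(out)
  }
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  rec <- rep(seq_along(v), nalt)
  aidx <- sequence(nalt)
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[rec]
  pos <- BiocGenerics::start(rr)[rec]
  ref <- as.character(VariantAnnotation::ref(v))[rec]
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  geno <- VariantAnnotation::geno(v)
  gt <- if ("GT" %in% names(geno)) geno$GT[, 1L] else rep(NA_character_, length(v))
  ad <- if ("AD" %in% names(geno)) geno$AD[, 1L] else NULL

  n <- length(rec)
  zyg <- character(n)
  ad_ref <- integer(n)
  ad_alt <- integer(n)
  keep <- rep(TRUE, n)
  warned_gt <- FALSE
  for (i in seq_len(n)) {
    r <- rec[i]
    adr <- if (!is.null(ad)) ad[[r]] else NULL
    ad_ref[i] <- if (!is.null(adr) && length(adr) >= 1L) adr[1L] else NA_integer_
    ad_alt[i] <- if (!is.null(adr) && length(adr) >= aidx[i] + 1L)
      adr[aidx[i] + 1L] else NA_integer_
    g <- gt[r]
    copies <- NA_integer_
    if (!is.na(g) && g != ".") {
      alleles <- suppressWarnings(
        as.integer(strsplit(g, "[/|]")[[1]]))
      if (!anyNA(alleles)) copies <- sum(alleles == aidx[i])
    }
    if (!is.na(copies) && copies > 0L) {
      zyg[i] <- if (copies >= 2L) "hom" else "het"
    } else {
      # GT missing or does not carry this allele: allele-fraction rule
      if (!warned_gt && (is.na(g) || g == ".")) {
        warning("GT missing in '", path,
                "'; falling back to allele-fraction zygosity rule",
                call. = FALSE)
        warned_gt <- TRUE
      }
      tot <- ad_ref[i] + ad_alt[i]
      frac <- if (!is.na(tot) && tot > 0) ad_alt[i] / tot else NA_real_
      if (is.na(frac) || frac < 0.2) {
        keep[i] <- FALSE
      } else {
        zyg[i] <- if (frac >= 0.8) "hom" else "het"
      }
    }
  }
  if (any(!keep))
    warning(sum(!keep), " allele(s) in '", path,
            "' dropped (no genotype support and alt fraction < 0.2)",
            call. = FALSE)
  out <- data.frame(plant_id = plant_id, caller_id = caller_id,
                    chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, stringsAsFactors = FALSE)
  out$vtype <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                      "SNV", "indel")
  out$zygosity <- zyg
  out$ad_ref <- ad_ref
  out$ad_alt <- ad_alt
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Write variant calls to a single-sample VCF file
#'
#' Emits a minimal valid VCF 4.2 with GT and AD fields that round-trips
#' through [read_vcf()].  Calls must be sorted by chromosome (in first
#' appearance order) and position.
#'
#' @param calls data.frame as returned by [read_vcf()].
#' @param path output file.
#' @param sample sample column name; defaults to the plant id.
#' @export
write_vcf <- function(calls, path, sample = NULL) {
  if (nrow(calls) > 0L) {
    ord <- order(match(calls$chrom, unique(calls$chrom)), calls$pos)
    if (!identical(ord, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, pos) before writing")
  }
  if (is.null(sample))
    sample <- if (nrow(calls)) calls$plant_id[1] else "sample"
  plant <- if (nrow(calls)) calls$plant_id[1] else sample
  caller <- if (nrow(calls)) calls$caller_id[1] else "unknown"
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##mutscape_plant=", plant),
    paste0("##mutscape_caller=", caller),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- character(0)
  if (nrow(calls) > 0L) {
    gt <- ifelse(calls$zygosity == "hom", "1/1", "0/1")
    adr <- ifelse(is.na(calls$ad_ref), 0L, calls$ad_ref)
    ada <- ifelse(is.na(calls$ad_alt), 0L, calls$ad_alt)
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", ".", "GT:AD",
                  paste0(gt, ":", adr, ",", ada), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- annotation ------------------------------------------------------------

#' Read a gene annotation and derive region classes
#'
#' Accepts GFF3 or GTF (auto-detected from the attribute-column syntax)
#' and returns the gene/exon intervals together with the four derived
#' region classes: genic (gene spans including introns), exonic,
#' intronic (gene minus exon) and intergenic (genome minus genes).
#'
#' @param path GFF3/GTF file.
#' @param genome `DNAStringSet` reference; defines chromosome lengths.
#' @return An object of class `AnnotationSet`: a list with `genes`,
#'   `exons` ([GenomicRanges::GRanges]) and `regions` (named list of
#'   reduced `GRanges` for genic/exonic/intronic/intergenic).
#' @export
read_annotation <- function(path, genome) {
  fmt <- sniff_gff_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  seqlen <- genome_seqlengths(genome)
  bad <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                 names(seqlen))
  if (length(bad))
    stop("annotation references unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  over_end <- BiocGenerics::end(gr) > seqlen[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(over_end))
    stop("annotation feature(s) extend beyond chromosome end at line(s): ",
         paste(head(which(over_end), 5), collapse = ", "))
  annotation_set(genes, exons, genome)
}

sniff_gff_format <- function(path) {
  lines <- readLines(path, n = 200L)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return("gff3")
  attr9 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][9]
  if (is.na(attr9)) return("gff3")
  if (grepl("=", attr9, fixed = TRUE)) "gff3" else "gtf"
}

#' Build an AnnotationSet from gene and exon intervals
#'
#' @param genes,exons `GRanges` of gene and exon features.
#' @param genome `DNAStringSet` reference (for chromosome lengths).
#' @return `AnnotationSet` list; see [read_annotation()].
#' @export
annotation_set <- function(genes, exons, genome) {
  seqlen <- genome_seqlengths(genome)
  si <- GenomeInfoDb::Seqinfo(names(seqlen), unname(seqlen))
  fix <- function(gr) {
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                 IRanges::ranges(gr),
                                 strand = BiocGenerics::strand(gr))
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqinfo(gr) <- si
    gr
  }
  genes <- fix(genes)
  exons <- fix(exons)
  genic <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  exonic <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  intronic <- GenomicRanges::setdiff(genic, exonic, ignore.strand = TRUE)
  intergenic <- GenomicRanges::gaps(genic)
  intergenic <- intergenic[BiocGenerics::strand(intergenic) == "*"]
  structure(list(genes = genes, exons = exons,
                 regions = list(genic = genic, exonic = exonic,
                                intronic = intronic,
                                intergenic = intergenic),
                 seqlengths = seqlen),
            class = "AnnotationSet")
}

#' Genome fraction covered by each region class
#'
#' @param annotation `AnnotationSet`.
#' @return named numeric vector of fractions over
#'   genic/exonic/intronic/intergenic.
#' @export
region_fractions <- function(annotation) {
  gl <- sum(as.numeric(annotation$seqlengths))
  vapply(annotation$regions,
         function(gr) sum(as.numeric(BiocGenerics::width(gr))) / gl,
         numeric(1))
}

#' Write gene/exon annotation to GFF3
#'
#' @param annotation `AnnotationSet`.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  fmt_row <- function(gr, type, id, parent = NULL) {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    paste(as.character(GenomeInfoDb::seqnames(gr)), "mutscape", type,
          BiocGenerics::start(gr), BiocGenerics::end(gr), ".",
          as.character(BiocGenerics::strand(gr)), ".", attrs, sep = "\t")
  }
  lines <- "##gff-version 3"
  if (length(genes)) {
    gid <- if (!is.null(genes$ID)) genes$ID else
      sprintf("gene%04d", seq_along(genes))
    lines <- c(lines, fmt_row(genes, "gene", gid))
    if (length(exons)) {
      par <- if (!is.null(exons$Parent)) as.character(unlist(exons$Parent)) else
        gid[GenomicRanges::findOverlaps(exons, genes, type = "within",
                                        select = "first")]
      eid <- sprintf("%s.exon%d", par, stats::ave(seq_along(exons), par,
                                                  FUN = seq_along))
      lines <- c(lines, fmt_row(exons, "exon", eid, par))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- TSV formats -----------------------------------------------------------

#' Read / write per-base pileup counts
#'
#' TSV with columns `plant_id`, `source` (DNA/RNA), `chrom`, `pos`,
#' `ref`, `nA`, `nC`, `nG`, `nT`.
#'
#' @param path TSV file.
#' @return data.frame of pileup counts.
#' @export
read_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("plant_id", "source", "chrom", "pos",
                       "ref", "nA", "nC", "nG", "nT"), path)
  df
}

#' @rdname read_pileup
#' @param pileup data.frame of pileup counts.
#' @export
write_pileup <- function(pileup, path) {
  write_tsv(pileup, path)
}

#' Read / write a cohort design table
#'
#' TSV with one row per plant: `plant_id`, `group`, `editor`, `guides`
#' (comma-separated guide names or empty), `callus_id`, `tdna_complete`,
#' `tdna_copies`, `expression_rpm`, `rna_sequenced`, `generation`,
#' `transgene`, `expression_tier`.
#'
#' @param path TSV file.
#' @return data.frame with one row per plant.
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(guides = "character",
                                  callus_id = "character"))
  stopifnot_cols(df, c("plant_id", "group", "editor", "guides"), path)
  if (anyDuplicated(df$plant_id))
    stop("duplicate plant_id in design: ", path)
  df
}

#' @rdname read_design
#' @param design data.frame as returned by [read_design()].
#' @export
write_design <- function(design, path) {
  write_tsv(design, path)
}

#' Read guide specifications
#'
#' TSV with columns `name`, `spacer` (20 nt), `pam_pattern` (IUPAC,
#' e.g. NGG or NG) and `editor_id`.
#'
#' @param path TSV file.
#' @return data.frame of guides.
#' @export
read_guides <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("name", "spacer", "pam_pattern"), path)
  bad <- grepl("[^ACGT]", df$spacer)
  if (any(bad))
    stop("spacer contains non-ACGT characters: ",
         paste(df$name[bad], collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
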