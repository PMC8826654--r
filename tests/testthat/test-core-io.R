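test_that("VCF write/read round-trips calls with genotypes and depths", {
  calls <- data.frame(plant_id = "p1", caller_id = "gatk",
                      chrom = c("chr1", "chr1", "chr2"),
                      pos = c(100L, 150L, 30L),
                      ref = c("A", "C", "AT"), alt = c("G", "T", "A"),
                      vtype = c("SNV", "SNV", "indel"),
                      zygosity = c("het", "hom", "het"),
                      ad_ref = c(12L, 0L, 9L), ad_alt = c(10L, 40L, 11L),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  expect_match(lines[grepl("\t100\t", lines)], "0/1:12,10")
  expect_match(lines[grepl("\t150\t", lines)], "1/1:0,40")
  expect_identical(read_vcf(path), calls)
})

test_that("empty call sets produce header-only VCFs that read back empty", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(make_calls(integer(0)), path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_identical(nrow(read_vcf(path)), 0L)
})

test_that("unsorted calls are rejected by write_vcf", {
  calls <- make_calls(c(200L, 100L))
  expect_error(write_vcf(calls, tempfile()), "sorted")
})

test_that("multi-allelic records split into one call per ALT allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    "chr1\t500\t.\tC\tG,T\t.\tPASS\t.\tGT:AD\t1/2:0,9,11"), path)
  calls <- read_vcf(path, plant_id = "p1", caller_id = "c1")
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$alt, c("G", "T"))
  expect_identical(calls$pos, c(500L, 500L))
  expect_identical(calls$zygosity, c("het", "het"))
  expect_identical(calls$ad_alt, c(9L, 11L))
})

test_that("missing GT falls back to the allele-fraction rule with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT:AD\t.:5,35",    # 0.875 -> hom
    "chr1\t20\t.\tA\tC\t.\tPASS\t.\tGT:AD\t.:20,20",   # 0.5   -> het
    "chr1\t30\t.\tA\tT\t.\tPASS\t.\tGT:AD\t.:38,2"),   # 0.05  -> drop
    path)
  w <- capture_warnings(calls <- read_vcf(path, "p1", "c1"))
  expect_true(any(grepl("allele-fraction", w)))
  expect_true(any(grepl("dropped", w)))
  expect_identical(calls$zygosity, c("hom", "het"))
  expect_identical(nrow(calls), 2L)
})

test_that("FASTA reading uppercases and records lengths", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 description text", "acgt", ">c2", "NNAA"), path)
  g <- read_fasta(path)
  expect_identical(names(g), c("c1", "c2"))
  expect_identical(as.character(g[["c1"]]), "ACGT")
  expect_identical(unname(Biostrings::width(g)), c(4L, 4L))
})

test_that("annotation-derived regions follow interval arithmetic", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", paste(rep("A", 30), collapse = "")), fa)
  genome <- read_fasta(fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1",
               "c1\tsrc\texon\t11\t14\t.\t+\t.\tID=g1.e1;Parent=g1"),
             gff)
  ann <- read_annotation(gff, genome)
  reg <- ann$regions
  expect_identical(BiocGenerics::start(reg$intronic), 15L)
  expect_identical(BiocGenerics::end(reg$intronic), 20L)
  expect_identical(BiocGenerics::start(reg$intergenic), c(1L, 21L))
  expect_identical(BiocGenerics::end(reg$intergenic), c(10L, 30L))
})

test_that("empty annotations classify the whole genome as intergenic", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", paste(rep("A", 30), collapse = "")), fa)
  genome <- read_fasta(fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  ann <- read_annotation(gff, genome)
  fr <- region_fractions(ann)
  expect_equal(unname(fr["intergenic"]), 1)
  expect_equal(unname(fr["genic"]), 0)
})

test_that("annotations referencing unknown or out-of-bounds features fail", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", paste(rep("A", 30), collapse = "")), fa)
  genome <- read_fasta(fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "cX\tsrc\tgene\t1\t5\t.\t+\t.\tID=g1"), gff)
  expect_error(read_annotation(gff, genome), "unknown chromosome")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t25\t40\t.\t+\t.\tID=g1"), gff)
  expect_error(read_annotation(gff, genome), "beyond chromosome end")
})

test_that("region classes partition random synthetic genomes exactly", {
  for (seed in c(2, 9)) {
    cfg <- sim_config(genome_length = 5e4, n_chrom = 2L,
                      rna_edit_loci = 5L)
    ga <- simulate_genome(cfg, seed)
    fr <- region_fractions(ga$annotation)
    expect_equal(fr[["genic"]] + fr[["intergenic"]], 1, tolerance = 1e-12)
    expect_equal(fr[["exonic"]] + fr[["intronic"]], fr[["genic"]],
                 tolerance = 1e-12)
  }
})

test_that("annotation GFF3 output round-trips through read_annotation", {
  cfg <- sim_config(genome_length = 5e4, n_chrom = 1L, rna_edit_loci = 5L)
  ga <- simulate_genome(cfg, 4)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ga$annotation, gff)
  back <- read_annotation(gff, ga$genome)
  expect_equal(region_fractions(back), region_fractions(ga$annotation))
  expect_identical(length(back$genes), length(ga$annotation$genes))
})

test_that("variant normalization trims shared affixes and left-shifts", {
  expect_identical(normalize_variant(100L, "AT", "GT"),
                   list(pos = 100L, ref = "A", alt = "G"))
  expect_identical(normalize_variant(100L, "CAG", "CG"),
                   list(pos = 100L, ref = "CA", alt = "C"))
  expect_identical(normalize_variant(50L, "A", "AGG"),
                   list(pos = 50L, ref = "A", alt = "AGG"))
  # suffix-padded caller spelling collapses onto the minimal key
  expect_identical(variant_key("c1", 10L, "ATG", "AG"),
                   variant_key("c1", 10L, "AT", "A"))
})
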