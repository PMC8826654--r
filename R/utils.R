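# Internal helpers shared across modules: variant keys, per-plant RNG
# streams, IUPAC matching tables.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# IUPAC code -> allowed genome bases.  Pattern N matches ACGT only, so a
# genome N never satisfies any pattern position.
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

comp_base <- function(x) unname(COMPLEMENT[x])

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(unname(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]])),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a variant to its minimal representation
#'
#' Trims the shared allele suffix, then the shared prefix (advancing the
#' position), so that equivalent indel spellings from different callers
#' collapse onto one key before set operations.
#'
#' @param pos 1-based position of the first ref base.
#' @param ref,alt allele strings.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # trim shared suffix, keeping at least one base in each allele
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim shared prefix
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Canonical string key for a variant
#'
#' `chrom:pos:ref:alt` after [normalize_variant()]; the matching unit
#' for every intersection, subtraction and overlap in the package.
#'
#' @param chrom,pos,ref,alt variant fields (vectorized).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  if (n == 0L) return(character(0))
  norm <- Map(normalize_variant, pos, ref, alt)
  paste(chrom,
        vapply(norm, `[[`, integer(1), "pos"),
        vapply(norm, `[[`, character(1), "ref"),
        vapply(norm, `[[`, character(1), "alt"),
        sep = ":")
}

# Attach a `key` column to a call data.frame if absent.
with_keys <- function(calls) {
  if (nrow(calls) == 0L) {
    calls$key <- character(0)
    return(calls)
  }
  if (is.null(calls$key)) {
    calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  }
  calls
}

# Stable 32-bit hash of a string, for deriving per-plant RNG streams
# from (seed, plant_id) so that adding a plant never perturbs others.
str_hash <- function(s) {
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + str_hash(id)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

empty_calls <- function() {
  data.frame(plant_id = character(0), caller_id = character(0),
             chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             vtype = character(0), zygosity = character(0),
             ad_ref = integer(0), ad_alt = integer(0),
             stringsAsFactors = FALSE)
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
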