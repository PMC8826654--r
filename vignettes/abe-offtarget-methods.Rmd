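---
title: "Methods: profiling ABE-induced off-target mutations in transgenic plant cohorts"
author: "mutscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling ABE-induced off-target mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

# Scope and model

Adenine base editors (ABEs) — Cas9 nickases fused to engineered tRNA
adenosine deaminases (TadA8e, TadA9) — convert A•T pairs to G•C without
double-strand breaks. Besides the guide-directed on-target edit, the
deaminase can act independently of the sgRNA, leaving genome-wide
heterozygous A>G DNA mutations and transcriptome-wide A-to-G RNA
editing. `mutscape` implements the full analysis chain used to profile
these effects in transgenic plant cohorts (here parameterized for rice,
which lacks an endogenous ADAR background, so every RNA A-to-G signal is
attributable to the transgene):

1. **Variant confidence.** SNVs are kept when all three independent
   callers agree (indels when two agree); agreement is decided on
   normalized variant keys (shared allele suffix, then prefix, is
   trimmed so caller spelling dialects collapse onto one key). Everything
   observed in the wild-type background panel is pooled and removed by
   key. Remaining homozygous loci are screened with an exact binomial
   test (below) and removed, leaving the heterozygous induced set.
2. **Guide dependence.** Putative sgRNA-dependent sites are located by
   exhaustive scanning under two budgets: at most 6 mismatches over the
   full 20-nt spacer, or at most 2 mismatches within the PAM-proximal
   12-nt seed, always requiring an IUPAC PAM match. On-target
   (0-mismatch) spans are masked from the off-target set.
3. **Spectra and enrichment.** Substitutions are strand-collapsed into
   six classes (A>G counts both A>G and T>C); genomic regions are derived
   from the annotation (genic = gene spans, exonic, intronic = gene minus
   exon, intergenic = complement) and enrichment is the SNV fraction over
   the region's length fraction. All group contrasts use the one-tailed
   Wilcoxon rank-sum test with the reporting convention `***` p < 0.001,
   `**` p < 0.01, `*` p < 0.1.
4. **T-DNA.** Fragment integrity is called from coverage over the
   LB..RB span (a feature is missing below 10% of the span mean); the
   copy number of a primary transformant is the T-DNA mean coverage over
   half the genome mean, because T0 insertions are hemizygous. Plants
   regenerated from the same callus are partitioned into unique and
   common SNV sets; common variants predate the first division of the
   transformed cell (stages 1–2), unique ones arise later (stage 3).
5. **RNA editing.** RNA-only SNVs are RNA consensus calls absent from
   the plant's genome consensus and from the pooled infection-control
   transcriptomes. At a reference A the editing ratio is G/(A+G) (C/(C+T)
   at a reference T), reported only above 10 reads of coverage. Each ABE
   plant's ratios over the combined locus set are tested (one-tailed)
   against the concatenated Cas-only ratios; ABE expression is
   RPM = mean(Cas reads, TadA reads)/(library size in millions).
6. **Clustered editing.** For each focal A>G locus, flanking positions
   within ±30 bp are counted: eligible = A/T reference with coverage
   > 10, edited = editing ratio > 0.05 (both thresholds strict). DNA
   clusters are single-linkage merges of a plant's A>G SNVs within
   30 bp; plants with at least one cluster form group 1.

## The binomial homozygosity screen

If each allele of a plant mutates independently with probability $p$,
genotypes at a locus follow $P(\text{hom}) = p^2$,
$P(\text{het}) = 2p(1-p)$, $P(\text{wt}) = (1-p)^2$. We estimate
$\hat p = (2 n_{hom} + n_{het}) / (2n)$ from the cohort's genotype
counts and test the number of homozygotes among carriers against the
carrier-conditional probability
$P(\text{hom}\mid\text{carrier}) = \hat p / (2 - \hat p)$ with an exact
upper-tail binomial test. The model form is fixed by the genotype
probabilities above; the test statistic (carrier-conditional exact upper
tail, default flag level $\alpha = 0.01$ per locus) is this package's
formalization, since a per-locus test must condition on something
observable and carriers are what recurrence tables report. Loci that
reject are shared homozygous variants incompatible with independent
allele mutation — residual background that escaped the wild-type panel —
and are removed. Monte-Carlo calibration under the null (10,000 loci)
confirms the exact tail keeps the type-I error at or below the nominal
level.

# The synthetic cohort generator

Every stage is testable without external data because the package ships
a generator that emulates the study design with a complete truth table.
The defaults are the generator's definition of the study conditions, at
desk scale:

| Parameter | Default | Meaning |
|---|---|---|
| `genome_length`, `n_chrom` | 2 Mb, 2 | uniform ACGT chromosomes |
| `gene_fraction` | 0.3 | gene span share; 1–3 exons per gene |
| arms | 3/3/3/3 + 4×3 | wild-type, tissue culture, infection, Cas-only, and 3 plants per editor (rBE46b, rBE49b: NGG; rBE50, rBE53: NG) |
| `background_hom_snvs`, `background_indels` | 80, 30 | shared homozygous background in every plant |
| `residual_hom_snvs`, `residual_hom_carrier` | 10, 0.5 | seed-stock variants absent from the wild-type panel; the homozygosity screen's substrate |
| `tissue_culture_het_snvs` | 150 | Poisson per-plant het SNVs, uniform spectrum (1/6 per class) |
| `abe_induced_snvs`, `induced_ag_fraction` | 250, 0.6 | induced het SNVs; A>G class share |
| `genic_enrichment` | 1.5 | length-normalized genic enrichment of induced A>G |
| `sibling_common_snvs`; common/unique A>G fraction | 100; 0.4 / 0.8 | callus sibling structure (stages 1–2 vs 3) |
| `partial_induced_scale` | 0.3 | induced-load reduction for partial T-DNA insertions |
| clusters | 2 per first plant of each editor, 2–10 members | planted A>G clusters; members on consecutive A/T positions |
| `rna_edit_loci`, `rna_ratio_mean` | 300, 0.3 | exonic edited adenines; per-locus ratio in high-expression plants |
| `yan_bias` | 0.9 | probability of T/C at the transcript −1 position |
| `caller_sensitivity`, `caller_fp_per_mb` | 0.95, 5 | independent per-caller detection; private false positives |
| `coverage_mean`, `base_error` | 41, 0.002 | sequencing depth and symmetric error rate |
| expression tiers | RPM 100 vs 5; 2 of 6 T0 transcriptomes high | drives RNA editing activity |
| `n_t1` | 4 | T1 offspring of the first high-expression plant; half segregate away the transgene |

Reproducibility: every plant (and every callus, and every cohort-level
draw) uses an RNG stream derived from `(seed, identifier)`, so adding a
plant never perturbs the others and two runs with the same seed are
byte-identical on disk.

**What the generator emulates:** shared homozygous background with a
segregating residual component; private heterozygous tissue-culture
mutations of uniform spectrum; induced heterozygous SNVs with an
elevated A>G share, genic enrichment and sibling stage structure;
three-caller concordance with independent dropout and private false
positives; expression-dependent RNA editing with a pyrimidine −1
context; clustered DNA and RNA editing; T-DNA coverage encoding copy
number and missing fragments. **What it does not emulate:** read-level
artifacts (mapping bias, strand bias, duplicates), repeat-mediated indel
ambiguity, linkage between mutations, caller-specific error signatures,
splice structure in RNA coverage, or insertion-site sequence context.
Passing tests therefore validate the analysis logic and its statistical
calibration under the stated generative model, not caller behaviour on
real reads.

## Numerical choices

- **Coordinates.** All interval arithmetic uses the R/Bioconductor
  1-based closed convention (`IRanges`/`GenomicRanges`), which maps 1:1
  onto VCF and GFF coordinates; no 0-based layer is introduced, removing
  one conversion rather than adding one.
- **Key normalization.** Indel keys are reduced to the minimal
  representation (trim shared suffix, then prefix). Repeat-aware
  left-alignment against the reference is not performed; within the
  generator's variant model the minimal representation is unique.
- **Zygosity.** Taken from GT when present; otherwise alt-fraction
  ≥ 0.8 is homozygous, 0.2–0.8 heterozygous, < 0.2 dropped with a
  warning. Caller disagreements resolve by majority, ties to
  heterozygous (conservative: hom-only filters then keep the variant).
- **Strict thresholds.** Editing ratios need coverage strictly greater
  than 10; flanking numerators need ratios strictly greater than 0.05.
  Offset 0 (the focal SNV) is excluded from flanking summaries.
- **Wilcoxon mode.** Exact null when both groups have ≤ 10 values and
  no ties; otherwise normal approximation with tie-corrected variance
  and continuity correction. For pure-noise editing-ratio vectors
  (massive ties at 0) the approximation is calibrated — measured null
  P(p < 0.1) ≈ 0.10 — so "non-significant" judgments about null plants
  are made at the α = 0.05 level that the RNA-mutation call itself uses.
- **RNA locus count and the noise floor.** With base error 0.002 and
  41× coverage, a flanking position crosses the 0.05 ratio threshold
  with probability ≈ 1.5 × 10⁻⁴. Per-offset denominators are about half
  the locus count, so ≥ 200 loci keep a single noise call below the
  0.01 profile line; the default of 300 loci also matches the scale of
  a combined transcriptome locus set.
- **Cluster placement.** Planted cluster members occupy consecutive A/T
  positions (gaps ≪ 30 bp) inside a 60-bp span, and scattered induced
  SNVs are kept 100 bp away from planted clusters, so truth member
  counts are exactly recoverable; anchors carry the same genic
  enrichment as other induced A>G SNVs.
- **Degenerate inputs.** Plants with no SNVs report percentages as
  missing (never 0/0); empty groups make comparisons missing rather
  than failing; loci at chromosome edges contribute truncated,
  renormalized motif columns; a cohort without T1 plants skips the
  segregation stage with a message.

## Design decisions that were genuinely open

- Published consensus workflows rarely state how multi-allelic records
  or caller indel dialects are reconciled; we split multi-allelics into
  one record per ALT and match on normalized keys.
- Background subtraction uses the union over background plants
  (per-plant subtraction is intentionally not offered).
- "Genic" includes introns and UTRs; enrichment is length-normalized
  (the count-fraction is also emitted).
- The on-target mask covers protospacer plus PAM with a configurable
  flank (default 0).
- The RNA-mutation call is a compound rule — more than 5 RNA-only A>G
  SNVs *and* a significant per-plant ratio test (α = 0.05) — because the
  narrative description couples both properties.
- The DNA cluster merge distance defaults to 30 bp, the flanking window
  used throughout; it is exposed as a parameter.
- `run_pipeline` recomputes every stage on every run instead of caching
  by input checksums: stages are pure functions and the default cohort
  completes in about two minutes, so reproducibility is kept trivially
  byte-exact.

# Problem sizes used by the test-suite

Module tests run on a reduced cohort (200-kb genome, proportionally
reduced variant counts); the guide-search oracle equivalence sweeps
twenty 50-kb genomes under both budgets and PAMs; the spectrum and
sibling sweeps use 20 seeds and the RNA sweep 10 seeds of the reduced
cohort; Monte-Carlo calibration of the homozygosity test uses 10,000
loci; the end-to-end determinism check runs the full default 2-Mb cohort
twice. These sizes are the package's chosen desk-scale study conditions;
the same code runs unchanged on larger genomes.

# Worked example

```{r example, eval = FALSE}
library(mutscape)
cohort <- simulate_cohort(sim_config(), seed = 1)
write_cohort(cohort, "cohort")
res <- run_pipeline("cohort", "report")

# per-plant mutation spectra and the ABE-vs-control contrast
head(res$spectra)
res$comparisons

# RNA editing calls and expression grouping
res$rna$grouping$groups
```

# Known limitations

- The generator's caller emulation draws detection independently per
  caller; real callers share failure modes (low coverage, repeats), so
  real three-way intersections are less independent than 0.95³.
- Insertion-site detection from reads is out of scope; sibling identity
  travels in the cohort design table.
- The homozygosity screen conditions on carriers and estimates p from
  the same locus; for very small carrier counts the exact tail is
  conservative.
- Flanking profiles require per-base pileups at the loci of interest;
  the package does not compute pileups from BAM files.
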