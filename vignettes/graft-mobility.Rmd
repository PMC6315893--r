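---
title: "Tracing graft-mobile mRNAs with diagnostic SNPs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing graft-mobile mRNAs with diagnostic SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftscope)
```

## The detection model

A grafted plant is a chimera of two genotypes. Wherever the scion and
the rootstock are *homozygous for different alleles* at a SNP — a
**diagnostic locus** — any read carrying the scion allele that shows up
in the rootstock's RNA library (or vice versa) identifies a transcript
that crossed the graft junction. `graftscope` operationalizes this in
four steps, each with explicit, configurable thresholds
(`mobility_config()`):

1. **Replicate merging.** Biological replicates of each RNA library are
   summed position-wise (`merge_replicates()`) to raise coverage before
   any thresholding.
2. **Consensus genotyping.** At each site the dominant allele is the
   base with the highest read count. A site is called homozygous iff
   that count is at least `min_reads` (default 5, inclusive) *and* its
   frequency strictly exceeds `hom_freq` (default 0.95). The strict
   inequalities are deliberate: 19 reads of 20 (exactly 0.95) is not
   called. Ties for the dominant allele are never called — the
   conservative choice, since a tied site carries no genotype
   information at these depths.
3. **Mobility support.** At a diagnostic locus, the receptor library
   supports incoming donor transcripts iff (a) donor-allele reads
   strictly exceed `donor_fraction` (default 0.05) of the receptor
   site depth; (b) the site shows *exactly two* alleles above a noise
   floor, and they are the donor and receptor alleles — a third allele
   indicates mismapping or a paralog and voids the site; (c) the donor
   allele is absent, above the same noise floor, from the receptor's
   **pre-graft control** library at that position. The noise floor for
   "an allele is present" is ≥ `presence_min_reads` (2) reads and
   ≥ `presence_min_frac` (1%) of depth; no published value exists for
   this floor, so it is exposed and documented rather than hidden.
   Zero receptor depth is "unsupported", not an error.
4. **Gene aggregation.** Supported loci map to genes by transcript
   span; a gene needs `min_support_snps` (default 1) supporting loci
   per direction. Genes supported in both directions are
   *bidirectional*; the directional tallies each include bidirectional
   genes and the union count follows inclusion–exclusion
   (`a + b − both`).

### Two genotyping routes

Diagnostic loci can come from (i) genomic variant calls
(`diagnostic_loci_from_vcf()`): a partner is homozygous-alternate where
it has a homozygous SNP record, homozygous-reference where it has no
record at a position the other partner varies, and uncalled where the
record is heterozygous or multi-allelic; or (ii) RNA pileup consensus
of the pre-graft libraries (`find_diagnostic_loci()`). Both yield the
same locus table shape and feed the same downstream caller. The
genomic route is the primary one (genotypes from DNA are independent of
expression); the package exposes the two routes as two functions rather
than a mode flag, which keeps each contract testable on its own.

### Why a per-partner pre-graft control

The conflict-free condition needs a library that is guaranteed free of
donor transcripts. A *mixture* control (scion + rootstock pooled before
grafting) necessarily contains both genotypes' alleles and cannot
exclude anything by presence; the implemented control is therefore a
per-partner pre-graft library. Sites missing from the control pass the
check — absence of coverage is treated as absence of evidence of
conflict, because failing every poorly-covered control site would make
sensitivity depend on control depth rather than on the graft libraries.

### Thresholding after merging

Read-count thresholds are applied once, to the merged counts. Applying
the ≥ 5-read rule per replicate instead would make the effective
stringency depend on the replicate count; post-merge thresholding
keeps one interpretable rule and matches the stated purpose of merging
(raising coverage to make the thresholds reachable).

## Variant post-filtering

`apply_filters()` runs quality → coverage → density, with the mean
depth computed on the *input* set before any removal.

* **Quality**: records with QUAL strictly below `min_qual` (30) are
  removed; a record at exactly 30 survives.
* **Coverage**: the retained band is the closed interval
  [0.5·mean, 2·mean]. The mean is the arithmetic mean of per-variant
  DP values — the pipeline starts from calls, not alignments, so
  per-variant depth proxies "average coverage of mapped reads". The
  proxy preserves the rule's purpose (relative-depth outlier removal);
  both factors are configurable.
* **Density**: a SNP is removed if *any* 10-nt window containing it
  holds more than 3 SNPs; the whole violating cluster is dropped.
  Removing only "excess" SNPs would require an arbitrary choice of
  which ones; dropping the cluster is deterministic and independent of
  window anchoring. InDels are exempt (the criterion concerns SNPs)
  but are subject to the quality and coverage filters.

## Consequence annotation

Region assignment uses the precedence CDS > UTR > intron across all
overlapping transcripts so every variant gets exactly one region and
percentages are well defined; remaining ties break deterministically by
gene id. Codon effects are computed on the coding strand (minus-strand
alleles complemented) under the standard genetic code; a change in the
initiator ATG is `start_lost` regardless of its amino-acid effect.
Impact tiers follow the SnpEff convention: nonsense / start_lost /
stop_lost / frameshift → high, missense → moderate, synonymous → low,
everything non-coding → modifier. In-frame InDels are tiered
*moderate* (the SnpEff convention; the tier table that motivated this
package does not mention them). Splice-site effects are not modelled:
variants in introns are modifiers wherever they fall. Heterozygous
variants are annotated by their alternate allele exactly like
homozygous ones — zygosity is orthogonal to consequence. SNPs in the
first or last codon are additionally flagged (`in_start_stop`) to
mirror the "variants in start/stop codons" statistic of resequencing
surveys, independent of their codon-level effect. Models whose CDS
length is not a multiple of 3 are annotated but marked
`low_confidence`.

All printed ratios and percentages use two decimals rounded half away
from zero (`round_half_away()`), matching how such tables are
conventionally printed; base R's round-half-to-even would differ at
exact ties.

## The synthetic world

`simulation_config()` defaults describe one fixed scenario; they are
not tuned per test.

| parameter | default | rationale |
|---|---|---|
| genome | 3 chromosomes × 200 kb, 40 genes each | smallest size at which per-chromosome statistics and gene-level aggregation are non-trivial |
| SNP density | 26.7/kb (rootstock), 10.6/kb (scion), 2.2/kb common | the observed scale for a wide inter-specific pair vs a reference close to one parent |
| heterozygosity | 0.32 vs 0.98 | the asymmetry that makes one partner a poor diagnostic-allele source and the other a good one |
| Ts/Tv target | 1.75 | plant resequencing surveys report ≈ 1.7–1.85; per-SNP transition probability Ts/Tv ÷ (Ts/Tv + 1) |
| InDel lengths | geometric, P(1) = 0.535, cap 40 bp | mononucleotide-dominant spectrum with a hard 40 bp cap |
| insertions | 47% | surveys report slightly deletion-biased calls |
| RNA depth | Poisson mean 60× | enough for the ≥ 5-read / 95% rules to be reachable at most sites |
| error rate | 0.005/base, uniform over the 3 other bases | Illumina-scale post-filter error |
| mobile genes | 30 of 120, directions 1/3 : 1/2 : 1/6, one tissue each | enough planted positives for stable sensitivity estimates |
| donor abundance | 10% of site depth | safely above the 5% rule yet far from parity; lower it to probe the detection boundary |

Base counts are drawn as independent Poissons with mean
`depth × p(base)` — a Poisson-thinned multinomial, distributionally
equivalent to drawing a Poisson total and splitting it multinomially,
and fully vectorised. "Depth" of a site is therefore the realised sum
of its four base counts, and every table in the package preserves that
identity. Heterozygous sites emit both alleles at 50:50 in
expectation; mobile genes are drawn only from genes that actually
contain an exonic diagnostic locus, so every planted positive is
recoverable in principle; per-genotype variant quality is Normal(45, 8)
and genomic DP Poisson(30), so the post-calling filters remove a small
realistic fraction rather than nothing.

**What a green test establishes — and what it does not.** The
generator emulates allele counts at independent sites. It does not
simulate read alignment (no mismapping, no paralog collapse), RNA
splicing, expression variation between genes or replicates, strand
information, or InDel reads in pileups. A green recovery test
therefore establishes that the caller implements its stated decision
rules correctly at realistic counts — not that those rules are robust
to alignment artefacts, which in real data are handled upstream and by
the two-allele/conflict-free conditions whose false-positive behaviour
this simulation only partially exercises.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; InDels carry the VCF
  anchor base and their length is the anchored difference.
* Multi-sample VCFs: only the first sample's GT is read.
* Pileup parsing is strand-collapsed (`.`/`,` both count as the
  reference base); indel blocks, read start/end markers and `*`
  placeholders are skipped, so parsed depth equals the mpileup depth
  column minus skipped symbols.
* Empty inputs: readers return empty tables; `mean_depth()` of an
  empty set is an error (the coverage filter would be meaningless);
  an empty diagnostic-locus set yields empty calls and zero tallies.
* All generator randomness derives from `simulation_config(seed)` via
  small fixed offsets, so identical seeds give byte-identical FASTA /
  GFF3 / VCF / pileup output.

## Known limitations

* Mobility is assessed per (gene, tissue, direction); transcript
  isoforms are not distinguished.
* The density filter treats each chromosome independently and assumes
  sorted input (unsorted input errors rather than sorting silently).
* `assign_region()` locates InDels by their anchor base only; a long
  deletion spanning a region boundary is classified by its left edge.
* Consequence calls ignore phase between nearby variants (each variant
  is evaluated against the reference codon).
* The dataset-scale headline numbers of real grafting surveys (millions
  of SNPs, thousands of mobile genes) require the original sequencing
  data; the package reproduces their *arithmetic* exactly and their
  *structure* at desk scale.
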