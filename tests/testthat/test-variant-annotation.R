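test_that("substitution_class partitions the 12 ordered base pairs", {
  expect_equal(substitution_class("A", "G"), "transition")
  expect_equal(substitution_class("C", "G"), "transversion")
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- substitution_class(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_error(substitution_class("A", "A"), "differ")
})

test_that("assign_region follows containment with CDS > UTR > intron", {
  fx <- fixture_genes()
  v <- variant_records(c("chr1", "chr1", "chr1"), c(20, 12, 5),
                       c("A", "A", "A"), c("G", "G", "G"),
                       50, 30, rep("homozygous", 3))
  r <- assign_region(v, fx$genes)
  # variant_records sorts by position: 5 (intergenic), 12 (5'UTR 11..15),
  # 20 (CDS 16..33)
  expect_equal(r$region, c("intergenic", "UTR", "CDS"))
  expect_equal(r$gene_id, c(NA, "geneP", "geneP"))
})

test_that("assign_region matches a linear interval-scan oracle", {
  cfg <- simulation_config(seed = 11, n_chromosomes = 1,
                           genes_per_chromosome = 12,
                           chrom_length = 30000L)
  ref <- simulate_reference(cfg)
  set.seed(12)
  v <- random_variants(1000, max_pos = 30000L)
  expect_equal(assign_region(v, ref$genes),
               oracle_assign_region(v, ref$genes))
})

test_that("codon_effect agrees with the hand-typed table on all 576 cases", {
  codons <- names(AA_TABLE)
  n_checked <- 0L
  for (codon in codons) {
    for (p in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
        expect_equal(codon_effect(codon, p, alt),
                     oracle_codon_effect(codon, p, alt),
                     label = paste(codon, p, alt))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 576L)
})

test_that("coding_effect is strand-aware and flags start/stop changes", {
  fx <- fixture_genes()
  genome <- fx$genome
  gp <- fx$genes[[1L]]; gm <- fx$genes[[2L]]
  # CDS is ATG GCT TGG CGA TTA TAA at chr1:16..33
  mkv <- function(chrom, pos, ref, alt)
    variant_records(chrom, pos, ref, alt, 50, 30, "homozygous")
  # codon 2 GCT -> GCC: synonymous (both Ala), 3rd position 21
  expect_equal(coding_effect(mkv("chr1", 21, "T", "C"), gp, genome),
               "synonymous")
  # codon 3 TGG -> TGA (pos 24 G>A): nonsense
  expect_equal(coding_effect(mkv("chr1", 24, "G", "A"), gp, genome),
               "nonsense")
  # stop codon TAA -> CAA (pos 31): stop_lost
  expect_equal(coding_effect(mkv("chr1", 31, "T", "C"), gp, genome),
               "stop_lost")
  # initiator ATG (pos 16 A>G): start_lost
  expect_equal(coding_effect(mkv("chr1", 16, "A", "G"), gp, genome),
               "start_lost")
  expect_error(coding_effect(mkv("chr1", 5, "A", "G"), gp, genome),
               "outside the CDS")

  # strand symmetry: the mirrored variant on the - strand gene gives the
  # identical effect (mirror of chr1 pos p is chr2 pos L - p + 1 with
  # the complemented alleles)
  L <- fx$L
  cases <- list(c(21, "T", "C"), c(24, "G", "A"), c(31, "T", "C"),
                c(16, "A", "G"), c(22, "T", "A"), c(27, "A", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (cs in cases) {
    p <- as.integer(cs[1])
    eff_plus <- coding_effect(mkv("chr1", p, cs[2], cs[3]), gp, genome)
    eff_minus <- coding_effect(
      mkv("chr2", L - p + 1L, comp[[cs[2]]], comp[[cs[3]]]), gm, genome)
    expect_equal(eff_minus, eff_plus, label = paste("mirror of pos", p))
  }
})

test_that("classify_indel splits frameshift / in-frame / noncoding", {
  v <- variant_records(rep("c", 3), c(10, 20, 30),
                       c("AT", "A", "AGG"), c("A", "ACGT", "A"),
                       50, 30, rep("homozygous", 3))
  expect_equal(classify_indel(v, c("CDS", "CDS", "intron")),
               c("frameshift", "inframe_indel", "noncoding"))
})

test_that("impact tiers and functional classes follow the SnpEff scheme", {
  eff <- c("nonsense", "start_lost", "stop_lost", "frameshift",
           "missense", "inframe_indel", "synonymous", "noncoding")
  expect_equal(impact_tier(eff),
               c("high", "high", "high", "high", "moderate", "moderate",
                 "low", "modifier"))
  expect_equal(functional_class(eff),
               c("nonsense", "none", "none", "none", "missense", "none",
                 "silent", "none"))
})

test_that("annotate_variants yields one region/effect/impact per variant", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 1,
                           genes_per_chromosome = 10,
                           chrom_length = 40000L)
  ref <- simulate_reference(cfg)
  v <- simulate_genotype(ref, cfg, "rootstock")
  ann <- annotate_variants(v, ref$genes, ref$genome)
  expect_equal(nrow(ann), nrow(v))
  expect_true(all(ann$region %in% c("CDS", "UTR", "intron", "intergenic")))
  expect_true(all(ann$impact %in% c("high", "moderate", "low", "modifier")))
  # intergenic implies modifier impact and no functional class
  ig <- ann$region == "intergenic"
  expect_true(all(ann$impact[ig] == "modifier"))
  expect_true(all(ann$functional_class[ig] == "none"))
  # functional classes partition classified CDS SNPs
  cds_snp <- ann$region == "CDS" & is_snp(v)
  fc <- ann$functional_class[cds_snp]
  known <- ann$effect[cds_snp] %in% c("missense", "nonsense", "synonymous")
  expect_equal(sum(fc %in% c("missense", "nonsense", "silent")), sum(known))

  # agreement with the generator's own (independent) truth table
  tr <- attr(v, "truth")
  expect_equal(ann$region, tr$region)
  has_eff <- !is.na(tr$effect)
  expect_equal(ann$effect[has_eff], tr$effect[has_eff])
})
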