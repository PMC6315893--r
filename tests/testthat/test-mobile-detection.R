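sc <- function(pos, A = 0, C = 0, G = 0, T = 0, chrom = "chr1") {
  site_counts(rep(chrom, length(pos)), pos, A, C, G, T)
}

test_that("merge_replicates sums base counts position-wise", {
  r1 <- sc(5, A = 3)
  expect_equal(as.data.frame(merge_replicates(list(r1))), as.data.frame(r1))
  r2 <- sc(5, A = 2, G = 1)
  m <- merge_replicates(list(r1, r2))
  expect_equal(m$count_A, 5L)
  expect_equal(m$count_G, 1L)
  expect_equal(m$depth, 6L)
  # positions present in any replicate appear once
  r3 <- sc(9, C = 4)
  m <- merge_replicates(list(r1, r3))
  expect_equal(m$pos, c(5L, 9L))
  # conservation: merged depth equals the sum of replicate depths
  set.seed(41)
  reps <- lapply(1:3, function(i)
    sc(sort(sample(100, 50)), A = rpois(50, 8), G = rpois(50, 4)))
  m <- merge_replicates(reps)
  expect_equal(sum(m$depth), sum(sapply(reps, function(r) sum(r$depth))))
})

test_that("consensus_genotype enforces min reads and strict 95% rule", {
  expect_equal(consensus_genotype(sc(1, A = 20)), "A")
  # 19/20 = 0.95 exactly, not > 0.95
  expect_true(is.na(consensus_genotype(sc(1, A = 19, G = 1))))
  expect_equal(consensus_genotype(sc(1, A = 39, G = 1)), "A")
  # dominant allele below 5 reads
  expect_true(is.na(consensus_genotype(sc(1, A = 4))))
  # tie for the dominant allele is no-call
  expect_true(is.na(consensus_genotype(sc(1, A = 10, G = 10))))
  expect_equal(consensus_genotype(sc(1:2, A = c(50, 0), G = c(0, 8))),
               c("A", "G"))
})

test_that("find_diagnostic_loci keeps divergent homozygous sites only", {
  scion <- sc(c(10, 20, 30), A = c(50, 50, 28), G = c(0, 0, 22))
  root <- sc(c(10, 20, 30), A = c(0, 50, 0), G = c(50, 0, 50))
  loci <- find_diagnostic_loci(scion, root)
  expect_equal(loci$pos, 10L)
  expect_equal(loci$scion_allele, "A")
  expect_equal(loci$rootstock_allele, "G")
  expect_equal(loci$scion_frac, 1)
})

test_that("planted divergent sites are recovered exactly", {
  # 100 divergent hom + 50 shared hom + 20 het sites
  set.seed(42)
  pos <- sample(10000, 170)
  d_pos <- sort(pos[1:100]); s_pos <- sort(pos[101:150]); h_pos <- sort(pos[151:170])
  scion <- sc(c(d_pos, s_pos, h_pos),
              A = c(rep(60, 100), rep(60, 50), rep(30, 20)),
              G = c(rep(0, 100), rep(0, 50), rep(30, 20)))
  root <- sc(c(d_pos, s_pos, h_pos),
             A = c(rep(0, 100), rep(60, 50), rep(30, 20)),
             C = c(rep(60, 100), rep(0, 50), rep(30, 20)))
  loci <- find_diagnostic_loci(scion, root)
  expect_equal(loci$pos, d_pos)
})

test_that("diagnostic_loci_from_vcf treats absent records as hom-ref", {
  a <- variant_records(c("c1", "c1", "c1"), c(10, 20, 30),
                       c("A", "C", "G"), c("G", "T", "A"), 50, 30,
                       c("homozygous", "heterozygous", "homozygous"))
  b <- variant_records(c("c1", "c1"), c(30, 40), c("G", "T"), c("C", "A"),
                       50, 30, c("homozygous", "homozygous"))
  loci <- diagnostic_loci_from_vcf(a, b)
  # pos 10: a hom-alt G vs b hom-ref A -> diagnostic
  # pos 20: a heterozygous -> excluded
  # pos 30: both hom for different alts (A vs C) -> diagnostic
  # pos 40: b hom-alt A vs a hom-ref T -> diagnostic
  expect_equal(loci$pos, c(10L, 30L, 40L))
  expect_equal(loci$scion_allele, c("G", "A", "T"))
  expect_equal(loci$rootstock_allele, c("A", "C", "A"))
})

test_that("detect_mobility applies fraction, two-allele and control rules", {
  locus <- data.frame(chrom = "chr1", pos = 100L, scion_allele = "A",
                      rootstock_allele = "G", scion_reads = 60L,
                      scion_frac = 1, rootstock_reads = 60L,
                      rootstock_frac = 1, stringsAsFactors = FALSE)
  clean_ctrl <- sc(100, G = 80)
  # donor fraction 0.10 with clean control: supported
  r <- detect_mobility(locus, sc(100, G = 90, A = 10), clean_ctrl,
                       donor = "scion")
  expect_true(r$supported)
  expect_equal(r$donor_frac, 0.10)
  # 3% donor reads: below the strict 5% rule
  r <- detect_mobility(locus, sc(100, G = 97, A = 3), clean_ctrl,
                       donor = "scion")
  expect_false(r$supported)
  # three alleles above the noise floor: unsupported
  r <- detect_mobility(locus, sc(100, G = 80, A = 10, T = 10), clean_ctrl,
                       donor = "scion")
  expect_false(r$supported)
  # donor allele present in the pre-graft control: conflict
  r <- detect_mobility(locus, sc(100, G = 90, A = 10),
                       sc(100, G = 70, A = 10), donor = "scion")
  expect_false(r$supported)
  # zero receptor depth is unsupported, not an error
  r <- detect_mobility(locus, sc(1, G = 10), clean_ctrl, donor = "scion")
  expect_false(r$supported)
})

test_that("raising thresholds never gains supported loci", {
  set.seed(43)
  n <- 200
  pos <- sort(sample(100000, n))
  loci <- data.frame(chrom = "c1", pos = pos, scion_allele = "A",
                     rootstock_allele = "G", scion_reads = 60L,
                     scion_frac = 1, rootstock_reads = 60L,
                     rootstock_frac = 1, stringsAsFactors = FALSE)
  donor_n <- rbinom(n, 60, 0.08)
  rna <- sc(pos, G = 60 - donor_n, A = donor_n)
  prev <- Inf
  for (f in c(0.05, 0.08, 0.12, 0.20)) {
    cfg <- mobility_config(donor_fraction = f)
    got <- sum(detect_mobility(loci, rna, NULL, cfg, donor = "scion")$supported)
    expect_lte(got, prev)
    prev <- got
  }
  # min_reads acts at the genotyping stage: raising it never yields
  # more diagnostic loci
  scion_gt <- sc(pos, A = rpois(n, 20))
  root_gt <- sc(pos, G = rpois(n, 20))
  prev <- Inf
  for (mr in c(1, 5, 10, 25)) {
    cfg <- mobility_config(min_reads = mr)
    got <- nrow(find_diagnostic_loci(scion_gt, root_gt, cfg))
    expect_lte(got, prev)
    prev <- got
  }
})

test_that("aggregate_genes forms directional sets with Fig-style tallies", {
  genes <- structure(list(
    gene_model("g1", "g1.t", "c1", "+", exons = cbind(1L, 1000L),
               cds = cbind(101L, 700L)),
    gene_model("g2", "g2.t", "c1", "+", exons = cbind(2001L, 3000L),
               cds = cbind(2101L, 2700L))),
    class = "gene_model_list")
  mk_loci <- function(pos, dir) data.frame(
    chrom = "c1", pos = pos, scion_allele = "A", rootstock_allele = "G",
    scion_reads = 60L, scion_frac = 1, rootstock_reads = 60L,
    rootstock_frac = 1, donor_count = 6L, donor_frac = 0.1,
    receptor_depth = 60L, supported = TRUE, direction = dir,
    stringsAsFactors = FALSE)
  # one gene, one direction
  res <- aggregate_genes(mk_loci(150, "scion_to_rootstock"), genes)
  expect_equal(res$calls$gene_id, "g1")
  expect_equal(res$calls$direction, "scion_to_rootstock")
  expect_equal(res$tally[["union"]], 1L)

  # gene supported in both directions is bidirectional, union counts once
  both <- rbind(mk_loci(c(150, 220), "scion_to_rootstock"),
                mk_loci(350, "rootstock_to_scion"),
                mk_loci(2200, "rootstock_to_scion"))
  res <- aggregate_genes(both, genes)
  expect_equal(res$calls$direction[res$calls$gene_id == "g1"],
               "bidirectional")
  expect_equal(res$tally,
               c(scion_to_rootstock = 1L, rootstock_to_scion = 2L,
                 bidirectional = 1L, union = 2L))
  expect_equal(res$tally[["union"]],
               res$tally[["scion_to_rootstock"]] +
                 res$tally[["rootstock_to_scion"]] -
                 res$tally[["bidirectional"]])
  # a locus outside every gene is dropped and counted
  res <- aggregate_genes(mk_loci(1500, "scion_to_rootstock"), genes)
  expect_equal(res$n_dropped_loci, 1L)
  expect_equal(nrow(res$calls), 0L)
})

test_that("min_support_snps gates gene calls", {
  genes <- structure(list(
    gene_model("g1", "g1.t", "c1", "+", exons = cbind(1L, 1000L),
               cds = cbind(101L, 700L))), class = "gene_model_list")
  loci <- data.frame(chrom = "c1", pos = c(150L, 300L), scion_allele = "A",
                     rootstock_allele = "G", scion_reads = 60L,
                     scion_frac = 1, rootstock_reads = 60L,
                     rootstock_frac = 1, donor_count = 6L, donor_frac = 0.1,
                     receptor_depth = 60L, supported = TRUE,
                     direction = "scion_to_rootstock",
                     stringsAsFactors = FALSE)
  res1 <- aggregate_genes(loci[1, ], genes,
                          mobility_config(min_support_snps = 2))
  expect_equal(nrow(res1$calls), 0L)
  res2 <- aggregate_genes(loci, genes, mobility_config(min_support_snps = 2))
  expect_equal(res2$calls$n_support, 2L)
})
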