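# generator tests run on a scaled-down genome so the whole file stays
# fast; the full default configuration is exercised in test-acceptance.R
small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chromosomes = 1,
                    genes_per_chromosome = 10, chrom_length = 40000L,
                    n_mobile_genes = 4L, ...)
}

test_that("simulate_reference round-trips through FASTA/GFF3 readers", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  td <- tempfile(); dir.create(td)
  write_reference(ref, file.path(td, "r.fa"), file.path(td, "g.gff3"))
  genome <- read_genome(file.path(td, "r.fa"))
  genes <- read_gff3(file.path(td, "g.gff3"), genome)
  expect_length(genes, 10L)
  expect_false(any(vapply(genes, function(m) m$cds_incomplete, logical(1))))
  expect_equal(as.character(genome[["chr1"]]),
               as.character(ref$genome[["chr1"]]))
  # parsed models agree with the generator's models interval-for-interval
  for (k in seq_along(genes)) {
    expect_equal(genes[[k]]$cds, ref$genes[[k]]$cds)
    expect_equal(genes[[k]]$exons, ref$genes[[k]]$exons)
    expect_equal(genes[[k]]$utr5, ref$genes[[k]]$utr5)
    expect_equal(genes[[k]]$phase, ref$genes[[k]]$phase)
  }
})

test_that("generated CDSs start with ATG, end with a stop, no internal stops", {
  cfg <- small_cfg(seed = 5)
  ref <- simulate_reference(cfg)
  for (m in ref$genes) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(coding_sequence(m, ref$genome))))
    expect_true(startsWith(aa, "M"))
    expect_true(endsWith(aa, "*"))
    expect_false(grepl("[*].", aa))   # no stop before the last codon
    expect_equal(cds_length(m) %% 3L, 0L)
  }
})

test_that("simulation is byte-identical for a fixed seed", {
  cfg <- small_cfg(seed = 9)
  out1 <- tempfile(); out2 <- tempfile()
  write_simulation(cfg, out1)
  write_simulation(cfg, out2)
  for (f in list.files(out1, recursive = TRUE)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_gt(length(list.files(out1, recursive = TRUE)), 10L)
})

test_that("simulate_genotype hits its target Ts/Tv and zygosity split", {
  cfg <- small_cfg(seed = 2, snp_density_rootstock = 26.7,
                   het_rootstock = 0.32)
  ref <- simulate_reference(cfg)
  v <- simulate_genotype(ref, cfg, "rootstock")
  snp <- v[is_snp(v), ]
  n <- nrow(snp)
  expect_gt(n, 800)
  cls <- substitution_class(snp$ref, snp$alt)
  p_ts <- mean(cls == "transition")
  p_target <- 1.75 / 2.75
  expect_lt(abs(p_ts - p_target), 3 * sqrt(p_target * (1 - p_target) / n))
  p_het <- mean(snp$zygosity == "heterozygous")
  expect_lt(abs(p_het - 0.32), 3 * sqrt(0.32 * 0.68 / n))

  # near-total heterozygosity for the scion-like genotype
  v2 <- simulate_genotype(ref, cfg, "scion")
  s2 <- v2[is_snp(v2), ]
  expect_lt(abs(mean(s2$zygosity == "heterozygous") - 0.98),
            3 * sqrt(0.98 * 0.02 / nrow(s2)) + 0.005)

  # density zero yields nothing
  cfg0 <- small_cfg(seed = 2, snp_density_scion = 0, snp_density_common = 0,
                    indel_density_scion = 0, indel_density_common = 0)
  expect_equal(nrow(simulate_genotype(simulate_reference(cfg0), cfg0,
                                      "scion")), 0L)
})

test_that("InDel lengths are geometric, mononucleotide-dominant, max 40", {
  cfg <- small_cfg(seed = 6, indel_density_rootstock = 10)
  ref <- simulate_reference(cfg)
  v <- simulate_genotype(ref, cfg, "rootstock")
  len <- indel_length(v)
  len <- len[!is.na(len)]
  expect_gt(length(len), 200)
  expect_true(all(len >= 1 & len <= 40))
  p1 <- mean(len == 1)
  expect_lt(abs(p1 - 0.535), 3 * sqrt(0.535 * 0.465 / length(len)))
})

test_that("common component makes the two genotypes overlap as configured", {
  cfg <- small_cfg(seed = 3)
  ref <- simulate_reference(cfg)
  a <- simulate_genotype(ref, cfg, "scion")
  b <- simulate_genotype(ref, cfg, "rootstock")
  p <- partition_variants(a, b)
  L_kb <- cfg$chrom_length / 1000
  exp_common <- (cfg$snp_density_common + cfg$indel_density_common) * L_kb
  expect_gt(nrow(p$common), 0.8 * exp_common)
  expect_lte(nrow(p$common), nrow(a))
})

test_that("graft pileups conserve depth and honour the truth table", {
  cfg <- small_cfg(seed = 4)
  ref <- simulate_reference(cfg)
  scion <- simulate_genotype(ref, cfg, "scion")
  rootstock <- simulate_genotype(ref, cfg, "rootstock")
  graft <- simulate_graft_pileups(ref, scion, rootstock, cfg)
  lib <- graft$libraries$leaf$scion[[1]]
  expect_equal(lib$depth,
               lib$count_A + lib$count_C + lib$count_G + lib$count_T)
  expect_equal(nrow(graft$truth$mobile_genes), 4L)
  # every planted mobile gene has >= 1 exonic diagnostic locus
  expect_true(all(graft$truth$mobile_genes$gene_id %in%
                    graft$truth$diagnostic_loci$gene_id))
  # re-genotyping the pre-graft controls recovers planted hom genotypes
  ctrl <- merge_replicates(graft$controls$rootstock)
  al <- consensus_genotype(ctrl)
  truth_loci <- graft$truth$diagnostic_loci
  i <- match(paste(truth_loci$chrom, truth_loci$pos),
             paste(ctrl$chrom, ctrl$pos))
  agree <- mean(al[i] == truth_loci$rootstock_allele, na.rm = TRUE)
  called <- mean(!is.na(al[i]))
  expect_gt(agree, 0.999)
  expect_gt(called, 0.95)
})
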