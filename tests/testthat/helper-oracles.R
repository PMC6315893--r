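# Independent oracles used by the derived-value tests.  These stay
# deliberately naive: brute-force enumeration, a hand-typed amino-acid
# table, and plain loops, so they share no code path with the package.

# standard genetic code, typed out by hand (not Biostrings)
AA_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_codon_effect <- function(codon, pos, alt) {
  alt_codon <- codon
  substr(alt_codon, pos, pos) <- alt
  a <- AA_TABLE[[codon]]; b <- AA_TABLE[[alt_codon]]
  if (a == "*" && b != "*") "stop_lost"
  else if (b == "*" && a != "*") "nonsense"
  else if (a == b) "synonymous"
  else "missense"
}

# exhaustive sliding-window SNP density filter: every window of `w`
# consecutive bases is enumerated; SNPs in any window holding more than
# `maxs` SNPs are removed (InDels untouched)
oracle_density_filter <- function(records, w = 10L, maxs = 3L) {
  drop <- rep(FALSE, nrow(records))
  snp <- is_snp(records)
  for (ch in unique(records$chrom)) {
    idx <- which(snp & records$chrom == ch)
    if (length(idx) == 0L) next
    pos <- records$pos[idx]
    for (p in (min(pos) - w + 1L):max(pos)) {
      inside <- pos >= p & pos <= p + w - 1L
      if (sum(inside) > maxs) drop[idx[inside]] <- TRUE
    }
  }
  records[!drop, , drop = FALSE]
}

# plain interval scan for region assignment (CDS > UTR > intron)
oracle_assign_region <- function(variants, genes) {
  res <- data.frame(region = rep("intergenic", nrow(variants)),
                    gene_id = rep(NA_character_, nrow(variants)),
                    stringsAsFactors = FALSE)
  rank <- c(CDS = 1L, UTR = 2L, intron = 3L, intergenic = 4L)
  for (i in seq_len(nrow(variants))) {
    best <- "intergenic"; best_gene <- NA_character_
    for (m in genes) {
      if (m$chrom != variants$chrom[i]) next
      p <- variants$pos[i]
      sp <- transcript_span(m)
      if (p < sp[1L] || p > sp[2L]) next
      hit_in <- function(mat) nrow(mat) > 0L &&
        any(p >= mat[, 1L] & p <= mat[, 2L])
      reg <- if (hit_in(m$cds)) "CDS"
             else if (hit_in(m$utr5) || hit_in(m$utr3)) "UTR"
             else if (!hit_in(m$exons)) "intron"
             else "UTR"
      better <- rank[reg] < rank[best] ||
        (rank[reg] == rank[best] && (is.na(best_gene) || m$gene_id < best_gene))
      if (better) { best <- reg; best_gene <- m$gene_id }
    }
    res$region[i] <- best; res$gene_id[i] <- best_gene
  }
  res
}

random_variants <- function(n, chrom = "chr1", max_pos = 1000L,
                            qual = 50, depth = 30) {
  pos <- sort(sample.int(max_pos, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1L))
  variant_records(rep(chrom, n), pos, ref, alt,
                  qual = rep(qual, n)[1:n], depth = rep(depth, n)[1:n],
                  zygosity = sample(c("homozygous", "heterozygous"), n,
                                    replace = TRUE))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# tiny two-gene fixture: one + strand, and its mirror as a - strand
# gene with the reverse-complement sequence, used for strand symmetry
fixture_genes <- function() {
  # chr1: gene P at 11..40, exon 11..40, CDS 16..33 (ATG ... TAA)
  #   seq:    5 bp pad, utr5 11..15, CDS "ATGGCTTGGCGATTATAA" 16..33, utr3 34..40
  plus_cds <- "ATGGCTTGGCGATTATAA"
  chr1 <- paste0("CCCCCCCCCC", "TTTTT", plus_cds, "GGGGGGG", "CCCCCCCCCC")
  # chr2 = reverse complement of chr1; gene M occupies mirrored coords
  chr2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chr1)))
  L <- nchar(chr1)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  gp <- gene_model("geneP", "geneP.t1", "chr1", "+",
                   exons = cbind(11L, 40L), cds = cbind(16L, 33L))
  # mirror of interval [a, b] on chr2 is [L - b + 1, L - a + 1]
  gm <- gene_model("geneM", "geneM.t1", "chr2", "-",
                   exons = cbind(L - 40L + 1L, L - 11L + 1L),
                   cds = cbind(L - 33L + 1L, L - 16L + 1L))
  list(genome = genome,
       genes = structure(list(gp, gm), class = "gene_model_list"),
       L = L, plus_cds = plus_cds)
}
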