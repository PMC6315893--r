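#' Simulation configuration
#'
#' Parameters of the synthetic grafting world: a small multi-chromosome
#' genome with protein-coding genes, two diploid genotypes called
#' against it (one highly homozygous and SNP-dense, one almost fully
#' heterozygous, mirroring a wide inter-specific graft pair), and RNA
#' pileup libraries for grafted scion/rootstock tissues in which a
#' chosen set of genes exports transcripts across the graft junction.
#'
#' Densities are per kb and include the shared (`*_common`) component,
#' so e.g. the rootstock genotype carries
#' `snp_density_rootstock` SNPs/kb of which `snp_density_common`/kb are
#' also present in the scion.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_chromosomes,chrom_length,genes_per_chromosome genome shape.
#' @param snp_density_scion,snp_density_rootstock,snp_density_common
#'   SNPs per kb (totals per genotype; common shared by both).
#' @param het_scion,het_rootstock heterozygous fraction per genotype.
#' @param ts_tv target transition/transversion ratio (per-SNP
#'   transition probability `ts_tv / (ts_tv + 1)`).
#' @param indel_density_scion,indel_density_rootstock,indel_density_common
#'   InDels per kb.
#' @param indel_geom_p geometric length parameter (P(length = 1));
#'   lengths truncated at 40 bp.
#' @param insertion_prob probability an InDel is an insertion.
#' @param genomic_depth,qual_mean,qual_sd per-variant DP (Poisson mean)
#'   and QUAL (normal) for the simulated calls.
#' @param rna_depth mean RNA coverage per exonic site (Poisson).
#' @param error_rate per-base sequencing error rate (substituted
#'   uniformly over the three non-template bases).
#' @param n_mobile_genes number of planted graft-transmitting genes.
#' @param direction_probs probabilities of the three mobility patterns
#'   (scion_to_rootstock, rootstock_to_scion, bidirectional).
#' @param donor_transcript_fraction donor transcript abundance as a
#'   fraction of receptor-site depth.
#' @param n_replicates biological replicates per RNA library.
#' @param tissues sampled tissues; each mobile gene is planted in one.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_chromosomes = 3L,
                              chrom_length = 200000L,
                              genes_per_chromosome = 40L,
                              snp_density_scion = 10.6,
                              snp_density_rootstock = 26.7,
                              snp_density_common = 2.2,
                              het_scion = 0.98, het_rootstock = 0.32,
                              ts_tv = 1.75,
                              indel_density_scion = 0.85,
                              indel_density_rootstock = 2.54,
                              indel_density_common = 0.4,
                              indel_geom_p = 0.535,
                              insertion_prob = 0.47,
                              genomic_depth = 30, qual_mean = 45,
                              qual_sd = 8,
                              rna_depth = 60, error_rate = 0.005,
                              n_mobile_genes = 30L,
                              direction_probs = c(scion_to_rootstock = 10 / 30,
                                                  rootstock_to_scion = 15 / 30,
                                                  bidirectional = 5 / 30),
                              donor_transcript_fraction = 0.10,
                              n_replicates = 3L,
                              tissues = c("leaf", "stem")) {
  stopifnot(het_scion >= 0, het_scion <= 1, het_rootstock >= 0,
            het_rootstock <= 1, error_rate >= 0, error_rate <= 1,
            donor_transcript_fraction >= 0, donor_transcript_fraction <= 1,
            snp_density_common <= snp_density_scion,
            snp_density_common <= snp_density_rootstock,
            abs(sum(direction_probs) - 1) < 1e-8, ts_tv > 0)
  structure(as.list(environment()), class = "simulation_config")
}

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons
sense_codons <- function() {
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, STOP_CODONS)
}

# internal: design one gene in transcript ("o") coordinates.
# o-space runs 1..span in transcription order on both strands; genomic
# mapping is o -> start - 1 + o (+ strand) or start + span - o (-).
design_gene <- function(tag) {
  n_codons <- sample(60:150, 1L)
  cds_len <- 3L * n_codons
  coding <- paste0("ATG",
                   paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
                         collapse = ""),
                   sample(STOP_CODONS, 1L))
  utr5 <- sample(30:80, 1L)
  utr3 <- sample(30:80, 1L)
  tlen <- utr5 + cds_len + utr3
  n_exons <- sample(1:3, 1L)
  cuts <- integer(0L)
  if (n_exons > 1L) {
    for (k in 1:50) {
      cuts <- sort(sample(seq(60L, tlen - 60L), n_exons - 1L))
      if (all(diff(c(0L, cuts, tlen)) >= 50L)) break
    }
  }
  exon_t <- cbind(start = c(1L, cuts + 1L), end = c(cuts, tlen))
  introns <- if (n_exons > 1L) sample(80:200, n_exons - 1L, replace = TRUE)
             else integer(0L)
  # o-coordinates: exons shifted by cumulative intron length before them
  shift <- c(0L, cumsum(introns))
  exon_o <- exon_t + shift[seq_len(n_exons)]
  span <- tlen + sum(introns)
  tseq <- paste0(paste(rand_bases(utr5), collapse = ""), coding,
                 paste(rand_bases(utr3), collapse = ""))
  segs <- character(0L)
  for (k in seq_len(n_exons)) {
    segs <- c(segs, substr(tseq, exon_t[k, 1L], exon_t[k, 2L]))
    if (k < n_exons)
      segs <- c(segs, paste(rand_bases(introns[k]), collapse = ""))
  }
  list(tag = tag, tlen = tlen, span = span, utr5 = utr5, utr3 = utr3,
       cds_len = cds_len, coding = coding, tseq = tseq,
       exon_t = exon_t, exon_o = exon_o, introns = introns,
       oseq = paste(segs, collapse = ""))
}

# intersect transcript-range [lo, hi] with exons, in o-coordinates
t_range_to_o <- function(g, lo, hi) {
  out <- NULL
  for (k in seq_len(nrow(g$exon_t))) {
    s <- max(lo, g$exon_t[k, 1L]); e <- min(hi, g$exon_t[k, 2L])
    if (s <= e) {
      d <- g$exon_o[k, 1L] - g$exon_t[k, 1L]
      out <- rbind(out, c(s + d, e + d))
    }
  }
  out
}

o_to_genomic <- function(iv, start, span, strand) {
  if (is.null(iv)) return(NULL)
  if (strand == "+") cbind(start - 1L + iv[, 1L], start - 1L + iv[, 2L])
  else cbind(start + span - iv[, 2L], start + span - iv[, 1L])
}

#' Simulate a reference genome with gene models
#'
#' Generates uniform-random chromosomes and plants non-overlapping
#' multi-exon protein-coding genes (ATG start, stop codon, CDS length a
#' multiple of 3, no internal stops), each with 5'/3' UTRs and random
#' strand.  The design is fully determined by `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `sim_reference` with elements `genome`
#'   (`DNAStringSet`), `genes` (`gene_model_list`) and `layout`
#'   (internal per-gene truth used by the generator).
#' @export
simulate_reference <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  genome <- list()
  genes <- list()
  layout <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    chr_seq <- rand_bases(cfg$chrom_length)
    pos <- 1L
    for (gi in seq_len(cfg$genes_per_chromosome)) {
      gid <- sprintf("gene_%s_%03d", chrom, gi)
      g <- design_gene(gid)
      gap <- sample(200:800, 1L)
      start <- pos + gap
      if (start + g$span > cfg$chrom_length - 200L)
        stop("gene placement failed on ", chrom,
             "; lower genes_per_chromosome or raise chrom_length")
      strand <- sample(c("+", "-"), 1L)
      plus_seq <- if (strand == "+") g$oseq else revcomp(g$oseq)
      chr_seq[start:(start + g$span - 1L)] <-
        strsplit(plus_seq, "", fixed = TRUE)[[1L]]
      cds_o <- t_range_to_o(g, g$utr5 + 1L, g$utr5 + g$cds_len)
      utr5_o <- t_range_to_o(g, 1L, g$utr5)
      utr3_o <- t_range_to_o(g, g$utr5 + g$cds_len + 1L, g$tlen)
      model <- gene_model(
        gene_id = gid, tx_id = paste0(gid, ".t1"), chrom = chrom,
        strand = strand,
        exons = o_to_genomic(g$exon_o, start, g$span, strand),
        cds = o_to_genomic(cds_o, start, g$span, strand),
        utr5 = o_to_genomic(if (strand == "+") utr5_o else utr5_o,
                            start, g$span, strand),
        utr3 = o_to_genomic(utr3_o, start, g$span, strand))
      genes[[length(genes) + 1L]] <- model
      layout[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                            start = start, span = g$span, utr5 = g$utr5,
                            cds_len = g$cds_len, tlen = g$tlen,
                            exon_o = g$exon_o, exon_t = g$exon_t,
                            coding = g$coding)
      pos <- start + g$span
    }
    genome[[chrom]] <- paste(chr_seq, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(genome))
  structure(list(genome = genome,
                 genes = structure(genes, class = "gene_model_list"),
                 layout = layout, cfg = cfg),
            class = "sim_reference")
}

# o-coordinate of a genomic position within a gene layout, or NA
genomic_to_o <- function(lay, gpos) {
  if (lay$strand == "+") gpos - lay$start + 1L
  else lay$start + lay$span - gpos
}

# region of a genomic position per the generator's own arithmetic
# (independent of assign_region): CDS/UTR/intron/intergenic + transcript
# CDS offset for coding positions
layout_region <- function(lay, gpos) {
  o <- genomic_to_o(lay, gpos)
  if (o < 1L || o > lay$span) return(list(region = "intergenic", t = NA))
  k <- which(o >= lay$exon_o[, 1L] & o <= lay$exon_o[, 2L])
  if (length(k) == 0L) return(list(region = "intron", t = NA))
  t <- lay$exon_t[k, 1L] + (o - lay$exon_o[k, 1L])
  if (t <= lay$utr5 || t > lay$utr5 + lay$cds_len)
    return(list(region = "UTR", t = t))
  list(region = "CDS", t = t, cds_off = t - lay$utr5)
}

# transition partner and the two transversion partners per base
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

draw_alt <- function(ref, ts_prob) {
  n <- length(ref)
  is_ts <- stats::runif(n) < ts_prob
  alt <- character(n)
  alt[is_ts] <- TS_PARTNER[ref[is_ts]]
  for (i in which(!is_ts)) alt[i] <- sample(TV_PARTNERS[[ref[i]]], 1L)
  alt
}

# shared variant component, regenerated identically for both genotypes
sim_common_variants <- function(ref, cfg) {
  set.seed(cfg$seed + 11L)
  sim_variant_positions(ref, cfg, cfg$snp_density_common,
                        cfg$indel_density_common, exclude = NULL)
}

# draw SNP and InDel positions + alleles (no zygosity/qual yet)
sim_variant_positions <- function(ref, cfg, snp_per_kb, indel_per_kb,
                                  exclude = NULL) {
  out <- NULL
  for (chrom in names(ref$genome)) {
    L <- length(ref$genome[[chrom]])
    chr_bases <- strsplit(as.character(ref$genome[[chrom]]), "",
                          fixed = TRUE)[[1L]]
    n_snp <- round(snp_per_kb * L / 1000)
    n_ind <- round(indel_per_kb * L / 1000)
    pool <- 2:(L - 45L)
    if (!is.null(exclude)) pool <- setdiff(pool, exclude$pos[exclude$chrom == chrom])
    pos <- sample(pool, n_snp + n_ind)
    snp_pos <- sort(pos[seq_len(n_snp)])
    ind_pos <- sort(pos[n_snp + seq_len(n_ind)])
    snp_ref <- chr_bases[snp_pos]
    snp_alt <- draw_alt(snp_ref, cfg$ts_tv / (cfg$ts_tv + 1))
    lens <- pmin(stats::rgeom(n_ind, cfg$indel_geom_p) + 1L, 40L)
    is_ins <- stats::runif(n_ind) < cfg$insertion_prob
    anchor <- chr_bases[ind_pos]
    ind_ref <- ind_alt <- character(n_ind)
    for (i in seq_len(n_ind)) {
      if (is_ins[i]) {
        ind_ref[i] <- anchor[i]
        ind_alt[i] <- paste(c(anchor[i], rand_bases(lens[i])), collapse = "")
      } else {
        ind_ref[i] <- paste(chr_bases[ind_pos[i]:(ind_pos[i] + lens[i])],
                            collapse = "")
        ind_alt[i] <- anchor[i]
      }
    }
    out <- rbind(out,
                 data.frame(chrom = rep(chrom, n_snp), pos = snp_pos,
                            ref = snp_ref, alt = snp_alt,
                            stringsAsFactors = FALSE),
                 data.frame(chrom = rep(chrom, n_ind), pos = ind_pos,
                            ref = ind_ref, alt = ind_alt,
                            stringsAsFactors = FALSE))
  }
  out
}

#' Simulate one genotype's variant calls
#'
#' Plants SNPs and InDels on the reference at the configured densities:
#' alternate alleles are drawn with transition probability
#' `ts_tv / (ts_tv + 1)`, zygosity is Bernoulli with the genotype's
#' heterozygous fraction, and InDel lengths are geometric (truncated at
#' 40 bp, mononucleotide-dominant).  The shared component
#' (`*_density_common`) is regenerated identically for both genotypes,
#' so calling this for `"scion"` and `"rootstock"` yields overlapping
#' call sets with a known common part.
#'
#' @param ref a `sim_reference`.
#' @param cfg a [simulation_config()].
#' @param genotype `"scion"` or `"rootstock"`.
#' @return a `variant_records` table with attribute `truth`: a
#'   data.frame of per-variant region (generator arithmetic, not
#'   [assign_region()]) and coding effect for CDS SNPs.
#' @export
simulate_genotype <- function(ref, cfg = simulation_config(),
                              genotype = c("scion", "rootstock")) {
  genotype <- match.arg(genotype)
  common <- sim_common_variants(ref, cfg)
  set.seed(cfg$seed + if (genotype == "scion") 13L else 17L)
  dens_snp <- (if (genotype == "scion") cfg$snp_density_scion
               else cfg$snp_density_rootstock) - cfg$snp_density_common
  dens_ind <- (if (genotype == "scion") cfg$indel_density_scion
               else cfg$indel_density_rootstock) - cfg$indel_density_common
  het <- if (genotype == "scion") cfg$het_scion else cfg$het_rootstock
  specific <- sim_variant_positions(ref, cfg, dens_snp, dens_ind,
                                    exclude = common)
  v <- rbind(common, specific)
  n <- nrow(v)
  zyg <- ifelse(stats::runif(n) < het, "heterozygous", "homozygous")
  qual <- round(pmax(stats::rnorm(n, cfg$qual_mean, cfg$qual_sd), 1), 1)
  depth <- stats::rpois(n, cfg$genomic_depth)
  depth[depth < 1L] <- 1L
  rec <- variant_records(v$chrom, v$pos, v$ref, v$alt, qual, depth, zyg)
  attr(rec, "truth") <- genotype_truth(rec, ref)
  rec
}

# generator-side region/effect truth table for a variant set
genotype_truth <- function(rec, ref) {
  region <- rep("intergenic", nrow(rec))
  effect <- rep(NA_character_, nrow(rec))
  gene <- rep(NA_character_, nrow(rec))
  snp <- is_snp(rec)
  for (lay in ref$layout) {
    sel <- which(rec$chrom == lay$chrom & rec$pos >= lay$start &
                   rec$pos <= lay$start + lay$span - 1L)
    for (i in sel) {
      r <- layout_region(lay, rec$pos[i])
      region[i] <- r$region
      gene[i] <- lay$gene_id
      if (r$region == "CDS" && snp[i]) {
        off <- r$cds_off
        codon_i <- (off - 1L) %/% 3L
        within <- (off - 1L) %% 3L + 1L
        codon <- substr(lay$coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
        alt <- if (lay$strand == "+") rec$alt[i] else comp_base(rec$alt[i])
        effect[i] <- if (codon_i == 0L) "start_lost"
                     else codon_effect(codon, within, alt)
      }
    }
  }
  data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
             region = region, gene_id = gene, effect = effect,
             stringsAsFactors = FALSE)
}

# per-genotype allele pair at every exonic site
exon_site_table <- function(ref) {
  rows <- NULL
  for (lay in ref$layout) {
    m <- NULL
    for (k in seq_len(nrow(lay$exon_o))) {
      o <- lay$exon_o[k, 1L]:lay$exon_o[k, 2L]
      g <- if (lay$strand == "+") lay$start - 1L + o else lay$start + lay$span - o
      m <- c(m, g)
    }
    rows <- rbind(rows, data.frame(chrom = lay$chrom, pos = sort(m),
                                   gene_id = lay$gene_id,
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
  chr_bases <- lapply(names(ref$genome), function(ch)
    strsplit(as.character(ref$genome[[ch]]), "", fixed = TRUE)[[1L]])
  names(chr_bases) <- names(ref$genome)
  rows$ref <- unlist(Map(function(ch, p) chr_bases[[ch]][p],
                         rows$chrom, rows$pos), use.names = FALSE)
  rownames(rows) <- NULL
  rows
}

apply_genotype_alleles <- function(sites, variants) {
  a1 <- sites$ref; a2 <- sites$ref
  v <- variants[is_snp(variants), , drop = FALSE]
  i <- match(paste(sites$chrom, sites$pos), paste(v$chrom, v$pos))
  hit <- !is.na(i)
  hom <- hit & v$zygosity[i] == "homozygous"
  het <- hit & v$zygosity[i] == "heterozygous"
  a1[hom] <- v$alt[i[hom]]
  a2[hom] <- v$alt[i[hom]]
  a2[het] <- v$alt[i[het]]
  cbind(a1 = a1, a2 = a2)
}

# expected base fractions per site given an allele pair and error rate
allele_probs <- function(alleles, error_rate) {
  n <- nrow(alleles)
  p <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
  p[cbind(seq_len(n), match(alleles[, 1L], BASES))] <-
    p[cbind(seq_len(n), match(alleles[, 1L], BASES))] + 0.5
  p[cbind(seq_len(n), match(alleles[, 2L], BASES))] <-
    p[cbind(seq_len(n), match(alleles[, 2L], BASES))] + 0.5
  p * (1 - error_rate) + (1 - p) * error_rate / 3
}

draw_library <- function(sites, probs, depth_mean) {
  lam <- probs * depth_mean
  cnt <- matrix(stats::rpois(length(lam), lam), nrow(probs), 4L)
  site_counts(sites$chrom, sites$pos, cnt[, 1L], cnt[, 2L], cnt[, 3L],
              cnt[, 4L])
}

#' Simulate graft RNA pileups with a known truth table
#'
#' For every exonic site of every gene, draws per-library A/C/G/T read
#' counts as Poisson-thinned multinomials around `rna_depth`: each
#' partner's library carries its own alleles (heterozygous sites 50:50
#' in expectation) plus uniform sequencing error, and genes planted as
#' mobile additionally contribute donor-genotype reads at
#' `donor_transcript_fraction` of site depth in the recipient partner's
#' library of the designated tissue.  Pre-graft control libraries carry
#' no donor reads.  Mobile genes are drawn only from genes with at
#' least one exonic diagnostic locus (both genotypes homozygous for
#' different alleles), so every planted gene is recoverable in
#' principle.
#'
#' @param ref a `sim_reference`.
#' @param scion,rootstock genotype call sets from [simulate_genotype()].
#' @param cfg a [simulation_config()].
#' @return a list of class `sim_graft` with `libraries[[tissue]][[partner]]`
#'   (list of `n_replicates` [site_counts()] tables),
#'   `controls[[partner]]` (same shape), and `truth`: `mobile_genes`
#'   (gene_id, tissue, direction) and `diagnostic_loci` (chrom, pos,
#'   scion_allele, rootstock_allele, gene_id).
#' @export
simulate_graft_pileups <- function(ref, scion, rootstock,
                                   cfg = simulation_config()) {
  sites <- exon_site_table(ref)
  al_s <- apply_genotype_alleles(sites, scion)
  al_r <- apply_genotype_alleles(sites, rootstock)
  hom_s <- al_s[, 1L] == al_s[, 2L]
  hom_r <- al_r[, 1L] == al_r[, 2L]
  diag <- hom_s & hom_r & al_s[, 1L] != al_r[, 1L]
  truth_loci <- data.frame(chrom = sites$chrom[diag], pos = sites$pos[diag],
                           scion_allele = al_s[diag, 1L],
                           rootstock_allele = al_r[diag, 1L],
                           gene_id = sites$gene_id[diag],
                           stringsAsFactors = FALSE)
  eligible <- unique(truth_loci$gene_id)
  if (cfg$n_mobile_genes > length(eligible))
    stop("not enough genes with exonic diagnostic loci (",
         length(eligible), ") for n_mobile_genes = ", cfg$n_mobile_genes)
  set.seed(cfg$seed + 23L)
  mobile <- if (cfg$n_mobile_genes > 0L)
    sample(eligible, cfg$n_mobile_genes) else character(0L)
  direction <- if (length(mobile))
    sample(names(cfg$direction_probs), length(mobile), replace = TRUE,
           prob = cfg$direction_probs) else character(0L)
  tissue <- if (length(mobile))
    sample(cfg$tissues, length(mobile), replace = TRUE) else character(0L)
  truth_mobile <- data.frame(gene_id = mobile, tissue = tissue,
                             direction = direction, stringsAsFactors = FALSE)

  probs_s <- allele_probs(al_s, cfg$error_rate)
  probs_r <- allele_probs(al_r, cfg$error_rate)
  f <- cfg$donor_transcript_fraction
  # receptor-library probabilities with donor transcripts mixed in for
  # genes mobile into that (tissue, partner)
  mixed_probs <- function(receptor, tis) {
    base <- if (receptor == "scion") probs_s else probs_r
    donor <- if (receptor == "scion") probs_r else probs_s
    into <- if (receptor == "scion") c("rootstock_to_scion", "bidirectional")
            else c("scion_to_rootstock", "bidirectional")
    gsel <- truth_mobile$gene_id[truth_mobile$direction %in% into &
                                   truth_mobile$tissue == tis]
    w <- ifelse(sites$gene_id %in% gsel, f, 0)
    base * (1 - w) + donor * w
  }
  libraries <- list()
  k <- 0L
  for (tis in cfg$tissues) {
    libraries[[tis]] <- list()
    for (partner in c("scion", "rootstock")) {
      p <- mixed_probs(partner, tis)
      reps <- vector("list", cfg$n_replicates)
      for (r in seq_len(cfg$n_replicates)) {
        k <- k + 1L
        set.seed(cfg$seed + 100L + k)
        reps[[r]] <- draw_library(sites, p, cfg$rna_depth)
      }
      libraries[[tis]][[partner]] <- reps
    }
  }
  controls <- list()
  for (partner in c("scion", "rootstock")) {
    p <- if (partner == "scion") probs_s else probs_r
    reps <- vector("list", cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      k <- k + 1L
      set.seed(cfg$seed + 100L + k)
      reps[[r]] <- draw_library(sites, p, cfg$rna_depth)
    }
    controls[[partner]] <- reps
  }
  structure(list(libraries = libraries, controls = controls,
                 truth = list(mobile_genes = truth_mobile,
                              diagnostic_loci = truth_loci),
                 sites = sites, cfg = cfg),
            class = "sim_graft")
}

#' Write a simulated reference to FASTA and GFF3
#'
#' @param ref a `sim_reference`.
#' @param fasta,gff output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_reference <- function(ref, fasta, gff) {
  lines <- character(0L)
  for (ch in names(ref$genome)) {
    s <- as.character(ref$genome[[ch]])
    chunks <- substring(s, seq(1L, nchar(s), 70L),
                        pmin(seq(1L, nchar(s), 70L) + 69L, nchar(s)))
    lines <- c(lines, paste0(">", ch), chunks)
  }
  writeLines(lines, fasta)
  rows <- c("##gff-version 3")
  for (m in ref$genes) {
    sp <- transcript_span(m)
    feat <- function(type, start, end, attrs, phase = ".") {
      paste(m$chrom, "graftscope", type, start, end, ".", m$strand, phase,
            attrs, sep = "\t")
    }
    rows <- c(rows,
              feat("gene", sp[1L], sp[2L], paste0("ID=", m$gene_id)),
              feat("mRNA", sp[1L], sp[2L],
                   paste0("ID=", m$tx_id, ";Parent=", m$gene_id)))
    add_rows <- function(mat, type, phases = NULL) {
      out <- character(0L)
      for (k in seq_len(nrow(mat))) {
        ph <- if (is.null(phases)) "." else phases[k]
        out <- c(out, feat(type, mat[k, 1L], mat[k, 2L],
                           paste0("ID=", m$tx_id, ".", type, k,
                                  ";Parent=", m$tx_id), ph))
      }
      out
    }
    rows <- c(rows, add_rows(m$exons, "exon"),
              add_rows(m$cds, "CDS", m$phase),
              add_rows(m$utr5, "five_prime_UTR"),
              add_rows(m$utr3, "three_prime_UTR"))
  }
  writeLines(rows, gff)
  invisible(c(fasta, gff))
}

#' Run the full mobility pipeline on a synthetic dataset
#'
#' Generates reference, genotypes and graft pileups, filters the
#' genotype calls, derives diagnostic loci from the genomic route,
#' merges RNA replicates, calls mobile genes per tissue, and scores the
#' calls against the planted truth.
#'
#' @param cfg a [simulation_config()].
#' @param mob_cfg a [mobility_config()].
#' @return list with `sensitivity`, `fdr`, `direction_accuracy`,
#'   `n_planted`, `n_called`, `calls` (all tissues), `truth`,
#'   `tallies` (per tissue), and the intermediate objects `ref`, `loci`.
#' @export
evaluate_mobility_recovery <- function(cfg = simulation_config(),
                                       mob_cfg = mobility_config()) {
  ref <- simulate_reference(cfg)
  scion <- simulate_genotype(ref, cfg, "scion")
  rootstock <- simulate_genotype(ref, cfg, "rootstock")
  fs <- apply_filters(scion)$records
  fr <- apply_filters(rootstock)$records
  loci <- diagnostic_loci_from_vcf(fs, fr)
  graft <- simulate_graft_pileups(ref, scion, rootstock, cfg)
  ctrl_s <- merge_replicates(graft$controls$scion)
  ctrl_r <- merge_replicates(graft$controls$rootstock)
  calls <- NULL
  tallies <- list()
  for (tis in cfg$tissues) {
    rna_s <- merge_replicates(graft$libraries[[tis]]$scion)
    rna_r <- merge_replicates(graft$libraries[[tis]]$rootstock)
    res <- call_mobile_genes(loci, rna_s, rna_r, ctrl_s, ctrl_r,
                             ref$genes, mob_cfg, tissue = tis)
    calls <- rbind(calls, res$calls)
    tallies[[tis]] <- res$tally
  }
  truth <- graft$truth$mobile_genes
  key <- function(d) paste(d$gene_id, d$tissue)
  called <- if (is.null(calls)) character(0L) else key(calls)
  planted <- key(truth)
  tp <- intersect(called, planted)
  sens <- if (length(planted)) length(tp) / length(planted) else NA_real_
  fdr <- if (length(called)) 1 - length(tp) / length(called) else 0
  dir_ok <- if (length(tp)) {
    cd <- calls$direction[match(tp, called)]
    td <- truth$direction[match(tp, planted)]
    mean(cd == td)
  } else NA_real_
  list(sensitivity = sens, fdr = fdr, direction_accuracy = dir_ok,
       n_planted = length(planted), n_called = length(called),
       calls = calls, truth = truth, tallies = tallies,
       ref = ref, loci = loci)
}
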