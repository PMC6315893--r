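#' Mobile-transcript detection thresholds
#'
#' Thresholds of the diagnostic-SNP mobility caller.  A site is called
#' homozygous when the dominant allele has at least `min_reads`
#' supporting reads and strictly more than `hom_freq` of the depth.
#' Donor transcripts are supported at a diagnostic locus when the donor
#' allele carries strictly more than `donor_fraction` of receptor reads,
#' the receptor site shows exactly two alleles above the noise floor,
#' and the donor allele is absent from the receptor's pre-graft control.
#'
#' @param min_reads minimum reads on the dominant allele (inclusive).
#' @param hom_freq dominant-allele frequency for homozygosity
#'   (strict ">", default 0.95).
#' @param donor_fraction minimum donor-allele read share at a supported
#'   site (strict ">", default 0.05).
#' @param min_support_snps diagnostic SNPs required per mobile gene.
#' @param presence_min_reads,presence_min_frac noise floor above which
#'   an allele counts as "present" for the two-allele and control
#'   checks (defaults: 2 reads and 1% of depth).
#' @return a list of class `mobility_config`.
#' @export
mobility_config <- function(min_reads = 5L, hom_freq = 0.95,
                            donor_fraction = 0.05, min_support_snps = 1L,
                            presence_min_reads = 2L,
                            presence_min_frac = 0.01) {
  stopifnot(donor_fraction > 0, donor_fraction < hom_freq, hom_freq <= 1,
            min_reads >= 1L, min_support_snps >= 1L)
  structure(list(min_reads = as.integer(min_reads), hom_freq = hom_freq,
                 donor_fraction = donor_fraction,
                 min_support_snps = as.integer(min_support_snps),
                 presence_min_reads = as.integer(presence_min_reads),
                 presence_min_frac = presence_min_frac),
            class = "mobility_config")
}

#' Merge replicate pileups
#'
#' Element-wise sum of base counts across biological replicates;
#' positions present in any replicate appear once.
#'
#' @param replicates a list of [site_counts()] tables.
#' @return one merged `site_counts` table.
#' @export
merge_replicates <- function(replicates) {
  if (length(replicates) == 1L) return(replicates[[1L]])
  x <- do.call(rbind, lapply(replicates, as.data.frame))
  agg <- stats::aggregate(x[paste0("count_", BASES)],
                          by = list(chrom = x$chrom, pos = x$pos), FUN = sum)
  site_counts(agg$chrom, agg$pos, agg$count_A, agg$count_C,
              agg$count_G, agg$count_T)
}

#' Consensus genotype of pileup sites
#'
#' The dominant allele is the base with the highest count (a tie means
#' no call).  The site is homozygous for that allele iff its count is
#' at least `min_reads` and its frequency strictly exceeds `hom_freq`.
#'
#' @param sites a [site_counts()] table.
#' @param cfg a [mobility_config()].
#' @return character vector (one per site) holding the homozygous
#'   allele, or `NA` for not-homozygous sites.
#' @export
consensus_genotype <- function(sites, cfg = mobility_config()) {
  m <- as.matrix(sites[paste0("count_", BASES)])
  if (nrow(m) == 0L) return(character(0L))
  top <- apply(m, 1L, max)
  n_at_top <- rowSums(m == top)
  which_top <- max.col(m, ties.method = "first")
  allele <- BASES[which_top]
  ok <- n_at_top == 1L & top >= cfg$min_reads & sites$depth > 0 &
    top / sites$depth > cfg$hom_freq
  allele[!ok] <- NA_character_
  allele
}

#' Diagnostic loci from genotyped pileups
#'
#' Positions covered in both graft partners where each partner is
#' homozygous (per [consensus_genotype()]) for a different allele.
#'
#' @param scion_sites,rootstock_sites merged [site_counts()] tables for
#'   the two partners.
#' @param cfg a [mobility_config()].
#' @return data.frame of class `diagnostic_loci`: chrom, pos,
#'   scion_allele, rootstock_allele, and per-partner supporting reads
#'   and allele fractions.
#' @export
find_diagnostic_loci <- function(scion_sites, rootstock_sites,
                                 cfg = mobility_config()) {
  gs <- consensus_genotype(scion_sites, cfg)
  gr <- consensus_genotype(rootstock_sites, cfg)
  s <- data.frame(chrom = scion_sites$chrom, pos = scion_sites$pos,
                  scion_allele = gs,
                  scion_reads = allele_count(scion_sites, gs),
                  scion_depth = scion_sites$depth, stringsAsFactors = FALSE)
  r <- data.frame(chrom = rootstock_sites$chrom, pos = rootstock_sites$pos,
                  rootstock_allele = gr,
                  rootstock_reads = allele_count(rootstock_sites, gr),
                  rootstock_depth = rootstock_sites$depth,
                  stringsAsFactors = FALSE)
  m <- merge(s, r, by = c("chrom", "pos"))
  m <- m[!is.na(m$scion_allele) & !is.na(m$rootstock_allele) &
           m$scion_allele != m$rootstock_allele, , drop = FALSE]
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    scion_allele = m$scion_allele,
                    rootstock_allele = m$rootstock_allele,
                    scion_reads = m$scion_reads,
                    scion_frac = m$scion_reads / m$scion_depth,
                    rootstock_reads = m$rootstock_reads,
                    rootstock_frac = m$rootstock_reads / m$rootstock_depth,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_loci", "data.frame")
  out
}

allele_count <- function(sites, allele) {
  m <- as.matrix(sites[paste0("count_", BASES)])
  out <- rep(NA_integer_, nrow(sites))
  ok <- !is.na(allele)
  if (any(ok)) out[ok] <- m[cbind(which(ok), match(allele[ok], BASES))]
  out
}

#' Diagnostic loci from genomic variant calls
#'
#' The genomic-sequencing route: each partner's genotype at a SNP
#' position is its homozygous alternate allele when a homozygous SNP
#' record exists there, the reference allele when no record exists, and
#' no-call when the record is heterozygous or the position is
#' multi-allelic.  Diagnostic loci are positions where both partners
#' have a call and the calls differ.  Only positions carrying a SNP in
#' at least one partner are considered (elsewhere both are reference).
#'
#' @param scion_variants,rootstock_variants `variant_records` tables
#'   (typically post-[apply_filters()]).
#' @return a `diagnostic_loci` table (read supports are `NA`: genomic
#'   evidence, not pileup counts).
#' @export
diagnostic_loci_from_vcf <- function(scion_variants, rootstock_variants) {
  genotype_at <- function(v) {
    v <- v[is_snp(v), , drop = FALSE]
    key <- paste(v$chrom, v$pos)
    multi <- key %in% key[duplicated(key)]
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
               allele = ifelse(multi | v$zygosity != "homozygous",
                               NA_character_, v$alt),
               het = v$zygosity == "heterozygous" | multi,
               stringsAsFactors = FALSE)
  }
  a <- genotype_at(scion_variants)
  b <- genotype_at(rootstock_variants)
  m <- merge(a, b, by = c("chrom", "pos"), all = TRUE,
             suffixes = c("_s", "_r"))
  # a partner with no record at a covered SNP position is homozygous
  # reference there; the reference base comes from the other partner
  ref <- ifelse(is.na(m$ref_s), m$ref_r, m$ref_s)
  consistent <- is.na(m$ref_s) | is.na(m$ref_r) | m$ref_s == m$ref_r
  gs <- ifelse(is.na(m$ref_s), ref, m$allele_s)
  gr <- ifelse(is.na(m$ref_r), ref, m$allele_r)
  keep <- consistent & !is.na(gs) & !is.na(gr) & gs != gr
  out <- data.frame(chrom = m$chrom[keep], pos = m$pos[keep],
                    scion_allele = gs[keep], rootstock_allele = gr[keep],
                    scion_reads = NA_integer_, scion_frac = NA_real_,
                    rootstock_reads = NA_integer_, rootstock_frac = NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_loci", "data.frame")
  out
}

#' Test diagnostic loci for donor-transcript support
#'
#' A locus supports mobility into the receptor when (a) donor-allele
#' reads exceed `donor_fraction` of the receptor RNA depth (strict),
#' (b) the receptor site shows exactly the two expected alleles (donor
#' and receptor) above the noise floor, and (c) the donor allele is
#' absent above the noise floor from the receptor's pre-graft control
#' library at that position (conflict-free condition).  Zero receptor
#' depth is unsupported, not an error; a position absent from the
#' control is treated as conflict-free.
#'
#' @param loci a `diagnostic_loci` table.
#' @param receptor_sites merged receptor RNA [site_counts()].
#' @param control_sites merged pre-graft control [site_counts()] for the
#'   receptor partner (may be `NULL` to skip check (c)).
#' @param cfg a [mobility_config()].
#' @param donor `"scion"` or `"rootstock"`: which partner's allele is
#'   the travelling one.
#' @return `loci` with added columns `donor_count`, `donor_frac`,
#'   `receptor_depth`, `supported`.
#' @export
detect_mobility <- function(loci, receptor_sites, control_sites = NULL,
                            cfg = mobility_config(),
                            donor = c("scion", "rootstock")) {
  donor <- match.arg(donor)
  donor_allele <- if (donor == "scion") loci$scion_allele else loci$rootstock_allele
  receptor_allele <- if (donor == "scion") loci$rootstock_allele else loci$scion_allele
  i <- match(paste(loci$chrom, loci$pos),
             paste(receptor_sites$chrom, receptor_sites$pos))
  m <- as.matrix(receptor_sites[paste0("count_", BASES)])
  depth <- receptor_sites$depth
  n <- nrow(loci)
  donor_count <- integer(n); rdepth <- integer(n)
  supported <- rep(FALSE, n)
  present <- function(counts, dp) {
    counts >= cfg$presence_min_reads & counts >= cfg$presence_min_frac * dp
  }
  ok <- !is.na(i)
  if (any(ok)) {
    ii <- i[ok]
    cm <- m[ii, , drop = FALSE]
    dp <- depth[ii]
    dc <- cm[cbind(seq_len(nrow(cm)), match(donor_allele[ok], BASES))]
    rc <- cm[cbind(seq_len(nrow(cm)), match(receptor_allele[ok], BASES))]
    donor_count[ok] <- dc
    rdepth[ok] <- dp
    pres <- present(cm, dp)
    n_present <- rowSums(pres)
    donor_present <- pres[cbind(seq_len(nrow(cm)), match(donor_allele[ok], BASES))]
    receptor_present <- pres[cbind(seq_len(nrow(cm)), match(receptor_allele[ok], BASES))]
    two_alleles <- n_present == 2L & donor_present & receptor_present
    frac_ok <- dp > 0 & dc / pmax(dp, 1L) > cfg$donor_fraction
    supported[ok] <- frac_ok & two_alleles
  }
  if (!is.null(control_sites) && any(supported)) {
    j <- match(paste(loci$chrom, loci$pos),
               paste(control_sites$chrom, control_sites$pos))
    cm <- as.matrix(control_sites[paste0("count_", BASES)])
    has_ctrl <- !is.na(j) & supported
    if (any(has_ctrl)) {
      jj <- j[has_ctrl]
      dcc <- cm[cbind(jj, match(donor_allele[has_ctrl], BASES))]
      conflict <- present(dcc, control_sites$depth[jj])
      supported[which(has_ctrl)[conflict]] <- FALSE
    }
  }
  out <- loci
  out$donor_count <- donor_count
  out$donor_frac <- ifelse(rdepth > 0, donor_count / rdepth, 0)
  out$receptor_depth <- rdepth
  out$supported <- supported
  out
}

#' Aggregate supported loci into gene-level mobility calls
#'
#' Maps supported diagnostic loci to gene models by transcript span,
#' forms per-direction gene sets, labels genes supported in both
#' directions bidirectional, and reports the Fig-style direction
#' tallies: each directional tally includes the bidirectional genes,
#' and the union follows inclusion-exclusion.
#'
#' @param supported_loci data.frame of supported loci with a
#'   `direction` column (`"scion_to_rootstock"` /
#'   `"rootstock_to_scion"`) and the columns of `diagnostic_loci`.
#' @param genes a `gene_model_list`.
#' @param cfg a [mobility_config()]; genes need at least
#'   `min_support_snps` supporting loci per direction.
#' @param tissue label copied onto the calls.
#' @return list with `calls` (gene_id, tissue, direction, n_support,
#'   best_donor_frac), `tally` (named counts: scion_to_rootstock,
#'   rootstock_to_scion, bidirectional, union) and `n_dropped_loci`
#'   (supported loci outside every transcript).
#' @export
aggregate_genes <- function(supported_loci, genes, cfg = mobility_config(),
                            tissue = "leaf") {
  spans <- do.call(rbind, lapply(genes, function(m) {
    sp <- transcript_span(m)
    data.frame(chrom = m$chrom, start = sp[1L], end = sp[2L],
               gene_id = m$gene_id, stringsAsFactors = FALSE)
  }))
  empty_calls <- data.frame(gene_id = character(), tissue = character(),
                            direction = character(), n_support = integer(),
                            best_donor_frac = numeric(),
                            stringsAsFactors = FALSE)
  tally0 <- c(scion_to_rootstock = 0L, rootstock_to_scion = 0L,
              bidirectional = 0L, union = 0L)
  if (is.null(spans) || nrow(supported_loci) == 0L)
    return(list(calls = empty_calls, tally = tally0,
                n_dropped_loci = nrow(supported_loci)))
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  vr <- GenomicRanges::GRanges(supported_loci$chrom,
                               IRanges::IRanges(supported_loci$pos,
                                                supported_loci$pos))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  n_dropped <- nrow(supported_loci) - length(unique(q))
  if (length(q) == 0L)
    return(list(calls = empty_calls, tally = tally0,
                n_dropped_loci = n_dropped))
  df <- data.frame(gene_id = spans$gene_id[s],
                   direction = supported_loci$direction[q],
                   donor_frac = supported_loci$donor_frac[q],
                   stringsAsFactors = FALSE)
  df$locus <- q
  df <- unique(df)
  agg <- stats::aggregate(locus ~ gene_id + direction, data = df,
                          FUN = function(x) length(unique(x)))
  names(agg)[names(agg) == "locus"] <- "n_support"
  best <- stats::aggregate(donor_frac ~ gene_id + direction, data = df,
                           FUN = max)
  agg <- merge(agg, best, by = c("gene_id", "direction"))
  agg <- agg[agg$n_support >= cfg$min_support_snps, , drop = FALSE]
  s2r <- unique(agg$gene_id[agg$direction == "scion_to_rootstock"])
  r2s <- unique(agg$gene_id[agg$direction == "rootstock_to_scion"])
  bidi <- intersect(s2r, r2s)
  call_dir <- function(g) {
    if (g %in% bidi) "bidirectional"
    else if (g %in% s2r) "scion_to_rootstock"
    else "rootstock_to_scion"
  }
  genes_all <- sort(union(s2r, r2s))
  calls <- do.call(rbind, lapply(genes_all, function(g) {
    rows <- agg[agg$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, tissue = tissue, direction = call_dir(g),
               n_support = sum(rows$n_support),
               best_donor_frac = max(rows$donor_frac),
               stringsAsFactors = FALSE)
  })) %||% empty_calls
  tally <- c(scion_to_rootstock = length(s2r),
             rootstock_to_scion = length(r2s),
             bidirectional = length(bidi),
             union = union_with_overlap(length(s2r), length(r2s),
                                        length(bidi)))
  list(calls = calls, tally = tally, n_dropped_loci = n_dropped)
}

#' End-to-end mobile-gene calling for one tissue
#'
#' Runs both directions of the mobility test for one tissue: tests each
#' diagnostic locus for scion-allele reads in the rootstock RNA
#' (scion_to_rootstock) and rootstock-allele reads in the scion RNA
#' (rootstock_to_scion), then aggregates to gene level.
#'
#' @param loci a `diagnostic_loci` table (from
#'   [diagnostic_loci_from_vcf()] or [find_diagnostic_loci()]).
#' @param scion_rna,rootstock_rna merged RNA [site_counts()] for the
#'   tissue.
#' @param scion_control,rootstock_control merged pre-graft control
#'   [site_counts()] per partner (or `NULL`).
#' @param genes a `gene_model_list`.
#' @param cfg a [mobility_config()].
#' @param tissue tissue label.
#' @return as [aggregate_genes()], plus `supported_loci`.
#' @export
call_mobile_genes <- function(loci, scion_rna, rootstock_rna,
                              scion_control = NULL, rootstock_control = NULL,
                              genes, cfg = mobility_config(),
                              tissue = "leaf") {
  s2r <- detect_mobility(loci, rootstock_rna, rootstock_control, cfg,
                         donor = "scion")
  r2s <- detect_mobility(loci, scion_rna, scion_control, cfg,
                         donor = "rootstock")
  s2r <- s2r[s2r$supported, , drop = FALSE]
  r2s <- r2s[r2s$supported, , drop = FALSE]
  if (nrow(s2r)) s2r$direction <- "scion_to_rootstock"
  else s2r$direction <- character(0L)
  if (nrow(r2s)) r2s$direction <- "rootstock_to_scion"
  else r2s$direction <- character(0L)
  supported <- rbind(s2r, r2s)
  res <- aggregate_genes(supported, genes, cfg, tissue = tissue)
  res$supported_loci <- supported
  res
}
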