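#' Transition or transversion
#'
#' A/G and C/T substitutions are transitions; the four other unordered
#' base pairs (A/C, A/T, C/G, G/T) are transversions.
#'
#' @param ref,alt single distinct bases (vectorized).
#' @return character vector of `"transition"` / `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("substitution_class requires single bases")
  if (any(ref == alt)) stop("ref and alt bases must differ")
  purine <- c("A", "G")
  same_family <- (ref %in% purine) == (alt %in% purine)
  ifelse(same_family, "transition", "transversion")
}

# region precedence when transcripts overlap; smaller rank wins
REGION_RANK <- c(CDS = 1L, UTR = 2L, intron = 3L, intergenic = 4L)

# internal: flatten gene models into a GRanges of CDS/UTR/intron pieces
region_ranges <- function(genes) {
  rows <- list()
  for (m in genes) {
    add <- function(mat, region) {
      if (nrow(mat) == 0L) return(NULL)
      data.frame(chrom = m$chrom, start = mat[, 1L], end = mat[, 2L],
                 region = region, gene_id = m$gene_id,
                 stringsAsFactors = FALSE)
    }
    span <- transcript_span(m)
    introns <- interval_setdiff(matrix(span, ncol = 2L), m$exons)
    utr <- rbind(m$utr5, m$utr3)
    rows[[length(rows) + 1L]] <- rbind(add(m$cds, "CDS"), add(utr, "UTR"),
                                       add(introns, "intron"))
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         region = df$region, gene_id = df$gene_id)
}

interval_setdiff <- function(a, b) {
  ia <- IRanges::IRanges(a[, 1L], a[, 2L])
  ib <- if (nrow(b)) IRanges::IRanges(b[, 1L], b[, 2L]) else IRanges::IRanges()
  r <- IRanges::setdiff(ia, ib)
  normalize_intervals(cbind(IRanges::start(r), IRanges::end(r)))
}

#' Assign each variant to a genomic region
#'
#' A variant position falling inside any transcript is genic, with its
#' sub-region resolved by the precedence CDS > UTR > intron across all
#' overlapping transcripts; everything else is intergenic.  InDels are
#' located by their anchor position.
#'
#' @param variants a `variant_records` table.
#' @param genes a `gene_model_list` from [read_gff3()].
#' @return a `data.frame` with columns `region`
#'   (CDS/UTR/intron/intergenic) and `gene_id` (NA when intergenic),
#'   one row per variant in input order.
#' @export
assign_region <- function(variants, genes) {
  out <- data.frame(region = rep("intergenic", nrow(variants)),
                    gene_id = rep(NA_character_, nrow(variants)),
                    stringsAsFactors = FALSE)
  rr <- region_ranges(genes)
  if (is.null(rr) || nrow(variants) == 0L) return(out)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(vr, rr)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  rank <- REGION_RANK[rr$region[s]]
  # per variant keep the highest-precedence hit; ties broken by gene id
  ord <- order(q, rank, rr$gene_id[s])
  first <- !duplicated(q[ord])
  sel <- ord[first]
  out$region[q[sel]] <- rr$region[s[sel]]
  out$gene_id[q[sel]] <- rr$gene_id[s[sel]]
  out
}

#' Effect of a single-base codon change
#'
#' Pure codon-table logic shared by [coding_effect()]: mutates one
#' position of a codon and compares translations under the standard
#' genetic code.
#'
#' @param codon reference codon (coding strand, 3 bases).
#' @param pos_in_codon 1, 2 or 3.
#' @param alt_base replacement base on the coding strand.
#' @return one of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"stop_lost"`.
#' @export
codon_effect <- function(codon, pos_in_codon, alt_base) {
  codon <- toupper(codon)
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- toupper(alt_base)
  if (alt_codon == codon) stop("alt base equals reference base")
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

#' Codon-level effect of a coding SNP
#'
#' Locates the variant within the spliced CDS of `gene` (strand-aware:
#' minus-strand alleles are complemented and the codon is read from the
#' coding strand), mutates the affected codon and translates.  A change
#' destroying the initiator ATG is `start_lost`.
#'
#' @param variant one-row `variant_records` table holding a SNP.
#' @param gene a `gene_model` whose CDS contains the variant.
#' @param genome `DNAStringSet` reference sequence.
#' @return effect string: synonymous, missense, nonsense, stop_lost or
#'   start_lost.
#' @export
coding_effect <- function(variant, gene, genome) {
  stopifnot(nrow(variant) == 1L)
  if (!is_snp(variant)) stop("coding_effect handles SNPs only")
  off <- cds_offset(gene, variant$pos)
  if (is.na(off))
    stop("variant at ", variant$chrom, ":", variant$pos,
         " is outside the CDS of ", gene$gene_id)
  cds <- coding_sequence(gene, genome)
  alt <- if (gene$strand == "+") variant$alt else comp_base(variant$alt)
  codon_i <- (off - 1L) %/% 3L            # 0-based codon index
  within <- (off - 1L) %% 3L + 1L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  eff <- codon_effect(codon, within, alt)
  if (codon_i == 0L && codon == "ATG") return("start_lost")
  eff
}

# internal: 1-based offset of a genomic position within the spliced CDS
# (in transcription order); NA when outside the CDS
cds_offset <- function(gene, pos) {
  cds <- gene$cds
  if (nrow(cds) == 0L) return(NA_integer_)
  inside <- pos >= cds[, 1L] & pos <= cds[, 2L]
  if (!any(inside)) return(NA_integer_)
  i <- which(inside)[1L]
  lens <- cds[, 2L] - cds[, 1L] + 1L
  if (gene$strand == "+") {
    before <- if (i > 1L) sum(lens[seq_len(i - 1L)]) else 0L
    before + (pos - cds[i, 1L]) + 1L
  } else {
    after_i <- if (i < nrow(cds)) sum(lens[(i + 1L):nrow(cds)]) else 0L
    after_i + (cds[i, 2L] - pos) + 1L
  }
}

#' Classify an InDel by reading-frame consequence
#'
#' In CDS, a length change that is not a multiple of 3 is a frameshift,
#' otherwise an in-frame indel; outside CDS the call is noncoding.
#'
#' @param variants a `variant_records` table of InDels.
#' @param region region vector from [assign_region()].
#' @return character vector of effects.
#' @export
classify_indel <- function(variants, region) {
  len <- indel_length(variants)
  ifelse(region == "CDS",
         ifelse(len %% 3L != 0L, "frameshift", "inframe_indel"),
         "noncoding")
}

#' Impact tier of a consequence call
#'
#' SnpEff-style tiers: nonsense/start_lost/stop_lost/frameshift are
#' high, missense and in-frame indels moderate, synonymous low, and
#' intron/UTR/intergenic/noncoding changes sequence modifiers.
#'
#' @param effect effect vector.
#' @return character vector of `"high"`, `"moderate"`, `"low"`,
#'   `"modifier"`.
#' @export
impact_tier <- function(effect) {
  out <- rep("modifier", length(effect))
  out[effect %in% c("nonsense", "start_lost", "stop_lost", "frameshift")] <- "high"
  out[effect %in% c("missense", "inframe_indel")] <- "moderate"
  out[effect == "synonymous"] <- "low"
  out
}

#' Functional class of a consequence call
#'
#' @param effect effect vector.
#' @return `"missense"`, `"nonsense"`, `"silent"` or `"none"`.
#' @export
functional_class <- function(effect) {
  out <- rep("none", length(effect))
  out[effect == "missense"] <- "missense"
  out[effect == "nonsense"] <- "nonsense"
  out[effect == "synonymous"] <- "silent"
  out
}

#' Annotate a variant set against gene models
#'
#' Driver combining [assign_region()], [coding_effect()],
#' [classify_indel()], [impact_tier()] and [functional_class()] into one
#' table.  Non-CDS SNPs receive effect `noncoding`.  SNPs overlapping
#' the first or last codon of a CDS are flagged in `in_start_stop`
#' regardless of their codon-level effect, mirroring the
#' start/stop-codon variant tally of resequencing surveys.  Models
#' flagged `cds_incomplete` yield `low_confidence = TRUE`.
#'
#' @param variants a `variant_records` table.
#' @param genes a `gene_model_list`.
#' @param genome `DNAStringSet` reference sequence.
#' @return a `data.frame` with columns chrom, pos, ref, alt, region,
#'   gene_id, effect, impact, functional_class, in_start_stop,
#'   low_confidence.
#' @export
annotate_variants <- function(variants, genes, genome) {
  reg <- assign_region(variants, genes)
  n <- nrow(variants)
  effect <- rep("noncoding", n)
  in_ss <- rep(FALSE, n)
  lowconf <- rep(FALSE, n)
  models <- stats::setNames(genes, vapply(genes, function(m) m$gene_id,
                                          character(1L)))
  snp <- is_snp(variants)
  indel <- is_indel(variants)
  effect[indel] <- classify_indel(variants[indel, , drop = FALSE],
                                  reg$region[indel])
  cds_snp <- which(snp & reg$region == "CDS")
  for (i in cds_snp) {
    m <- models[[reg$gene_id[i]]]
    if (is.null(m)) next
    off <- cds_offset(m, variants$pos[i])
    if (is.na(off)) {
      # precedence picked a different overlapping transcript's CDS;
      # fall back to any model of the same chromosome containing it
      cand <- Filter(function(g) g$chrom == variants$chrom[i] &&
                       !is.na(cds_offset(g, variants$pos[i])), genes)
      if (length(cand) == 0L) next
      m <- cand[[1L]]
      off <- cds_offset(m, variants$pos[i])
    }
    effect[i] <- coding_effect(variants[i, , drop = FALSE], m, genome)
    lowconf[i] <- isTRUE(m$cds_incomplete)
    nc <- cds_length(m)
    in_ss[i] <- off <= 3L || off > nc - 3L
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             region = reg$region, gene_id = reg$gene_id,
             effect = effect, impact = impact_tier(effect),
             functional_class = functional_class(effect),
             in_start_stop = in_ss, low_confidence = lowconf,
             stringsAsFactors = FALSE)
}
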