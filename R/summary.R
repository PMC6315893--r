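#' Partition two genotypes' variants into common and specific sets
#'
#' Variant identity is the exact key (chrom, pos, ref, alt); the
#' intersection of the two call sets is "common", the remainders are
#' specific to each genotype.  SNPs and InDels are tallied separately.
#'
#' @param a,b `variant_records` tables for the two genotypes.
#' @param name_a,name_b labels used in the counts table.
#' @return a list of class `partition_result` with elements `common`,
#'   `specific_a`, `specific_b` (record tables, `common` carries the
#'   records of `a`) and `counts`, a data.frame of SNP/InDel totals per
#'   set.
#' @export
partition_variants <- function(a, b, name_a = "A", name_b = "B") {
  ka <- variant_key(a); kb <- variant_key(b)
  if (anyDuplicated(ka)) stop("duplicate variant keys in ", name_a)
  if (anyDuplicated(kb)) stop("duplicate variant keys in ", name_b)
  in_both <- ka %in% kb
  common <- a[in_both, , drop = FALSE]
  spec_a <- a[!in_both, , drop = FALSE]
  spec_b <- b[!(kb %in% ka), , drop = FALSE]
  cnt <- function(x) c(snp = sum(is_snp(x)), indel = sum(is_indel(x)))
  counts <- rbind(common = cnt(common),
                  specific_a = cnt(spec_a), specific_b = cnt(spec_b))
  structure(list(common = common, specific_a = spec_a, specific_b = spec_b,
                 counts = as.data.frame(counts),
                 name_a = name_a, name_b = name_b),
            class = "partition_result")
}

#' Summarize a variant set
#'
#' Computes the dataset-level summary printed by resequencing surveys:
#' SNP/InDel totals, insertion/deletion split, zygosity counts and
#' percentages, transition/transversion counts and Ts/Tv ratio, region
#' counts (genic split into CDS/UTR/intron), effect/impact/functional
#' class tallies when annotations are supplied, the InDel length
#' histogram, and per-chromosome counts and densities (variants per
#' 100 kb).  All ratios and percentages are rounded to 2 decimals, half
#' away from zero.
#'
#' @param variants a `variant_records` table.
#' @param annotations optional annotation table from
#'   [annotate_variants()], row-aligned with `variants`.
#' @param chrom_lengths optional named vector of chromosome lengths in
#'   bases; required for density fields, and an error if a chromosome
#'   carrying variants is missing from it.
#' @return a list of class `variant_summary`.
#' @export
summarize_variants <- function(variants, annotations = NULL,
                               chrom_lengths = NULL) {
  snp <- variants[is_snp(variants), , drop = FALSE]
  ind <- variants[is_indel(variants), , drop = FALSE]
  n_ins <- sum(nchar(ind$alt) > nchar(ind$ref))
  n_del <- sum(nchar(ind$alt) < nchar(ind$ref))
  n_het <- sum(snp$zygosity == "heterozygous")
  n_hom <- sum(snp$zygosity == "homozygous")
  ts <- if (nrow(snp)) sum(substitution_class(snp$ref, snp$alt) ==
                             "transition") else 0L
  tv <- nrow(snp) - ts
  out <- list(
    n_snp = nrow(snp), n_indel = nrow(ind),
    n_insertion = n_ins, n_deletion = n_del,
    n_heterozygous = n_het, n_homozygous = n_hom,
    pct_heterozygous = if (nrow(snp)) round_half_away(100 * n_het / nrow(snp)) else NA_real_,
    pct_homozygous = if (nrow(snp)) round_half_away(100 * n_hom / nrow(snp)) else NA_real_,
    n_transition = ts, n_transversion = tv,
    ts_tv_ratio = if (tv > 0) round_half_away(ts / tv) else NA_real_,
    indel_spectrum = indel_length_spectrum(ind))
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == nrow(variants))
    out$region_counts <- table_counts(annotations$region,
                                      c("CDS", "UTR", "intron", "intergenic"))
    out$n_genic <- sum(annotations$region != "intergenic")
    out$n_intergenic <- sum(annotations$region == "intergenic")
    out$pct_genic <- round_half_away(100 * out$n_genic / nrow(variants))
    out$effect_counts <- table_counts(annotations$effect,
                                      sort(unique(annotations$effect)))
    out$impact_counts <- table_counts(annotations$impact,
                                      c("high", "moderate", "low", "modifier"))
    out$functional_class_counts <-
      table_counts(annotations$functional_class,
                   c("missense", "nonsense", "silent", "none"))
    out$n_start_stop_codon <- sum(annotations$in_start_stop)
  }
  if (!is.null(chrom_lengths)) {
    chroms <- sort(unique(variants$chrom))
    missing <- setdiff(chroms, names(chrom_lengths))
    if (length(missing))
      stop("missing chromosome length for density computation: ",
           paste(missing, collapse = ", "))
    cnt <- table_counts(variants$chrom, chroms)
    dens <- round_half_away(cnt / (chrom_lengths[chroms] / 1e5))
    out$per_chromosome <- data.frame(chrom = chroms, n = as.integer(cnt),
                                     density_per_100kb = as.numeric(dens),
                                     stringsAsFactors = FALSE)
  }
  structure(out, class = "variant_summary")
}

table_counts <- function(x, levels) {
  t <- table(factor(x, levels = levels))
  stats::setNames(as.integer(t), levels)
}

#' Missense/silent functional-class ratio
#'
#' @param missense,silent counts of missense and silent coding SNPs.
#' @return `missense / silent` rounded to 2 decimals, or `NA` when
#'   `silent` is zero (ratio undefined).
#' @export
functional_class_ratio <- function(missense, silent) {
  if (silent == 0) return(NA_real_)
  round_half_away(missense / silent)
}

#' Union size from two overlapping set counts
#'
#' Inclusion-exclusion arithmetic for directional gene sets:
#' `a + b - both`, as used when combining the genes transmitted in each
#' direction (bidirectional genes counted once).
#'
#' @param a,b sizes of the two sets.
#' @param both size of their intersection; must not exceed `min(a, b)`.
#' @return the union count.
#' @export
union_with_overlap <- function(a, b, both) {
  if (both > min(a, b) || both < 0)
    stop("overlap count exceeds one of the set sizes")
  a + b - both
}

#' InDel length histogram
#'
#' Counts InDels per anchored length 1..40; lengths above 40 raise a
#' warning and are binned as 40.  Fractions of the total are reported as
#' percentages rounded to 2 decimals.
#'
#' @param indels a `variant_records` table of InDels.
#' @return data.frame with columns `length` (1..40), `count`, `pct`.
#' @export
indel_length_spectrum <- function(indels) {
  len <- indel_length(indels)
  len <- len[!is.na(len)]
  if (any(len > 40L)) {
    warning(sum(len > 40L), " InDel(s) longer than 40 bp binned as 40+")
    len[len > 40L] <- 40L
  }
  cnt <- table_counts(len, as.character(1:40))
  total <- sum(cnt)
  data.frame(length = 1:40, count = as.integer(cnt),
             pct = if (total > 0) round_half_away(100 * cnt / total) else
               rep(NA_real_, 40L))
}
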