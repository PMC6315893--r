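#' Post-calling filter configuration
#'
#' Thresholds for the three post-calling variant filters: a quality
#' floor, a relative-coverage band around the mean depth, and a local
#' SNP-density cap (no more than `density_max_snps` SNPs within any
#' `density_window`-nt window).
#'
#' @param min_qual quality threshold; records with `qual < min_qual`
#'   are removed (a record at exactly the threshold survives).
#' @param coverage_low_factor,coverage_high_factor multiples of the
#'   mean depth bounding the retained coverage band (closed interval).
#' @param density_window window width in nucleotides.
#' @param density_max_snps maximum SNPs tolerated in any window.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, coverage_low_factor = 0.5,
                          coverage_high_factor = 2.0,
                          density_window = 10L, density_max_snps = 3L) {
  stopifnot(coverage_low_factor > 0,
            coverage_low_factor < coverage_high_factor,
            density_window >= 1L, density_max_snps >= 1L)
  structure(list(min_qual = min_qual,
                 coverage_low_factor = coverage_low_factor,
                 coverage_high_factor = coverage_high_factor,
                 density_window = as.integer(density_window),
                 density_max_snps = as.integer(density_max_snps)),
            class = "filter_config")
}

#' Mean depth of a variant set
#'
#' Arithmetic mean of per-variant read depths, used as the proxy for
#' average mapped-read coverage by [filter_coverage()].
#'
#' @param records a `variant_records` table (non-empty).
#' @return mean depth in reads.
#' @export
mean_depth <- function(records) {
  if (nrow(records) == 0L) stop("cannot compute mean depth of empty input")
  mean(records$depth)
}

#' Coverage band filter
#'
#' Keeps records whose depth lies in the closed interval
#' `[coverage_low_factor * mean, coverage_high_factor * mean]`.
#'
#' @param records a `variant_records` table.
#' @param mean mean depth (must be > 0), normally from [mean_depth()].
#' @param cfg a [filter_config()].
#' @return the retained records, order preserved.
#' @export
filter_coverage <- function(records, mean, cfg = filter_config()) {
  stopifnot(mean > 0)
  keep <- records$depth >= cfg$coverage_low_factor * mean &
    records$depth <= cfg$coverage_high_factor * mean
  records[keep, , drop = FALSE]
}

#' Quality filter
#'
#' Removes records with `qual` below `cfg$min_qual` (strictly below: a
#' record at exactly the threshold is kept).
#'
#' @inheritParams filter_coverage
#' @return the retained records, order preserved.
#' @export
filter_quality <- function(records, cfg = filter_config()) {
  records[records$qual >= cfg$min_qual, , drop = FALSE]
}

#' Local SNP-density filter
#'
#' Removes every SNP lying in any window of `density_window` consecutive
#' bases (per chromosome) that contains more than `density_max_snps`
#' SNPs; the whole violating cluster is dropped, which makes the result
#' independent of window anchoring.  InDels pass through untouched.
#'
#' @inheritParams filter_coverage
#' @return the retained records, order preserved.
#' @export
filter_density <- function(records, cfg = filter_config()) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$chrom, records$pos)
  if (any(o != seq_along(o)))
    stop("filter_density requires records sorted by (chrom, pos)")
  snp <- is_snp(records)
  drop <- rep(FALSE, nrow(records))
  for (ch in unique(records$chrom[snp])) {
    idx <- which(snp & records$chrom == ch)
    pos <- records$pos[idx]
    # windows are anchored at each SNP; any SNP whose window [p, p+w-1]
    # holds > max SNPs condemns every SNP inside that window
    hi <- findInterval(pos + cfg$density_window - 1L, pos)
    lo <- seq_along(pos)
    bad_anchor <- which(hi - lo + 1L > cfg$density_max_snps)
    if (length(bad_anchor)) {
      for (a in bad_anchor) drop[idx[a:hi[a]]] <- TRUE
    }
  }
  records[!drop, , drop = FALSE]
}

#' Apply the full post-calling filter chain
#'
#' Filters are applied in order quality, coverage, density, with the
#' mean depth computed on the input before any removal.
#'
#' @inheritParams filter_coverage
#' @return a list with `records` (retained set) and `tally`, a named
#'   integer vector of per-stage removal counts.
#' @export
apply_filters <- function(records, cfg = filter_config()) {
  if (nrow(records) == 0L)
    return(list(records = records,
                tally = c(quality = 0L, coverage = 0L, density = 0L)))
  md <- mean_depth(records)
  q <- filter_quality(records, cfg)
  co <- filter_coverage(q, md, cfg)
  de <- filter_density(co, cfg)
  list(records = de,
       tally = c(quality = nrow(records) - nrow(q),
                 coverage = nrow(q) - nrow(co),
                 density = nrow(co) - nrow(de)),
       mean_depth = md)
}
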