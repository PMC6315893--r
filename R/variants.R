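#' Construct a table of variant records
#'
#' The central container of the package: one row per called variant
#' (SNP or InDel) against the reference genome.  Coordinates are 1-based
#' and InDels carry the VCF anchor base (`ref = "AT", alt = "A"` is a
#' 1 bp deletion).
#'
#' @param chrom chromosome identifiers.
#' @param pos 1-based reference positions (`pos >= 1`).
#' @param ref,alt reference and alternate allele strings over A/C/G/T;
#'   `ref != alt`, both non-empty.
#' @param qual calling quality scores.
#' @param depth supporting read counts (DP).
#' @param zygosity `"homozygous"` or `"heterozygous"`.
#' @return a `data.frame` of class `variant_records`, sorted by
#'   (chrom, pos).
#' @export
variant_records <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            qual = numeric(), depth = integer(),
                            zygosity = character()) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  qual = as.numeric(qual), depth = as.integer(depth),
                  zygosity = as.character(zygosity),
                  stringsAsFactors = FALSE)
  validate_variants(x)
  x <- order_variants(x)
  rownames(x) <- NULL
  class(x) <- c("variant_records", "data.frame")
  x
}

validate_variants <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$pos < 1L)) stop("variant positions must be >= 1")
  if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
  if (any(!nzchar(x$ref)) || any(!nzchar(x$alt)))
    stop("ref and alt alleles must be non-empty")
  bad <- grepl("[^ACGT]", x$ref) | grepl("[^ACGT]", x$alt)
  if (any(bad))
    stop("alleles must be strings over A/C/G/T (first offender: ",
         x$ref[bad][1L], "/", x$alt[bad][1L], ")")
  ok <- x$zygosity %in% c("homozygous", "heterozygous")
  if (!all(ok)) stop("zygosity must be 'homozygous' or 'heterozygous'")
  invisible(x)
}

#' SNP / InDel predicates and InDel length
#'
#' `is_snp()` is true where ref and alt are both single bases;
#' `is_indel()` where their lengths differ.  `indel_length()` is the
#' anchored length difference `abs(nchar(ref) - nchar(alt))` (NA for
#' SNPs).
#'
#' @param x a `variant_records` table.
#' @return logical (or integer) vector, one element per record.
#' @export
is_snp <- function(x) nchar(x$ref) == 1L & nchar(x$alt) == 1L

#' @rdname is_snp
#' @export
is_indel <- function(x) nchar(x$ref) != nchar(x$alt)

#' @rdname is_snp
#' @export
indel_length <- function(x) {
  len <- abs(nchar(x$ref) - nchar(x$alt))
  len[!is_indel(x)] <- NA_integer_
  len
}

#' Read variant calls from a VCF file
#'
#' Parses the VCF 4.x column layout into a [variant_records()] table.
#' Multi-allelic rows are expanded to one record per alternate allele.
#' Zygosity is taken from the first sample's GT field: a genotype whose
#' two alleles both equal the alt index is homozygous, anything else
#' carrying that alt is heterozygous.  Depth is taken from the sample DP
#' field, falling back to `DP=` in INFO.
#'
#' @param path path to an uncompressed VCF file.
#' @return a `variant_records` table sorted by (chrom, pos).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "##")
  is_header <- startsWith(lines, "#CHROM")
  body_idx <- which(!is_meta & !is_header & nzchar(lines))
  if (length(body_idx) == 0L) return(variant_records())

  out <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("malformed VCF row at line ", i, ": fewer than 8 columns")
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos))
      stop("malformed VCF row at line ", i, ": non-numeric POS '", f[2L], "'")
    if (length(f) < 10L)
      stop("VCF row at line ", i,
           " has no FORMAT/sample columns; a GT field is required")
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    smp <- strsplit(f[10L], ":", fixed = TRUE)[[1L]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i) || gt_i > length(smp))
      stop("VCF row at line ", i, ": first sample has no GT field")
    gt <- strsplit(smp[gt_i], "[/|]")[[1L]]
    dp_i <- match("DP", fmt)
    depth <- if (!is.na(dp_i) && dp_i <= length(smp)) {
      suppressWarnings(as.integer(smp[dp_i]))
    } else {
      m <- regmatches(f[8L], regexpr("(?:^|;)DP=([0-9]+)", f[8L]))
      if (length(m)) as.integer(sub(".*DP=", "", m)) else NA_integer_
    }
    qual <- suppressWarnings(as.numeric(f[6L]))
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    zyg <- vapply(seq_along(alts), function(a) {
      if (length(gt) == 2L && all(gt == as.character(a))) "homozygous"
      else "heterozygous"
    }, character(1L))
    out[[k]] <- data.frame(chrom = f[1L], pos = pos, ref = toupper(f[4L]),
                           alt = toupper(alts), qual = qual, depth = depth,
                           zygosity = zyg, stringsAsFactors = FALSE)
  }
  x <- do.call(rbind, out)
  x <- order_variants(x)
  rownames(x) <- NULL
  validate_variants(x)
  class(x) <- c("variant_records", "data.frame")
  x
}

#' Write variant records as VCF
#'
#' Emits a minimal single-sample VCF 4.2 file (GT:DP), one row per
#' record.  `read_vcf(write_vcf(x, f))` reproduces `x` field for field.
#'
#' @param x a `variant_records` table.
#' @param path output file path.
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, sample_name = "SAMPLE") {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample_name, sep = "\t"))
  x <- order_variants(x)
  gt <- ifelse(x$zygosity == "homozygous", "1/1", "0/1")
  rows <- paste(x$chrom, x$pos, ".", x$ref, x$alt, x$qual, "PASS", ".",
                "GT:DP", paste0(gt, ":", x$depth), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}
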