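#' Round half away from zero
#'
#' Rounding used for all printed percentages and ratios (matches the
#' usual "52.84%" style of variant-survey tables, where .005 rounds up).
#' Base R's [round()] rounds half to even and is not suitable.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: (chrom, pos, ref, alt) identity key
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# internal: stable (chrom, pos) ordering
order_variants <- function(x) {
  x[order(x$chrom, x$pos, x$ref, x$alt), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

comp_base <- function(b) unname(COMPLEMENT[b])

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
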