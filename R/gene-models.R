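#' Read a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims
#' sequence names at the first whitespace so they match GFF3/VCF
#' chromosome ids.
#'
#' @param path FASTA file path.
#' @return a `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Construct a gene model
#'
#' One stranded transcript structure used for consequence calls.  All
#' intervals are 1-based inclusive, stored as two-column matrices
#' (start, end) sorted by genomic start.  UTR intervals may be supplied
#' or inferred as exon minus CDS.
#'
#' @param gene_id,tx_id gene and transcript identifiers.
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 interval matrices with columns start, end.
#' @param phase integer vector of GFF3 phases, one per CDS interval
#'   (in genomic order).
#' @param cds_incomplete flag set when the concatenated CDS length is
#'   not a multiple of 3; consequence calls on such models are marked
#'   low-confidence.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, tx_id, chrom, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL, phase = NULL,
                       cds_incomplete = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- normalize_intervals(exons)
  cds <- normalize_intervals(cds)
  if (is.null(utr5) || is.null(utr3)) {
    utr <- infer_utrs(exons, cds, strand)
    utr5 <- utr5 %||% utr$utr5
    utr3 <- utr3 %||% utr$utr3
  } else {
    utr5 <- normalize_intervals(utr5)
    utr3 <- normalize_intervals(utr3)
  }
  if (is.null(phase)) phase <- cds_phases(cds, strand)
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3, phase = phase,
                 cds_incomplete = cds_incomplete),
            class = "gene_model")
}

normalize_intervals <- function(m) {
  if (is.null(m) || length(m) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(m), ncol = 2L)
  colnames(m) <- c("start", "end")
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L]))
    stop("intervals within a transcript must be non-overlapping")
  if (any(m[, 2L] < m[, 1L])) stop("interval end before start")
  m
}

# exon minus CDS, split into 5' and 3' sides by strand
infer_utrs <- function(exons, cds, strand) {
  empty <- normalize_intervals(NULL)
  if (nrow(cds) == 0L || nrow(exons) == 0L)
    return(list(utr5 = empty, utr3 = empty))
  ex <- IRanges::IRanges(exons[, 1L], exons[, 2L])
  cd <- IRanges::IRanges(cds[, 1L], cds[, 2L])
  ut <- IRanges::setdiff(ex, cd)
  cds_lo <- min(cds[, 1L]); cds_hi <- max(cds[, 2L])
  lo <- ut[IRanges::end(ut) < cds_lo]
  hi <- ut[IRanges::start(ut) > cds_hi]
  as_mat <- function(ir) {
    normalize_intervals(cbind(IRanges::start(ir), IRanges::end(ir)))
  }
  if (strand == "+") list(utr5 = as_mat(lo), utr3 = as_mat(hi))
  else list(utr5 = as_mat(hi), utr3 = as_mat(lo))
}

# GFF3 phase per CDS interval from cumulative coding length
cds_phases <- function(cds, strand) {
  if (nrow(cds) == 0L) return(integer())
  ord <- if (strand == "+") order(cds[, 1L]) else order(-cds[, 1L])
  lens <- cds[ord, 2L] - cds[ord, 1L] + 1L
  ph <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
  out <- integer(nrow(cds))
  out[ord] <- ph
  out
}

#' Total CDS length of a gene model
#' @param model a `gene_model`.
#' @return coding length in bases.
#' @export
cds_length <- function(model) {
  if (nrow(model$cds) == 0L) return(0L)
  sum(model$cds[, 2L] - model$cds[, 1L] + 1L)
}

#' Transcript span (first to last exon base) of a gene model
#' @param model a `gene_model`.
#' @return integer vector `c(start, end)`.
#' @export
transcript_span <- function(model) {
  c(min(model$exons[, 1L]), max(model$exons[, 2L]))
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features with [rtracklayer::import()] and
#' builds one [gene_model()] per mRNA.  UTRs are taken from
#' five_prime_UTR/three_prime_UTR features when present and inferred as
#' exon minus CDS otherwise.  A CDS whose total length is not divisible
#' by 3 flags the model `cds_incomplete` (a warning, not an error); a
#' CDS on a chromosome absent from `genome` is an error.
#'
#' @param path GFF3 file path.
#' @param genome optional `DNAStringSet` (see [read_genome()]) used to
#'   validate chromosome ids.
#' @return a list of `gene_model` objects (class `gene_model_list`).
#' @export
read_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(structure(list(), class = "gene_model_list"))
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  parent_of <- function(feat) {
    p <- feat$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1L))
  }
  models <- vector("list", length(mrna))
  for (k in seq_along(mrna)) {
    tx <- mrna[k]
    tx_id <- tx$ID %||% NA_character_
    gid <- parent_of(tx)[1L]
    if (is.na(gid)) gid <- tx_id
    kids <- gr[!is.na(parent_of(gr)) & parent_of(gr) == tx_id]
    pick <- function(t) {
      f <- kids[as.character(kids$type) == t]
      if (length(f) == 0L) return(NULL)
      cbind(GenomicRanges::start(f), GenomicRanges::end(f))
    }
    cds_f <- kids[as.character(kids$type) == "CDS"]
    chrom <- as.character(GenomicRanges::seqnames(tx))
    if (!is.null(genome) && length(cds_f) > 0L && !(chrom %in% names(genome)))
      stop("CDS of transcript ", tx_id, " references absent chromosome ", chrom)
    exons <- pick("exon")
    if (is.null(exons)) exons <- cbind(GenomicRanges::start(tx),
                                       GenomicRanges::end(tx))
    cds <- pick("CDS")
    total <- if (is.null(cds)) 0L else sum(cds[, 2L] - cds[, 1L] + 1L)
    incomplete <- total %% 3L != 0L && total > 0L
    models[[k]] <- gene_model(
      gene_id = gid, tx_id = tx_id, chrom = chrom,
      strand = as.character(GenomicRanges::strand(tx)),
      exons = exons, cds = cds,
      utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"),
      cds_incomplete = incomplete)
  }
  structure(models, class = "gene_model_list")
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS intervals in transcription order
#' (reverse-complemented for minus-strand genes).
#'
#' @param model a `gene_model`.
#' @param genome `DNAStringSet` holding the model's chromosome.
#' @return coding-strand DNA sequence as a character string.
#' @export
coding_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " absent from genome")
  chr <- genome[[model$chrom]]
  parts <- apply(model$cds, 1L, function(iv)
    as.character(Biostrings::subseq(chr, iv[1L], iv[2L])))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}
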