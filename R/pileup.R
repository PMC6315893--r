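#' Construct a table of per-site base counts
#'
#' One row per genomic position with A/C/G/T read counts from an RNA
#' pileup; `depth` is always the row sum of the four base counts.
#'
#' @param chrom chromosome ids.
#' @param pos 1-based positions.
#' @param count_A,count_C,count_G,count_T non-negative read counts.
#' @return a `data.frame` of class `site_counts` sorted by (chrom, pos).
#' @export
site_counts <- function(chrom = character(), pos = integer(),
                        count_A = integer(), count_C = integer(),
                        count_G = integer(), count_T = integer()) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  count_A = as.integer(count_A), count_C = as.integer(count_C),
                  count_G = as.integer(count_G), count_T = as.integer(count_T),
                  stringsAsFactors = FALSE)
  if (any(x$count_A < 0 | x$count_C < 0 | x$count_G < 0 | x$count_T < 0))
    stop("base counts must be non-negative")
  x$depth <- x$count_A + x$count_C + x$count_G + x$count_T
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("site_counts", "data.frame")
  x
}

# decode one mpileup base string into A/C/G/T counts.
# grammar handled: . , match ref; ACGTacgt mismatches; ^X read start
# (skip the mapping-quality char), $ read end, +n<seq>/-n<seq> indel
# blocks (skipped), * deletion placeholder and N (ignored).
decode_pileup_bases <- function(bases, ref, where) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  ref <- toupper(ref)
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L)
        stop("non-numeric indel block length in pileup at ", where)
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "." || ch == ",") {
      if (ref %in% BASES) counts[ref] <- counts[ref] + 1L
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% BASES) counts[up] <- counts[up] + 1L
      i <- i + 1L                      # '*', 'N', '<', '>' fall through
    }
  }
  counts
}

#' Read a samtools mpileup text file into per-site base counts
#'
#' Resolves `.`/`,` to the reference base, uppercases mismatches, and
#' skips indel blocks (`+n...`/`-n...`), read-start (`^x`) and read-end
#' (`$`) markers.  The reported `depth` is the sum of resolved A/C/G/T
#' counts (i.e. the mpileup depth column minus skipped symbols such as
#' `*` placeholders).
#'
#' @param path mpileup text file (chrom, pos, ref, depth, bases, quals).
#' @return a [site_counts()] table.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(site_counts())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(f) >= 5L
  if (!all(ncol_ok))
    stop("malformed pileup row at line ", which(!ncol_ok)[1L])
  chrom <- vapply(f, `[[`, character(1L), 1L)
  pos <- as.integer(vapply(f, `[[`, character(1L), 2L))
  ref <- vapply(f, `[[`, character(1L), 3L)
  bases <- vapply(f, `[[`, character(1L), 5L)

  # fast path: strings with no markers are pure match/mismatch runs
  simple <- !grepl("[+^$*><-]", bases)
  cnt <- matrix(0L, nrow = length(lines), ncol = 4L,
                dimnames = list(NULL, BASES))
  if (any(simple)) {
    b <- bases[simple]
    nref <- nchar(b) - nchar(gsub("[.,]", "", b))
    for (base in BASES) {
      m <- nchar(b) - nchar(gsub(base, "", gsub(tolower(base), base, b),
                                 fixed = TRUE))
      cnt[simple, base] <- m
    }
    r <- toupper(ref[simple])
    for (base in BASES) {
      sel <- r == base
      cnt[which(simple)[sel], base] <- cnt[which(simple)[sel], base] + nref[sel]
    }
  }
  for (i in which(!simple)) {
    cnt[i, ] <- decode_pileup_bases(bases[i], ref[i],
                                    paste0(chrom[i], ":", pos[i]))
  }
  site_counts(chrom, pos, cnt[, "A"], cnt[, "C"], cnt[, "G"], cnt[, "T"])
}

#' Write per-site base counts as mpileup text
#'
#' Emits one mpileup row per site; bases matching the reference (when a
#' genome is supplied) are written as `.`, everything else as explicit
#' base letters, with constant quality characters.  Round-trips through
#' [read_pileup()].
#'
#' @param x a [site_counts()] table.
#' @param path output file path.
#' @param genome optional `DNAStringSet`; without it the reference
#'   column is `N` and all reads are written as explicit letters.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(x, path, genome = NULL) {
  if (nrow(x) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ref <- rep("N", nrow(x))
  if (!is.null(genome)) {
    for (ch in unique(x$chrom)) {
      sel <- x$chrom == ch
      if (!ch %in% names(genome)) next
      ref[sel] <- strsplit(as.character(genome[[ch]]), "")[[1L]][x$pos[sel]]
    }
  }
  cols <- paste0("count_", BASES)
  bases <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    parts <- character(0L)
    for (b in seq_len(4L)) {
      n <- x[[cols[b]]][i]
      if (n == 0L) next
      sym <- if (BASES[b] == ref[i]) "." else BASES[b]
      parts <- c(parts, strrep(sym, n))
    }
    bases[i] <- paste(parts, collapse = "")
  }
  bases[!nzchar(bases)] <- "*"
  quals <- strrep("I", pmax(x$depth, 1L))
  writeLines(paste(x$chrom, x$pos, ref, x$depth, bases, quals, sep = "\t"),
             path)
  invisible(path)
}

#' Write site counts as a TSV table
#'
#' The `convert-pileup` CLI output: columns chrom, pos, A, C, G, T.
#'
#' @param x a [site_counts()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(x, path) {
  out <- data.frame(chrom = x$chrom, pos = x$pos, A = x$count_A,
                    C = x$count_C, G = x$count_G, T = x$count_T)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
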