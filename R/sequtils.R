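# Internal sequence utilities. Sequences are plain upper-case character
# scalars over {A,C,G,T,N} throughout the package; Biostrings objects are
# converted at the I/O boundary only.

.BASES <- c("A", "C", "G", "T")

# Uppercase-normalise and validate a nucleotide sequence.
.norm_seq <- function(x, allow_gap = FALSE, arg = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x))
    stop(arg, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  ok <- if (allow_gap) "^[ACGTN-]*$" else "^[ACGTN]*$"
  if (!grepl(ok, x))
    stop(arg, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  x
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide sequence
#'
#' @param x single nucleotide string over A,C,G,T,N.
#' @return the reverse complement, same alphabet.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  x <- .norm_seq(x)
  if (nchar(x) == 0L) return(x)
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  .chars_seq(rev(unname(map[.seq_chars(x)])))
}

# Random sequence from the current RNG stream.
.random_seq <- function(n, freqs = rep(0.25, 4)) {
  if (n <= 0L) return("")
  .chars_seq(sample(.BASES, n, replace = TRUE, prob = freqs))
}

# Slice with 0-based half-open coordinates (package-internal convention).
.slice <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the plain
#' named character vector representation used throughout the package.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

# GFF3 writer for the simple feature tables the pipeline emits.
# df columns: seqid, source, type, start0, end0 (0-based half-open), score,
# strand, attributes. Converts to 1-based closed on output.
.write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    out <- data.frame(
      seqid = df$seqid, source = df$source, type = df$type,
      start = df$start0 + 1L, end = df$end0,
      score = ifelse(is.na(df$score), ".", df$score),
      strand = ifelse(is.na(df$strand), ".", df$strand),
      phase = ".", attributes = df$attributes,
      stringsAsFactors = FALSE)
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
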