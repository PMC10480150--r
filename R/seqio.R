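#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a named
#' [Biostrings::DNAStringSet]. Sequences are uppercased and RNA `U` is
#' mapped to `T`, so DNA and RNA FASTA inputs are interchangeable. The
#' record id is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record.
#' @details The allowed alphabet is `A`, `C`, `G`, `T`, `N` (after the
#'   `U -> T` mapping). An empty file, duplicate ids, or characters outside
#'   this alphabet raise an error; the error for a stray character reports
#'   its position.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  for (i in seq_along(seqs)) check_alphabet(seqs[[i]], ids[[i]])
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write transcripts to a FASTA file
#'
#' @param x Named `DNAStringSet` or named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_seq_set(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' GC content of a transcript
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param t A single transcript (character string, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @return GC fraction in `[0, 1]` (multiply by 100 to report percent).
#' @examples
#' gc_content("ACGT") # 0.5
#' @export
gc_content <- function(t) {
  s <- as_seq_char(t)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        letters = c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0L) stop("cannot compute GC content of an all-N sequence")
  unname((counts[["C"]] + counts[["G"]]) / tot)
}
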