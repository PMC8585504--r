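#' Read and normalize DNA sequences from FASTA
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet], uppercasing and
#' mapping `U` to `T` so that downstream analyses see a uniform
#' `{A,C,G,T,N}` alphabet.
#'
#' @param path path to a FASTA file.
#' @return A `DNAStringSet`.
#' @export
#' @examples
#' fa <- system.file("extdata", "aba_btp1.fasta", package = "bstaContext")
#' readDnaFasta(fa)
readDnaFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Read protein sequences from FASTA
#'
#' Uppercases residues and strips gap characters so stored sequences obey
#' the no-gap invariant expected by the aligner.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return An [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  seqs <- gsub("[-.]", "", toupper(as.character(raw)))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Write sequences to FASTA
#'
#' Standard `>`-header FASTA wrapped at 60 columns.
#'
#' @param x an `XStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Coerce to a normalized DNAString
#'
#' Ingest normalization used throughout the package: uppercase, `U` mapped
#' to `T`; rejects characters outside the IUPAC DNA alphabet.
#'
#' @param x a character scalar, `DNAString`, or length-1 `DNAStringSet`.
#' @return A [Biostrings::DNAString].
#' @export
asDna <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(x[[1L]])
  }
  stopifnot(is.character(x), length(x) == 1L)
  Biostrings::DNAString(chartr("U", "T", toupper(x)))
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed (an involution). Thin wrapper over
#' [Biostrings::reverseComplement()] that applies the package's ingest
#' normalization first.
#'
#' @param x sequence coercible by [asDna()].
#' @return A `DNAString`.
#' @export
#' @examples
#' reverseComplementDna("AAA") # TTT
reverseComplementDna <- function(x) {
  Biostrings::reverseComplement(asDna(x))
}

#' Translate a DNA sequence in a chosen frame
#'
#' Translates with the standard genetic code starting at a 0-based frame
#' offset; any trailing partial codon is dropped and stop codons are
#' rendered as `*`.
#'
#' @param x sequence coercible by [asDna()].
#' @param frameOffset 0, 1 or 2.
#' @return An [Biostrings::AAString].
#' @export
#' @examples
#' translateFrame("ATGGTTAAT") # MVN
translateFrame <- function(x, frameOffset = 0L) {
  stopifnot(frameOffset %in% 0:2)
  x <- asDna(x)
  n <- length(x) - frameOffset
  ncod <- n %/% 3L
  if (ncod < 1L) return(Biostrings::AAString(""))
  sub <- Biostrings::subseq(x, frameOffset + 1L, frameOffset + 3L * ncod)
  Biostrings::translate(sub, no.init.codon = TRUE)
}
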