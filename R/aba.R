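#' The 63-bp aba element of prophage BTP1
#'
#' Returns the anti-BstA (aba) self-immunity element of the Salmonella
#' prophage BTP1 as a [Biostrings::DNAString]: 29 bp of sequence upstream
#' of the bstA start codon followed by the first 34 bp of the bstA coding
#' sequence, flanked by a direct "CCCGCC" repeat at its terminal ends.
#'
#' @return A 63-bp `DNAString`.
#' @export
#' @examples
#' partitionElement(abaBTP1())
abaBTP1 <- function() {
  fa <- system.file("extdata", "aba_btp1.fasta", package = "bstaContext")
  readDnaFasta(fa)[[1L]]
}

#' Partition a self-immunity element at its start codon
#'
#' Splits a short locus spanning a gene start into the upstream
#' (pre-ATG) portion and the coding portion (A of the ATG through the 3'
#' end). In `"auto"` mode the first forward-strand ATG is used; an
#' explicit 0-based offset may be given instead and must read ATG.
#'
#' @param seq sequence coercible by [asDna()].
#' @param start `"auto"` or a 0-based offset of the A of the ATG.
#' @param id identifier recorded on the element.
#' @return An [AbaElement-class].
#' @export
#' @examples
#' el <- partitionElement(abaBTP1())
#' upstreamLength(el) # 29
#' codingLength(el)   # 34
partitionElement <- function(seq, start = "auto", id = "element") {
  seq <- asDna(seq)
  n <- length(seq)
  if (identical(start, "auto")) {
    hit <- Biostrings::matchPattern("ATG", seq)
    if (length(hit) == 0L)
      stop("no ATG start codon found in sequence")
    off <- BiocGenerics::start(hit)[1L] - 1L
  } else {
    off <- as.integer(start)
    if (off < 0L || off + 3L > n ||
        as.character(Biostrings::subseq(seq, off + 1L, off + 3L)) != "ATG")
      stop("explicit offset ", off, " does not read ATG")
  }
  new("AbaElement",
      identifier = id,
      sequence = seq,
      startCodonOffset = as.integer(off),
      upstreamLength = as.integer(off),
      codingLength = as.integer(n - off))
}

#' Find maximal direct repeats in a short sequence
#'
#' Enumerates all maximal substrings of length at least `kMin` occurring
#' two or more times on the forward strand, with every (possibly
#' overlapping) occurrence position. Maximal means the motif cannot be
#' extended one base left or right with all occurrences following along;
#' sub-strings of a repeat that occur in exactly the same places are
#' therefore suppressed. Intended for short loci (quadratic scan).
#'
#' @param seq sequence coercible by [asDna()].
#' @param kMin minimum motif length (at least 2).
#' @return An [S4Vectors::DataFrame] with columns `motif`, `length`,
#'   `n_occ`, `occurrences` (an [IRanges::IntegerList] of 1-based start
#'   positions) and `terminal` (all `FALSE` here; see
#'   [findTerminalRepeat()]), ordered by motif length descending then
#'   alphabetically.
#' @export
#' @examples
#' findDirectRepeats(abaBTP1(), kMin = 6)
findDirectRepeats <- function(seq, kMin = 6L) {
  stopifnot(kMin >= 2L)
  s <- as.character(asDna(seq))
  n <- nchar(s)
  emptyResult <- S4Vectors::DataFrame(
    motif = character(0), length = integer(0), n_occ = integer(0),
    occurrences = IRanges::IntegerList(), terminal = logical(0))
  if (kMin > n - 1L) return(emptyResult)
  occ <- function(motif) {
    k <- nchar(motif)
    starts <- integer(0)
    for (p in seq_len(n - k + 1L))
      if (substr(s, p, p + k - 1L) == motif) starts <- c(starts, p)
    starts
  }
  motifs <- character(0); occs <- list()
  for (k in seq(kMin, n - 1L)) {
    cand <- unique(vapply(seq_len(n - k + 1L),
                          function(p) substr(s, p, p + k - 1L), character(1)))
    for (m in cand) {
      P <- occ(m)
      if (length(P) < 2L) next
      # maximality: extendable iff all occurrences share the flanking base
      leftExt <- all(P > 1L) &&
        length(unique(substring(s, P - 1L, P - 1L))) == 1L
      rightExt <- all(P + k - 1L < n) &&
        length(unique(substring(s, P + k, P + k))) == 1L
      if (leftExt || rightExt) next
      motifs <- c(motifs, m); occs <- c(occs, list(P))
    }
  }
  if (!length(motifs)) return(emptyResult)
  ord <- order(-nchar(motifs), motifs)
  S4Vectors::DataFrame(
    motif = motifs[ord],
    length = nchar(motifs[ord]),
    n_occ = lengths(occs)[ord],
    occurrences = IRanges::IntegerList(occs[ord]),
    terminal = rep(FALSE, length(ord)))
}

#' Find a direct repeat at the terminal ends of an element
#'
#' Among the maximal direct repeats of the sequence, returns the longest
#' one having an occurrence starting within the first `margin` bases and
#' an occurrence ending within the last `margin` bases — the criterion
#' operationalizing a "repeat at the terminal ends". Ties on length are
#' broken alphabetically.
#'
#' @inheritParams findDirectRepeats
#' @param margin how close to the ends an occurrence must lie (bp,
#'   at least `kMin`).
#' @return A one-row `DataFrame` as in [findDirectRepeats()] with
#'   `terminal = TRUE`, or `NULL` when no repeat qualifies.
#' @export
#' @examples
#' findTerminalRepeat(abaBTP1(), kMin = 6, margin = 10)$motif # "CCCGCC"
findTerminalRepeat <- function(seq, kMin = 6L, margin = 10L) {
  stopifnot(margin >= kMin)
  s <- as.character(asDna(seq))
  n <- nchar(s)
  reps <- findDirectRepeats(s, kMin)
  if (nrow(reps) == 0L) return(NULL)
  qualifies <- vapply(seq_len(nrow(reps)), function(i) {
    P <- reps$occurrences[[i]]
    k <- reps$length[i]
    any(P <= margin) && any(P + k - 1L >= n - margin + 1L)
  }, logical(1))
  if (!any(qualifies)) return(NULL)
  hit <- reps[qualifies, ]
  hit <- hit[order(-hit$length, hit$motif), ][1L, ]
  hit$terminal <- TRUE
  hit
}

#' Substitute a single base
#'
#' Replaces exactly one base, e.g. the G-to-T exchange converting a
#' CCCGCC repeat unit to CCCTCC in the mutant elements used to probe
#' repeat function.
#'
#' @param seq sequence coercible by [asDna()].
#' @param position 1-based position to replace.
#' @param newBase one of A, C, G, T.
#' @return A `DNAString` of unchanged length.
#' @export
applySubstitution <- function(seq, position, newBase) {
  seq <- asDna(seq)
  n <- length(seq)
  position <- as.integer(position)
  if (position < 1L || position > n)
    stop("position ", position, " outside sequence of length ", n)
  newBase <- toupper(newBase)
  if (!newBase %in% c("A", "C", "G", "T"))
    stop("newBase must be one of A, C, G, T")
  s <- as.character(seq)
  substr(s, position, position) <- newBase
  Biostrings::DNAString(s)
}

#' Locate a base inside each terminal-repeat occurrence
#'
#' Finds, programmatically rather than by hard-coded coordinates, the
#' 1-based sequence position of the first `base` within each occurrence
#' of the terminal direct repeat — e.g. the G of each CCCGCC unit, the
#' positions exchanged in the repeat-disrupting point mutants.
#'
#' @inheritParams findTerminalRepeat
#' @param base the base to locate within the repeat motif.
#' @return Integer vector of positions (one per occurrence), or `NULL`
#'   when there is no terminal repeat or the motif lacks `base`.
#' @export
#' @examples
#' locateRepeatBase(abaBTP1()) # G positions of the two CCCGCC units
locateRepeatBase <- function(seq, kMin = 6L, margin = 10L, base = "G") {
  term <- findTerminalRepeat(seq, kMin = kMin, margin = margin)
  if (is.null(term)) return(NULL)
  within <- regexpr(base, term$motif, fixed = TRUE)
  if (within < 0L) return(NULL)
  as.integer(term$occurrences[[1L]] + within - 1L)
}

#' Scan a short sequence for ATG-initiated open reading frames
#'
#' Walks every ATG on the requested strand(s) codon by codon. A complete
#' ORF ends at the first in-frame stop within the sequence; with
#' `allowRunoff`, frames that reach the end of the sequence without a
#' stop are reported as incomplete (the situation of a gene start inside
#' a short element whose coding sequence continues beyond it).
#'
#' @param seq sequence coercible by [asDna()].
#' @param minCodons minimum ORF length in codons, start codon included,
#'   stop excluded (default 1).
#' @param strands `"forward"` (default) or `"both"`.
#' @param allowRunoff report stop-less run-off frames (default `TRUE`).
#' @return A data.frame with columns `strand`, `frame` (0-2 on the
#'   scanned strand), `start`, `end` (1-based, forward-axis coordinates),
#'   `n_codons` and `complete`.
#' @export
#' @examples
#' scanOrfs("ATGAAATAA", minCodons = 2)
scanOrfs <- function(seq, minCodons = 1L, strands = c("forward", "both"),
                     allowRunoff = TRUE) {
  strands <- match.arg(strands)
  stopifnot(minCodons >= 1L)
  seq <- asDna(seq)
  n <- length(seq)
  out <- data.frame(strand = character(0), frame = integer(0),
                    start = integer(0), end = integer(0),
                    n_codons = integer(0), complete = logical(0))
  if (n < 3L) return(out)
  scanOne <- function(s, strandLabel) {
    rows <- list()
    ch <- strsplit(s, "")[[1L]]
    stops <- c("TAA", "TAG", "TGA")
    for (p in seq_len(n - 2L)) {
      if (paste(ch[p:(p + 2L)], collapse = "") != "ATG") next
      q <- p
      complete <- FALSE
      while (q + 2L <= n) {
        codon <- paste(ch[q:(q + 2L)], collapse = "")
        if (q > p && codon %in% stops) { complete <- TRUE; break }
        q <- q + 3L
      }
      if (complete) {
        endPos <- q + 2L
        ncod <- (q - p) %/% 3L       # codons before the stop
      } else {
        if (!allowRunoff) next
        endPos <- p + ((n - p + 1L) %/% 3L) * 3L - 1L
        ncod <- (endPos - p + 1L) %/% 3L
      }
      if (ncod < minCodons) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strandLabel, frame = (p - 1L) %% 3L,
        start = p, end = endPos, n_codons = ncod, complete = complete)
    }
    rows
  }
  rows <- scanOne(as.character(seq), "+")
  if (strands == "both") {
    rcRows <- scanOne(as.character(Biostrings::reverseComplement(seq)), "-")
    # map reverse-strand coordinates back onto the forward axis
    rcRows <- lapply(rcRows, function(r) {
      s2 <- n - r$end + 1L; e2 <- n - r$start + 1L
      r$start <- s2; r$end <- e2
      r
    })
    rows <- c(rows, rcRows)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Text diagram of an aba element
#'
#' A small annotated diagram showing the upstream/coding partition and
#' the terminal repeat occurrences of an element.
#'
#' @param element an [AbaElement-class].
#' @param kMin,margin passed to [findTerminalRepeat()].
#' @return Character vector of diagram lines.
#' @export
abaDiagram <- function(element, kMin = 6L, margin = 10L) {
  stopifnot(is(element, "AbaElement"))
  s <- as.character(element@sequence)
  n <- nchar(s)
  marker <- rep(" ", n)
  off <- element@startCodonOffset
  if (off + 3L <= n) marker[(off + 1L):(off + 3L)] <- "M"
  term <- findTerminalRepeat(s, kMin = kMin, margin = margin)
  if (!is.null(term)) {
    for (p in term$occurrences[[1L]])
      marker[p:(p + term$length - 1L)] <- "R"
  }
  c(paste0(">", element@identifier, " (", n, " bp; upstream ",
           element@upstreamLength, " bp, coding ",
           element@codingLength, " bp)"),
    s,
    paste(marker, collapse = ""),
    "R = terminal direct repeat, M = start codon")
}
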