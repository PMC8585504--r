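#' Affine-gap global alignment in EMBOSS Needle conventions
#'
#' Optimal global alignment of two ungapped sequences under an affine gap
#' model: the first residue of a gap costs `gapOpen` and each further
#' residue `gapExtend` (so a gap of length L costs
#' `gapOpen + (L - 1) * gapExtend`). With `endGapsPenalized = FALSE` (the
#' Needle default) terminal gaps score zero but are retained in the
#' returned alignment, so percent identity is computed over the full
#' alignment length.
#'
#' Among co-optimal alignments the traceback prefers match/mismatch
#' columns over gap-in-`a` columns over gap-in-`b` columns.
#'
#' @param a,b sequences: character scalars or `XString` objects. Must be
#'   non-empty and free of gap characters.
#' @param substitutionMatrix a scoring matrix, or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`, i.e. EBLOSUM62).
#' @param gapOpen,gapExtend gap penalties as positive numbers (defaults
#'   10 and 0.5, the Needle webserver defaults).
#' @param endGapsPenalized if `TRUE`, terminal gaps are charged like
#'   internal ones.
#' @param idA,idB identifiers recorded in the result.
#' @return A [NeedleAlignment-class].
#' @export
#' @examples
#' aln <- needleAlign("HEAGAWGHEE", "PAWHEAE")
#' percentIdentity(aln)
needleAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5,
                        endGapsPenalized = FALSE,
                        idA = "a", idB = "b") {
  A <- strsplit(toupper(as.character(a)), "")[[1L]]
  B <- strsplit(toupper(as.character(b)), "")[[1L]]
  if (length(A) == 0L || length(B) == 0L)
    stop("both sequences must be non-empty")
  if (any(A == "-") || any(B == "-"))
    stop("input sequences must not contain gap characters")
  mat <- resolveMatrix(substitutionMatrix)
  missing <- setdiff(unique(c(A, B)), rownames(mat))
  if (length(missing))
    stop("residue(s) absent from substitution matrix: ",
         paste(missing, collapse = ", "))
  n <- length(A); m <- length(B)
  NEG <- -Inf
  ## layers: M = a[i]~b[j]; X = a[i] vs gap (gap in b); Y = gap vs b[j] (gap in a)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  gapCost <- function(k) gapOpen + (k - 1L) * gapExtend
  if (n >= 1L)
    X[2L:(n + 1L), 1L] <- if (endGapsPenalized) -gapCost(seq_len(n)) else 0
  if (m >= 1L)
    Y[1L, 2L:(m + 1L)] <- if (endGapsPenalized) -gapCost(seq_len(m)) else 0
  for (i in seq_len(n)) {
    si <- mat[A[i], ]
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], Y[i, j], X[i, j]) + si[B[j]]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gapOpen,
                               X[i, j + 1L] - gapExtend,
                               Y[i, j + 1L] - gapOpen)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gapOpen,
                               X[i + 1L, j] - gapOpen,
                               Y[i + 1L, j] - gapExtend)
    }
  }
  ## endpoint: with free end gaps, the path may stop before consuming the
  ## tail of either sequence; the remainder becomes unpenalized terminal gaps
  layerAt <- function(i, j) {
    v <- c(M = M[i + 1L, j + 1L], Y = Y[i + 1L, j + 1L], X = X[i + 1L, j + 1L])
    list(layer = names(v)[which.max(v)], value = max(v))
  }
  endI <- n; endJ <- m
  best <- layerAt(n, m)
  if (!endGapsPenalized) {
    for (i in rev(seq_len(n) - 1L)) {     # stop early in a: tail of a gapped vs b? no: vs gap in b
      cand <- layerAt(i, m)
      if (cand$value > best$value) { best <- cand; endI <- i; endJ <- m }
    }
    for (j in rev(seq_len(m) - 1L)) {
      cand <- layerAt(n, j)
      if (cand$value > best$value) { best <- cand; endI <- n; endJ <- j }
    }
  }
  score <- best$value
  ## traceback with preference M > Y > X on ties
  alnA <- character(0); alnB <- character(0)
  if (endI < n) {       # unconsumed tail of a aligned to terminal gaps in b
    alnA <- A[(endI + 1L):n]; alnB <- rep("-", n - endI)
  } else if (endJ < m) {
    alnA <- rep("-", m - endJ); alnB <- B[(endJ + 1L):m]
  }
  i <- endI; j <- endJ; layer <- best$layer
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (j == 0L) {            # left boundary: remaining columns are gaps in b
      alnA <- c(A[seq_len(i)], alnA); alnB <- c(rep("-", i), alnB)
      break
    }
    if (i == 0L) {            # left boundary: remaining columns are gaps in a
      alnA <- c(rep("-", j), alnA); alnB <- c(B[seq_len(j)], alnB)
      break
    }
    if (layer == "M") {
      alnA <- c(A[i], alnA); alnB <- c(B[j], alnB)
      target <- M[i + 1L, j + 1L] - mat[A[i], B[j]]
      i <- i - 1L; j <- j - 1L
      layer <- pickLayer(M[i + 1L, j + 1L], Y[i + 1L, j + 1L], X[i + 1L, j + 1L],
                         target, eps)
    } else if (layer == "X") {
      alnA <- c(A[i], alnA); alnB <- c("-", alnB)
      cur <- X[i + 1L, j + 1L]
      i <- i - 1L
      if (j == 0L || i == 0L) next   # boundary branches above finish the walk
      layer <- pickLayer(M[i + 1L, j + 1L] - gapOpen,
                         Y[i + 1L, j + 1L] - gapOpen,
                         X[i + 1L, j + 1L] - gapExtend,
                         cur, eps)
    } else { # Y
      alnA <- c("-", alnA); alnB <- c(B[j], alnB)
      cur <- Y[i + 1L, j + 1L]
      j <- j - 1L
      if (j == 0L || i == 0L) next
      layer <- pickLayer(M[i + 1L, j + 1L] - gapOpen,
                         Y[i + 1L, j + 1L] - gapExtend,
                         X[i + 1L, j + 1L] - gapOpen,
                         cur, eps)
    }
  }
  new("NeedleAlignment",
      idA = idA, idB = idB,
      alignedA = paste(alnA, collapse = ""),
      alignedB = paste(alnB, collapse = ""),
      score = score)
}

# choose the predecessor layer reproducing `target`, preferring M > Y > X
pickLayer <- function(vM, vY, vX, target, eps) {
  if (is.finite(vM) && abs(vM - target) <= eps) return("M")
  if (is.finite(vY) && abs(vY - target) <= eps) return("Y")
  if (is.finite(vX) && abs(vX - target) <= eps) return("X")
  # numerical fallback: take the max with the same preference
  v <- c(M = vM, Y = vY, X = vX)
  names(v)[which.max(v)]
}

resolveMatrix <- function(substitutionMatrix) {
  if (is.matrix(substitutionMatrix)) return(substitutionMatrix)
  stopifnot(is.character(substitutionMatrix), length(substitutionMatrix) == 1L)
  env <- new.env()
  utils::data(list = substitutionMatrix, package = "Biostrings", envir = env)
  get(substitutionMatrix, envir = env)
}

#' Percent identity of a pairwise alignment
#'
#' `100 *` (columns with identical residues) `/` (total alignment columns,
#' gap columns included), rounded to one decimal — the convention of the
#' EMBOSS Needle "Identity" line.
#'
#' @param x a [NeedleAlignment-class], or a length-2 character vector of
#'   equal-length gapped sequences.
#' @param ... unused.
#' @return A single number (percent).
#' @export
#' @examples
#' percentIdentity(c("AC-GT", "ACGGT")) # 80
setMethod("percentIdentity", "NeedleAlignment", function(x, ...) {
  identityFromStrings(x@alignedA, x@alignedB)
})

#' @rdname percentIdentity
setMethod("percentIdentity", "character", function(x, ...) {
  stopifnot(length(x) == 2L)
  identityFromStrings(x[[1L]], x[[2L]])
})

identityFromStrings <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  if (length(ca) != length(cb)) stop("gapped sequences differ in length")
  if (length(ca) == 0L) stop("zero-length alignment: identity undefined")
  round(100 * sum(ca == cb & ca != "-") / length(ca), 1)
}

#' Collapse alignment columns gapped in a reference row
#'
#' Removes every column of a multiple alignment in which the reference row
#' holds a gap, the transform used to display large homolog alignments
#' compactly against a reference sequence. The removed column ranges are
#' reported so figure annotations can mark the collapse points.
#'
#' @param msa a named character vector of equal-length gapped rows, or an
#'   `XStringSet` / `MultipleAlignment`.
#' @param referenceId name of the reference row.
#' @return A list with `msa` (named character vector of collapsed rows),
#'   `removedColumns` (integer positions in the original alignment) and
#'   `removedRanges` (data.frame of start/end runs).
#' @export
collapseToReference <- function(msa, referenceId) {
  if (is(msa, "MultipleAlignment")) msa <- as.character(msa)
  if (is(msa, "XStringSet")) msa <- as.character(msa)
  stopifnot(is.character(msa), !is.null(names(msa)))
  if (!referenceId %in% names(msa))
    stop("reference sequence '", referenceId, "' not found in alignment")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length")
  refChars <- strsplit(msa[[referenceId]], "")[[1L]]
  drop <- which(refChars == "-")
  keep <- setdiff(seq_along(refChars), drop)
  rows <- vapply(strsplit(msa, ""), function(ch)
    paste(ch[keep], collapse = ""), character(1))
  names(rows) <- names(msa)
  ranges <- if (length(drop)) {
    runs <- split(drop, cumsum(c(1L, diff(drop) != 1L)))
    data.frame(start = vapply(runs, min, integer(1)),
               end = vapply(runs, max, integer(1)),
               row.names = NULL)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  list(msa = rows, removedColumns = drop, removedRanges = ranges)
}

#' Write an alignment in a Needle-like pair format
#'
#' Human-readable pairwise alignment report: identity count and
#' percentage over the full alignment length, gap count, score, and the
#' alignment in 50-column blocks with a match line.
#'
#' @param aln a [NeedleAlignment-class].
#' @param path optional output file; if `NULL` the text is returned.
#' @return The report lines, invisibly if written to `path`.
#' @export
writePairAlignment <- function(aln, path = NULL) {
  a <- strsplit(aln@alignedA, "")[[1L]]
  b <- strsplit(aln@alignedB, "")[[1L]]
  ncol <- length(a)
  nid <- sum(a == b & a != "-")
  ngap <- sum(a == "-" | b == "-")
  hdr <- c(
    "########################################",
    paste0("# 1: ", aln@idA),
    paste0("# 2: ", aln@idB),
    paste0("# Length: ", ncol),
    sprintf("# Identity: %5d/%d (%.1f%%)", nid, ncol, 100 * nid / ncol),
    sprintf("# Gaps:     %5d/%d (%.1f%%)", ngap, ncol, 100 * ngap / ncol),
    sprintf("# Score: %.1f", aln@score),
    "########################################",
    ""
  )
  marks <- ifelse(a == b & a != "-", "|",
                  ifelse(a == "-" | b == "-", " ", "."))
  blocks <- character(0)
  for (s in seq(1L, ncol, by = 50L)) {
    e <- min(s + 49L, ncol)
    blocks <- c(blocks,
      sprintf("%-12s %s", substr(aln@idA, 1, 12), paste(a[s:e], collapse = "")),
      sprintf("%-12s %s", "", paste(marks[s:e], collapse = "")),
      sprintf("%-12s %s", substr(aln@idB, 1, 12), paste(b[s:e], collapse = "")),
      "")
  }
  out <- c(hdr, blocks)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
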