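# Independent oracles used by the test suite. These deliberately use
# brute-force enumeration rather than the package's algorithms.

# score a pair of gapped strings under the affine model used by the
# aligner: a gap of length L costs open + (L-1)*extend; terminal gap
# runs are free when endFree
scoreGapped <- function(a, b, mat, open, extend, endFree = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb), !any(ca == "-" & cb == "-"))
  total <- 0
  n <- length(ca)
  for (i in seq_len(n))
    if (ca[i] != "-" && cb[i] != "-") total <- total + mat[ca[i], cb[i]]
  gapRuns <- function(isGap) {
    r <- rle(isGap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }
  for (runs in list(gapRuns(ca == "-"), gapRuns(cb == "-"))) {
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      if (endFree && (runs$start[k] == 1 || runs$end[k] == n)) next
      total <- total - (open + (runs$len[k] - 1) * extend)
    }
  }
  total
}

# enumerate every global alignment (no gap-vs-gap columns) of two short
# ungapped strings, as pairs of gapped strings
enumerateAlignments <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(list(c("", "")))
  out <- list()
  if (nchar(a) > 0 && nchar(b) > 0) {
    for (tail in enumerateAlignments(substring(a, 2), substring(b, 2)))
      out[[length(out) + 1]] <- c(paste0(substring(a, 1, 1), tail[1]),
                                  paste0(substring(b, 1, 1), tail[2]))
  }
  if (nchar(a) > 0) {
    for (tail in enumerateAlignments(substring(a, 2), b))
      out[[length(out) + 1]] <- c(paste0(substring(a, 1, 1), tail[1]),
                                  paste0("-", tail[2]))
  }
  if (nchar(b) > 0) {
    for (tail in enumerateAlignments(a, substring(b, 2)))
      out[[length(out) + 1]] <- c(paste0("-", tail[1]),
                                  paste0(substring(b, 1, 1), tail[2]))
  }
  out
}

# exhaustive optimal global alignment score by enumeration
bruteAlignScore <- function(a, b, mat, open, extend, endFree = TRUE) {
  max(vapply(enumerateAlignments(a, b), function(al)
    scoreGapped(al[1], al[2], mat, open, extend, endFree), numeric(1)))
}

# independent top-down memoized alignment oracle: recursion over
# (position in a, position in b, previous column type), with explicit
# free-terminal-gap states; structurally unlike the package's iterative
# three-matrix Gotoh
dpAlignScore <- function(a, b, mat, open, extend, endFree = TRUE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (i > n) {     # remaining b against terminal gaps in a
      if (endFree) return(0)
      len <- m - j + 1
      return(-(if (prev == "Y") len * extend else open + (len - 1) * extend))
    }
    if (j > m) {     # remaining a against terminal gaps in b
      if (endFree) return(0)
      len <- n - i + 1
      return(-(if (prev == "X") len * extend else open + (len - 1) * extend))
    }
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- mat[A[i], B[j]] + rec(i + 1, j + 1, "M")
    best <- max(best, -(if (prev == "X") extend else open) + rec(i + 1, j, "X"))
    best <- max(best, -(if (prev == "Y") extend else open) + rec(i, j + 1, "Y"))
    if (endFree && prev %in% c("S", "XF"))
      best <- max(best, rec(i + 1, j, "XF"))   # free left-terminal gap in b
    if (endFree && prev %in% c("S", "YF"))
      best <- max(best, rec(i, j + 1, "YF"))   # free left-terminal gap in a
    memo[[key]] <- best
    best
  }
  rec(1, 1, "S")
}

# simple +match/-mismatch matrix over a reduced alphabet
toyMatrix <- function(alphabet = c("A", "C", "G", "T"),
                      match = 5, mismatch = -4) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# brute-force maximal direct repeat enumeration (O(n^2 k))
bruteRepeats <- function(s, kMin) {
  n <- nchar(s)
  res <- list()
  if (kMin > n - 1) return(res)
  for (k in kMin:(n - 1)) {
    for (p in 1:(n - k + 1)) {
      m <- substring(s, p, p + k - 1)
      if (!is.null(res[[m]])) next
      P <- integer(0)
      for (q in 1:(n - k + 1))
        if (substring(s, q, q + k - 1) == m) P <- c(P, q)
      if (length(P) < 2) next
      leftExt <- all(P > 1) && length(unique(substring(s, P - 1, P - 1))) == 1
      rightExt <- all(P + k - 1 < n) &&
        length(unique(substring(s, P + k, P + k))) == 1
      if (!leftExt && !rightExt) res[[m]] <- P
    }
  }
  res
}

# brute-force interval-overlap membership for a neighborhood window;
# returns feature ids of genes overlapping the (possibly wrapped) window
bruteWindowMembers <- function(df, focalId, flank, contigLength = NULL,
                               circular = FALSE) {
  f <- df[df$feature_id == focalId, ]
  ws <- f$start - flank; we <- f$end + flank
  if (!circular) {
    if (ws < 1) ws <- 1
    if (!is.null(contigLength) && we > contigLength) we <- contigLength
  }
  ids <- character(0)
  for (i in seq_len(nrow(df))) {
    if (df$feature_id[i] == focalId) next
    shifts <- if (circular) c(0, -contigLength, contigLength) else 0
    for (d in shifts) {
      if (df$end[i] + d >= ws && df$start[i] + d <= we) {
        ids <- c(ids, df$feature_id[i])
        break
      }
    }
  }
  ids
}

# random DNA string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# a toy feature table: regularly spaced 1-kb genes on one contig
regularFeatureTable <- function(nGenes = 50, geneLen = 1000, spacing = 2000,
                                contig = "ctg1") {
  starts <- (seq_len(nGenes) - 1) * spacing + 1
  data.frame(feature_id = sprintf("g%02d", seq_len(nGenes)),
             contig = contig,
             start = starts,
             end = starts + geneLen - 1,
             strand = "+",
             product = "hypothetical protein",
             stringsAsFactors = FALSE)
}
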