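degap <- function(x) gsub("-", "", x)

test_that("aligning a sequence with itself scores the diagonal sum", {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B62 <- get("BLOSUM62", envir = env)
  s <- "HEAGAWGHEE"
  aln <- needleAlign(s, s)
  ch <- strsplit(s, "")[[1]]
  expect_equal(alignmentScore(aln), sum(B62[cbind(ch, ch)]))
  expect_equal(unname(alignedSeqs(aln)), c(s, s))
  expect_equal(percentIdentity(aln), 100.0)
})

test_that("classic pair matches the exhaustive enumeration oracle", {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B62 <- get("BLOSUM62", envir = env)
  aln <- needleAlign("HEAGAWGHEE", "PAWHEAE")
  oracle <- dpAlignScore("HEAGAWGHEE", "PAWHEAE", B62, 10, 0.5,
                         endFree = TRUE)
  expect_equal(alignmentScore(aln), oracle)
  # the returned alignment itself scores what it claims
  s <- alignedSeqs(aln)
  expect_equal(scoreGapped(s[[1]], s[[2]], B62, 10, 0.5, endFree = TRUE),
               alignmentScore(aln))
})

test_that("single-residue sequence aligns at its best placement", {
  mat <- toyMatrix()
  a <- "ACGTTG"
  for (b in c("A", "G", "T")) {
    aln <- needleAlign(a, b, substitutionMatrix = mat)
    placements <- vapply(seq_len(nchar(a)), function(i) {
      gapped <- paste0(strrep("-", i - 1), b, strrep("-", nchar(a) - i))
      scoreGapped(a, gapped, mat, 10, 0.5, endFree = TRUE)
    }, numeric(1))
    expect_equal(alignmentScore(aln), max(placements))
    expect_equal(degap(alignedSeqs(aln)[[2]]), b)
  }
})

test_that("aligner equals the enumeration oracle on random short pairs", {
  mat <- toyMatrix()
  set.seed(101)
  for (rep in 1:40) {
    a <- randomDna(sample(1:6, 1))
    b <- randomDna(sample(1:6, 1))
    for (endFree in c(TRUE, FALSE)) {
      aln <- needleAlign(a, b, substitutionMatrix = mat,
                         endGapsPenalized = !endFree)
      oracle <- bruteAlignScore(a, b, mat, 10, 0.5, endFree)
      # the two independent oracles must agree with each other too
      expect_equal(dpAlignScore(a, b, mat, 10, 0.5, endFree), oracle)
      expect_equal(alignmentScore(aln), oracle,
                   info = paste(a, b, "endFree", endFree))
      s <- alignedSeqs(aln)
      expect_equal(degap(s[[1]]), a)
      expect_equal(degap(s[[2]]), b)
      ca <- strsplit(s[[1]], "")[[1]]; cb <- strsplit(s[[2]], "")[[1]]
      expect_false(any(ca == "-" & cb == "-"))
      expect_equal(scoreGapped(s[[1]], s[[2]], mat, 10, 0.5, endFree),
                   alignmentScore(aln))
    }
  }
})

test_that("aligner score agrees with an independent implementation", {
  # Biostrings charges open + L*extend per gap; shifting its opening
  # penalty by one extension reproduces the open + (L-1)*extend model
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B62 <- get("BLOSUM62", envir = env)
  pairs <- list(c("HEAGAWGHEE", "PAWHEAE"),
                c("MKVLESRTA", "MKESRTTA"),
                c("WWAGHE", "AGHEWW"))
  for (p in pairs) {
    mine <- needleAlign(p[1], p[2], endGapsPenalized = FALSE)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p[1]), Biostrings::AAString(p[2]),
      substitutionMatrix = B62, gapOpening = 9.5, gapExtension = 0.5,
      type = "overlap")
    expect_equal(alignmentScore(mine), Biostrings::score(ref))
  }
})

test_that("aligner rejects invalid input", {
  expect_error(needleAlign("", "AC"), "non-empty")
  expect_error(needleAlign("AC", "AB", substitutionMatrix = toyMatrix()),
               "absent from substitution matrix")
})

test_that("percent identity follows the full-length Needle convention", {
  expect_equal(percentIdentity(c("AC-GT", "ACGGT")), 80.0)
  # symmetric in the two rows
  expect_equal(percentIdentity(c("ACGGT", "AC-GT")), 80.0)
  # invariant under simultaneous column permutation
  set.seed(5)
  a <- "AC-GTAG-A"; b <- "ACGG-AGTA"
  perm <- sample(nchar(a))
  pa <- paste(strsplit(a, "")[[1]][perm], collapse = "")
  pb <- paste(strsplit(b, "")[[1]][perm], collapse = "")
  expect_equal(percentIdentity(c(pa, pb)), percentIdentity(c(a, b)))
  expect_error(percentIdentity(c("", "")), "undefined")
  expect_error(percentIdentity(c("AC", "ACG")), "differ in length")
})

test_that("reference-gap columns collapse correctly", {
  msa <- c(ref = "AC-GT-A", s2 = "ACGGTTA", s3 = "A--GTTA")
  out <- collapseToReference(msa, "ref")
  expect_equal(unname(out$msa["ref"]), "ACGTA")
  expect_equal(unname(out$msa["s2"]), "ACGTA")
  expect_equal(unname(out$msa["s3"]), "A-GTA")
  expect_equal(out$removedColumns, c(3L, 6L))
  expect_equal(out$removedRanges$start, c(3L, 6L))
  expect_equal(out$removedRanges$end, c(3L, 6L))

  # reference without gaps: unchanged
  msa2 <- c(r = "ACGT", s = "A-GT")
  expect_equal(collapseToReference(msa2, "r")$msa, msa2)

  # all-gap reference: zero columns
  msa3 <- c(r = "---", s = "ACG")
  expect_equal(unname(collapseToReference(msa3, "r")$msa), c("", ""))

  # output width equals reference ungapped length (property)
  set.seed(9)
  for (i in 1:10) {
    w <- sample(5:25, 1)
    rows <- vapply(1:3, function(j) {
      ch <- sample(c("A", "C", "G", "-"), w, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    names(rows) <- c("ref", "a", "b")
    out <- collapseToReference(rows, "ref")
    expect_equal(unique(nchar(out$msa)),
                 nchar(gsub("-", "", rows[["ref"]])))
  }
  expect_error(collapseToReference(msa, "absent"), "not found")
})

test_that("pair-format output reports identity over full length", {
  aln <- needleAlign("HEAGAWGHEE", "PAWHEAE")
  txt <- writePairAlignment(aln)
  expect_true(any(grepl("# Identity:", txt)))
  idLine <- txt[grepl("# Identity:", txt)]
  expect_match(idLine, "/10 ")
})
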