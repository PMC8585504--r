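test_that("window is clipped and flagged at a linear contig edge", {
  df <- regularFeatureTable(nGenes = 25)
  df$start[1] <- 100; df$end[1] <- 1000
  nb <- extractNeighborhood(df, "g01", flank = 20000, contigLength = 50000)
  expect_equal(nb@windowStart, 1)
  expect_true(nb@leftTruncated)
  expect_false(nb@rightTruncated)
  expect_equal(length(leftGenes(nb)), 0L)
})

test_that("regularly spaced fixture yields ten complete genes per side", {
  df <- regularFeatureTable(nGenes = 50, geneLen = 1000, spacing = 2000)
  nb <- extractNeighborhood(df, "g25", flank = 20000, contigLength = 100000)
  expect_equal(length(leftGenes(nb)), 10L)
  expect_equal(length(rightGenes(nb)), 10L)
  got <- sort(c(leftGenes(nb)$feature_id, rightGenes(nb)$feature_id))
  oracle <- sort(bruteWindowMembers(df, "g25", 20000, 100000))
  expect_equal(got, oracle)
  # untruncated linear window spans exactly 2*flank + focal length
  expect_equal(nb@windowEnd - nb@windowStart + 1,
               2 * 20000 + (df$end[25] - df$start[25] + 1))
})

test_that("membership matches the interval-overlap oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(10:40, 1)
    starts <- sort(sample(1:80000, n))
    lens <- sample(200:1500, n, replace = TRUE)
    df <- data.frame(feature_id = sprintf("f%02d", 1:n), contig = "c",
                     start = starts, end = starts + lens,
                     strand = sample(c("+", "-"), n, TRUE),
                     product = "x", stringsAsFactors = FALSE)
    focal <- sample(df$feature_id, 1)
    flank <- sample(c(3000, 10000, 20000), 1)
    nb <- extractNeighborhood(df, focal, flank = flank, contigLength = 100000)
    got <- sort(c(leftGenes(nb)$feature_id, rightGenes(nb)$feature_id))
    expect_equal(got, sort(bruteWindowMembers(df, focal, flank, 100000)))
    # every returned gene overlaps the window
    genes <- flankGenes(nb)
    expect_true(all(GenomicRanges::end(genes) >= nb@windowStart &
                    GenomicRanges::start(genes) <= nb@windowEnd))
  }
})

test_that("circular contigs wrap and match the doubling oracle", {
  L <- 30000
  df <- regularFeatureTable(nGenes = 15, geneLen = 1000, spacing = 2000)
  df2 <- df
  nbLin <- extractNeighborhood(df, "g01", flank = 5000, contigLength = L)
  nb <- extractNeighborhood(df2, "g01", flank = 5000, contigLength = L,
                            circular = TRUE)
  expect_true(nb@wrapped)
  expect_false(nbLin@leftTruncated && nb@wrapped == FALSE)
  got <- sort(flankGenes(nb)$feature_id)
  oracle <- sort(bruteWindowMembers(df, "g01", 5000, L, circular = TRUE))
  expect_equal(got, oracle)
  # genes from the far end of the axis appear on the left flank
  expect_true(any(GenomicRanges::start(leftGenes(nb)) > 20000))
  # the wrapped window picks up more genes than the clipped linear one
  expect_gt(length(flankGenes(nb)), length(flankGenes(nbLin)))
})

test_that("extraction is invariant under input feature order", {
  df <- regularFeatureTable(nGenes = 30)
  set.seed(3)
  shuf <- df[sample(nrow(df)), ]
  nb1 <- extractNeighborhood(df, "g15", flank = 10000, contigLength = 60000)
  nb2 <- extractNeighborhood(shuf, "g15", flank = 10000, contigLength = 60000)
  expect_equal(leftGenes(nb1)$feature_id, leftGenes(nb2)$feature_id)
  expect_equal(rightGenes(nb1)$feature_id, rightGenes(nb2)$feature_id)
})

test_that("identity and configuration errors are raised", {
  df <- regularFeatureTable(nGenes = 10)
  expect_error(extractNeighborhood(df, "nope", flank = 1000), "not found")
  dup <- rbind(df, df[3, ])
  expect_error(extractNeighborhood(dup, "g03", flank = 1000), "duplicated")
  expect_error(
    extractNeighborhood(df, "g05", flank = 20000, contigLength = 20000,
                        circular = TRUE),
    "spans the whole circular contig")
  expect_error(
    extractNeighborhood(df, "g05", flank = 1000, circular = TRUE),
    "contigLength is required")
})

test_that("neighborhoods never cross contig boundaries", {
  df <- regularFeatureTable(nGenes = 10)
  other <- regularFeatureTable(nGenes = 10, contig = "ctg2")
  other$feature_id <- sprintf("h%02d", 1:10)
  both <- rbind(df, other)
  nb <- extractNeighborhood(both, "g05", flank = 20000)
  expect_false(any(grepl("^h", flankGenes(nb)$feature_id)))
})

test_that("strand-oriented mode swaps the sides for minus-strand focals", {
  df <- regularFeatureTable(nGenes = 9)
  df$strand[5] <- "-"
  plain <- extractNeighborhood(df, "g05", flank = 20000)
  oriented <- extractNeighborhood(df, "g05", flank = 20000,
                                  orientByStrand = TRUE)
  expect_equal(leftGenes(oriented)$feature_id, rightGenes(plain)$feature_id)
  expect_equal(rightGenes(oriented)$feature_id, leftGenes(plain)$feature_id)
})

test_that("GFF3 and feature-table readers produce equivalent tables", {
  df <- regularFeatureTable(nGenes = 5)
  df$product <- c("phage tail protein", "hypothetical protein",
                  "terminase large subunit", "x", "y")
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  grTsv <- readFeatureTable(tsv)
  expect_equal(grTsv$feature_id, df$feature_id)
  expect_equal(grTsv$product, df$product)
  expect_equal(GenomicRanges::start(grTsv), df$start)

  gff <- tempfile(fileext = ".gff3")
  bstaContext:::exportGff3(grTsv, gff)
  grGff <- readGffFeatures(gff)
  expect_equal(grGff$feature_id, df$feature_id)
  expect_equal(grGff$product, df$product)
  expect_equal(GenomicRanges::end(grGff), df$end)
  expect_equal(as.character(GenomicRanges::strand(grGff)),
               as.character(GenomicRanges::strand(grTsv)))
})
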