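# neighborhood fixture: 2 genes per side around a focal gene, with
# chosen products (left then right, outward order away from the focal)
toyNeighborhood <- function(leftProducts, rightProducts,
                            plasmid = FALSE, focalStrand = "+",
                            strands = NULL) {
  prods <- c(rev(leftProducts), "BstA family protein", rightProducts)
  n <- length(prods)
  focalIdx <- length(leftProducts) + 1
  starts <- (seq_len(n) - 1) * 1500 + 1
  df <- data.frame(
    feature_id = ifelse(seq_len(n) == focalIdx, "foc",
                        sprintf("g%02d", seq_len(n))),
    contig = "c", start = starts, end = starts + 999,
    strand = if (is.null(strands)) "+" else strands,
    product = prods, stringsAsFactors = FALSE)
  df$strand[focalIdx] <- focalStrand
  extractNeighborhood(df, "foc", flank = 20000, plasmid = plasmid)
}

test_that("keyword rule is a loose case-insensitive substring match", {
  expect_true(isPhageAnnotation("terminase large subunit"))
  expect_false(isPhageAnnotation("hypothetical protein"))
  expect_true(isPhageAnnotation("Prophage integrase"))
  expect_true(isPhageAnnotation("BACTERIOPHAGE holin"))
  expect_equal(isPhageAnnotation(c("phage tail", "porin")), c(TRUE, FALSE))
  # exclusion list vetoes pathological products
  expect_true(isPhageAnnotation("macrophage stimulating factor"))
  expect_false(isPhageAnnotation("macrophage stimulating factor",
                                 exclude = "macrophage"))
  # but a genuine keyword elsewhere in the product still matches
  expect_true(isPhageAnnotation("macrophage-like phage tail protein",
                                exclude = "macrophage"))
})

test_that("association calls follow the two-sided evidence rule", {
  high <- classifyAssociation(toyNeighborhood(
    c("phage tail protein", "x"), c("y", "terminase small subunit")))
  expect_equal(category(high), "prophage_associated")
  expect_equal(confidence(high), "high")
  expect_equal(evidence(high, "left"), "g02")

  low <- classifyAssociation(toyNeighborhood(
    c("phage tail protein", "x"), c("y", "z")))
  expect_equal(category(low), "prophage_associated")
  expect_equal(confidence(low), "low")
  expect_equal(length(evidence(low, "right")), 0L)

  indep <- classifyAssociation(toyNeighborhood(c("a", "b"), c("c", "d")))
  expect_equal(category(indep), "prophage_independent")
  expect_equal(confidence(indep), "not_applicable")

  pl <- classifyAssociation(toyNeighborhood(c("a"), c("b"), plasmid = TRUE))
  expect_true(isPlasmid(pl))
})

test_that("adding a non-keyword gene never changes a call", {
  base <- toyNeighborhood(c("phage portal protein"), c("x"))
  more <- toyNeighborhood(c("phage portal protein", "ABC transporter"),
                          c("x", "chaperone"))
  c1 <- classifyAssociation(base); c2 <- classifyAssociation(more)
  expect_equal(category(c1), category(c2))
  expect_equal(confidence(c1), confidence(c2))
})

test_that("domain-mode classification uses best-hit domain evidence", {
  nb <- toyNeighborhood(c("hyp1"), c("hyp2"))
  best <- data.frame(orf_id = c("g01", "g03"),
                     domain_accession = c("PF001", "PF002"),
                     domain_name = c("Phage_portal", "ABC_tran"),
                     stringsAsFactors = FALSE)
  nb <- annotateDomainHits(nb, best)
  call <- classifyAssociation(nb, mode = "domain",
                              phageDomains = "Phage_portal")
  expect_equal(category(call), "prophage_associated")
  expect_equal(confidence(call), "low")
  expect_error(classifyAssociation(toyNeighborhood("a", "b"), mode = "domain"),
               "annotateDomainHits")
})

test_that("domain tallies match a brute-force count in both units", {
  mkNb <- function(domsLeft, domsRight) {
    nb <- toyNeighborhood(rep("p", length(domsLeft)),
                          rep("q", length(domsRight)))
    ids <- c(leftGenes(nb)$feature_id, rightGenes(nb)$feature_id)
    best <- data.frame(orf_id = ids, domain_accession = "PF",
                       domain_name = c(rev(domsLeft), domsRight),
                       stringsAsFactors = FALSE)
    best <- best[!is.na(best$domain_name), ]
    annotateDomainHits(nb, best)
  }
  nbs <- list(mkNb(c("A", "B"), c("A", NA)),
              mkNb(c("B", "B"), c("C", "A")),
              mkNb(c(NA, NA), c("D", NA)))
  calls <- lapply(nbs, classifyAssociation)  # products "p"/"q": all independent
  tallyN <- tallyCooccurringDomains(nbs, calls, "prophage_independent",
                                    unit = "per_neighborhood")
  expect_equal(tallyN$counts[c("A", "B", "C", "D")],
               c(A = 2L, B = 2L, C = 1L, D = 1L))
  tallyG <- tallyCooccurringDomains(nbs, calls, "prophage_independent",
                                    unit = "per_gene")
  expect_equal(tallyG$counts[c("A", "B", "C", "D")],
               c(A = 3L, B = 3L, C = 1L, D = 1L))
  # ties are ranked alphabetically
  expect_equal(tallyN$top$domain_name[1:2], c("A", "B"))
  # no neighborhood in the other category -> empty summary
  empty <- tallyCooccurringDomains(nbs, calls, "prophage_associated")
  expect_equal(length(empty$counts), 0L)
  expect_equal(nrow(empty$top), 0L)
  expect_error(tallyCooccurringDomains(nbs, calls, "plasmid"), "unknown category")
  # permutation invariance
  perm <- c(3, 1, 2)
  tallyP <- tallyCooccurringDomains(nbs[perm], calls[perm],
                                    "prophage_independent")
  expect_equal(tallyP$counts, tallyN$counts)
})

test_that("repressor adjacency honours strand, distance and annotation", {
  # "cI repressor" immediately 5', same strand, small gap -> match
  nb <- toyNeighborhood(c("cI repressor protein", "x"), c("y"))
  hit <- detectRepressorAdjacency(nb)
  expect_equal(hit$feature_id, "g02")
  expect_lte(hit$gap, 1000)
  expect_equal(hit$matched_by, "keyword")

  # no repressor-annotated gene -> none
  expect_null(detectRepressorAdjacency(toyNeighborhood(c("x"), c("y"))))

  # repressor too far away for the gap limit -> none
  df <- data.frame(
    feature_id = c("rep", "foc"), contig = "c",
    start = c(1, 6100), end = c(1000, 7000), strand = "+",
    product = c("prophage repressor", "BstA"), stringsAsFactors = FALSE)
  nbFar <- extractNeighborhood(df, "foc", flank = 20000)
  expect_null(detectRepressorAdjacency(nbFar, maxGap = 1000))
  expect_false(is.null(detectRepressorAdjacency(nbFar, maxGap = 6000)))

  # opposite strand is rejected unless sameStrand is relaxed
  nbStr <- toyNeighborhood(c("cI repressor protein"), c("y"),
                           strands = c("-", "+", "+"))
  expect_null(detectRepressorAdjacency(nbStr))
  expect_false(is.null(detectRepressorAdjacency(nbStr, sameStrand = FALSE)))

  # minus-strand focal: 5' is the genome-right side
  dfm <- data.frame(
    feature_id = c("foc", "rep"), contig = "c",
    start = c(1000, 2100), end = c(2000, 3000), strand = "-",
    product = c("BstA", "phage repressor CI"), stringsAsFactors = FALSE)
  nbm <- extractNeighborhood(dfm, "foc", flank = 20000)
  hitm <- detectRepressorAdjacency(nbm)
  expect_equal(hitm$feature_id, "rep")
})

test_that("survey summaries recompute percentages from counts", {
  mkCall <- function(cat, plasmid = FALSE) {
    le <- if (cat == "prophage_associated") "g1" else character(0)
    new("AssociationCall", homologId = "h", category = cat,
        confidence = if (cat == "prophage_associated") "low" else "not_applicable",
        plasmid = plasmid, leftEvidence = le, rightEvidence = character(0))
  }
  calls <- c(replicate(57, mkCall("prophage_associated"), simplify = FALSE),
             replicate(15, mkCall("prophage_independent"), simplify = FALSE))
  s <- summarizeSurvey(calls)
  expect_equal(s@nTotal, 72L)
  expect_equal(pctIndependent(s), 21)    # 20.83 rounded
  expect_equal(pctAssociated(s), 79)     # 79.17 rounded
  expect_equal(pctAssociated(s, rounded = FALSE), 100 * 57 / 72)

  allA <- replicate(5, mkCall("prophage_associated"), simplify = FALSE)
  expect_equal(pctAssociated(summarizeSurvey(allA)), 100)
  expect_error(summarizeSurvey(list()), "empty")
})
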