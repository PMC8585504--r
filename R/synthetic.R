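#' Configuration for a synthetic homolog survey
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a curated set of focal homologs whose neighborhoods carry
#' phage-annotated genes on both sides (high-confidence prophage
#' association), one side (low confidence) or neither side
#' (putatively prophage-independent), at configurable rates, with a
#' fraction of plasmid-flagged records. The defaults mirror a 72-homolog
#' survey with 79% prophage association.
#'
#' @param nHomologs number of focal homologs (default 72).
#' @param fractionAssociated fraction of homologs with prophage
#'   association (default 0.79).
#' @param fractionHighConfidence fraction of the associated homologs with
#'   evidence on both sides (default 0.6).
#' @param fractionPlasmid fraction of plasmid-encoded homologs (default
#'   0.1).
#' @param flankGeneCount flank genes per side (default 12).
#' @param phageKeywordRate probability that a gene on a designated
#'   prophage side carries a phage-annotated product (default 0.6; at
#'   least one such gene per designated side is always planted).
#' @param backgroundKeywordRate probability of a phage-annotated product
#'   on non-designated sides (default 0; values above 0 make planted
#'   labels a lower bound rather than exact truth).
#' @param annotationNoiseRate probability that a gene's product is
#'   flipped between phage-annotated and neutral after construction
#'   (default 0).
#' @param domainScoreSd standard deviation of the Gaussian noise on
#'   synthetic domain bit scores (default 5).
#' @param seed integer seed driving all draws.
#' @return A validated list of class `surveyConfig`.
#' @export
surveyConfig <- function(nHomologs = 72L, fractionAssociated = 0.79,
                         fractionHighConfidence = 0.6,
                         fractionPlasmid = 0.1,
                         flankGeneCount = 12L,
                         phageKeywordRate = 0.6,
                         backgroundKeywordRate = 0,
                         annotationNoiseRate = 0,
                         domainScoreSd = 5,
                         seed = 1L) {
  cfg <- list(nHomologs = as.integer(nHomologs),
              fractionAssociated = fractionAssociated,
              fractionHighConfidence = fractionHighConfidence,
              fractionPlasmid = fractionPlasmid,
              flankGeneCount = as.integer(flankGeneCount),
              phageKeywordRate = phageKeywordRate,
              backgroundKeywordRate = backgroundKeywordRate,
              annotationNoiseRate = annotationNoiseRate,
              domainScoreSd = domainScoreSd,
              seed = as.integer(seed))
  fr <- c(cfg$fractionAssociated, cfg$fractionHighConfidence,
          cfg$fractionPlasmid, cfg$phageKeywordRate,
          cfg$backgroundKeywordRate, cfg$annotationNoiseRate)
  if (any(fr < 0 | fr > 1)) stop("all fractions/rates must lie in [0, 1]")
  if (cfg$nHomologs < 1L) stop("nHomologs must be at least 1")
  if (cfg$flankGeneCount < 1L) stop("flankGeneCount must be at least 1")
  class(cfg) <- "surveyConfig"
  cfg
}

#' Largest-remainder apportionment of label counts
#'
#' Splits `n` into integer counts as close to the target fractions as
#' possible: floors first, then remaining units to the largest
#' fractional remainders (ties to earlier categories). Deterministic and
#' seed-independent, so planted survey proportions depend only on the
#' configuration.
#'
#' @param n total count.
#' @param fractions named numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
#' @examples
#' apportionCounts(72, c(associated = 0.79, independent = 0.21))
apportionCounts <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, n >= 0)
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base), seq_along(fractions))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# planted product vocabularies: product <TAB> domain name (may be empty)
readVocabulary <- function(file) {
  lines <- readLines(system.file("extdata", file, package = "bstaContext"))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  data.frame(product = vapply(parts, `[[`, character(1), 1L),
             domain = vapply(parts, function(p)
               if (length(p) > 1L) p[[2L]] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' Truth table of planted labels for a survey
#'
#' Applies largest-remainder apportionment to the configured fractions
#' and assigns category, confidence and plasmid status to each homolog in
#' a fixed order. Seed-independent: two configurations differing only in
#' seed plant identical label proportions.
#'
#' @param config a [surveyConfig()].
#' @return A data.frame with columns `homolog_id`, `true_category`,
#'   `true_confidence`, `plasmid`.
#' @export
surveyTruth <- function(config) {
  stopifnot(inherits(config, "surveyConfig"))
  n <- config$nHomologs
  nCat <- apportionCounts(n, c(associated = config$fractionAssociated,
                               independent = 1 - config$fractionAssociated))
  nConf <- apportionCounts(nCat[["associated"]],
                           c(high = config$fractionHighConfidence,
                             low = 1 - config$fractionHighConfidence))
  nPlasmid <- apportionCounts(n, c(plasmid = config$fractionPlasmid,
                                   chromosome = 1 - config$fractionPlasmid))
  cat <- c(rep("prophage_associated", nCat[["associated"]]),
           rep("prophage_independent", nCat[["independent"]]))
  conf <- c(rep("high", nConf[["high"]]), rep("low", nConf[["low"]]),
            rep("not_applicable", nCat[["independent"]]))
  data.frame(
    homolog_id = sprintf("hom_%03d", seq_len(n)),
    true_category = cat,
    true_confidence = conf,
    plasmid = seq_len(n) <= nPlasmid[["plasmid"]],
    stringsAsFactors = FALSE)
}

#' Generate one synthetic neighborhood bundle
#'
#' Builds, deterministically from `seed`, a linear contig carrying a
#' focal homolog gene in the middle of `flankGeneCount` genes per side:
#' gene lengths uniform on 300-1500 bp, intergenic gaps on 20-200 bp,
#' alternating strand draws. Phage-annotated products (with matching
#' synthetic Pfam-style domain hits) are planted on both sides, one
#' side, or neither side according to the label, at
#' `phageKeywordRate` (at least one per designated side); afterwards
#' `annotationNoiseRate` independently flips each flank gene's product
#' between phage-annotated and neutral. The focal gene carries a custom
#' BstA-namespace domain hit.
#'
#' @param label one row of [surveyTruth()] (list or data.frame row with
#'   `homolog_id`, `true_category`, `true_confidence`, `plasmid`).
#' @param config a [surveyConfig()].
#' @param seed integer seed for this bundle.
#' @return A list with `features` (GRanges), `domtblout` (character
#'   lines), `fasta` ([Biostrings::DNAStringSet] contig), `metadata`
#'   (contig id/length, circular, plasmid, focal id) and `truth`.
#' @export
generateNeighborhoodBundle <- function(label, config, seed) {
  stopifnot(inherits(config, "surveyConfig"))
  label <- as.list(label)
  if (!label$true_category %in% c("prophage_associated", "prophage_independent"))
    stop("unknown true_category: ", label$true_category)
  if (label$true_category == "prophage_independent" &&
      label$true_confidence != "not_applicable")
    stop("independent labels must have confidence not_applicable")
  if (label$true_category == "prophage_associated" &&
      !label$true_confidence %in% c("high", "low"))
    stop("associated labels must have confidence high or low")
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  phageVocab <- readVocabulary("phage_products.txt")
  neutralVocab <- readVocabulary("neutral_products.txt")
  nSide <- config$flankGeneCount
  nGenes <- 2L * nSide + 1L
  lens <- round(stats::runif(nGenes, 300, 1500))
  gaps <- round(stats::runif(nGenes, 20, 200))  # gap before each gene
  starts <- cumsum(gaps + c(0, lens[-nGenes])) + 1L
  ends <- starts + lens - 1L
  contigLen <- ends[nGenes] + round(stats::runif(1, 20, 200))
  strands <- sample(c("+", "-"), nGenes, replace = TRUE)
  focalIdx <- nSide + 1L

  # designated phage sides per the label
  sides <- switch(label$true_confidence,
    high = c(TRUE, TRUE),
    low = if (stats::runif(1) < 0.5) c(TRUE, FALSE) else c(FALSE, TRUE),
    not_applicable = c(FALSE, FALSE))
  isPhage <- logical(nGenes)
  sideIdx <- list(seq_len(nSide), focalIdx + seq_len(nSide))
  for (sd in 1:2) {
    idx <- sideIdx[[sd]]
    if (sides[sd]) {
      draw <- stats::runif(length(idx)) < config$phageKeywordRate
      if (!any(draw)) draw[sample(length(idx), 1L)] <- TRUE
      isPhage[idx] <- draw
    } else if (config$backgroundKeywordRate > 0) {
      isPhage[idx] <- stats::runif(length(idx)) < config$backgroundKeywordRate
    }
  }
  # annotation noise: flip product class of flank genes
  if (config$annotationNoiseRate > 0) {
    flip <- stats::runif(nGenes) < config$annotationNoiseRate
    flip[focalIdx] <- FALSE
    isPhage <- xor(isPhage, flip)
  }

  pickRows <- function(vocab, k) vocab[sample(nrow(vocab), k, replace = TRUE), ]
  products <- character(nGenes); domains <- rep(NA_character_, nGenes)
  nP <- sum(isPhage)
  if (nP) {
    rows <- pickRows(phageVocab, nP)
    products[isPhage] <- rows$product; domains[isPhage] <- rows$domain
  }
  bg <- !isPhage; bg[focalIdx] <- FALSE
  if (any(bg)) {
    rows <- pickRows(neutralVocab, sum(bg))
    products[bg] <- rows$product; domains[bg] <- rows$domain
  }
  products[focalIdx] <- "BstA family phage-defense protein"
  domains[focalIdx] <- "BstA"

  hid <- label$homolog_id
  contig <- paste0("ctg_", hid)
  fids <- sprintf("%s_g%02d", hid, seq_len(nGenes))
  fids[focalIdx] <- hid
  features <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands,
    feature_id = fids, product = products)

  withDom <- which(!is.na(domains))
  bits <- pmax(15, stats::rnorm(length(withDom), mean = 60,
                                sd = config$domainScoreSd))
  orfLenAA <- pmax(50L, (ends[withDom] - starts[withDom] + 1L) %/% 3L - 10L)
  hits <- data.frame(
    orf_id = fids[withDom],
    domain_accession = ifelse(domains[withDom] == "BstA", "CUST001",
                              sprintf("PF%05d.1",
                                      1000L + match(domains[withDom],
                                                    sort(unique(domains[withDom]))))),
    domain_name = domains[withDom],
    bit_score = round(bits, 1),
    i_evalue = signif(10^(-bits / 3), 2),
    env_from = 5L,
    env_to = orfLenAA,
    description = "",
    stringsAsFactors = FALSE)

  contigSeq <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), contigLen, replace = TRUE), collapse = ""))
  names(contigSeq) <- contig

  list(features = features,
       domtblout = writeDomtblout(hits),
       fasta = contigSeq,
       metadata = list(contig_id = contig, contig_length = contigLen,
                       circular = FALSE, plasmid = isTRUE(label$plasmid),
                       focal_id = hid),
       truth = label)
}

#' Generate a full synthetic survey with ground truth
#'
#' Plants label proportions by largest-remainder apportionment (exact up
#' to integer rounding, independent of the seed) and generates one
#' neighborhood bundle per homolog, each from a sub-seed derived from the
#' configuration seed by counter so bundles are independently
#' reproducible.
#'
#' @param config a [surveyConfig()].
#' @return A list with `bundles` (list of
#'   [generateNeighborhoodBundle()] results, named by homolog) and
#'   `truth` (the [surveyTruth()] table).
#' @export
generateSurveyBundle <- function(config) {
  stopifnot(inherits(config, "surveyConfig"))
  truth <- surveyTruth(config)
  bundles <- lapply(seq_len(nrow(truth)), function(i) {
    generateNeighborhoodBundle(truth[i, ], config,
                               seed = deriveSeed(config$seed, i))
  })
  names(bundles) <- truth$homolog_id
  list(bundles = bundles, truth = truth)
}

#' Write a survey bundle to disk
#'
#' One sub-directory per homolog with `features.gff3`, `hits.domtblout`,
#' `contig.fasta` and `metadata.tsv`, plus a top-level `truth.tsv` —
#' standard formats consumed unchanged by [runSurvey()].
#'
#' @param survey result of [generateSurveyBundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSurveyBundle <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (hid in names(survey$bundles)) {
    b <- survey$bundles[[hid]]
    sub <- file.path(dir, hid)
    dir.create(sub, showWarnings = FALSE)
    exportGff3(b$features, file.path(sub, "features.gff3"))
    writeLines(b$domtblout, file.path(sub, "hits.domtblout"))
    writeFasta(b$fasta, file.path(sub, "contig.fasta"))
    md <- b$metadata
    utils::write.table(
      data.frame(contig_id = md$contig_id, contig_length = md$contig_length,
                 circular = md$circular, plasmid = md$plasmid,
                 focal_id = md$focal_id),
      file.path(sub, "metadata.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(survey$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# GFF3 writer with deterministic attribute layout (byte-stable output)
exportGff3 <- function(gr, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tbstaContext\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), GenomicRanges::end(gr),
                     as.character(GenomicRanges::strand(gr)),
                     gr$feature_id, gr$product))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survey bundle directory
#'
#' Counterpart of [writeSurveyBundle()]: loads every homolog
#' sub-directory back into the in-memory bundle structure.
#'
#' @param dir a directory written by [writeSurveyBundle()].
#' @return A list with `bundles` and `truth` (truth is `NULL` when no
#'   `truth.tsv` is present).
#' @export
readSurveyBundle <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (!length(subs)) stop("no homolog sub-directories found in ", dir)
  bundles <- lapply(subs, function(sub) {
    md <- utils::read.delim(file.path(sub, "metadata.tsv"))
    list(features = readGffFeatures(file.path(sub, "features.gff3")),
         domtblout = readLines(file.path(sub, "hits.domtblout")),
         fasta = readDnaFasta(file.path(sub, "contig.fasta")),
         metadata = as.list(md),
         truth = NULL)
  })
  names(bundles) <- basename(subs)
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath)) utils::read.delim(truthPath) else NULL
  list(bundles = bundles, truth = truth)
}
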