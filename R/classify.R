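#' Keyword test for phage-related gene annotations
#'
#' A product string is phage-annotated when any keyword occurs as a
#' case-insensitive substring — deliberately loose, so "Prophage
#' integrase" and "bacteriophage holin" match the keyword "phage". An
#' optional exclusion list vetoes pathological products (e.g.
#' "macrophage"); excluded substrings are masked out of the product
#' before the keywords are tested. The default exclusion list is empty.
#'
#' @param product character vector of annotation product strings.
#' @param keywords keywords to match (default `c("phage", "terminase")`).
#' @param exclude substrings removed from the product before matching.
#' @return A logical vector.
#' @export
#' @examples
#' isPhageAnnotation(c("terminase large subunit", "hypothetical protein"))
isPhageAnnotation <- function(product,
                              keywords = c("phage", "terminase"),
                              exclude = character(0)) {
  x <- tolower(as.character(product))
  for (ex in exclude)
    x <- gsub(tolower(ex), "", x, fixed = TRUE)
  hit <- rep(FALSE, length(x))
  for (kw in keywords)
    hit <- hit | grepl(tolower(kw), x, fixed = TRUE)
  hit
}

#' Classify a neighborhood as prophage-associated or -independent
#'
#' Applies the evidence rule to the left and right flanks of a
#' neighborhood: phage-annotated genes on both sides give a
#' high-confidence prophage association (guarding against a homolog
#' merely adjacent to an unrelated prophage region), on exactly one side
#' a low-confidence association, and on neither side the homolog is
#' called putatively prophage-independent. Evidence is either the
#' annotation-keyword rule ([isPhageAnnotation()], the default) or, in
#' `mode = "domain"`, membership of each gene's best domain hit in a
#' supplied phage-domain set (requires [annotateDomainHits()] first).
#'
#' @param nbhd a [GeneNeighborhood-class].
#' @param keywords,exclude passed to [isPhageAnnotation()] in keyword
#'   mode.
#' @param mode `"keyword"` (default) or `"domain"`.
#' @param phageDomains character vector of domain names and/or accessions
#'   counted as phage evidence in domain mode.
#' @return An [AssociationCall-class].
#' @export
classifyAssociation <- function(nbhd, keywords = c("phage", "terminase"),
                                exclude = character(0),
                                mode = c("keyword", "domain"),
                                phageDomains = character(0)) {
  stopifnot(is(nbhd, "GeneNeighborhood"))
  mode <- match.arg(mode)
  evidenceIds <- function(genes) {
    if (length(genes) == 0L) return(character(0))
    hit <- if (mode == "keyword") {
      isPhageAnnotation(genes$product, keywords, exclude)
    } else {
      if (is.null(genes$domain_name))
        stop("domain mode requires domain-annotated genes; ",
             "run annotateDomainHits() first")
      (!is.na(genes$domain_name) & genes$domain_name %in% phageDomains) |
        (!is.na(genes$domain_accession) &
           genes$domain_accession %in% phageDomains)
    }
    genes$feature_id[hit]
  }
  le <- evidenceIds(nbhd@leftGenes)
  re <- evidenceIds(nbhd@rightGenes)
  nl <- length(le) > 0L; nr <- length(re) > 0L
  new("AssociationCall",
      homologId = nbhd@homologId,
      category = if (nl || nr) "prophage_associated" else "prophage_independent",
      confidence = if (nl && nr) "high" else if (nl || nr) "low" else "not_applicable",
      plasmid = isTRUE(nbhd@plasmid),
      leftEvidence = le, rightEvidence = re)
}

#' Tally domains co-occurring with homologs of one category
#'
#' Counts best-hit domain names over the flank genes of all neighborhoods
#' whose association call matches `category` (the focal homolog's own hit
#' is excluded, as the focal gene belongs to neither flank). With
#' `unit = "per_neighborhood"` (default) a domain is counted at most once
#' per neighborhood; `"per_gene"` counts every gene carrying it. The
#' top-`n` list is ordered by count descending with alphabetical
#' tie-break.
#'
#' @param neighborhoods list of domain-annotated
#'   [GeneNeighborhood-class] objects.
#' @param calls list of matching [AssociationCall-class] objects (same
#'   order).
#' @param category `"prophage_associated"` or `"prophage_independent"`.
#' @param n length of the top list (default 10).
#' @param unit counting unit, see above.
#' @return A list with `category`, `counts` (named integer vector over
#'   all observed domains) and `top` (data.frame `rank`, `domain_name`,
#'   `count`).
#' @export
tallyCooccurringDomains <- function(neighborhoods, calls, category, n = 10,
                                    unit = c("per_neighborhood", "per_gene")) {
  unit <- match.arg(unit)
  if (!category %in% c("prophage_associated", "prophage_independent"))
    stop("unknown category: ", category)
  stopifnot(length(neighborhoods) == length(calls))
  cats <- vapply(calls, category2, character(1))
  sel <- which(cats == category)
  domains <- character(0)
  for (i in sel) {
    genes <- flankGenes(neighborhoods[[i]])
    if (is.null(genes$domain_name))
      stop("neighborhoods must be domain-annotated (annotateDomainHits)")
    d <- genes$domain_name[!is.na(genes$domain_name)]
    if (unit == "per_neighborhood") d <- unique(d)
    domains <- c(domains, d)
  }
  counts <- if (length(domains)) {
    tab <- table(domains)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  ord <- order(-counts, names(counts))
  top <- counts[ord][seq_len(min(n, length(counts)))]
  list(category = category,
       counts = counts,
       top = data.frame(rank = seq_along(top),
                        domain_name = names(top),
                        count = as.integer(top),
                        row.names = NULL))
}

# category() is also a generic slot accessor; internal helper for vapply
category2 <- function(x) x@category

#' Detect a putative prophage repressor gene 5' of the focal homolog
#'
#' BstA-family genes frequently sit immediately downstream of a prophage
#' repressor (the cI-bstA architecture). This reports the nearest gene 5'
#' of the focal gene — on the same strand by default, with an intergenic
#' gap of at most `maxGap` — whose product matches a repressor keyword or
#' whose best domain hit is in `repressorDomains`.
#'
#' @param nbhd a [GeneNeighborhood-class].
#' @param repressorKeywords case-insensitive substrings matched against
#'   products (default `"repressor"`).
#' @param repressorDomains domain names/accessions counted as repressor
#'   evidence (requires domain annotation when non-empty).
#' @param maxGap maximum intergenic gap in bp (default 1000).
#' @param sameStrand require the repressor on the focal strand (default
#'   `TRUE`).
#' @return A one-row data.frame (`feature_id`, `product`, `gap`,
#'   `matched_by`) or `NULL` when no candidate matches.
#' @export
detectRepressorAdjacency <- function(nbhd,
                                     repressorKeywords = "repressor",
                                     repressorDomains = character(0),
                                     maxGap = 1000, sameStrand = TRUE) {
  stopifnot(is(nbhd, "GeneNeighborhood"))
  focal <- nbhd@focal
  fStrand <- as.character(GenomicRanges::strand(focal))
  genes <- flankGenes(nbhd)
  if (length(genes) == 0L) return(NULL)
  if (fStrand == "-") {
    upstream <- GenomicRanges::start(genes) > GenomicRanges::end(focal)
    gap <- GenomicRanges::start(genes) - GenomicRanges::end(focal) - 1L
  } else {
    upstream <- GenomicRanges::end(genes) < GenomicRanges::start(focal)
    gap <- GenomicRanges::start(focal) - GenomicRanges::end(genes) - 1L
  }
  keep <- upstream & gap <= maxGap
  if (sameStrand)
    keep <- keep & as.character(GenomicRanges::strand(genes)) == fStrand
  if (!any(keep)) return(NULL)
  cand <- genes[keep]
  candGap <- gap[keep]
  ord <- order(candGap)
  cand <- cand[ord]; candGap <- candGap[ord]
  byKw <- isPhageAnnotation(cand$product, keywords = repressorKeywords)
  byDom <- if (length(repressorDomains) && !is.null(cand$domain_name)) {
    (!is.na(cand$domain_name) & cand$domain_name %in% repressorDomains) |
      (!is.na(cand$domain_accession) &
         cand$domain_accession %in% repressorDomains)
  } else rep(FALSE, length(cand))
  hit <- which(byKw | byDom)
  if (!length(hit)) return(NULL)
  k <- hit[1L]
  data.frame(feature_id = cand$feature_id[k],
             product = cand$product[k],
             gap = candGap[k],
             matched_by = if (byKw[k]) "keyword" else "domain",
             stringsAsFactors = FALSE)
}

#' Summarize a survey of association calls
#'
#' Aggregates per-homolog calls into counts and percentages of
#' prophage-associated vs putatively prophage-independent homologs, plus
#' the number of plasmid-encoded homologs. Percentages are stored exactly;
#' accessors report them rounded to the nearest integer.
#'
#' @param calls a non-empty list of [AssociationCall-class] objects.
#' @return A [SurveySummary-class].
#' @export
summarizeSurvey <- function(calls) {
  if (length(calls) == 0L) stop("cannot summarize an empty survey")
  cats <- vapply(calls, category2, character(1))
  nA <- sum(cats == "prophage_associated")
  nI <- sum(cats == "prophage_independent")
  nP <- sum(vapply(calls, function(x) isTRUE(x@plasmid), logical(1)))
  nT <- length(calls)
  new("SurveySummary",
      nTotal = as.integer(nT),
      nAssociated = as.integer(nA),
      nIndependent = as.integer(nI),
      nPlasmid = as.integer(nP),
      pctAssociated = 100 * nA / nT,
      pctIndependent = 100 * nI / nT)
}
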