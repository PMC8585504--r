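#' Run the full prophage-association survey
#'
#' End-to-end orchestration over a set of homolog bundles: per homolog,
#' extract the +/- `flank` neighborhood, reduce domain hits to the best
#' significant hit per ORF, classify prophage association, and test
#' repressor adjacency; then aggregate a [SurveySummary-class] and the
#' top-N co-occurring domain tallies for both categories. Homologs whose
#' extraction fails are reported and skipped with a warning.
#'
#' @param x a survey: the result of [generateSurveyBundle()], a bundle
#'   directory written by [writeSurveyBundle()], or a bare list of
#'   bundles (each with `features`, `domtblout`, `metadata`).
#' @param flank neighborhood half-width in bp (default 20000).
#' @param evalueThreshold i-E-value significance cutoff (default 1e-3).
#' @param keywords,exclude keyword rule, see [isPhageAnnotation()].
#' @param topN length of the co-occurrence top lists (default 10).
#' @param mode classifier evidence mode, `"keyword"` (default) or
#'   `"domain"`.
#' @param phageDomains phage-domain set for domain mode.
#' @param tallyUnit co-occurrence counting unit (see
#'   [tallyCooccurringDomains()]).
#' @param outDir if non-NULL, `survey.tsv` and `cooccurrence.tsv` are
#'   written there.
#' @return A list with `summary` ([SurveySummary-class]), `calls`
#'   (per-homolog data.frame), `cooccurrence` (long data.frame over both
#'   categories), `callObjects`, `neighborhoods` and `skipped`
#'   (character vector of failed homolog ids).
#' @export
runSurvey <- function(x, flank = 20000, evalueThreshold = 1e-3,
                      keywords = c("phage", "terminase"),
                      exclude = character(0), topN = 10,
                      mode = c("keyword", "domain"),
                      phageDomains = character(0),
                      tallyUnit = c("per_neighborhood", "per_gene"),
                      outDir = NULL) {
  mode <- match.arg(mode)
  tallyUnit <- match.arg(tallyUnit)
  bundles <- if (is.character(x) && length(x) == 1L) {
    readSurveyBundle(x)$bundles
  } else if (!is.null(x$bundles)) {
    x$bundles
  } else {
    x
  }
  if (!length(bundles)) stop("empty survey: no homolog bundles")
  nbhds <- list(); calls <- list(); rows <- list(); skipped <- character(0)
  for (hid in names(bundles)) {
    b <- bundles[[hid]]
    res <- tryCatch({
      md <- b$metadata
      nb <- extractNeighborhood(
        b$features, focalId = md$focal_id, flank = flank,
        contigLength = md$contig_length,
        circular = isTRUE(md$circular), plasmid = isTRUE(md$plasmid))
      best <- bestHitPerOrf(readDomtblout(b$domtblout), evalueThreshold)
      nb <- annotateDomainHits(nb, best)
      call <- classifyAssociation(nb, keywords = keywords, exclude = exclude,
                                  mode = mode, phageDomains = phageDomains)
      repr <- detectRepressorAdjacency(nb)
      list(nb = nb, call = call, repr = repr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("homolog ", hid, " skipped: ", conditionMessage(res),
              call. = FALSE)
      skipped <- c(skipped, hid)
      next
    }
    nbhds[[hid]] <- res$nb
    calls[[hid]] <- res$call
    rows[[hid]] <- data.frame(
      homolog_id = homologId(res$call),
      category = category(res$call),
      confidence = confidence(res$call),
      plasmid = isPlasmid(res$call),
      n_left_evidence = length(evidence(res$call, "left")),
      n_right_evidence = length(evidence(res$call, "right")),
      repressor_adjacent = !is.null(res$repr),
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) stop("empty survey result: all homologs failed")
  callTable <- do.call(rbind, rows)
  rownames(callTable) <- NULL
  summary <- summarizeSurvey(calls)
  cooc <- do.call(rbind, lapply(
    c("prophage_associated", "prophage_independent"), function(cat) {
      t <- tallyCooccurringDomains(nbhds, calls, cat, n = topN,
                                   unit = tallyUnit)
      if (nrow(t$top) == 0L) return(NULL)
      cbind(category = cat, t$top)
    }))
  if (is.null(cooc))
    cooc <- data.frame(category = character(0), rank = integer(0),
                       domain_name = character(0), count = integer(0))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(callTable, file.path(outDir, "survey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cooc, file.path(outDir, "cooccurrence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = summary, calls = callTable, cooccurrence = cooc,
       callObjects = calls, neighborhoods = nbhds, skipped = skipped)
}

#' Analyse self-immunity elements from FASTA
#'
#' Per element: start-codon partition, terminal direct repeat, and ORF
#' scan. Elements that cannot be partitioned (no ATG) are reported in
#' `failures` and the run continues.
#'
#' @param x path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param kMin minimum repeat length (default 6).
#' @param margin terminal margin in bp (default 10).
#' @param minCodons minimum ORF length for the ORF scan (default 3).
#' @param outDir if non-NULL, `aba_report.tsv` and `aba_diagrams.txt`
#'   are written there.
#' @return A list with `report` (one row per element: length, upstream,
#'   coding, terminal repeat motif and positions, ORF count), `elements`,
#'   `diagrams` and `failures`.
#' @export
runAbaReport <- function(x, kMin = 6L, margin = 10L, minCodons = 3L,
                         outDir = NULL) {
  seqs <- if (is.character(x)) readDnaFasta(x) else x
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("element_", seq_along(seqs))
  rows <- list(); elements <- list(); diagrams <- character(0)
  failures <- character(0)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    el <- tryCatch(partitionElement(s, id = id), error = function(e) e)
    if (inherits(el, "error")) {
      warning("element ", id, ": ", conditionMessage(el), call. = FALSE)
      failures <- c(failures, id)
      next
    }
    term <- findTerminalRepeat(s, kMin = kMin, margin = margin)
    orfs <- scanOrfs(s, minCodons = minCodons, allowRunoff = TRUE)
    rows[[id]] <- data.frame(
      element = id,
      length = length(s),
      upstream = upstreamLength(el),
      coding = codingLength(el),
      terminal_repeat = if (is.null(term)) NA_character_ else term$motif,
      repeat_positions = if (is.null(term)) NA_character_ else
        paste(term$occurrences[[1L]], collapse = ","),
      n_orfs = nrow(orfs),
      stringsAsFactors = FALSE)
    elements[[id]] <- el
    diagrams <- c(diagrams, abaDiagram(el, kMin = kMin, margin = margin), "")
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element = character(0), length = integer(0),
               upstream = integer(0), coding = integer(0),
               terminal_repeat = character(0), repeat_positions = character(0),
               n_orfs = integer(0))
  rownames(report) <- NULL
  if (length(seqs) == 0L) warning("empty FASTA: nothing to report")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(outDir, "aba_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(diagrams, file.path(outDir, "aba_diagrams.txt"))
  }
  list(report = report, elements = elements, diagrams = diagrams,
       failures = failures)
}

#' Pairwise identity of protein homologs
#'
#' Needle-convention percent identities, either of every sequence
#' against one reference (the typical homolog-vs-reference panel) or
#' all-vs-all.
#'
#' @param x path to a protein FASTA or an [Biostrings::AAStringSet] with
#'   unique names.
#' @param reference identifier of the reference sequence, or `NULL` for
#'   all-vs-all.
#' @param ... passed to [needleAlign()] (matrix, gap penalties).
#' @param outDir if non-NULL, `identity.tsv` is written there.
#' @return A data.frame with columns `id_a`, `id_b`,
#'   `percent_identity`, `alignment_length`, `score`.
#' @export
runIdentity <- function(x, reference = NULL, ..., outDir = NULL) {
  seqs <- if (is.character(x) && length(x) == 1L) readProteinFasta(x) else x
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in input")
  if (length(seqs) < 2L) stop("need at least two sequences")
  pairs <- if (is.null(reference)) {
    utils::combn(names(seqs), 2L, simplify = FALSE)
  } else {
    if (!reference %in% names(seqs))
      stop("reference '", reference, "' not found")
    lapply(setdiff(names(seqs), reference), function(id) c(id, reference))
  }
  rows <- lapply(pairs, function(p) {
    aln <- needleAlign(as.character(seqs[[p[1L]]]),
                       as.character(seqs[[p[2L]]]),
                       idA = p[1L], idB = p[2L], ...)
    data.frame(id_a = p[1L], id_b = p[2L],
               percent_identity = percentIdentity(aln),
               alignment_length = nchar(alignedSeqs(aln)[[1L]]),
               score = alignmentScore(aln),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outDir, "identity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
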