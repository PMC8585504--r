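#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses the `--domtblout` dialect written by hmmscan/hmmsearch:
#' `#`-prefixed comment lines, 22 whitespace-delimited fixed leading
#' fields, then a free-text target description. Field naming is mapped so
#' that `orf_id` is always the protein and `domain_*` the profile model:
#' in `hmmscan` output the model is the target and the protein the query
#' (the default here); in `hmmsearch` output the roles are reversed.
#'
#' @param x path to a domtblout file, or a character vector of its lines.
#' @param program `"hmmscan"` (default) or `"hmmsearch"`; controls the
#'   target/query role mapping.
#' @return A data.frame of domain hits with columns `orf_id`,
#'   `domain_accession`, `domain_name`, `bit_score` (per-domain bits),
#'   `i_evalue` (independent E-value), `env_from`, `env_to`,
#'   `description`.
#' @export
readDomtblout <- function(x, program = c("hmmscan", "hmmsearch")) {
  program <- match.arg(program)
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n"))
  lineNo <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines)) {
    return(data.frame(orf_id = character(0), domain_accession = character(0),
                      domain_name = character(0), bit_score = numeric(0),
                      i_evalue = numeric(0), env_from = integer(0),
                      env_to = integer(0), description = character(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 22L)
  if (length(bad))
    stop("domtblout line ", lineNo[bad[1L]], ": expected at least 22 fields, got ",
         length(fields[[bad[1L]]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  desc <- vapply(fields, function(f)
    if (length(f) > 22L) paste(f[23:length(f)], collapse = " ") else "",
    character(1))
  if (program == "hmmscan") {
    domName <- get(1L); domAcc <- get(2L); orf <- get(4L)
  } else {
    orf <- get(1L); domName <- get(4L); domAcc <- get(5L)
  }
  out <- data.frame(
    orf_id = orf,
    domain_accession = domAcc,
    domain_name = domName,
    bit_score = as.numeric(get(14L)),
    i_evalue = as.numeric(get(13L)),
    env_from = as.integer(get(20L)),
    env_to = as.integer(get(21L)),
    description = desc,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$bit_score) || anyNA(out$i_evalue))
    stop("domtblout: non-numeric score/E-value field")
  if (any(out$env_from > out$env_to))
    stop("domtblout: env_from > env_to")
  out
}

#' Write domain hits as HMMER3 domtblout text
#'
#' Emits a minimal but format-faithful hmmscan-dialect domtblout (comment
#' header, 22 fixed fields, description last) so that synthetic surveys
#' round-trip through the same reader used for real HMMER output.
#'
#' @param hits a data.frame as returned by [readDomtblout()].
#' @param path optional output file.
#' @return The text lines (invisibly when written to `path`).
#' @export
writeDomtblout <- function(hits, path = NULL) {
  hdr <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  rows <- character(0)
  if (nrow(hits)) {
    tlen <- hits$env_to - hits$env_from + 1L
    rows <- sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
      hits$domain_name, hits$domain_accession, tlen,
      hits$orf_id, "-", tlen + 20L,
      hits$i_evalue, hits$bit_score, 0.1, 1L, 1L,
      hits$i_evalue, hits$i_evalue, hits$bit_score, 0.1,
      1L, tlen, hits$env_from, hits$env_to, hits$env_from, hits$env_to,
      0.95,
      ifelse(nzchar(hits$description), hits$description, "-"))
  }
  out <- c(hdr, rows, "#")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Reduce domain hits to the best significant hit per ORF
#'
#' Discards hits with independent E-value above `evalueThreshold`, then
#' keeps, per ORF, the hit with the highest per-domain bit score; ties are
#' broken by lower i-E-value, then lexicographically by domain accession.
#' ORFs with no surviving hit are absent from the result.
#'
#' @param hits a data.frame of domain hits (see [readDomtblout()]).
#' @param evalueThreshold significance cutoff on the independent E-value
#'   (default `1e-3`).
#' @param rankBy `"bit_score"` (default) or `"evalue"` — whether "highest
#'   scoring" ranks by bits or by smallest i-E-value.
#' @return A data.frame with one row per ORF, row names = `orf_id`.
#' @export
bestHitPerOrf <- function(hits, evalueThreshold = 1e-3,
                          rankBy = c("bit_score", "evalue")) {
  rankBy <- match.arg(rankBy)
  stopifnot(evalueThreshold > 0)
  empty <- hits[0, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[hits$i_evalue <= evalueThreshold, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  primary <- if (rankBy == "bit_score") -hits$bit_score else hits$i_evalue
  ord <- order(hits$orf_id, primary, hits$i_evalue, hits$domain_accession)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$orf_id), , drop = FALSE]
  rownames(out) <- out$orf_id
  out
}

#' Attach best domain hits to neighborhood genes
#'
#' Joins a per-ORF best-hit table onto the flank and focal genes of a
#' [GeneNeighborhood-class] by `feature_id`, adding `domain_name` and
#' `domain_accession` metadata columns (`NA` where an ORF has no
#' significant hit). Required for the domain-evidence classifier mode and
#' for domain co-occurrence tallies.
#'
#' @param nbhd a `GeneNeighborhood`.
#' @param bestHits a data.frame from [bestHitPerOrf()].
#' @return The neighborhood with annotated gene tables.
#' @export
annotateDomainHits <- function(nbhd, bestHits) {
  stopifnot(is(nbhd, "GeneNeighborhood"))
  addCols <- function(gr) {
    idx <- match(gr$feature_id, bestHits$orf_id)
    gr$domain_name <- ifelse(is.na(idx), NA_character_,
                             bestHits$domain_name[idx])
    gr$domain_accession <- ifelse(is.na(idx), NA_character_,
                                  bestHits$domain_accession[idx])
    gr
  }
  nbhd@leftGenes <- addCols(nbhd@leftGenes)
  nbhd@rightGenes <- addCols(nbhd@rightGenes)
  nbhd@focal <- addCols(nbhd@focal)
  validObject(nbhd)
  nbhd
}
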