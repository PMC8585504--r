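#' Read gene features from GFF3
#'
#' Imports a GFF3 annotation via [rtracklayer::import()] and reduces it to
#' the gene-feature table used by the neighborhood extractor: one row per
#' CDS (or gene, when no CDS records are present) with a stable
#' `feature_id` and the free-text `product`.
#'
#' @param path path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id`
#'   and `product`.
#' @export
readGffFeatures <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr))) {
    types <- as.character(gr$type)
    keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
    gr <- gr[keep]
  }
  mc <- S4Vectors::mcols(gr)
  fid <- if ("locus_tag" %in% colnames(mc) && !all(is.na(mc$locus_tag))) {
    as.character(mc$locus_tag)
  } else if ("ID" %in% colnames(mc)) {
    as.character(mc$ID)
  } else {
    paste0("feature_", seq_along(gr))
  }
  prod <- if ("product" %in% colnames(mc)) as.character(mc$product) else
    rep(NA_character_, length(gr))
  prod[is.na(prod)] <- ""
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(feature_id = fid, product = prod)
  gr
}

#' Read gene features from a TSV feature table
#'
#' Fallback tabular input with columns `feature_id`, `contig`, `start`,
#' `end`, `strand`, `product` (1-based inclusive coordinates).
#'
#' @param path path to a tab-separated table with a header row.
#' @return A `GRanges` as from [readGffFeatures()].
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("feature_id", "contig", "start", "end", "strand", "product")
  if (!all(need %in% names(df)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  featuresAsGRanges(df)
}

# build the internal GRanges representation from a plain data.frame
featuresAsGRanges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    feature_id = as.character(df$feature_id),
    product = ifelse(is.na(df$product), "", as.character(df$product))
  )
}

#' Extract the gene neighborhood around a focal homolog
#'
#' Builds the window `[start(focal) - flank, end(focal) + flank]` anchored
#' to the focal gene's outer coordinates, clips it to the contig on linear
#' contigs (recording truncation) or wraps it modulo the contig length on
#' circular ones, and collects every gene overlapping the window by at
#' least 1 bp. Flanking genes are assigned to the left or right side by
#' midpoint relative to the focal gene's midpoint. Neighborhoods never
#' cross contig boundaries: only features on the focal gene's contig are
#' considered.
#'
#' @param features a `GRanges` with `feature_id` and `product` metadata
#'   columns (see [readGffFeatures()]), or a data.frame with columns
#'   `feature_id`, `contig`, `start`, `end`, `strand`, `product`.
#' @param focalId `feature_id` of the focal homolog; must occur exactly
#'   once.
#' @param flank window half-width in bp (default 20000, i.e. a 40-kb
#'   total neighborhood).
#' @param contigLength contig length in bp; required for circular contigs,
#'   optional (enables right-truncation bookkeeping) for linear ones.
#' @param circular whether the contig is circular.
#' @param plasmid plasmid status of the sequence record, carried through
#'   to classification.
#' @param orientByStrand if `TRUE`, the left/right flank lists are swapped
#'   for focal genes on the minus strand, so "left" means 5' of the gene;
#'   default `FALSE` (genome-coordinate sides).
#' @return A [GeneNeighborhood-class].
#' @export
extractNeighborhood <- function(features, focalId, flank = 20000,
                                contigLength = NULL, circular = FALSE,
                                plasmid = FALSE, orientByStrand = FALSE) {
  if (is.data.frame(features)) features <- featuresAsGRanges(features)
  stopifnot(is(features, "GRanges"), flank > 0)
  hit <- which(features$feature_id == focalId)
  if (length(hit) == 0L) stop("focal feature '", focalId, "' not found")
  if (length(hit) > 1L) stop("focal feature '", focalId, "' is duplicated")
  focal <- features[hit]
  contig <- as.character(GenomicRanges::seqnames(focal))
  others <- features[-hit]
  others <- others[as.character(GenomicRanges::seqnames(others)) == contig]

  fs <- GenomicRanges::start(focal); fe <- GenomicRanges::end(focal)
  ws <- fs - flank; we <- fe + flank
  leftTrunc <- FALSE; rightTrunc <- FALSE; wrapped <- FALSE
  L <- if (is.null(contigLength)) NA_real_ else as.numeric(contigLength)

  if (circular) {
    if (is.na(L)) stop("contigLength is required for circular contigs")
    if (we - ws + 1 >= L)
      stop("window (", we - ws + 1, " bp) spans the whole circular contig (",
           L, " bp)")
    wrapped <- ws < 1 || we > L
  } else {
    if (ws < 1) { ws <- 1; leftTrunc <- TRUE }
    if (!is.na(L) && we > L) { we <- L; rightTrunc <- TRUE }
  }

  os <- GenomicRanges::start(others); oe <- GenomicRanges::end(others)
  if (!circular) {
    keep <- oe >= ws & os <= we
    shift <- rep(0, length(others))
  } else {
    # a gene overlaps the wrapped window iff one of its ±L shifted copies
    # overlaps the raw [ws, we] interval on the unrolled axis
    shift <- rep(NA_real_, length(others))
    for (d in c(0, -L, L)) {
      ok <- is.na(shift) & (oe + d) >= ws & (os + d) <= we
      shift[ok] <- d
    }
    keep <- !is.na(shift)
    shift[is.na(shift)] <- 0
  }
  sel <- others[keep]
  selShift <- shift[keep]
  mid <- (os[keep] + oe[keep]) / 2 + selShift
  focalMid <- (fs + fe) / 2
  isLeft <- mid < focalMid
  ord <- order(os[keep] + selShift)
  sel <- sel[ord]; isLeft <- isLeft[ord]
  left <- sel[isLeft]; right <- sel[!isLeft]
  if (orientByStrand && as.character(GenomicRanges::strand(focal)) == "-") {
    tmp <- left
    left <- right
    right <- tmp
  }
  new("GeneNeighborhood",
      homologId = focalId,
      focal = focal,
      leftGenes = left,
      rightGenes = right,
      windowStart = ws, windowEnd = we,
      leftTruncated = leftTrunc, rightTruncated = rightTrunc,
      wrapped = wrapped, circular = circular,
      contigLength = L, plasmid = plasmid)
}
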