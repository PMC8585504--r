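#' Accessors for bstaContext S4 classes
#'
#' Small accessor generics so that user code never touches slots directly.
#' `homologId()`, `category()`, `confidence()`, `isPlasmid()` apply to
#' [AssociationCall-class] and [GeneNeighborhood-class]; `leftGenes()`,
#' `rightGenes()`, `focalGene()`, `flankGenes()` to neighborhoods;
#' `alignedSeqs()` and `alignmentScore()` to [NeedleAlignment-class];
#' `upstreamLength()`, `codingLength()`, `startCodonOffset()` to
#' [AbaElement-class]; `pctAssociated()`/`pctIndependent()` to
#' [SurveySummary-class] (rounded to the nearest integer percent by
#' default, `rounded = FALSE` for the exact value).
#'
#' @param x an object of the respective class.
#' @param ... for the percentage accessors, `rounded` (default `TRUE`);
#'   for `evidence()`, `side` (`"left"`, `"right"` or `"both"`).
#' @return The respective slot value or derived quantity.
#' @name accessors
#' @aliases homologId category confidence isPlasmid leftGenes rightGenes
#'   focalGene flankGenes evidence alignedSeqs alignmentScore
#'   upstreamLength codingLength startCodonOffset pctAssociated
#'   pctIndependent
NULL

#' @rdname accessors
setMethod("homologId", "GeneNeighborhood", function(x) x@homologId)
#' @rdname accessors
setMethod("homologId", "AssociationCall", function(x) x@homologId)
#' @rdname accessors
setMethod("category", "AssociationCall", function(x) x@category)
#' @rdname accessors
setMethod("confidence", "AssociationCall", function(x) x@confidence)
#' @rdname accessors
setMethod("isPlasmid", "AssociationCall", function(x) x@plasmid)
#' @rdname accessors
setMethod("isPlasmid", "GeneNeighborhood", function(x) x@plasmid)
#' @rdname accessors
setMethod("leftGenes", "GeneNeighborhood", function(x) x@leftGenes)
#' @rdname accessors
setMethod("rightGenes", "GeneNeighborhood", function(x) x@rightGenes)
#' @rdname accessors
setMethod("focalGene", "GeneNeighborhood", function(x) x@focal)

#' @rdname accessors
setMethod("flankGenes", "GeneNeighborhood", function(x) {
  suppressWarnings(c(x@leftGenes, x@rightGenes))
})

#' @rdname accessors
setMethod("evidence", "AssociationCall", function(x, side = c("both", "left", "right")) {
  side <- match.arg(side)
  switch(side,
    left = x@leftEvidence,
    right = x@rightEvidence,
    both = list(left = x@leftEvidence, right = x@rightEvidence)
  )
})

#' @rdname accessors
setMethod("alignedSeqs", "NeedleAlignment", function(x) {
  stats::setNames(c(x@alignedA, x@alignedB), c(x@idA, x@idB))
})
#' @rdname accessors
setMethod("alignmentScore", "NeedleAlignment", function(x) x@score)

#' @rdname accessors
setMethod("upstreamLength", "AbaElement", function(x) x@upstreamLength)
#' @rdname accessors
setMethod("codingLength", "AbaElement", function(x) x@codingLength)
#' @rdname accessors
setMethod("startCodonOffset", "AbaElement", function(x) x@startCodonOffset)

#' @rdname accessors
setMethod("pctAssociated", "SurveySummary", function(x, rounded = TRUE) {
  if (rounded) roundHalfUp(x@pctAssociated) else x@pctAssociated
})
#' @rdname accessors
setMethod("pctIndependent", "SurveySummary", function(x, rounded = TRUE) {
  if (rounded) roundHalfUp(x@pctIndependent) else x@pctIndependent
})

setMethod("show", "NeedleAlignment", function(object) {
  cat("NeedleAlignment:", object@idA, "vs", object@idB, "\n")
  cat("  columns:", nchar(object@alignedA),
      " score:", format(object@score), "\n")
  cat("  identity:", format(percentIdentity(object), nsmall = 1), "%\n")
})

setMethod("show", "GeneNeighborhood", function(object) {
  cat("GeneNeighborhood for", object@homologId, "\n")
  cat("  window: [", object@windowStart, ",", object@windowEnd, "]",
      if (object@wrapped) "(wrapped)" else "", "\n")
  cat("  flank genes: ", length(object@leftGenes), " left / ",
      length(object@rightGenes), " right", sep = "")
  if (object@leftTruncated || object@rightTruncated) {
    cat("  [truncated:",
        paste(c("left", "right")[c(object@leftTruncated, object@rightTruncated)],
              collapse = ","), "]")
  }
  cat("\n")
})

setMethod("show", "AssociationCall", function(object) {
  cat("AssociationCall:", object@homologId, "->", object@category,
      paste0("(", object@confidence, ")"),
      if (object@plasmid) "[plasmid]" else "", "\n")
  cat("  evidence genes:", length(object@leftEvidence), "left /",
      length(object@rightEvidence), "right\n")
})

setMethod("show", "SurveySummary", function(object) {
  cat("SurveySummary of", object@nTotal, "homologs\n")
  cat("  prophage-associated:  ", object@nAssociated,
      " (", pctAssociated(object), "%)\n", sep = "")
  cat("  prophage-independent: ", object@nIndependent,
      " (", pctIndependent(object), "%)\n", sep = "")
  cat("  plasmid-encoded:      ", object@nPlasmid, "\n", sep = "")
})

setMethod("show", "AbaElement", function(object) {
  cat("AbaElement", object@identifier, ":", length(object@sequence), "bp\n")
  cat("  upstream:", object@upstreamLength, "bp | coding:",
      object@codingLength, "bp (ATG at offset",
      object@startCodonOffset, ")\n")
})
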