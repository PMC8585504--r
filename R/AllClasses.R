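#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
NULL

#' Pairwise global alignment in Needle conventions
#'
#' Holds one affine-gap global alignment of two protein (or nucleotide)
#' sequences, full-length: terminal gaps are kept in the gapped strings so
#' that percent identity can be computed over the complete alignment length,
#' as the EMBOSS Needle "Identity" line does.
#'
#' @slot idA,idB identifiers of the two sequences.
#' @slot alignedA,alignedB gapped sequence strings of equal length.
#' @slot score alignment score in substitution-matrix units.
#'
#' @seealso [needleAlign()], [percentIdentity()]
#' @exportClass NeedleAlignment
setClass("NeedleAlignment",
  representation(
    idA = "character", idB = "character",
    alignedA = "character", alignedB = "character",
    score = "numeric"
  )
)

setValidity("NeedleAlignment", function(object) {
  msg <- NULL
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned strings must have equal length")
  a <- strsplit(object@alignedA, "")[[1]]
  b <- strsplit(object@alignedB, "")[[1]]
  if (any(a == "-" & b == "-"))
    msg <- c(msg, "alignment contains a gap-vs-gap column")
  if (is.null(msg)) TRUE else msg
})

#' Gene neighborhood around a focal homolog
#'
#' The region `flank` bp either side of a focal gene, with every annotated
#' gene overlapping that window by at least 1 bp assigned to the left or
#' right flank by midpoint. Truncation at contig edges and wrapping on
#' circular contigs are recorded rather than silently discarded.
#'
#' @slot homologId identifier of the focal homolog.
#' @slot focal a length-1 [GenomicRanges::GRanges] for the focal gene.
#' @slot leftGenes,rightGenes `GRanges` of flanking genes, ordered by
#'   position; the focal gene is in neither.
#' @slot windowStart,windowEnd the (clipped) window coordinates.
#' @slot leftTruncated,rightTruncated whether the window was clipped at a
#'   contig edge.
#' @slot wrapped whether the window wraps the origin of a circular contig.
#' @slot circular whether the contig is circular.
#' @slot contigLength contig length in bp (`NA` if unknown).
#' @slot plasmid plasmid status from the sequence-record metadata.
#'
#' @seealso [extractNeighborhood()]
#' @exportClass GeneNeighborhood
setClass("GeneNeighborhood",
  representation(
    homologId = "character",
    focal = "GRanges",
    leftGenes = "GRanges",
    rightGenes = "GRanges",
    windowStart = "numeric",
    windowEnd = "numeric",
    leftTruncated = "logical",
    rightTruncated = "logical",
    wrapped = "logical",
    circular = "logical",
    contigLength = "numeric",
    plasmid = "logical"
  )
)

setValidity("GeneNeighborhood", function(object) {
  msg <- NULL
  if (length(object@focal) != 1L)
    msg <- c(msg, "focal must contain exactly one gene")
  fid <- object@focal$feature_id
  if (fid %in% c(object@leftGenes$feature_id, object@rightGenes$feature_id))
    msg <- c(msg, "focal gene must not appear in a flank list")
  if (is.null(msg)) TRUE else msg
})

#' Prophage-association call for one homolog
#'
#' Classification of a [GeneNeighborhood-class] as prophage-associated or
#' putatively prophage-independent, with a confidence grade: `high` when
#' phage-annotated genes occur on both sides of the focal gene, `low` when
#' on exactly one side, and `not_applicable` when on neither (the
#' independent category).
#'
#' @slot homologId focal homolog identifier.
#' @slot category `"prophage_associated"` or `"prophage_independent"`.
#' @slot confidence `"high"`, `"low"` or `"not_applicable"`.
#' @slot plasmid plasmid status copied from the neighborhood.
#' @slot leftEvidence,rightEvidence feature ids of the matching genes.
#'
#' @seealso [classifyAssociation()]
#' @exportClass AssociationCall
setClass("AssociationCall",
  representation(
    homologId = "character",
    category = "character",
    confidence = "character",
    plasmid = "logical",
    leftEvidence = "character",
    rightEvidence = "character"
  )
)

setValidity("AssociationCall", function(object) {
  msg <- NULL
  nl <- length(object@leftEvidence) > 0L
  nr <- length(object@rightEvidence) > 0L
  if (!object@category %in% c("prophage_associated", "prophage_independent"))
    msg <- c(msg, "unknown category")
  if (!object@confidence %in% c("high", "low", "not_applicable"))
    msg <- c(msg, "unknown confidence")
  want <- if (!nl && !nr) "not_applicable" else if (nl && nr) "high" else "low"
  if (object@confidence != want)
    msg <- c(msg, "confidence inconsistent with evidence lists")
  wantCat <- if (!nl && !nr) "prophage_independent" else "prophage_associated"
  if (object@category != wantCat)
    msg <- c(msg, "category inconsistent with evidence lists")
  if (is.null(msg)) TRUE else msg
})

#' Survey-level association summary
#'
#' Counts and percentages of prophage-associated vs putatively
#' prophage-independent homologs across a survey. Percentages are stored
#' exactly and rounded to the nearest integer for reporting.
#'
#' @slot nTotal,nAssociated,nIndependent,nPlasmid counts.
#' @slot pctAssociated,pctIndependent exact percentages.
#'
#' @seealso [summarizeSurvey()]
#' @exportClass SurveySummary
setClass("SurveySummary",
  representation(
    nTotal = "integer",
    nAssociated = "integer",
    nIndependent = "integer",
    nPlasmid = "integer",
    pctAssociated = "numeric",
    pctIndependent = "numeric"
  )
)

setValidity("SurveySummary", function(object) {
  msg <- NULL
  if (object@nAssociated + object@nIndependent != object@nTotal)
    msg <- c(msg, "category counts must sum to nTotal")
  if (is.null(msg)) TRUE else msg
})

#' An anti-BstA (aba) self-immunity element
#'
#' A short DNA locus partitioned at a start codon into an upstream
#' (pre-ATG) portion and a coding portion running from the A of the ATG to
#' the 3' end. The 63-bp aba element of prophage BTP1 partitions into 29 bp
#' upstream and 34 bp coding.
#'
#' @slot identifier element name.
#' @slot sequence a [Biostrings::DNAString] of the element.
#' @slot startCodonOffset 0-based offset of the A of the ATG.
#' @slot upstreamLength,codingLength partition lengths in bp.
#'
#' @seealso [partitionElement()], [abaBTP1()]
#' @exportClass AbaElement
setClass("AbaElement",
  representation(
    identifier = "character",
    sequence = "DNAString",
    startCodonOffset = "integer",
    upstreamLength = "integer",
    codingLength = "integer"
  )
)

setValidity("AbaElement", function(object) {
  msg <- NULL
  n <- length(object@sequence)
  off <- object@startCodonOffset
  if (object@upstreamLength != off)
    msg <- c(msg, "upstreamLength must equal startCodonOffset")
  if (object@upstreamLength + object@codingLength != n)
    msg <- c(msg, "partition lengths must sum to sequence length")
  if (off + 3L > n ||
      as.character(Biostrings::subseq(object@sequence, off + 1L, off + 3L)) != "ATG")
    msg <- c(msg, "sequence at startCodonOffset must read ATG")
  if (is.null(msg)) TRUE else msg
})
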