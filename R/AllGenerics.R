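#' @rdname percentIdentity
#' @export
setGeneric("percentIdentity", function(x, ...) standardGeneric("percentIdentity"))

#' @rdname accessors
#' @export
setGeneric("homologId", function(x) standardGeneric("homologId"))

#' @rdname accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname accessors
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))

#' @rdname accessors
#' @export
setGeneric("isPlasmid", function(x) standardGeneric("isPlasmid"))

#' @rdname accessors
#' @export
setGeneric("leftGenes", function(x) standardGeneric("leftGenes"))

#' @rdname accessors
#' @export
setGeneric("rightGenes", function(x) standardGeneric("rightGenes"))

#' @rdname accessors
#' @export
setGeneric("focalGene", function(x) standardGeneric("focalGene"))

#' @rdname accessors
#' @export
setGeneric("flankGenes", function(x) standardGeneric("flankGenes"))

#' @rdname accessors
#' @export
setGeneric("evidence", function(x, ...) standardGeneric("evidence"))

#' @rdname accessors
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname accessors
#' @export
setGeneric("upstreamLength", function(x) standardGeneric("upstreamLength"))

#' @rdname accessors
#' @export
setGeneric("codingLength", function(x) standardGeneric("codingLength"))

#' @rdname accessors
#' @export
setGeneric("startCodonOffset", function(x) standardGeneric("startCodonOffset"))

#' @rdname accessors
#' @export
setGeneric("pctAssociated", function(x, ...) standardGeneric("pctAssociated"))

#' @rdname accessors
#' @export
setGeneric("pctIndependent", function(x, ...) standardGeneric("pctIndependent"))
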