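#' @rdname PeptideChain-accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("chainSeq", function(x) standardGeneric("chainSeq"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("sgCoords", function(x) standardGeneric("sgCoords"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("disulfides", function(x) standardGeneric("disulfides"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("nBondsAny", function(x) standardGeneric("nBondsAny"))
#' @rdname PeptideChain-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname DRPPartition-accessors
#' @export
setGeneric("clusterMembers", function(x, ...) standardGeneric("clusterMembers"))
#' @rdname DRPPartition-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname DRPPartition-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname PairMatrix-accessors
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))
#' @rdname PairMatrix-accessors
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))
#' @rdname PairMatrix-accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname ChainAlignment-accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @rdname ChainAlignment-accessors
#' @export
setGeneric("pairDistances", function(x) standardGeneric("pairDistances"))
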