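#' Accessors for PeptideChain objects
#'
#' @param x a \linkS4class{PeptideChain}.
#' @return \code{chainId}, \code{chainSeq}: character scalars.
#'   \code{caCoords}, \code{sgCoords}: n x 3 numeric matrices.
#'   \code{disulfides}: data.frame of intra-chain bonds (columns \code{i},
#'   \code{j}, \code{provenance}). \code{nBondsAny}: integer count of bonds
#'   involving the chain, inter-chain included. \code{nResidues}: integer.
#' @name PeptideChain-accessors
#' @aliases chainId chainSeq caCoords sgCoords disulfides nBondsAny nResidues
NULL

#' @rdname PeptideChain-accessors
#' @export
setMethod("chainId", "PeptideChain", function(x) x@chainId)
#' @rdname PeptideChain-accessors
#' @export
setMethod("chainSeq", "PeptideChain", function(x) x@sequence)
#' @rdname PeptideChain-accessors
#' @export
setMethod("caCoords", "PeptideChain", function(x) x@ca)
#' @rdname PeptideChain-accessors
#' @export
setMethod("sgCoords", "PeptideChain", function(x) x@sg)
#' @rdname PeptideChain-accessors
#' @export
setMethod("disulfides", "PeptideChain", function(x) x@bonds)
#' @rdname PeptideChain-accessors
#' @export
setMethod("nBondsAny", "PeptideChain", function(x) x@nBondsAny)
#' @rdname PeptideChain-accessors
#' @export
setMethod("nResidues", "PeptideChain", function(x) nrow(x@ca))

setMethod("show", "PeptideChain", function(object) {
  cat(sprintf("PeptideChain %s: %d residues, %d intra-chain disulfide bond(s), %d involving the chain (model %d)\n",
              object@chainId, nrow(object@ca), nrow(object@bonds),
              object@nBondsAny, object@modelUsed))
  cat(" sequence:", object@sequence, "\n")
})

#' Accessors for DRPPartition objects
#'
#' @param x a \linkS4class{DRPPartition}.
#' @param rank optional integer; restrict to the cluster of that rank.
#' @param ... unused.
#' @return \code{clusterMembers}: list of character vectors (or one vector if
#'   \code{rank} is given); \code{clusterSizes}: integer vector;
#'   \code{representatives}: character vector (NA where unselected).
#' @name DRPPartition-accessors
#' @aliases clusterMembers clusterSizes representatives
NULL

#' @rdname DRPPartition-accessors
#' @export
setMethod("clusterMembers", "DRPPartition", function(x, rank = NULL) {
  if (is.null(rank)) x@clusters else x@clusters[[rank]]
})
#' @rdname DRPPartition-accessors
#' @export
setMethod("clusterSizes", "DRPPartition", function(x) lengths(x@clusters))
#' @rdname DRPPartition-accessors
#' @export
setMethod("representatives", "DRPPartition", function(x) x@representatives)

setMethod("show", "DRPPartition", function(object) {
  k <- length(object@clusters)
  cat(sprintf("DRPPartition: %d chain(s) in %d cluster(s)\n",
              length(unlist(object@clusters)), k))
  for (r in seq_len(min(k, 10L))) {
    rep <- object@representatives[r]
    cat(sprintf("  rank %d (n=%d%s): %s\n", r, length(object@clusters[[r]]),
                if (is.na(rep)) "" else paste0(", rep=", rep),
                paste(utils::head(object@clusters[[r]], 6L), collapse = " ")))
  }
  if (k > 10L) cat("  ...\n")
})

#' Accessors for PairMatrix objects
#'
#' @param x a \linkS4class{PairMatrix}.
#' @return \code{pairValues}: the symmetric score matrix; \code{matrixKind}:
#'   \code{"similarity"} or \code{"distance"}; \code{pairLabels}: chain ids.
#' @name PairMatrix-accessors
#' @aliases pairValues matrixKind pairLabels
NULL

#' @rdname PairMatrix-accessors
#' @export
setMethod("pairValues", "PairMatrix", function(x) x@values)
#' @rdname PairMatrix-accessors
#' @export
setMethod("matrixKind", "PairMatrix", function(x) x@kind)
#' @rdname PairMatrix-accessors
#' @export
setMethod("pairLabels", "PairMatrix", function(x) rownames(x@values))

setMethod("show", "PairMatrix", function(object) {
  cat(sprintf("PairMatrix (%s): %d x %d\n", object@kind,
              nrow(object@values), ncol(object@values)))
})

#' Accessors for ChainAlignment objects
#'
#' @param x a \linkS4class{ChainAlignment}.
#' @return \code{alignedPairs}: m x 2 integer matrix of residue index pairs;
#'   \code{pairDistances}: numeric C-alpha distances after superposition.
#' @name ChainAlignment-accessors
#' @aliases alignedPairs pairDistances
NULL

#' @rdname ChainAlignment-accessors
#' @export
setMethod("alignedPairs", "ChainAlignment", function(x) x@pairs)
#' @rdname ChainAlignment-accessors
#' @export
setMethod("pairDistances", "ChainAlignment", function(x) x@pairDistances)

setMethod("show", "ChainAlignment", function(object) {
  cat(sprintf("ChainAlignment %s vs %s: %d pair(s), %d within %.1f A\n",
              object@idA, object@idB, nrow(object@pairs),
              sum(object@pairDistances <= object@contactCutoff),
              object@contactCutoff))
})
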