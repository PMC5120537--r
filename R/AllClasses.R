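#' @import methods
NULL

#' PeptideChain: one polypeptide chain with C-alpha trace and disulfide bonds
#'
#' Container for a single chain of a disulfide-rich peptide (DRP): the
#' ordered C-alpha coordinates, the one-letter sequence, cysteine S-gamma
#' coordinates where resolved, and the chain's intra-chain disulfide bonds.
#' Residue positions are 1-based indices into the retained (C-alpha bearing)
#' residues, renumbered contiguously.
#'
#' @slot chainId character; four lowercase characters of the PDB identifier
#'   followed by the original-case chain letter, e.g. \code{"2crdA"}.
#' @slot sequence character; one-letter sequence (\code{"X"} for
#'   non-standard residues).
#' @slot resNames character vector of 3-letter residue names.
#' @slot resIds character vector of author residue numbers (with insertion
#'   code where present), kept for emitting coloring scripts.
#' @slot ca numeric matrix (n x 3) of C-alpha coordinates in Angstrom.
#' @slot sg numeric matrix (n x 3) of S-gamma coordinates; rows are NA for
#'   residues that are not cysteines or whose S-gamma was not resolved.
#' @slot bonds data.frame with columns \code{i}, \code{j} (residue positions,
#'   \code{i < j}) and \code{provenance} (\code{"ssbond_record"} or
#'   \code{"geometric"}); intra-chain bonds only.
#' @slot nBondsAny integer; number of disulfide bonds involving at least one
#'   cysteine of this chain, including inter-chain bonds.
#' @slot modelUsed integer; model number the coordinates were taken from.
#' @export
setClass("PeptideChain", representation(
  chainId   = "character",
  sequence  = "character",
  resNames  = "character",
  resIds    = "character",
  ca        = "matrix",
  sg        = "matrix",
  bonds     = "data.frame",
  nBondsAny = "integer",
  modelUsed = "integer"
))

setValidity("PeptideChain", function(object) {
  n <- nrow(object@ca)
  msg <- character(0)
  if (nchar(object@sequence) != n)
    msg <- c(msg, "sequence length must equal the number of residues")
  if (length(object@resNames) != n || length(object@resIds) != n)
    msg <- c(msg, "resNames/resIds must have one entry per residue")
  if (ncol(object@ca) != 3 || any(!is.finite(object@ca)))
    msg <- c(msg, "ca must be a finite n x 3 matrix")
  if (!identical(dim(object@sg), dim(object@ca)))
    msg <- c(msg, "sg must have the same dimensions as ca")
  b <- object@bonds
  if (nrow(b)) {
    if (!all(c("i", "j", "provenance") %in% names(b)))
      msg <- c(msg, "bonds needs columns i, j, provenance")
    else {
      if (any(b$i >= b$j)) msg <- c(msg, "bonds must satisfy i < j")
      pos <- c(b$i, b$j)
      if (any(pos < 1L) || any(pos > n))
        msg <- c(msg, "bond positions out of range")
      else {
        if (any(duplicated(pos)))
          msg <- c(msg, "a cysteine may participate in at most one intra-chain bond")
        letters1 <- strsplit(object@sequence, "")[[1]]
        if (any(letters1[pos] != "C"))
          msg <- c(msg, "bond positions must be cysteines")
        if (any(!is.finite(object@sg[pos, ])))
          msg <- c(msg, "bonded cysteines must have S-gamma coordinates")
      }
    }
  }
  if (length(object@nBondsAny) != 1L || object@nBondsAny < nrow(b))
    msg <- c(msg, "nBondsAny must be a single integer >= number of intra-chain bonds")
  if (length(msg)) msg else TRUE
})

#' ChainAlignment: an order-preserving residue equivalence between two chains
#'
#' Result of a pairwise rigid-body structure alignment: the matched residue
#' index pairs, the rigid transform mapping chain A onto chain B's frame, and
#' the per-pair C-alpha distances after the transform. Native overlap and
#' sequence identity are derived from this object.
#'
#' @slot idA,idB character chain identifiers.
#' @slot pairs integer matrix (m x 2) of (pos_a, pos_b) residue index pairs,
#'   strictly increasing in both columns.
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric length-3 translation (Angstrom).
#' @slot pairDistances numeric; C-alpha distance per pair after transform.
#' @slot contactCutoff numeric; contact criterion in Angstrom (3.5).
#' @export
setClass("ChainAlignment", representation(
  idA = "character", idB = "character",
  pairs = "matrix",
  rotation = "matrix", translation = "numeric",
  pairDistances = "numeric",
  contactCutoff = "numeric"
))

setValidity("ChainAlignment", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (ncol(p) != 2) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) > 1 && (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0)))
    msg <- c(msg, "pairs must be strictly increasing in both columns")
  if (length(object@pairDistances) != nrow(p))
    msg <- c(msg, "pairDistances must have one value per pair")
  R <- object@rotation
  if (!isTRUE(all.equal(det(R), 1, tolerance = 1e-6)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "rotation must be proper orthogonal")
  if (object@contactCutoff <= 0) msg <- c(msg, "contactCutoff must be > 0")
  if (length(msg)) msg else TRUE
})

#' PairMatrix: symmetric matrix of pairwise scores between chains
#'
#' @slot values symmetric numeric matrix with chain ids as dimnames; the
#'   diagonal is 1 for similarities and 0 for distances.
#' @slot kind \code{"similarity"} (values in [0,1]) or \code{"distance"}.
#' @export
setClass("PairMatrix", representation(
  values = "matrix",
  kind = "character"
))

setValidity("PairMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!object@kind %in% c("similarity", "distance"))
    msg <- c(msg, "kind must be 'similarity' or 'distance'")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must have identical row/column names")
  if (any(is.na(v)))
    msg <- c(msg, "values must be complete (no missing entries)")
  else {
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "values must be symmetric")
    dtarget <- if (object@kind == "similarity") 1 else 0
    if (nrow(v) && max(abs(diag(v) - dtarget)) > 1e-9)
      msg <- c(msg, sprintf("diagonal must be %g for kind=%s", dtarget, object@kind))
    if (object@kind == "similarity" && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "similarity values must lie in [0,1]")
    if (object@kind == "distance" && min(v) < -1e-9)
      msg <- c(msg, "distances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' DRPPartition: a disjoint, exhaustive assignment of chains to clusters
#'
#' Clusters are stored in rank order (rank 1 = most populated; ties broken by
#' the lexicographically smallest member id). Representatives are optional
#' until selected.
#'
#' @slot clusters list of character vectors of member chain ids, ordered by
#'   rank.
#' @slot representatives character vector parallel to \code{clusters}
#'   (NA until selected).
#' @export
setClass("DRPPartition", representation(
  clusters = "list",
  representatives = "character"
))

setValidity("DRPPartition", function(object) {
  msg <- character(0)
  all_members <- unlist(object@clusters, use.names = FALSE)
  if (any(duplicated(all_members)))
    msg <- c(msg, "clusters must be disjoint")
  sizes <- lengths(object@clusters)
  if (length(sizes) > 1 && any(diff(sizes) > 0))
    msg <- c(msg, "clusters must be ordered by non-increasing size")
  if (length(object@representatives) != length(object@clusters))
    msg <- c(msg, "one representative slot per cluster (NA allowed)")
  ok <- !is.na(object@representatives)
  if (any(ok) && !all(mapply(function(r, m) r %in% m,
                             object@representatives[ok],
                             object@clusters[ok])))
    msg <- c(msg, "each representative must be a member of its cluster")
  if (length(msg)) msg else TRUE
})

#' StarMSA: star multiple alignment anchored on a cluster representative
#'
#' One column per representative residue; each member row holds the residue
#' aligned to that reference position, or a gap. Member residues with no
#' reference equivalent are dropped (no extra columns are inserted).
#'
#' @slot reference character; chain id of the representative (anchor).
#' @slot members character; chain ids, one per row (includes the reference).
#' @slot aln character matrix (members x columns) of one-letter codes,
#'   \code{"-"} for gaps.
#' @slot index integer matrix parallel to \code{aln}; the member residue
#'   position occupying each cell (NA at gaps).
#' @export
setClass("StarMSA", representation(
  reference = "character",
  members = "character",
  aln = "matrix",
  index = "matrix"
))

setValidity("StarMSA", function(object) {
  msg <- character(0)
  if (!object@reference %in% object@members)
    msg <- c(msg, "reference must be one of the members")
  if (nrow(object@aln) != length(object@members))
    msg <- c(msg, "aln must have one row per member")
  if (!identical(dim(object@aln), dim(object@index)))
    msg <- c(msg, "aln and index must have identical dimensions")
  refrow <- match(object@reference, object@members)
  if (!is.na(refrow) && nrow(object@aln) &&
      any(object@aln[refrow, ] == "-"))
    msg <- c(msg, "reference row must be gap-free")
  if (length(msg)) msg else TRUE
})

#' ConservationProfile: per-column conservation scores and colors
#'
#' Sum-of-pairs conservation of a star alignment: per column the raw mean
#' BLOSUM62 score over residue pairs, its z-score normalization clamped to
#' [-2, 2], and the blue-to-yellow RGB color used for structure coloring.
#'
#' @slot raw numeric; per-column mean pairwise substitution score.
#' @slot normalized numeric; z-scores clamped to [-2, 2].
#' @slot rgb integer matrix (columns x 3) with components in 0..255.
#' @export
setClass("ConservationProfile", representation(
  raw = "numeric",
  normalized = "numeric",
  rgb = "matrix"
))

setValidity("ConservationProfile", function(object) {
  msg <- character(0)
  if (length(object@normalized) != length(object@raw))
    msg <- c(msg, "raw and normalized must have equal length")
  if (nrow(object@rgb) != length(object@raw) || ncol(object@rgb) != 3)
    msg <- c(msg, "rgb must be a (columns x 3) matrix")
  if (length(object@normalized) &&
      (min(object@normalized) < -2 - 1e-9 || max(object@normalized) > 2 + 1e-9))
    msg <- c(msg, "normalized scores must lie in [-2, 2]")
  if (length(object@rgb) && (min(object@rgb) < 0 || max(object@rgb) > 255))
    msg <- c(msg, "rgb components must lie in 0..255")
  if (length(msg)) msg else TRUE
})
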