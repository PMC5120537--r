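#' Pairwise iterative structure alignment
#'
#' Aligns two peptide chains by rigid-body superposition without using
#' sequence information. The procedure is: (1) an initial residue
#' correspondence from dynamic programming over the similarity of
#' intramolecular C-alpha distance profiles (window of 5 residues);
#' (2) least-squares superposition on the current pairs; (3) re-derivation of
#' the pairs by dynamic programming on the inter-structure C-alpha distance
#' matrix with cell score \code{max(0, d0 - d_ij)} and a linear gap penalty;
#' steps 2-3 repeat until the pair set is unchanged or \code{maxIter}
#' iterations. DP ties prefer the diagonal move, then the move advancing
#' chain A, making the result fully deterministic.
#'
#' @param a,b \linkS4class{PeptideChain} objects with at least 3 residues.
#' @param d0 score offset in Angstrom for the distance-based DP (default 7).
#' @param gap linear gap penalty (default 1).
#' @param maxIter maximum refinement iterations (default 50).
#' @param contactCutoff contact criterion in Angstrom stored on the result
#'   (default 3.5).
#' @param seedD0 score offset for the profile-based seeding DP (default 3).
#' @return a \linkS4class{ChainAlignment}.
#' @seealso [nativeOverlap()], [sequenceIdentity()]
#' @export
alignPair <- function(a, b, d0 = 7, gap = 1, maxIter = 50L,
                      contactCutoff = 3.5, seedD0 = 3) {
  ca <- caCoords(a); cb <- caCoords(b)
  if (nrow(ca) < 3L || nrow(cb) < 3L)
    stop("alignPair requires chains with at least 3 residues")

  S0 <- .profile_similarity(ca, cb, seedD0)
  pairs <- nw_align_cpp(S0, gap)
  if (nrow(pairs) == 0L) pairs <- cbind(1L, 1L)

  # Trimmed superposition: fit on the well-matched core (pairs within the
  # contact cutoff) when at least 3 such pairs exist, so residues that are
  # genuinely displaced cannot drag the frame into a compromise fit.
  trimmed_fit <- function(pairs) {
    pa <- ca[pairs[, 1], , drop = FALSE]
    pb <- cb[pairs[, 2], , drop = FALSE]
    fit <- kabschSuperpose(pa, pb)
    core_prev <- rep(TRUE, nrow(pa))
    for (t in 1:10) {
      d <- row_norms(apply_transform(fit, pa) - pb)
      core <- d <= contactCutoff
      if (sum(core) < 3L || identical(core, core_prev)) break
      fit <- kabschSuperpose(pa[core, , drop = FALSE],
                             pb[core, , drop = FALSE])
      core_prev <- core
    }
    fit
  }

  fit <- NULL
  for (iter in seq_len(maxIter)) {
    fit <- trimmed_fit(pairs)
    moved <- apply_transform(fit, ca)
    D <- .cross_dist(moved, cb)
    S <- pmax(d0 - D, 0)
    new_pairs <- nw_align_cpp(S, gap)
    # residues matched at or beyond d0 carry no score: not equivalences
    new_pairs <- new_pairs[S[new_pairs] > 0, , drop = FALSE]
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) break
    pairs <- new_pairs
    if (nrow(pairs) == 0L) break
  }

  if (nrow(pairs) == 0L) {
    dists <- numeric(0)
    if (is.null(fit)) fit <- kabschSuperpose(ca[1, , drop = FALSE],
                                             cb[1, , drop = FALSE])
  } else {
    fit <- trimmed_fit(pairs)
    moved <- apply_transform(fit, ca[pairs[, 1], , drop = FALSE])
    dists <- row_norms(moved - cb[pairs[, 2], , drop = FALSE])
  }

  new("ChainAlignment",
      idA = chainId(a), idB = chainId(b),
      pairs = pairs,
      rotation = fit$rotation, translation = fit$translation,
      pairDistances = dists,
      contactCutoff = contactCutoff)
}

# Intramolecular distance profile of each residue: C-alpha distances to the
# neighbours at sequence offsets -2,-1,+1,+2 (window 5). Sequence-independent
# and invariant under rigid motion, so it can seed the alignment.
.distance_profile <- function(ca) {
  n <- nrow(ca)
  offs <- c(-2L, -1L, 1L, 2L)
  prof <- matrix(NA_real_, n, length(offs))
  for (k in seq_along(offs)) {
    o <- offs[k]
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    prof[i[ok], k] <- sqrt(rowSums((ca[i[ok], , drop = FALSE] -
                                    ca[j[ok], , drop = FALSE])^2))
  }
  prof
}

.profile_similarity <- function(ca, cb, seedD0) {
  pa <- .distance_profile(ca)
  pb <- .distance_profile(cb)
  n <- nrow(pa); m <- nrow(pb)
  S <- matrix(0, n, m)
  for (k in seq_len(ncol(pa))) {
    d <- abs(outer(pa[, k], pb[, k], "-"))
    d[is.na(d)] <- 0
    S <- S + d
  }
  cnt <- outer(rowSums(!is.na(pa)), rowSums(!is.na(pb)), pmin)
  cnt[cnt == 0] <- 1
  pmax(seedD0 - S / cnt, 0)   # matrix first: pmax keeps dims of its first arg
}

.cross_dist <- function(x, y) {
  # pairwise Euclidean distances between rows of x and rows of y
  xx <- rowSums(x * x); yy <- rowSums(y * y)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

#' Native overlap of an alignment
#'
#' The fraction of aligned C-alpha pairs within the contact cutoff (3.5
#' Angstrom, inclusive) after superposition, divided by the length of the
#' longer (default) or shorter chain. A self-alignment has native overlap 1;
#' the value lies in [0, 1].
#'
#' @param aln a \linkS4class{ChainAlignment}.
#' @param lenA,lenB integer chain lengths of the aligned chains.
#' @param denominator \code{"longer"} (default) or \code{"shorter"}.
#' @param contactCutoff contact criterion in Angstrom; defaults to the
#'   cutoff stored on the alignment.
#' @return numeric fraction in [0, 1].
#' @export
nativeOverlap <- function(aln, lenA, lenB,
                          denominator = c("longer", "shorter"),
                          contactCutoff = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(contactCutoff)) contactCutoff <- aln@contactCutoff
  hits <- sum(aln@pairDistances <= contactCutoff)
  den <- if (denominator == "longer") max(lenA, lenB) else min(lenA, lenB)
  hits / den
}

#' Sequence identity over structurally equivalent residues
#'
#' 100 times the number of aligned residue pairs with identical amino-acid
#' type, divided by the length of the longer chain.
#'
#' @param aln a \linkS4class{ChainAlignment}.
#' @param seqA,seqB one-letter sequences of the aligned chains.
#' @return percent identity in [0, 100].
#' @export
sequenceIdentity <- function(aln, seqA, seqB) {
  la <- strsplit(seqA, "")[[1]]
  lb <- strsplit(seqB, "")[[1]]
  p <- aln@pairs
  same <- if (nrow(p)) sum(la[p[, 1]] == lb[p[, 2]]) else 0L
  100 * same / max(length(la), length(lb))
}
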