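#' Enumerate disulfide-bond mappings between two chains
#'
#' Every way of placing the bonds of the smaller set in one-to-one
#' correspondence with bonds of the larger set, times every cysteine
#' orientation of each mapped bond (which cysteine of one bond corresponds to
#' which of the other). For bond counts \code{nA}, \code{nB} this yields
#' exactly \code{P(max, min) * 2^min} mappings, with \code{P} the falling
#' factorial; e.g. two 3-bond peptides give 48 mappings (6 bond pairings x 8
#' orientation combinations). Enumeration order is deterministic.
#'
#' @param nA,nB integer bond counts, each in 1..4.
#' @return list of mappings; each mapping is a list with \code{bondPairs}
#'   (min(nA,nB) x 2 integer matrix of (bond_a, bond_b) indices) and
#'   \code{flip} (logical vector; \code{TRUE} crosses the cysteine
#'   correspondence of that mapped bond).
#' @export
enumerateBondMappings <- function(nA, nB) {
  if (nA < 1L || nB < 1L)
    stop("both chains must have at least one disulfide bond")
  m <- min(nA, nB); M <- max(nA, nB)
  swap <- nA > nB   # enumerate injections of the smaller side into the larger

  inj <- .injections(m, M)                      # each row: image of 1..m in 1..M
  flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m),
                                 KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", nrow(inj) * nrow(flips))
  k <- 0L
  for (i in seq_len(nrow(inj))) {
    small <- seq_len(m); large <- inj[i, ]
    bp <- if (swap) cbind(large, small) else cbind(small, large)
    colnames(bp) <- c("a", "b")
    for (f in seq_len(nrow(flips))) {
      k <- k + 1L
      out[[k]] <- list(bondPairs = bp, flip = as.logical(flips[f, ]))
    }
  }
  out
}

# All ordered selections (injections) of m items from 1..M, in lexicographic
# order of the image vector; m, M <= 4 so this stays tiny.
.injections <- function(m, M) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(M)), m),
                                KEEP.OUT.ATTRS = FALSE))
  keep <- apply(grid, 1L, function(r) !anyDuplicated(r))
  grid <- grid[keep, , drop = FALSE]
  grid[do.call(order, split(grid, col(grid))), , drop = FALSE]
}

#' Score one disulfide-bond mapping
#'
#' Superposes the mapped cysteine C-alpha atoms of chain \code{a} onto their
#' counterparts in chain \code{b} by least squares, then aggregates the
#' distances between all equivalent C-alpha and S-gamma atoms (4 atoms per
#' mapped bond). Unmapped bonds of the larger set are ignored.
#'
#' @param mapping one element of [enumerateBondMappings()].
#' @param a,b \linkS4class{PeptideChain} objects.
#' @param aggregation \code{"mean"} (default), \code{"sum"} or \code{"rms"}
#'   over the equivalent-atom distances.
#' @return distance in Angstrom (non-negative).
#' @export
scoreMapping <- function(mapping, a, b,
                         aggregation = c("mean", "sum", "rms")) {
  aggregation <- match.arg(aggregation)
  ba <- disulfides(a); bb <- disulfides(b)
  bp <- mapping$bondPairs
  m <- nrow(bp)

  posA <- matrix(0L, m, 2); posB <- matrix(0L, m, 2)
  for (k in seq_len(m)) {
    pa <- c(ba$i[bp[k, 1]], ba$j[bp[k, 1]])
    pb <- c(bb$i[bp[k, 2]], bb$j[bp[k, 2]])
    if (mapping$flip[k]) pb <- rev(pb)
    posA[k, ] <- pa; posB[k, ] <- pb
  }
  ia <- as.vector(t(posA)); ib <- as.vector(t(posB))

  sga <- sgCoords(a)[ia, , drop = FALSE]
  sgb <- sgCoords(b)[ib, , drop = FALSE]
  if (any(!is.finite(sga)))
    stop("missing S-gamma coordinate on chain ", chainId(a),
         " residue ", ia[which(!is.finite(sga[, 1]))[1]])
  if (any(!is.finite(sgb)))
    stop("missing S-gamma coordinate on chain ", chainId(b),
         " residue ", ib[which(!is.finite(sgb[, 1]))[1]])

  caa <- caCoords(a)[ia, , drop = FALSE]
  cab <- caCoords(b)[ib, , drop = FALSE]
  fit <- kabschSuperpose(caa, cab)
  dca <- row_norms(apply_transform(fit, caa) - cab)
  dsg <- row_norms(apply_transform(fit, sga) - sgb)
  d <- c(dca, dsg)
  switch(aggregation,
         mean = mean(d),
         sum = sum(d),
         rms = sqrt(mean(d^2)))
}

#' Disulfide distance between two chains
#'
#' The minimum of [scoreMapping()] over all bond mappings and cysteine
#' orientations from [enumerateBondMappings()]. Symmetric in its arguments;
#' ties are resolved by enumeration order.
#'
#' @inheritParams scoreMapping
#' @return list with \code{score} (Angstrom) and \code{mapping} (the best
#'   mapping, augmented with its \code{score}).
#' @export
disulfideDistance <- function(a, b, aggregation = c("mean", "sum", "rms")) {
  aggregation <- match.arg(aggregation)
  na <- nrow(disulfides(a)); nb <- nrow(disulfides(b))
  if (na < 1L || nb < 1L)
    stop("disulfideDistance requires chains with at least one intra-chain bond")
  maps <- enumerateBondMappings(na, nb)
  best <- NULL; best_score <- Inf
  for (mp in maps) {
    s <- scoreMapping(mp, a, b, aggregation)
    if (s < best_score) { best_score <- s; best <- mp }
  }
  best$score <- best_score
  list(score = best_score, mapping = best)
}
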