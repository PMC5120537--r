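#' Build a symmetric pairwise score matrix
#'
#' Evaluates a symmetric metric once per unordered chain pair (n(n-1)/2
#' evaluations). If \code{cacheFile} is given and exists with matching labels
#' the matrix is loaded instead of recomputed; after computing, the matrix is
#' written there, so reruns are free and byte-identical.
#'
#' @param chains list of \linkS4class{PeptideChain}.
#' @param metric function \code{(a, b) -> numeric} (e.g. native overlap or
#'   disulfide distance between two chains).
#' @param kind \code{"similarity"} or \code{"distance"}; fixes the diagonal
#'   (1 or 0) and the merge direction in [averageLinkage()].
#' @param cacheFile optional TSV path for caching.
#' @return a \linkS4class{PairMatrix}.
#' @export
buildPairMatrix <- function(chains, metric, kind = c("similarity", "distance"),
                            cacheFile = NULL) {
  kind <- match.arg(kind)
  ids <- vapply(chains, chainId, character(1))
  if (anyDuplicated(ids)) stop("duplicate chain ids")
  if (!is.null(cacheFile) && file.exists(cacheFile)) {
    pm <- readPairMatrix(cacheFile, kind)
    if (identical(pairLabels(pm), ids)) return(pm)
  }
  n <- length(ids)
  v <- matrix(if (kind == "similarity") 1 else 0, n, n,
              dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    val <- metric(chains[[i]], chains[[j]])
    v[i, j] <- val; v[j, i] <- val
  }
  pm <- new("PairMatrix", values = v, kind = kind)
  if (!is.null(cacheFile)) writePairMatrix(pm, cacheFile)
  pm
}

#' @rdname buildPairMatrix
#' @param pm a \linkS4class{PairMatrix}.
#' @param path TSV file path (header row and column of chain ids).
#' @export
writePairMatrix <- function(pm, path) {
  v <- round(pairValues(pm), 6)
  df <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname buildPairMatrix
#' @export
readPairMatrix <- function(path, kind = c("similarity", "distance")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$id
  storage.mode(v) <- "double"
  new("PairMatrix", values = v, kind = kind)
}

#' Average-linkage agglomerative clustering with cutoff termination
#'
#' Each chain starts as a singleton cluster. Repeatedly, the pair of clusters
#' with the best average inter-cluster score is merged, where the average is
#' the unweighted mean over all cross-cluster chain pairs (UPGMA-style, not
#' the mean of previous linkage values). For a similarity matrix a merge
#' requires average >= cutoff (higher is better); for a distance matrix it
#' requires average <= cutoff. Iteration stops when no candidate merge passes
#' the cutoff test. Ties are broken toward the candidate pair with the
#' lexicographically smallest (minimum member id of the first cluster, then
#' of the second), so the partition is deterministic and invariant under
#' input ordering.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param cutoff merge threshold in the metric's range (inclusive).
#' @return list with \code{partition} (a ranked \linkS4class{DRPPartition})
#'   and \code{trace} (data.frame of merge events: step, members of the two
#'   merged clusters, linkage value).
#' @export
averageLinkage <- function(pm, cutoff) {
  v <- pairValues(pm)
  sim <- matrixKind(pm) == "similarity"
  ids <- rownames(v)
  clusters <- as.list(ids)
  trace <- data.frame(step = integer(0), cluster_x = character(0),
                      cluster_y = character(0), value = numeric(0))
  step <- 0L
  while (length(clusters) > 1L) {
    # canonical ordering of clusters by smallest member id
    mins <- vapply(clusters, min, character(1))
    ord <- order(mins)
    clusters <- clusters[ord]
    mins <- mins[ord]

    best <- NULL; best_val <- if (sim) -Inf else Inf
    k <- length(clusters)
    for (x in seq_len(k - 1)) for (y in seq((x + 1), k)) {
      avg <- mean(v[clusters[[x]], clusters[[y]]])
      better <- if (sim) avg > best_val else avg < best_val
      if (better) { best_val <- avg; best <- c(x, y) }
    }
    passes <- if (sim) best_val >= cutoff else best_val <= cutoff
    if (!passes) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step,
      cluster_x = paste(sort(clusters[[best[1]]]), collapse = ","),
      cluster_y = paste(sort(clusters[[best[2]]]), collapse = ","),
      value = best_val))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(partition = rankPartition(clusters), trace = trace)
}

#' Rank clusters by size
#'
#' Orders clusters by non-increasing size, breaking ties by the
#' lexicographically smallest member id, and returns a valid
#' \linkS4class{DRPPartition} (representatives unset).
#'
#' @param clusters list of character vectors of member ids.
#' @param representatives optional character vector parallel to
#'   \code{clusters}.
#' @return a \linkS4class{DRPPartition}.
#' @export
rankPartition <- function(clusters, representatives = NULL) {
  clusters <- lapply(clusters, function(m) sort(unique(m)))
  if (is.null(representatives))
    representatives <- rep(NA_character_, length(clusters))
  mins <- vapply(clusters, function(m) m[1], character(1))
  ord <- order(-lengths(clusters), mins)
  new("DRPPartition", clusters = clusters[ord],
      representatives = representatives[ord])
}
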