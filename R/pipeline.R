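#' Pipeline configuration
#'
#' Collects every numeric constant of the clustering protocol with its
#' default: the 3.5 Angstrom contact criterion, the 0.7
#' native-overlap cluster cutoff, the 2.0 Angstrom disulfide-distance cutoff
#' for knottin reclustering, the SCOP knottin fold id \code{"g.3"} with its
#' 4-member threshold, the top-25 singleton snapshot, and the top-20 report.
#'
#' @param overlap_contact_cutoff contact criterion in Angstrom (3.5).
#' @param overlap_cluster_cutoff native-overlap merge cutoff (0.7).
#' @param ss_cluster_cutoff disulfide-distance merge cutoff in Angstrom (2.0).
#' @param ss_aggregation aggregation of equivalent-atom distances:
#'   \code{"mean"} (default), \code{"sum"} or \code{"rms"}.
#' @param knottin_fold_id SCOP fold identifier marking knottins ("g.3").
#' @param knottin_min_members knottin annotations needed before a cluster is
#'   pooled for reclustering (4).
#' @param singleton_top_n size of the top-cluster snapshot that can receive
#'   singletons (25).
#' @param report_top_n clusters reported in the summary tables (20).
#' @param max_residues,min_bonds,max_bonds,bond_counting DRP filter, see
#'   [filterDrps()].
#' @param seed integer seed for any stochastic component.
#' @return named list of validated settings.
#' @export
pipelineConfig <- function(overlap_contact_cutoff = 3.5,
                           overlap_cluster_cutoff = 0.7,
                           ss_cluster_cutoff = 2.0,
                           ss_aggregation = c("mean", "sum", "rms"),
                           knottin_fold_id = "g.3",
                           knottin_min_members = 4L,
                           singleton_top_n = 25L,
                           report_top_n = 20L,
                           max_residues = 50L, min_bonds = 1L,
                           max_bonds = 4L,
                           bond_counting = "any_involving_chain",
                           seed = 1L) {
  ss_aggregation <- match.arg(ss_aggregation)
  stopifnot(overlap_contact_cutoff > 0, overlap_cluster_cutoff > 0,
            ss_cluster_cutoff > 0, knottin_min_members >= 1L,
            singleton_top_n >= report_top_n)
  list(overlap_contact_cutoff = overlap_contact_cutoff,
       overlap_cluster_cutoff = overlap_cluster_cutoff,
       ss_cluster_cutoff = ss_cluster_cutoff,
       ss_aggregation = ss_aggregation,
       knottin_fold_id = knottin_fold_id,
       knottin_min_members = as.integer(knottin_min_members),
       singleton_top_n = as.integer(singleton_top_n),
       report_top_n = as.integer(report_top_n),
       max_residues = as.integer(max_residues),
       min_bonds = as.integer(min_bonds),
       max_bonds = as.integer(max_bonds),
       bond_counting = bond_counting,
       seed = as.integer(seed))
}

#' All-pairs alignment tables
#'
#' Aligns every unordered chain pair once and tabulates native overlap with
#' both denominators plus sequence identity. The longer-denominator overlap
#' is the similarity used for initial clustering and representative
#' selection; the shorter-denominator table drives the second singleton pass.
#'
#' @param chains list of \linkS4class{PeptideChain}.
#' @param contactCutoff contact criterion in Angstrom.
#' @return list with \code{longer}, \code{shorter}
#'   (\linkS4class{PairMatrix} similarities) and \code{seqId} (numeric
#'   matrix, percent).
#' @export
alignmentTables <- function(chains, contactCutoff = 3.5) {
  ids <- vapply(chains, chainId, character(1))
  n <- length(chains)
  lo <- matrix(1, n, n, dimnames = list(ids, ids))
  sh <- lo
  si <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    a <- chains[[i]]; b <- chains[[j]]
    aln <- alignPair(a, b, contactCutoff = contactCutoff)
    la <- nResidues(a); lb <- nResidues(b)
    lo[i, j] <- lo[j, i] <- nativeOverlap(aln, la, lb, "longer")
    sh[i, j] <- sh[j, i] <- nativeOverlap(aln, la, lb, "shorter")
    si[i, j] <- si[j, i] <- sequenceIdentity(aln, chainSeq(a), chainSeq(b))
  }
  list(longer = new("PairMatrix", values = lo, kind = "similarity"),
       shorter = new("PairMatrix", values = sh, kind = "similarity"),
       seqId = si)
}

#' Initial native-overlap clustering (pipeline step ii)
#'
#' Average-linkage clustering of the longer-denominator native-overlap
#' similarity matrix, merging while the average overlap is at least
#' \code{cfg$overlap_cluster_cutoff}.
#'
#' @param chains filtered, deduplicated \linkS4class{PeptideChain} list.
#' @param cfg a [pipelineConfig()].
#' @param tables optional precomputed [alignmentTables()].
#' @return a ranked \linkS4class{DRPPartition}.
#' @export
runInitialClustering <- function(chains, cfg = pipelineConfig(),
                                 tables = NULL) {
  if (length(chains) < 2L)
    return(rankPartition(lapply(chains, chainId)))
  if (is.null(tables))
    tables <- alignmentTables(chains, cfg$overlap_contact_cutoff)
  averageLinkage(tables$longer, cfg$overlap_cluster_cutoff)$partition
}

#' Knottin reclustering by disulfide distance (pipeline step iii)
#'
#' Every cluster containing at least \code{cfg$knottin_min_members} chains
#' annotated with the knottin SCOP fold is pooled in its entirety (non-
#' knottin co-members included), and the pooled chains are reclustered by
#' average-linkage on the disulfide distance with cutoff
#' \code{cfg$ss_cluster_cutoff}. All other clusters pass through untouched.
#' Pooled chains without an intra-chain bond cannot be scored; they are left
#' behind in their original cluster with a warning.
#'
#' @param partition a ranked \linkS4class{DRPPartition}.
#' @param chains list of \linkS4class{PeptideChain} (named by id or in any
#'   order).
#' @param folds named character vector mapping chain id to SCOP fold id;
#'   chains missing from it are treated as unannotated, never as knottins.
#' @param cfg a [pipelineConfig()].
#' @return a ranked \linkS4class{DRPPartition}.
#' @export
reclusterKnottins <- function(partition, chains, folds = character(0),
                              cfg = pipelineConfig()) {
  chains <- .chain_index(chains)
  members <- clusterMembers(partition)
  n_knot <- vapply(members, function(m)
    sum(folds[m] == cfg$knottin_fold_id, na.rm = TRUE), integer(1))
  pool_idx <- which(n_knot >= cfg$knottin_min_members)
  if (!length(pool_idx)) return(partition)

  pooled <- unlist(members[pool_idx], use.names = FALSE)
  scorable <- vapply(pooled, function(id)
    nrow(disulfides(chains[[id]])) >= 1L, logical(1))
  if (any(!scorable))
    warning("excluded from knottin reclustering (no intra-chain bond): ",
            paste(pooled[!scorable], collapse = ", "))
  residual <- lapply(members[pool_idx], function(m)
    m[m %in% pooled[!scorable]])
  residual <- residual[lengths(residual) > 0]
  pooled <- pooled[scorable]

  new_clusters <- list()
  if (length(pooled) == 1L) {
    new_clusters <- list(pooled)
  } else if (length(pooled) > 1L) {
    pm <- buildPairMatrix(chains[pooled], function(a, b)
      disulfideDistance(a, b, cfg$ss_aggregation)$score, "distance")
    new_clusters <- clusterMembers(averageLinkage(pm, cfg$ss_cluster_cutoff)$partition)
  }
  rankPartition(c(members[-pool_idx], residual, new_clusters))
}

#' Reassign singletons into the most populated clusters (steps iv and v)
#'
#' Takes a snapshot of the top \code{cfg$singleton_top_n} clusters by rank.
#' Every chain outside the snapshot whose native overlap to at least one
#' snapshot-cluster member reaches \code{cfg$overlap_cluster_cutoff} is moved
#' into the qualifying cluster containing the member of maximal overlap
#' (ties: larger cluster, then lower rank). All moves are evaluated against
#' the snapshot and applied as one batch (no cascading within a pass), then
#' clusters are re-ranked. The first pass uses the longer-chain denominator,
#' the second the shorter.
#'
#' @param partition a ranked \linkS4class{DRPPartition}.
#' @param tables an [alignmentTables()] result (or a list with a
#'   \linkS4class{PairMatrix} under the chosen mode).
#' @param mode \code{"longer"} or \code{"shorter"} overlap denominator.
#' @param cfg a [pipelineConfig()].
#' @return a ranked \linkS4class{DRPPartition}.
#' @export
reassignSingletons <- function(partition, tables,
                               mode = c("longer", "shorter"),
                               cfg = pipelineConfig()) {
  mode <- match.arg(mode)
  v <- pairValues(tables[[mode]])
  members <- clusterMembers(partition)
  k <- length(members)
  top_n <- min(cfg$singleton_top_n, k)
  if (top_n >= k) return(partition)
  top <- members[seq_len(top_n)]        # snapshot: sizes frozen at pass start
  top_sizes <- lengths(top)

  dest <- character(0)
  movers <- character(0)
  for (x in unlist(members[-seq_len(top_n)], use.names = FALSE)) {
    best <- vapply(top, function(m) max(v[x, m]), numeric(1))
    qual <- which(best >= cfg$overlap_cluster_cutoff)
    if (!length(qual)) next
    ord <- qual[order(-best[qual], -top_sizes[qual], qual)]
    movers <- c(movers, x)
    dest <- c(dest, ord[1])
  }
  if (!length(movers)) return(partition)

  new_members <- members
  for (t in seq_along(movers)) {
    d <- as.integer(dest[t])
    new_members <- lapply(new_members, function(m) setdiff(m, movers[t]))
    new_members[[d]] <- c(new_members[[d]], movers[t])
  }
  rankPartition(new_members[lengths(new_members) > 0])
}

#' Select a cluster representative
#'
#' The member with the largest mean native overlap (longer denominator) to
#' all other members; a singleton cluster yields its sole member; ties go to
#' the lexicographically smallest id.
#'
#' @param members character vector of member chain ids.
#' @param overlap a \linkS4class{PairMatrix} (or numeric matrix) of pairwise
#'   native overlaps covering the members.
#' @return chain id of the representative.
#' @export
selectRepresentative <- function(members, overlap) {
  if (length(members) == 1L) return(members)
  v <- if (is(overlap, "PairMatrix")) pairValues(overlap) else overlap
  members <- sort(members)
  avg <- vapply(members, function(m)
    mean(v[m, setdiff(members, m)]), numeric(1))
  members[which.max(avg)]             # first max = smallest id on ties
}

#' Summarize a partition (Table 1/2-style report)
#'
#' Per cluster: rank, name (modal SCOP fold of members, mechanically
#' assigned, or \code{"unassigned"}), member count, average pairwise sequence
#' identity, average length, the representative and its mean native overlap
#' to co-members. Also: the representatives' pairwise native-overlap matrix
#' (top \code{cfg$report_top_n} clusters) whose diagonal holds each
#' representative's within-cluster mean overlap, the median off-diagonal
#' value of that matrix, and the coverage curve (cumulative fraction of
#' chains in the top k clusters).
#'
#' @param partition a ranked \linkS4class{DRPPartition} (representatives are
#'   selected here if unset).
#' @param chains list of \linkS4class{PeptideChain}.
#' @param tables an [alignmentTables()] result.
#' @param folds named character vector of SCOP fold annotations.
#' @param cfg a [pipelineConfig()].
#' @return list with \code{partition} (representatives filled in),
#'   \code{clusters} (data.frame), \code{repMatrix}, \code{medianOffDiagonal}
#'   and \code{coverage} (data.frame rank/cumulative fraction).
#' @export
makeReport <- function(partition, chains, tables, folds = character(0),
                       cfg = pipelineConfig()) {
  chains <- .chain_index(chains)
  v <- pairValues(tables$longer)
  si <- tables$seqId
  members <- clusterMembers(partition)
  k <- length(members)

  reps <- representatives(partition)
  for (r in seq_len(k)) if (is.na(reps[r]))
    reps[r] <- selectRepresentative(members[[r]], v)
  partition <- new("DRPPartition", clusters = members,
                   representatives = reps)

  rep_avg <- vapply(seq_len(k), function(r) {
    others <- setdiff(members[[r]], reps[r])
    if (!length(others)) 1 else mean(v[reps[r], others])
  }, numeric(1))

  name_of <- function(m) {
    f <- folds[m]; f <- f[!is.na(f)]
    if (!length(f)) return("unassigned")
    tab <- sort(table(f), decreasing = TRUE)
    names(tab)[1]
  }
  avg_si <- vapply(members, function(m) {
    if (length(m) < 2) return(NA_real_)
    mean(si[m, m][upper.tri(diag(length(m)))])
  }, numeric(1))
  avg_len <- vapply(members, function(m)
    mean(vapply(chains[m], nResidues, integer(1))), numeric(1))

  clusters_df <- data.frame(
    rank = seq_len(k),
    name = vapply(members, name_of, character(1)),
    n_members = lengths(members),
    avg_seq_id = round(avg_si, 1),
    avg_length = round(avg_len, 1),
    representative = reps,
    rep_avg_overlap = round(rep_avg, 2),
    stringsAsFactors = FALSE)

  top <- seq_len(min(cfg$report_top_n, k))
  rep_ids <- reps[top]
  rep_mat <- v[rep_ids, rep_ids, drop = FALSE]
  diag(rep_mat) <- rep_avg[top]
  med_off <- if (length(top) > 1)
    stats::median(rep_mat[upper.tri(rep_mat)]) else NA_real_

  sizes <- lengths(members)
  coverage <- data.frame(rank = seq_len(k),
                         coverage = cumsum(sizes) / sum(sizes))

  list(partition = partition, clusters = clusters_df,
       repMatrix = rep_mat, medianOffDiagonal = med_off,
       coverage = coverage)
}

#' Run the full clustering pipeline
#'
#' Executes the five protocol steps in order: (i) DRP filtering and
#' deduplication, (ii) native-overlap average-linkage clustering at 0.7,
#' (iii) knottin reclustering by disulfide distance at 2.0 Angstrom,
#' (iv) longer-denominator singleton reassignment, (v) shorter-denominator
#' singleton reassignment; then representative selection and reporting.
#' Fully deterministic for fixed inputs and configuration.
#'
#' @param chains list of \linkS4class{PeptideChain}, or a directory/file
#'   paths accepted by [readPeptideChains()].
#' @param folds named character vector mapping chain id to SCOP fold id.
#' @param cfg a [pipelineConfig()].
#' @param outdir optional directory; when given, intermediate partitions and
#'   the report tables are written there.
#' @param skipKnottinRecluster,skipSingletons step toggles.
#' @return list with \code{partition}, \code{report}, \code{steps} (named
#'   list of the partition after each step) and \code{tables}.
#' @export
runPipeline <- function(chains, folds = character(0),
                        cfg = pipelineConfig(), outdir = NULL,
                        skipKnottinRecluster = FALSE,
                        skipSingletons = FALSE) {
  if (is.character(chains)) chains <- readPeptideChains(chains)
  drps <- filterDrps(chains, cfg$max_residues, cfg$min_bonds, cfg$max_bonds,
                     cfg$bond_counting)
  if (!length(drps)) stop("stage filter: no chains pass the DRP filter")
  drps <- deduplicateDrps(drps)

  tables <- alignmentTables(drps, cfg$overlap_contact_cutoff)
  steps <- list()
  p <- runInitialClustering(drps, cfg, tables)
  steps$initial <- p
  p <- if (skipKnottinRecluster) p else reclusterKnottins(p, drps, folds, cfg)
  steps$knottin <- p
  if (!skipSingletons) {
    p <- reassignSingletons(p, tables, "longer", cfg)
    steps$longer_singletons <- p
    p <- reassignSingletons(p, tables, "shorter", cfg)
    steps$shorter_singletons <- p
  }
  report <- makeReport(p, drps, tables, folds, cfg)
  p <- report$partition

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    nm <- c(initial = "partition_step2.json", knottin = "partition_step3.json",
            longer_singletons = "partition_step4.json",
            shorter_singletons = "partition_step5.json")
    for (s in names(steps))
      writePartitionJson(steps[[s]], file.path(outdir, nm[[s]]))
    writePartitionJson(p, file.path(outdir, "partition_final.json"))
    utils::write.table(report$clusters, file.path(outdir, "table2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rm1 <- data.frame(id = rownames(report$repMatrix),
                      round(report$repMatrix, 2), check.names = FALSE)
    utils::write.table(rm1, file.path(outdir, "table1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$coverage, file.path(outdir, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- vapply(steps, function(s) length(clusterMembers(s)), integer(1))
    writeLines(c(sprintf("chains_input\t%d", length(chains)),
                 sprintf("drps_filtered\t%d", length(drps)),
                 sprintf("clusters_%s\t%d", names(counts), counts)),
               file.path(outdir, "log.txt"))
  }
  list(partition = p, report = report, steps = steps, tables = tables)
}

#' Write and read a partition as JSON
#'
#' Cluster rank maps to its member list (and representative when selected).
#'
#' @param partition a \linkS4class{DRPPartition}.
#' @param path file path.
#' @export
writePartitionJson <- function(partition, path) {
  members <- clusterMembers(partition)
  reps <- representatives(partition)
  recs <- lapply(seq_along(members), function(r) {
    rec <- list(rank = r, members = members[[r]])
    if (!is.na(reps[r])) rec$representative <- reps[r]
    rec
  })
  names(recs) <- as.character(seq_along(members))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writePartitionJson
#' @export
readPartitionJson <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  clusters <- lapply(recs, function(r) unlist(r$members))
  reps <- vapply(recs, function(r)
    if (is.null(r$representative)) NA_character_ else r$representative,
    character(1))
  new("DRPPartition", clusters = unname(clusters), representatives = unname(reps))
}

#' Read a fold-annotation table
#'
#' Tab-separated file with two columns: chain id and SCOP fold identifier.
#'
#' @param path TSV file path.
#' @return named character vector.
#' @export
readFoldsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chain_id", "fold"))
  structure(df$fold, names = df$chain_id)
}

.chain_index <- function(chains) {
  if (is(chains, "PeptideChain")) chains <- list(chains)
  names(chains) <- vapply(chains, chainId, character(1))
  chains
}
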