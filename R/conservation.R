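#' Star multiple alignment anchored on the cluster representative
#'
#' Each member is pairwise structure-aligned to the representative; one MSA
#' column is created per representative residue. A member residue paired to
#' reference residue r occupies column r; member residues with no reference
#' equivalent are dropped (no extra columns), and reference columns without a
#' member equivalent show a gap in that member's row. The representative is,
#' by construction, the most central member of its cluster, which makes it a
#' natural anchor.
#'
#' @param members list of \linkS4class{PeptideChain} cluster members (the
#'   representative must be among them).
#' @param representative chain id of the anchor.
#' @param alignFun pairwise aligner, by default [alignPair()].
#' @return a \linkS4class{StarMSA}.
#' @export
buildStarMsa <- function(members, representative, alignFun = alignPair) {
  members <- .chain_index(members)
  if (!length(members)) stop("empty cluster")
  if (!representative %in% names(members))
    stop("representative must be one of the members")
  ref <- members[[representative]]
  ncol <- nResidues(ref)
  ids <- names(members)

  aln_mat <- matrix("-", length(ids), ncol,
                    dimnames = list(ids, NULL))
  idx_mat <- matrix(NA_integer_, length(ids), ncol,
                    dimnames = list(ids, NULL))
  for (id in ids) {
    ch <- members[[id]]
    letters1 <- strsplit(chainSeq(ch), "")[[1]]
    if (id == representative) {
      pairs <- cbind(seq_len(ncol), seq_len(ncol))
    } else {
      pairs <- alignedPairs(alignFun(ch, ref))
    }
    if (nrow(pairs)) {
      aln_mat[id, pairs[, 2]] <- letters1[pairs[, 1]]
      idx_mat[id, pairs[, 2]] <- pairs[, 1]
    }
  }
  new("StarMSA", reference = representative, members = ids,
      aln = aln_mat, index = idx_mat)
}

#' Sum-of-pairs conservation scores (AL2CO style)
#'
#' Per column, the raw score is the mean BLOSUM62 substitution value over all
#' unordered pairs of non-gap residues; columns with fewer than two non-gap
#' cells receive the minimum raw score of the scoreable columns. Raw scores
#' are normalized to z-scores over columns and clamped to [-2, 2] (all zero
#' when the column variance vanishes), then mapped to blue-to-yellow colors
#' with [scoreToRgb()].
#'
#' @param msa a \linkS4class{StarMSA} with at least two rows.
#' @param matrix substitution matrix (defaults to BLOSUM62).
#' @return a \linkS4class{ConservationProfile}.
#' @export
al2coScores <- function(msa, matrix = NULL) {
  if (length(msa@members) < 2L)
    stop("conservation scoring needs an alignment with at least 2 rows")
  if (is.null(matrix)) matrix <- blosum62()
  nc <- ncol(msa@aln)
  raw <- rep(NA_real_, nc)
  for (col in seq_len(nc)) {
    res <- msa@aln[, col]
    res <- res[res != "-"]
    if (length(res) < 2L) next
    prs <- utils::combn(res, 2)
    raw[col] <- mean(matrix[cbind(prs[1, ], prs[2, ])])
  }
  if (all(is.na(raw))) {
    raw[] <- 0
  } else {
    raw[is.na(raw)] <- min(raw, na.rm = TRUE)
  }
  s <- stats::sd(raw)
  normalized <- if (length(raw) < 2 || s == 0) rep(0, nc)
                else clamp((raw - mean(raw)) / s, -2, 2)
  new("ConservationProfile", raw = raw, normalized = normalized,
      rgb = scoreToRgb(normalized))
}

#' Map a normalized conservation score to an RGB color
#'
#' Linear interpolation from blue \code{[0, 0, 255]} at score -2 to yellow
#' \code{[255, 255, 0]} at score +2, with components rounded half-up to
#' integers. Inputs are clamped to [-2, 2].
#'
#' @param normalized numeric score(s).
#' @return integer matrix (length(normalized) x 3) with columns r, g, b.
#' @examples
#' scoreToRgb(c(-2, 0, 2))
#' @export
scoreToRgb <- function(normalized) {
  t <- (clamp(normalized, -2, 2) + 2) / 4
  m <- cbind(r = round_half_up(255 * t),
             g = round_half_up(255 * t),
             b = round_half_up(255 * (1 - t)))
  storage.mode(m) <- "integer"
  m
}

#' Emit a PyMOL residue-coloring script
#'
#' One \code{set_color}/\code{color} command pair per aligned member residue,
#' carrying the RGB of that residue's alignment column. Residues outside the
#' alignment get a configurable default color. Ordering (member id, then
#' residue) and formatting are deterministic, so reruns are byte-identical.
#'
#' @param members list of \linkS4class{PeptideChain} cluster members.
#' @param profile a \linkS4class{ConservationProfile} for the cluster's MSA.
#' @param msa the matching \linkS4class{StarMSA}.
#' @param defaultColor integer RGB triple for unaligned residues
#'   (default grey, c(128, 128, 128)).
#' @return character scalar: the script text.
#' @export
emitColoringScript <- function(members, profile, msa,
                               defaultColor = c(128L, 128L, 128L)) {
  members <- .chain_index(members)
  out <- c("# conservation coloring: blue [0,0,255] = diverse, yellow [255,255,0] = conserved",
           sprintf("set_color drp_default, [%d, %d, %d]",
                   defaultColor[1], defaultColor[2], defaultColor[3]))
  for (id in sort(msa@members)) {
    ch <- members[[id]]
    colored <- rep(NA_integer_, nResidues(ch))
    for (col in seq_len(ncol(msa@index))) {
      i <- msa@index[id, col]
      if (!is.na(i)) colored[i] <- col
    }
    for (i in seq_len(nResidues(ch))) {
      resi <- ch@resIds[i]
      if (is.na(colored[i])) {
        out <- c(out, sprintf("color drp_default, %s and resi %s", id, resi))
      } else {
        rgb <- profile@rgb[colored[i], ]
        cname <- sprintf("drp_%s_%s", id, resi)
        out <- c(out,
                 sprintf("set_color %s, [%d, %d, %d]",
                         cname, rgb[1], rgb[2], rgb[3]),
                 sprintf("color %s, %s and resi %s", cname, id, resi))
      }
    }
  }
  paste(c(out, ""), collapse = "\n")
}

#' Conservation TSV for a cluster
#'
#' Tabulates, per aligned member residue: the member id, residue id, MSA
#' column, normalized conservation score and RGB components.
#'
#' @inheritParams emitColoringScript
#' @return data.frame.
#' @export
conservationTable <- function(members, profile, msa) {
  members <- .chain_index(members)
  rows <- list()
  for (id in sort(msa@members)) {
    ch <- members[[id]]
    for (col in seq_len(ncol(msa@index))) {
      i <- msa@index[id, col]
      if (is.na(i)) next
      rows[[length(rows) + 1L]] <- data.frame(
        member = id, residue = ch@resIds[i], column = col,
        normalized_score = round(profile@normalized[col], 4),
        r = profile@rgb[col, 1], g = profile@rgb[col, 2],
        b = profile@rgb[col, 3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
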