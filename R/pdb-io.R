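#' Parse PDB text into peptide chains
#'
#' Reads the first model of a PDB-format entry into one
#' \linkS4class{PeptideChain} per chain. ATOM records are parsed with
#' \pkg{bio3d}; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken toward altloc \code{"A"}); residues without a
#' C-alpha atom are dropped and positions renumbered contiguously; insertion
#' codes are preserved in the residue ordering. Disulfide bonds are the union
#' of SSBOND-declared pairs and geometric pairs (S-gamma distance at most
#' \code{sgCutoff}), with greedy nearest-first pairing so each cysteine joins
#' at most one bond. \code{nBondsAny} additionally counts inter-chain bonds
#' touching the chain (lone insulin B chains thereby still qualify as DRPs).
#'
#' @param pdbText character; PDB file content (single string or vector of
#'   lines).
#' @param pdbId 4-character PDB identifier; defaults to the HEADER idCode
#'   when present, else \code{"xxxx"}. Chain ids become
#'   \code{tolower(pdbId)} + chain letter, e.g. \code{"2crdA"}.
#' @param sgCutoff geometric S-gamma/S-gamma bond cutoff in Angstrom
#'   (default 2.5; the canonical bond length is about 2.05).
#' @return list of \linkS4class{PeptideChain} objects.
#' @export
parsePdbChains <- function(pdbText, pdbId = NULL, sgCutoff = 2.5) {
  lines <- if (length(pdbText) == 1L && grepl("\n", pdbText))
    strsplit(pdbText, "\n", fixed = TRUE)[[1]] else pdbText

  if (is.null(pdbId)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    pdbId <- if (length(hdr) && nchar(hdr[1]) >= 66)
      trimws(substr(hdr[1], 63, 66)) else ""
    if (!nzchar(pdbId)) pdbId <- "xxxx"
  }
  pdbId <- tolower(pdbId)

  # restrict to the first model (everything before the first ENDMDL)
  model_used <- 1L
  mstart <- which(startsWith(lines, "MODEL"))
  if (length(mstart)) {
    model_used <- suppressWarnings(as.integer(substr(lines[mstart[1]], 11, 14)))
    if (is.na(model_used)) model_used <- 1L
    mend <- which(startsWith(lines, "ENDMDL"))
    if (length(mend)) {
      drop <- setdiff(seq_along(lines), seq_len(mend[1]))
      lines_first <- lines[c(seq_len(mend[1]),
                             drop[!startsWith(lines[drop], "ATOM") &
                                  !startsWith(lines[drop], "HETATM") &
                                  !startsWith(lines[drop], "TER")])]
    } else lines_first <- lines
  } else lines_first <- lines

  atom_idx <- which(startsWith(lines_first, "ATOM"))
  if (!length(atom_idx)) stop("no ATOM records found (empty input)")
  bad <- atom_idx[is.na(suppressWarnings(
    as.numeric(substr(lines_first[atom_idx], 31, 38))))]
  if (length(bad))
    stop("unreadable ATOM record at line ", bad[1], ": ",
         trimws(lines_first[bad[1]]))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines_first, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found (empty input)")
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: per (chain,resno,insert,atom name) keep the
  # highest-occupancy record, ties toward the alphabetically first altloc
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(akey, unique(akey)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no chains with C-alpha atoms (empty input)")
  sg <- at[at$elety == "SG", , drop = FALSE]
  sg_lookup <- paste(sg$chain, sg$resno, sg$insert, sep = "\r")

  chains <- list()
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]   # file order, insertions kept
    n <- nrow(cc)
    camat <- as.matrix(cc[, c("x", "y", "z")])
    dimnames(camat) <- NULL
    sgmat <- matrix(NA_real_, n, 3)
    key <- paste(cc$chain, cc$resno, cc$insert, sep = "\r")
    hit <- match(key, sg_lookup)
    ok <- !is.na(hit) & cc$resid == "CYS"
    if (any(ok))
      sgmat[ok, ] <- as.matrix(sg[hit[ok], c("x", "y", "z")])
    chains[[ch]] <- list(
      chain_letter = ch,
      res_key = key,
      resNames = cc$resid,
      resIds = paste0(cc$resno, cc$insert),
      ca = camat, sg = sgmat,
      sequence = paste(aa3_to_1(cc$resid), collapse = "")
    )
  }

  ssbond <- .parse_ssbond(lines_first)
  bonds <- .detect_disulfides(chains, ssbond, sgCutoff)

  out <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    cid <- paste0(pdbId, ch$chain_letter)
    intra <- bonds[bonds$chain1 == ch$chain_letter &
                   bonds$chain2 == ch$chain_letter, , drop = FALSE]
    bdf <- data.frame(i = pmin(intra$pos1, intra$pos2),
                      j = pmax(intra$pos1, intra$pos2),
                      provenance = intra$provenance,
                      stringsAsFactors = FALSE)
    bdf <- bdf[order(bdf$i), , drop = FALSE]
    rownames(bdf) <- NULL
    n_any <- sum(bonds$chain1 == ch$chain_letter |
                 bonds$chain2 == ch$chain_letter)
    out[[k]] <- new("PeptideChain",
                    chainId = cid,
                    sequence = ch$sequence,
                    resNames = ch$resNames,
                    resIds = ch$resIds,
                    ca = ch$ca, sg = ch$sg,
                    bonds = bdf,
                    nBondsAny = as.integer(n_any),
                    modelUsed = as.integer(model_used))
  }
  names(out) <- vapply(out, chainId, character(1))
  out
}

.parse_ssbond <- function(lines) {
  ss <- lines[startsWith(lines, "SSBOND")]
  if (!length(ss))
    return(data.frame(res1 = character(0), chain1 = character(0),
                      res2 = character(0), chain2 = character(0),
                      name1 = character(0), name2 = character(0)))
  pad <- function(x, n) formatC(x, width = n, flag = "-")
  ss <- vapply(ss, pad, character(1), n = 40)
  data.frame(
    name1  = trimws(substr(ss, 12, 14)),
    chain1 = substr(ss, 16, 16),
    res1   = paste0(trimws(substr(ss, 18, 21)), trimws(substr(ss, 22, 22))),
    name2  = trimws(substr(ss, 26, 28)),
    chain2 = substr(ss, 30, 30),
    res2   = paste0(trimws(substr(ss, 32, 35)), trimws(substr(ss, 36, 36))),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Resolve declared + geometric disulfide bonds across all chains of an entry.
# Returns a data.frame of bonds with chain letters, residue positions (1-based
# within each chain) and provenance.
.detect_disulfides <- function(chains, ssbond, sgCutoff) {
  # global table of cysteines with resolved S-gamma
  cys <- do.call(rbind, lapply(chains, function(ch) {
    ok <- which(ch$resNames == "CYS" & is.finite(ch$sg[, 1]))
    if (!length(ok)) return(NULL)
    data.frame(chain = ch$chain_letter, pos = ok,
               res = paste0(ch$resIds[ok]),
               x = ch$sg[ok, 1], y = ch$sg[ok, 2], z = ch$sg[ok, 3],
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chain1 = character(0), pos1 = integer(0),
                      chain2 = character(0), pos2 = integer(0),
                      provenance = character(0))
  if (is.null(cys) || nrow(cys) < 1) return(empty)
  ckey <- paste(cys$chain, cys$res, sep = "\r")
  # all residues, to tell "points at a non-cysteine" from "unresolved"
  allres <- do.call(rbind, lapply(chains, function(ch)
    data.frame(key = paste(ch$chain_letter, ch$resIds, sep = "\r"),
               name = ch$resNames, stringsAsFactors = FALSE)))

  declared <- empty
  if (nrow(ssbond)) {
    for (r in seq_len(nrow(ssbond))) {
      k1 <- paste(ssbond$chain1[r], ssbond$res1[r], sep = "\r")
      k2 <- paste(ssbond$chain2[r], ssbond$res2[r], sep = "\r")
      named_res <- allres$name[match(c(k1, k2), allres$key)]
      if (ssbond$name1[r] != "CYS" || ssbond$name2[r] != "CYS" ||
          any(!is.na(named_res) & named_res != "CYS")) {
        warning("SSBOND record names a non-cysteine residue; skipped")
        next
      }
      i <- match(k1, ckey)
      j <- match(k2, ckey)
      if (is.na(i) || is.na(j)) {
        warning("SSBOND record references an unresolved cysteine; skipped")
        next
      }
      declared <- rbind(declared, data.frame(
        chain1 = cys$chain[i], pos1 = cys$pos[i],
        chain2 = cys$chain[j], pos2 = cys$pos[j],
        provenance = "ssbond_record", stringsAsFactors = FALSE))
    }
  }

  dist_of <- function(i, j)
    sqrt(sum((as.numeric(cys[i, c("x", "y", "z")]) -
              as.numeric(cys[j, c("x", "y", "z")]))^2))
  idx_of <- function(chain, pos) which(cys$chain == chain & cys$pos == pos)

  # enforce one bond per cysteine among declared records: keep the
  # geometrically closer pair when a cysteine appears twice
  if (nrow(declared) > 1) {
    dd <- vapply(seq_len(nrow(declared)), function(r)
      dist_of(idx_of(declared$chain1[r], declared$pos1[r]),
              idx_of(declared$chain2[r], declared$pos2[r])), numeric(1))
    keep <- rep(TRUE, nrow(declared))
    used <- character(0)
    for (r in order(dd)) {
      k1 <- paste(declared$chain1[r], declared$pos1[r])
      k2 <- paste(declared$chain2[r], declared$pos2[r])
      if (k1 %in% used || k2 %in% used) {
        keep[r] <- FALSE
        warning("conflicting SSBOND records pair a cysteine twice; ",
                "keeping the geometrically closer pair")
      } else used <- c(used, k1, k2)
    }
    declared <- declared[keep, , drop = FALSE]
  }

  paired <- c(paste(declared$chain1, declared$pos1),
              paste(declared$chain2, declared$pos2))
  free <- which(!(paste(cys$chain, cys$pos) %in% paired))

  geom <- empty
  if (length(free) >= 2) {
    cand <- t(utils::combn(free, 2))
    d <- vapply(seq_len(nrow(cand)), function(r)
      dist_of(cand[r, 1], cand[r, 2]), numeric(1))
    ok <- d <= sgCutoff
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    used <- integer(0)
    for (r in order(d)) {            # greedy nearest-first
      if (cand[r, 1] %in% used || cand[r, 2] %in% used) next
      used <- c(used, cand[r, ])
      geom <- rbind(geom, data.frame(
        chain1 = cys$chain[cand[r, 1]], pos1 = cys$pos[cand[r, 1]],
        chain2 = cys$chain[cand[r, 2]], pos2 = cys$pos[cand[r, 2]],
        provenance = "geometric", stringsAsFactors = FALSE))
    }
  }
  rbind(declared, geom)
}

#' Read peptide chains from PDB files
#'
#' @param paths character vector of PDB file paths, or a single directory
#'   (all \code{*.pdb} files within, sorted by name). The PDB identifier is
#'   taken from each file name (stem), falling back to the HEADER record.
#' @param sgCutoff geometric disulfide cutoff, see [parsePdbChains()].
#' @return list of \linkS4class{PeptideChain} objects, named by chain id.
#' @export
readPeptideChains <- function(paths, sgCutoff = 2.5) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.pdb$", full.names = TRUE))
  out <- list()
  for (p in paths) {
    stem <- sub("\\.pdb$", "", basename(p))
    pdbId <- if (nchar(stem) == 4L) stem else NULL
    out <- c(out, parsePdbChains(readLines(p), pdbId = pdbId,
                                 sgCutoff = sgCutoff))
  }
  out
}

#' Filter chains to disulfide-rich peptides
#'
#' Retains chains with fewer than \code{maxResidues} residues (strict) and a
#' disulfide bond count between \code{minBonds} and \code{maxBonds}
#' inclusive. By default the count includes inter-chain bonds involving the
#' chain, so e.g. an insulin B chain with only inter-chain bonds qualifies;
#' set \code{bondCounting = "intra_chain_only"} to count intra-chain bonds
#' only. Input order is preserved.
#'
#' @param chains list of \linkS4class{PeptideChain}.
#' @param maxResidues exclusive residue-count bound (default 50).
#' @param minBonds,maxBonds inclusive bond-count range (defaults 1 and 4).
#' @param bondCounting \code{"any_involving_chain"} (default) or
#'   \code{"intra_chain_only"}.
#' @return filtered list of chains.
#' @export
filterDrps <- function(chains, maxResidues = 50L, minBonds = 1L,
                       maxBonds = 4L,
                       bondCounting = c("any_involving_chain",
                                        "intra_chain_only")) {
  bondCounting <- match.arg(bondCounting)
  stopifnot(minBonds >= 1L, minBonds <= maxBonds, maxResidues > 0L)
  keep <- vapply(chains, function(ch) {
    nb <- if (bondCounting == "any_involving_chain") nBondsAny(ch)
          else nrow(disulfides(ch))
    nResidues(ch) < maxResidues && nb >= minBonds && nb <= maxBonds
  }, logical(1))
  chains[keep]
}

#' Discard structurally identical duplicate chains
#'
#' Within each group of mutually identical chains (pairwise 100% sequence
#' identity and native overlap 1.0 with both denominators), only the chain
#' with the lexicographically smallest id survives. Chains are pre-bucketed
#' by exact sequence string, so alignments are only computed within buckets;
#' this cannot change the result because 100% identity over the longer
#' denominator forces byte-identical sequences.
#'
#' @param chains list of \linkS4class{PeptideChain}.
#' @param alignFun pairwise aligner, by default [alignPair()].
#' @return deduplicated list, input order preserved.
#' @export
deduplicateDrps <- function(chains, alignFun = alignPair) {
  if (length(chains) < 2L) return(chains)
  ids <- vapply(chains, chainId, character(1))
  seqs <- vapply(chains, chainSeq, character(1))
  parent <- seq_along(chains)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  for (sq in unique(seqs[duplicated(seqs)])) {
    grp <- which(seqs == sq)
    for (u in seq_along(grp)[-1]) for (v in seq_len(u - 1)) {
      i <- grp[v]; j <- grp[u]
      aln <- alignFun(chains[[i]], chains[[j]])
      la <- nResidues(chains[[i]]); lb <- nResidues(chains[[j]])
      if (sequenceIdentity(aln, seqs[i], seqs[j]) == 100 &&
          nativeOverlap(aln, la, lb, "longer") == 1 &&
          nativeOverlap(aln, la, lb, "shorter") == 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }

  root <- vapply(seq_along(chains), find, integer(1))
  keep <- logical(length(chains))
  for (r in unique(root)) {
    members <- which(root == r)
    keep[members[order(ids[members])[1]]] <- TRUE
  }
  chains[keep]
}

#' Write and read the chain cache (JSON)
#'
#' One JSON record per chain with deterministic field order: id, sequence,
#' residue ids/names, C-alpha and S-gamma coordinates (Angstrom, 3 decimal
#' places), intra-chain bonds, the any-bond count and the model number.
#'
#' @param chains list of \linkS4class{PeptideChain}.
#' @param path file path.
#' @return \code{readChainsJson} returns the list of chains (named by id);
#'   \code{writeChainsJson} returns \code{path} invisibly.
#' @export
writeChainsJson <- function(chains, path) {
  recs <- lapply(chains, function(ch) {
    sg <- sgCoords(ch)
    list(id = chainId(ch),
         sequence = chainSeq(ch),
         res_ids = ch@resIds,
         res_names = ch@resNames,
         ca = round(caCoords(ch), 3),
         sg = round(sg, 3),
         bonds = disulfides(ch),
         n_bonds_any = nBondsAny(ch),
         model = ch@modelUsed)
  })
  names(recs) <- NULL
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname writeChainsJson
#' @export
readChainsJson <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  out <- lapply(seq_len(nrow(recs)), function(k) {
    r <- recs[k, ]
    bonds <- r$bonds[[1]]
    if (is.null(bonds) || !length(bonds))
      bonds <- data.frame(i = integer(0), j = integer(0),
                          provenance = character(0))
    ca <- r$ca[[1]]; sg <- r$sg[[1]]
    ca <- matrix(as.numeric(ca), ncol = 3)
    sg <- matrix(as.numeric(sg), ncol = 3)
    new("PeptideChain",
        chainId = r$id, sequence = r$sequence,
        resNames = unlist(r$res_names), resIds = unlist(r$res_ids),
        ca = ca, sg = sg,
        bonds = data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                           provenance = as.character(bonds$provenance)),
        nBondsAny = as.integer(r$n_bonds_any),
        modelUsed = as.integer(r$model))
  })
  names(out) <- vapply(out, chainId, character(1))
  out
}

#' Emit PDB-format text for peptide chains
#'
#' Writes a minimal, valid PDB entry (HEADER, SSBOND, ATOM, TER, END) for the
#' given chains of one entry. Only C-alpha atoms (and cysteine S-gamma atoms)
#' are written, which is all the package's metrics consume. The output
#' round-trips through [parsePdbChains()] with identical sequence, bond
#' topology, and coordinates to the millesimal Angstrom.
#'
#' @param chains a \linkS4class{PeptideChain} or list of them (same entry).
#' @return character scalar of PDB text.
#' @export
pdbText <- function(chains) {
  if (is(chains, "PeptideChain")) chains <- list(chains)
  pdbId <- toupper(substr(chainId(chains[[1]]), 1, 4))
  out <- sprintf("HEADER    DE NOVO PEPTIDE                         01-JAN-00   %s", pdbId)

  ser <- 0L
  for (ch in chains) {
    b <- disulfides(ch)
    letter <- substr(chainId(ch), 5, 5)
    for (r in seq_len(nrow(b))) {
      ser <- ser + 1L
      out <- c(out, sprintf("SSBOND %3d CYS %s %4s    CYS %s %4s",
                            ser, letter, ch@resIds[b$i[r]],
                            letter, ch@resIds[b$j[r]]))
    }
  }

  aser <- 0L
  for (ch in chains) {
    letter <- substr(chainId(ch), 5, 5)
    ca <- caCoords(ch); sg <- sgCoords(ch)
    for (i in seq_len(nrow(ca))) {
      aser <- aser + 1L
      out <- c(out, .atom_line(aser, "CA", ch@resNames[i], letter,
                               ch@resIds[i], ca[i, ], "C"))
      if (is.finite(sg[i, 1])) {
        aser <- aser + 1L
        out <- c(out, .atom_line(aser, "SG", ch@resNames[i], letter,
                                 ch@resIds[i], sg[i, ], "S"))
      }
    }
    out <- c(out, sprintf("TER   %5d      %3s %s", aser + 1L,
                          ch@resNames[nrow(ca)], letter))
  }
  paste(c(out, "END", ""), collapse = "\n")
}

.atom_line <- function(serial, name, resName, chain, resId, xyz, element) {
  icode <- " "
  resno <- resId
  if (grepl("[A-Za-z]$", resId)) {
    icode <- substr(resId, nchar(resId), nchar(resId))
    resno <- substr(resId, 1, nchar(resId) - 1)
  }
  sprintf("ATOM  %5d  %-3s %3s %s%4s%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resName, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}
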