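#' Specification of one synthetic fold family
#'
#' Describes a family of small single-chain peptide structures built from an
#' idealized template backbone (canonical C-alpha geometry, ~3.8 Angstrom
#' consecutive spacing) with S-gamma pseudo-atoms placed so bonded cysteine
#' pairs sit at about 2.05 Angstrom. Members are the template plus isotropic
#' Gaussian coordinate noise, a random rigid motion, and optional loop-length
#' variation; sequences are random except for cysteines at bond positions.
#'
#' @param family_name ground-truth label; two specs may share a label (e.g.
#'   knottin loop-length variants that belong to one true family).
#' @param template one of \code{"beta_hairpin"}, \code{"helix_loop_helix"},
#'   \code{"circular_loop"}, \code{"knottin_core"}.
#' @param n_members number of members to generate.
#' @param n_residues residue count of the base member (< 50; for
#'   \code{knottin_core} this is 20 core residues plus the loop).
#' @param n_bonds number of disulfide bonds (1-4); positions are picked
#'   automatically from template geometry unless \code{bond_layout} is given.
#' @param bond_layout optional integer matrix/list of (i, j) cysteine
#'   positions; validated against achievable S-gamma geometry.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom (per
#'   axis).
#' @param loop_indel_range integer length-2 vector; per-member residues
#'   inserted (positive) or deleted (negative) in the designated loop.
#' @param id_prefix two lowercase characters used to build chain ids
#'   (\code{"<prefix><NN>A"}).
#' @param fold optional SCOP-style fold annotation for the family
#'   (knottins: \code{"g.3"}).
#' @param seed integer RNG seed for the family stream.
#' @return validated list of class \code{"FamilySpec"}.
#' @export
familySpec <- function(family_name, template, n_members, n_residues,
                       n_bonds = 2L, bond_layout = NULL, noise_sigma = 0.3,
                       loop_indel_range = c(0L, 0L), id_prefix,
                       fold = NA_character_, seed = 1L) {
  template <- match.arg(template, c("beta_hairpin", "helix_loop_helix",
                                    "circular_loop", "knottin_core"))
  stopifnot(n_members >= 1L, n_residues < 50L, n_bonds >= 1L, n_bonds <= 4L,
            noise_sigma >= 0, length(loop_indel_range) == 2L,
            loop_indel_range[1] <= loop_indel_range[2],
            nchar(id_prefix) == 2L)
  structure(list(family_name = family_name, template = template,
                 n_members = as.integer(n_members),
                 n_residues = as.integer(n_residues),
                 n_bonds = as.integer(n_bonds), bond_layout = bond_layout,
                 noise_sigma = noise_sigma,
                 loop_indel_range = as.integer(loop_indel_range),
                 id_prefix = id_prefix, fold = fold, seed = as.integer(seed)),
            class = "FamilySpec")
}

# ---- idealized template backbones -----------------------------------------

# m points strictly between P and Q on a half-ellipse bulging along u; the
# bulge height grows with m so loops of different lengths occupy different
# regions of space.
.arc_points <- function(P, Q, u, m) {
  if (m <= 0L) return(matrix(numeric(0), 0, 3))
  e1 <- Q - P; L <- sqrt(sum(e1^2)); e1 <- e1 / L
  u <- u - sum(u * e1) * e1
  u <- u / sqrt(sum(u^2))
  a <- L / 2; mid <- (P + Q) / 2
  h <- max(2.0, 1.3 * m)
  th <- pi * seq_len(m) / (m + 1)
  t(vapply(th, function(t) mid - a * cos(t) * e1 + h * sin(t) * u,
           numeric(3)))
}

# A template backbone: C-alpha coordinates for the base residue count plus
# `indel` extra (or fewer) residues absorbed entirely by the designated loop
# segment. Returns ca, the base loop indices, and loop_end (base index after
# which downstream positions shift by the indel).
.template_ca <- function(template, n, indel = 0L) {
  zig <- function(i) 0.6 * (-1)^i
  switch(template,
    beta_hairpin = {
      h <- (n - 2L) %/% 2L
      turn <- n - 2L * h + indel
      if (turn < 1L) stop("loop deletion leaves no turn residues")
      s1 <- t(vapply(seq_len(h), function(i)
        c((i - 1) * 3.63, 0, zig(i)), numeric(3)))
      s2 <- t(vapply(seq_len(h), function(i)
        c((h - i) * 3.63, 4.8, -zig(i)), numeric(3)))
      tp <- .arc_points(s1[h, ], s2[1, ], c(1, 0, 0), turn)
      list(ca = rbind(s1, tp, s2), loop = h + seq_len(n - 2L * h),
           loop_end = n - h)
    },
    helix_loop_helix = {
      h <- (n - 4L) %/% 2L
      loop <- n - 2L * h + indel
      if (loop < 1L) stop("loop deletion leaves no loop residues")
      hx <- function(i, y0, sgn)
        c(1.5 * (i - 1), y0 + 2.3 * cos(sgn * 100 * pi / 180 * (i - 1)),
          2.3 * sin(sgn * 100 * pi / 180 * (i - 1)))
      h1 <- t(vapply(seq_len(h), hx, numeric(3), y0 = 0, sgn = 1))
      h2 <- t(vapply(seq_len(h), function(i) hx(h - i + 1, 10, -1),
                     numeric(3)))
      lp <- .arc_points(h1[h, ], h2[1, ], c(0, 0.3, 1), loop)
      list(ca = rbind(h1, lp, h2), loop = h + seq_len(n - 2L * h),
           loop_end = n - h)
    },
    circular_loop = {
      # collapsed macrocycle: two runs joined by rounded caps (radius r), a
      # saddle-like z twist keeps it non-planar and distinct from hairpins
      if (indel != 0L)
        stop("circular_loop does not support loop indels")
      r <- 3.5
      P <- 3.8 * n                      # path perimeter
      L <- (P - 2 * pi * r) / 2         # straight-run length
      if (L <= 0) stop("circular_loop needs more residues")
      s <- 3.8 * (seq_len(n) - 1)
      xy <- t(vapply(s, function(si) {
        if (si < L) c(si, -r)
        else if (si < L + pi * r) {
          a <- (si - L) / r - pi / 2
          c(L + r * cos(a), r * sin(a))
        } else if (si < 2 * L + pi * r) c(L - (si - L - pi * r), r)
        else {
          a <- (si - 2 * L - pi * r) / r + pi / 2
          c(r * cos(a), r * sin(a))
        }
      }, numeric(2)))
      z <- 3.0 * sin(2 * (2 * pi * s / P))
      list(ca = cbind(xy, z), loop = integer(0), loop_end = n)
    },
    knottin_core = {
      nl <- n - 20L + indel
      if (nl < 2L) stop("knottin_core needs a loop of at least 2 residues")
      s1 <- t(vapply(1:5, function(i) c((i - 1) * 3.6, 0, zig(i)), numeric(3)))
      tn <- rbind(c(4 * 3.6 + 2.6, 1.4, 0.5), c(4 * 3.6 + 2.6, 3.4, -0.5))
      s2 <- t(vapply(1:5, function(i) c((5 - i) * 3.6, 4.8, -zig(i)), numeric(3)))
      cn <- rbind(c(-2.5, 4.0, 1.8), c(-4.0, 2.5, 4.0))
      tl <- t(vapply(1:6, function(i)
        c(1.5 * (i - 1), 2.4 + 1.8 * cos(100 * pi / 180 * i),
          6.5 + 1.8 * sin(100 * pi / 180 * i)), numeric(3)))
      lp <- .arc_points(cn[2, ], tl[1, ], c(-0.6, -1, 0.5), nl)
      list(ca = rbind(s1, tn, s2, cn, lp, tl), loop = 14L + seq_len(n - 20L),
           loop_end = n - 6L)
    },
    stop("unknown template"))
}

# Pick n_bonds disulfide positions from the base template geometry: pairs at
# sequence separation >= 5 outside the loop whose C-alpha distance allows an
# S-gamma bridge; longest-range achievable pairs first, one bond per residue.
.pick_bonds <- function(ca, loop, n_bonds) {
  n <- nrow(ca)
  cand <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  cand <- cand[cand[, 2] - cand[, 1] >= 5L, , drop = FALSE]
  cand <- cand[!(cand[, 1] %in% loop) & !(cand[, 2] %in% loop), , drop = FALSE]
  d <- sqrt(rowSums((ca[cand[, 1], , drop = FALSE] -
                     ca[cand[, 2], , drop = FALSE])^2))
  ok <- d >= 4.2 & d <= 7.2
  cand <- cand[ok, , drop = FALSE]
  ord <- order(-(cand[, 2] - cand[, 1]), cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used <- integer(0); picked <- NULL
  for (r in seq_len(nrow(cand))) {
    if (cand[r, 1] %in% used || cand[r, 2] %in% used) next
    picked <- rbind(picked, cand[r, ])
    used <- c(used, cand[r, ])
    if (nrow(picked) == n_bonds) break
  }
  if (is.null(picked) || nrow(picked) < n_bonds)
    stop("geometrically impossible bond layout: template offers only ",
         if (is.null(picked)) 0L else nrow(picked), " achievable bond(s)")
  picked[order(picked[, 1]), , drop = FALSE]
}

# Place S-gamma pseudo-atoms so each bonded pair sits 2.05 Angstrom apart on
# the segment between the two C-alpha atoms.
.place_sg <- function(ca, bonds) {
  sg <- matrix(NA_real_, nrow(ca), 3)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    v <- ca[j, ] - ca[i, ]
    D <- sqrt(sum(v^2))
    if (D < 2.1 || D > 8.0)
      stop("geometrically impossible bond layout: C-alpha pair (", i, ",", j,
           ") at ", round(D, 2), " Angstrom")
    u <- v / D
    off <- (D - 2.05) / 2
    sg[i, ] <- ca[i, ] + off * u
    sg[j, ] <- ca[j, ] - off * u
  }
  sg
}

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate one synthetic fold family
#'
#' Builds the family's idealized template, places disulfide S-gamma atoms,
#' and emits \code{n_members} perturbed copies (Gaussian noise, random rigid
#' motion, loop indels within the stated range). Deterministic for a fixed
#' spec seed, independent of platform.
#'
#' @param spec a [familySpec()].
#' @return list of \linkS4class{PeptideChain} (ids
#'   \code{"<prefix><NN>A"}).
#' @export
generateFamily <- function(spec) {
  base <- .template_ca(spec$template, spec$n_residues)
  bonds <- if (is.null(spec$bond_layout)) {
    .pick_bonds(base$ca, base$loop, spec$n_bonds)
  } else {
    bl <- spec$bond_layout
    if (is.list(bl)) bl <- do.call(rbind, bl)
    bl <- cbind(pmin(bl[, 1], bl[, 2]), pmax(bl[, 1], bl[, 2]))
    if (any(bl %in% base$loop))
      stop("bond_layout may not place cysteines in the variable loop")
    bl
  }

  with_seed(spec$seed, {
    lapply(seq_len(spec$n_members), function(m) {
      k <- if (spec$loop_indel_range[1] == spec$loop_indel_range[2])
        spec$loop_indel_range[1]
      else sample(seq(spec$loop_indel_range[1], spec$loop_indel_range[2]), 1L)
      tpl <- .template_ca(spec$template, spec$n_residues, k)
      b <- bonds
      b[b > base$loop_end] <- b[b > base$loop_end] + k
      sg <- .place_sg(tpl$ca, b)

      n <- nrow(tpl$ca)
      ca <- tpl$ca + matrix(rnorm(3 * n, sd = spec$noise_sigma), n, 3)
      sgn <- sg + matrix(rnorm(3 * n, sd = spec$noise_sigma), n, 3)
      sgn[!is.finite(sg)] <- NA_real_
      R <- .random_rotation(); tr <- runif(3, -20, 20)
      ca <- t(R %*% t(ca)) + matrix(tr, n, 3, byrow = TRUE)
      sgn <- t(R %*% t(sgn)) + matrix(tr, n, 3, byrow = TRUE)
      sgn[!is.finite(sg)] <- NA_real_

      letters1 <- sample(setdiff(names(.aa1to3), "C"), n, replace = TRUE)
      letters1[as.vector(b)] <- "C"
      id <- sprintf("%s%02dA", spec$id_prefix, m)
      new("PeptideChain",
          chainId = id,
          sequence = paste(letters1, collapse = ""),
          resNames = aa1_to_3(letters1),
          resIds = as.character(seq_len(n)),
          ca = ca, sg = sgn,
          bonds = data.frame(i = as.integer(b[, 1]), j = as.integer(b[, 2]),
                             provenance = rep("ssbond_record", nrow(b))),
          nBondsAny = nrow(b), modelUsed = 1L)
    })
  })
}

# Displace a contiguous residue segment of a chain by a constant vector
# (plus nothing else), returning a new chain under a new id.
.displace_segment <- function(chain, seg, shift, new_id) {
  ca <- caCoords(chain); sg <- sgCoords(chain)
  ca[seg, ] <- ca[seg, , drop = FALSE] +
    matrix(shift, length(seg), 3, byrow = TRUE)
  ok <- is.finite(sg[, 1]) & seq_len(nrow(sg)) %in% seg
  if (any(ok))
    sg[ok, ] <- sg[ok, , drop = FALSE] +
      matrix(shift, sum(ok), 3, byrow = TRUE)
  initialize(chain, chainId = new_id, ca = ca, sg = sg)
}

# Unit vector orthogonal to a segment's axis and to its offset from the
# molecular centroid (out-of-plane for sheet-like templates).
.perp_shift <- function(ca, seg) {
  axis <- ca[max(seg), ] - ca[min(seg), ]
  ref <- colMeans(ca[seg, , drop = FALSE]) - colMeans(ca)
  u <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1])
  if (sqrt(sum(u^2)) < 1e-6) u <- c(-axis[2], axis[1], axis[3])
  u / sqrt(sum(u^2))
}

# Keep a contiguous residue window of a chain (window must contain at least
# one complete disulfide bond so the truncation still qualifies as a DRP).
.truncate_chain <- function(chain, window, new_id) {
  b <- disulfides(chain)
  keep <- b$i %in% window & b$j %in% window
  b <- b[keep, , drop = FALSE]
  if (!nrow(b)) stop("truncation window contains no complete disulfide bond")
  b$i <- match(b$i, window); b$j <- match(b$j, window)
  letters1 <- strsplit(chainSeq(chain), "")[[1]][window]
  new("PeptideChain",
      chainId = new_id,
      sequence = paste(letters1, collapse = ""),
      resNames = chain@resNames[window],
      resIds = as.character(seq_along(window)),
      ca = caCoords(chain)[window, , drop = FALSE],
      sg = sgCoords(chain)[window, , drop = FALSE],
      bonds = b, nBondsAny = nrow(b), modelUsed = 1L)
}

#' Generate a labeled clustering benchmark
#'
#' Generates every family, checks that distinct families are structurally
#' separated (native overlap at most \code{collision_cutoff} between members
#' of different ground-truth labels; specs sharing a label are exempt, and
#' knottin loop variants are verified to sit below the 0.7 full-length
#' cutoff while their disulfide distance stays below 2.0 Angstrom), and
#' optionally engineers singleton decoys:
#' \itemize{
#' \item a pair \code{dx01A}/\code{dx02A} derived from the first member of
#'   \code{host_longer}: \code{dx01A} has one segment displaced so its best
#'   overlap to the host stays at or above 0.7 (absorbed by the
#'   longer-denominator singleton pass) while \code{dx02A} has a second
#'   segment displaced and never qualifies against the original family
#'   members (it can still follow \code{dx01A} in the second pass once that
#'   decoy has joined the host cluster); the two decoys are mutually more
#'   similar than either is to the host, so initial clustering leaves them
#'   as their own small cluster;
#' \item a truncation \code{dy01A} of the first member of
#'   \code{host_shorter}, below 0.7 with the longer denominator but 1.0 with
#'   the shorter one (absorbed only by the shorter-denominator pass).
#' }
#'
#' @param specs list of [familySpec()]; per-family seeds are derived from
#'   \code{seed}.
#' @param seed integer root seed.
#' @param withDecoys generate the three decoys (default TRUE).
#' @param host_longer,host_shorter family names hosting the decoys.
#' @param validate run the generation-time separation self-checks.
#' @param collision_cutoff maximal allowed cross-family native overlap (0.6).
#' @return list with \code{chains} (named list), \code{truth} (named
#'   character: chain id to family label, decoys excluded), \code{decoys}
#'   (character ids) and \code{folds} (named character annotations).
#' @export
generateBenchmark <- function(specs, seed = 1L, withDecoys = TRUE,
                              host_longer = "hairpin_large",
                              host_shorter = "helix_loop_helix",
                              validate = TRUE, collision_cutoff = 0.6) {
  if (length(specs) < 2L) stop("need at least two family specs")
  fam_seeds <- with_seed(seed, sample.int(1e6L, length(specs)))
  families <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- fam_seeds[i]
    families[[i]] <- generateFamily(sp)
  }

  chains <- unlist(families, recursive = FALSE)
  names(chains) <- vapply(chains, chainId, character(1))
  truth <- structure(
    rep(vapply(specs, `[[`, character(1), "family_name"),
        vapply(specs, `[[`, integer(1), "n_members")),
    names = names(chains))
  folds <- structure(
    rep(vapply(specs, `[[`, character(1), "fold"),
        vapply(specs, `[[`, integer(1), "n_members")),
    names = names(chains))
  folds <- folds[!is.na(folds)]

  if (validate) .check_separation(families, specs, collision_cutoff)

  decoys <- character(0)
  if (withDecoys) {
    fam_names <- vapply(specs, `[[`, character(1), "family_name")
    hostL <- families[[match(host_longer, fam_names)]][[1]]
    hostS <- families[[match(host_shorter, fam_names)]][[1]]

    nL <- nResidues(hostL)
    k1 <- round(0.26 * nL); k2 <- round(0.21 * nL)
    seg1 <- (nL - k1 + 1L):nL
    seg2 <- (nL - k1 - k2 + 1L):(nL - k1)
    # shift perpendicular to the segment axis so the displaced residues
    # cannot re-register onto neighbouring positions of the template
    d1 <- .displace_segment(hostL, seg1,
                            12 * .perp_shift(caCoords(hostL), seg1), "dx01A")
    d2 <- .displace_segment(d1, seg2,
                            -12 * .perp_shift(caCoords(d1), seg2), "dx02A")

    nS <- nResidues(hostS)
    L <- ceiling(0.6 * nS)
    b1 <- disulfides(hostS)
    start <- NA_integer_
    for (r in seq_len(nrow(b1))) {
      if (b1$j[r] - b1$i[r] + 1L <= L) {
        start <- max(1L, min(b1$i[r], nS - L + 1L)); break
      }
    }
    if (is.na(start)) stop("no disulfide bond fits in the truncation window")
    d3 <- .truncate_chain(hostS, start:(start + L - 1L), "dy01A")

    if (validate) .check_decoys(d1, d2, d3, hostL, hostS)
    decoys <- c("dx01A", "dx02A", "dy01A")
    chains <- c(chains, list(dx01A = d1, dx02A = d2, dy01A = d3))
  }

  list(chains = chains, truth = truth, decoys = decoys, folds = folds)
}

.check_separation <- function(families, specs, collision_cutoff) {
  for (i in seq_along(specs)[-1]) for (j in seq_len(i - 1)) {
    a <- families[[i]][[1]]; b <- families[[j]][[1]]
    aln <- alignPair(a, b)
    ov <- nativeOverlap(aln, nResidues(a), nResidues(b), "longer")
    same <- specs[[i]]$family_name == specs[[j]]$family_name
    if (!same && ov > collision_cutoff)
      stop("family collision: ", specs[[i]]$family_name, " vs ",
           specs[[j]]$family_name, " overlap ", round(ov, 2),
           " exceeds ", collision_cutoff, "; use more distinct templates")
    if (same) {
      # template-level properties: compare noise-free realizations so the
      # check reflects the design, not one noisy draw
      ta <- specs[[i]]; ta$noise_sigma <- 0; ta$n_members <- 1L; ta$seed <- 1L
      tb <- specs[[j]]; tb$noise_sigma <- 0; tb$n_members <- 1L; tb$seed <- 1L
      a0 <- generateFamily(ta)[[1]]; b0 <- generateFamily(tb)[[1]]
      ov0 <- nativeOverlap(alignPair(a0, b0), nResidues(a0), nResidues(b0),
                           "longer")
      if (ov0 >= 0.7)
        stop("loop-variant specs of '", specs[[i]]$family_name,
             "' are not separated below the 0.7 full-length cutoff (",
             round(ov0, 2), ")")
      ss <- disulfideDistance(a0, b0)$score
      if (ss >= 2.0)
        stop("loop-variant specs of '", specs[[i]]$family_name,
             "' do not share core bond geometry (disulfide distance ",
             round(ss, 2), " Angstrom)")
    }
  }
}

.check_decoys <- function(d1, d2, d3, hostL, hostS) {
  ovL <- function(x, y)
    nativeOverlap(alignPair(x, y), nResidues(x), nResidues(y), "longer")
  o1 <- ovL(d1, hostL)
  if (o1 < 0.7 || o1 > 0.8)
    stop("longer-singleton decoy off target: overlap ", round(o1, 3))
  o2 <- ovL(d2, hostL)
  if (o2 >= 0.7) stop("second decoy must stay below the cutoff: ", round(o2, 3))
  o12 <- ovL(d1, d2)
  if (o12 <= o1) stop("decoy pair must be mutually closest: ", round(o12, 3))
  o3 <- ovL(d3, hostS)
  if (o3 >= 0.7) stop("truncation decoy too similar (longer): ", round(o3, 3))
  o3s <- nativeOverlap(alignPair(d3, hostS), nResidues(d3), nResidues(hostS),
                       "shorter")
  if (o3s < 0.7) stop("truncation decoy must qualify with the shorter denominator")
}

#' The default six-family benchmark
#'
#' Two beta-hairpin families of different size, a helix-loop-helix family, a
#' circular-loop (conotoxin-like) family, and two knottin-core specs sharing
#' one ground-truth label but differing in loop length (4 vs 14 residues),
#' all with 10 members at 0.3 Angstrom coordinate noise, plus the three
#' engineered singleton decoys.
#'
#' @param seed integer root seed.
#' @param n_members members per family (default 10).
#' @param noise_sigma coordinate noise in Angstrom (default 0.3).
#' @param withDecoys include the singleton decoys (default TRUE).
#' @return see [generateBenchmark()].
#' @export
defaultBenchmark <- function(seed = 1L, n_members = 10L, noise_sigma = 0.3,
                             withDecoys = TRUE) {
  specs <- list(
    familySpec("hairpin_small", "beta_hairpin", n_members, 22L, 2L,
               noise_sigma = noise_sigma, id_prefix = "hs", fold = "b.1",
               seed = 1L),
    familySpec("hairpin_large", "beta_hairpin", n_members, 38L, 3L,
               noise_sigma = noise_sigma, id_prefix = "hl", fold = "b.2",
               seed = 1L),
    familySpec("helix_loop_helix", "helix_loop_helix", n_members, 28L, 2L,
               noise_sigma = noise_sigma, id_prefix = "hh", fold = "a.1",
               seed = 1L),
    familySpec("circular_loop", "circular_loop", n_members, 12L, 1L,
               noise_sigma = noise_sigma, id_prefix = "cl", fold = "g.9",
               seed = 1L),
    familySpec("knottin", "knottin_core", n_members, 24L, 3L,
               noise_sigma = noise_sigma, loop_indel_range = c(0L, 2L),
               id_prefix = "ka", fold = "g.3", seed = 1L),
    familySpec("knottin", "knottin_core", n_members, 38L, 3L,
               noise_sigma = noise_sigma, loop_indel_range = c(0L, 2L),
               id_prefix = "kb", fold = "g.3", seed = 1L))
  generateBenchmark(specs, seed = seed, withDecoys = withDecoys)
}

#' Write a benchmark to disk as PDB files plus a truth table
#'
#' One PDB file per chain (named by the 4-character id stem) and a
#' \code{truth.tsv} (chain id, family label; decoys marked
#' \code{"decoy"}) plus \code{folds.tsv}.
#'
#' @param benchmark a [generateBenchmark()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in benchmark$chains) {
    stem <- substr(chainId(ch), 1, 4)
    writeLines(pdbText(ch), file.path(dir, paste0(stem, ".pdb")))
  }
  ids <- names(benchmark$chains)
  lab <- ifelse(ids %in% benchmark$decoys, "decoy",
                benchmark$truth[ids])
  utils::write.table(data.frame(chain_id = ids, family = lab),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f <- benchmark$folds
  utils::write.table(data.frame(chain_id = names(f), fold = unname(f)),
                     file.path(dir, "folds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
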