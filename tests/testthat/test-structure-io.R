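# Hand-written PDB fragments for parser behaviour checks.

atom_line <- function(serial, name, res, chain, resno, x, y, z,
                      occ = 1, alt = " ", icode = " ", elem = "C") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, res, chain, resno, icode, x, y, z, occ, 0, elem)
}

test_that("first-model policy and per-chain extraction", {
  lines <- c(
    "HEADER    TOXIN                                   01-JAN-90   9XYZ",
    "MODEL        1",
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "CA", "SER", "A", 3, 7.6, 0, 0),
    atom_line(4, "CA", "ALA", "B", 1, 0, 10, 0),
    atom_line(5, "CA", "GLY", "B", 2, 3.8, 10, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "CA", "ALA", "A", 1, 99, 99, 99),
    "ENDMDL", "END")
  chains <- parsePdbChains(lines)
  expect_length(chains, 2)
  expect_named(chains, c("9xyzA", "9xyzB"))
  expect_equal(chains[["9xyzA"]]@modelUsed, 1L)
  expect_equal(chainSeq(chains[["9xyzA"]]), "AGS")
  expect_equal(caCoords(chains[["9xyzA"]])[1, ], c(0, 0, 0))
})

test_that("residues without C-alpha are dropped and renumbered contiguously", {
  lines <- c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "N", "SER", "A", 3, 7.6, 0, 0, elem = "N"),  # no CA
    atom_line(4, "CA", "THR", "A", 4, 11.4, 0, 0),
    "END")
  ch <- parsePdbChains(lines, pdbId = "9xyz")[[1]]
  expect_equal(nResidues(ch), 3)
  expect_equal(chainSeq(ch), "AGT")
  expect_equal(ch@resIds, c("1", "2", "4"))
})

test_that("altlocs resolve to highest occupancy and insertion codes are kept", {
  lines <- c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.6, alt = "B"),
    atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(4, "CA", "SER", "A", 2, 6.0, 0, 0, icode = "A"),
    "END")
  ch <- parsePdbChains(lines, pdbId = "9xyz")[[1]]
  expect_equal(nResidues(ch), 3)
  expect_equal(caCoords(ch)[1, 1], 5)      # occupancy 0.6 wins
  expect_equal(ch@resIds, c("1", "2", "2A"))
})

test_that("parse errors name the offending line; empty input errors", {
  bad <- c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END")
  bad[1] <- sub("   0.000", "  xx.000", bad[1], fixed = TRUE)
  expect_error(parsePdbChains(bad), "line 1")
  expect_error(parsePdbChains(c("REMARK nothing here", "END")), "no ATOM")
})

test_that("disulfide detection combines SSBOND records and geometry", {
  # two cysteines at S-gamma distance 2.04 with no SSBOND: geometric bond
  mk_cys_lines <- function(d) c(
    atom_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
    atom_line(2, "SG", "CYS", "A", 1, 0, 2, 0, elem = "S"),
    atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(4, "CA", "GLY", "A", 3, 7.6, 0, 0),
    atom_line(5, "CA", "CYS", "A", 4, 11.4, 0, 0),
    atom_line(6, "SG", "CYS", "A", 4, d, 2, 0, elem = "S"),
    "END")
  ch <- parsePdbChains(mk_cys_lines(2.04), pdbId = "9xyz")[[1]]
  expect_equal(nrow(disulfides(ch)), 1)
  expect_equal(disulfides(ch)$provenance, "geometric")
  expect_equal(disulfides(ch)$i, 1L)
  expect_equal(disulfides(ch)$j, 4L)

  # 6.0 Angstrom apart: no bond
  ch <- parsePdbChains(mk_cys_lines(6.0), pdbId = "9xyz")[[1]]
  expect_equal(nrow(disulfides(ch)), 0)
  expect_equal(nBondsAny(ch), 0L)

  # SSBOND naming a non-cysteine is skipped with a warning
  lines <- c("SSBOND   1 CYS A    2    CYS A    3",
             mk_cys_lines(2.04))
  expect_warning(parsePdbChains(lines, pdbId = "9xyz"), "non-cysteine")
})

test_that("inter-chain bonds count toward nBondsAny but not bonds", {
  # insulin-like arrangement: chain A holds one intra-chain bond and two
  # cysteines bonded across to chain B
  ca_a <- matrix(c(seq(0, by = 3.8, length.out = 8), rep(0, 16)), 8, 3)
  ca_b <- matrix(c(seq(0, by = 3.8, length.out = 4), rep(50, 8)), 4, 3)
  sg_a <- matrix(NA_real_, 8, 3)
  sg_a[1, ] <- c(0, 1, 0); sg_a[3, ] <- c(0, 3, 0)      # intra pair, 2.0 apart
  sg_a[5, ] <- c(10, 1, 0); sg_a[7, ] <- c(20, 1, 0)    # bonded into chain B
  sg_b <- matrix(NA_real_, 4, 3)
  sg_b[1, ] <- c(10, 1, 2); sg_b[3, ] <- c(20, 1, 2)
  seq_a <- "CACACACA"; seq_b <- "CACA"
  A <- mk_chain(ca_a, id = "9insA", seq = seq_a, sg = sg_a)
  B <- mk_chain(ca_b, id = "9insB", seq = seq_b, sg = sg_b)
  chains <- parsePdbChains(pdbText(list(A, B)), pdbId = "9ins")
  expect_equal(nrow(disulfides(chains[["9insA"]])), 1)
  expect_equal(nBondsAny(chains[["9insA"]]), 3L)
  expect_equal(nBondsAny(chains[["9insB"]]), 2L)
})

test_that("the DRP filter applies strict and inclusive bounds", {
  mk_len <- function(n, nb, id) mk_chain(matrix(rnorm(3 * n), n, 3), id = id,
                                         n_bonds_any = nb)
  chains <- list(mk_len(50, 2, "aa50A"), mk_len(49, 1, "aa49A"),
                 mk_len(30, 5, "aa30A"), mk_len(30, 4, "aa31A"),
                 mk_len(10, 0, "aa10A"))
  kept <- filterDrps(chains)
  expect_equal(vapply(kept, chainId, character(1)), c("aa49A", "aa31A"))
  # idempotence
  expect_identical(vapply(filterDrps(kept), chainId, character(1)),
                   vapply(kept, chainId, character(1)))
  # intra-only counting ignores inter-chain bonds
  expect_length(filterDrps(chains, bondCounting = "intra_chain_only"), 0)
})

test_that("deduplication keeps one lexicographically smallest survivor", {
  base <- hairpin_family(1, n_res = 18, sigma = 0)[[1]]
  copies <- list(methods::initialize(base, chainId = "1aaaB"),
                 methods::initialize(base, chainId = "1bbbA"),
                 methods::initialize(base, chainId = "1aaaA"))
  out <- deduplicateDrps(copies)
  expect_equal(vapply(out, chainId, character(1)), "1aaaA")

  # same sequence but a displaced loop: both retained
  seg <- 14:18
  shifted <- drpclust:::.displace_segment(
    base, seg, 9 * drpclust:::.perp_shift(caCoords(base), seg), "1cccA")
  out <- deduplicateDrps(list(base, shifted))
  expect_length(out, 2)
})

test_that("dedup removes exactly the identical group members", {
  fam <- hairpin_family(6, n_res = 18, sigma = 0.4, seed = 23)
  dup <- methods::initialize(fam[[2]], chainId = "zz01A")
  dup2 <- methods::initialize(fam[[2]], chainId = "zz02A")
  dup3 <- methods::initialize(fam[[2]], chainId = "zz03A")
  dup4 <- methods::initialize(fam[[4]], chainId = "zz04A")
  chains <- c(fam, list(dup, dup2, dup3, dup4))   # 10 chains, 4 duplicates
  out <- deduplicateDrps(chains)
  expect_length(out, 6)
  ids <- vapply(out, chainId, character(1))
  expect_true(all(vapply(fam, chainId, character(1)) %in% ids))
  # exhaustive pairwise check: no identical pair survives
  for (i in seq_along(out)[-1]) for (j in seq_len(i - 1)) {
    a <- out[[i]]; b <- out[[j]]
    aln <- alignPair(a, b)
    same <- sequenceIdentity(aln, chainSeq(a), chainSeq(b)) == 100 &&
      nativeOverlap(aln, nResidues(a), nResidues(b), "longer") == 1
    expect_false(same)
  }
})

test_that("PDB text round-trips through the parser", {
  fam <- generateFamily(familySpec("rt", "knottin_core", 1, 26L, 3L,
                                   noise_sigma = 0.3, id_prefix = "rt",
                                   seed = 14))
  ch <- fam[[1]]
  back <- parsePdbChains(pdbText(ch))
  expect_length(back, 1)
  rt <- back[[1]]
  expect_equal(chainId(rt), chainId(ch))
  expect_equal(chainSeq(rt), chainSeq(ch))
  expect_equal(disulfides(rt)$i, disulfides(ch)$i)
  expect_equal(disulfides(rt)$j, disulfides(ch)$j)
  expect_lt(max(abs(caCoords(rt) - caCoords(ch))), 1e-3)
  ok <- is.finite(sgCoords(ch)[, 1])
  expect_lt(max(abs(sgCoords(rt)[ok, ] - sgCoords(ch)[ok, ])), 1e-3)
})

test_that("the JSON chain cache round-trips", {
  fam <- hairpin_family(2, n_res = 16, sigma = 0.2, seed = 3)
  f <- tempfile(fileext = ".json")
  writeChainsJson(fam, f)
  back <- readChainsJson(f)
  expect_equal(names(back), vapply(fam, chainId, character(1)))
  expect_equal(chainSeq(back[[1]]), chainSeq(fam[[1]]))
  expect_lt(max(abs(caCoords(back[[2]]) - caCoords(fam[[2]]))), 1e-3)
  expect_equal(disulfides(back[[1]]), disulfides(fam[[1]]))
  # deterministic bytes
  f2 <- tempfile(fileext = ".json")
  writeChainsJson(fam, f2)
  expect_identical(readLines(f), readLines(f2))
})
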