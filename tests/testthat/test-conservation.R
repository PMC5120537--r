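toy_msa <- function(rows, reference = names(rows)[1]) {
  aln <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  idx <- t(apply(aln, 1, function(r) {
    out <- rep(NA_integer_, length(r))
    out[r != "-"] <- seq_len(sum(r != "-"))
    out
  }))
  rownames(idx) <- rownames(aln) <- names(rows)
  new("StarMSA", reference = reference, members = names(rows),
      aln = aln, index = idx)
}

test_that("star alignment of identical chains is rectangular and gap-free", {
  fam <- hairpin_family(1, n_res = 14, sigma = 0, seed = 19)
  mk <- function(id) methods::initialize(fam[[1]], chainId = id)
  members <- list(mk("cp01A"), mk("cp02A"), mk("cp03A"))
  msa <- buildStarMsa(members, "cp02A")
  expect_equal(dim(msa@aln), c(3L, 14L))
  expect_false(any(msa@aln == "-"))
  expect_true(all(msa@aln == msa@aln[rep(1, 3), ]))
})

test_that("members missing reference residues show gaps, extras are dropped", {
  fam <- hairpin_family(1, n_res = 14, sigma = 0, seed = 19)
  ref <- fam[[1]]
  shorter <- mk_chain(caCoords(ref)[1:11, ], id = "sh01A",
                      seq = substr(chainSeq(ref), 1, 11))
  msa <- buildStarMsa(list(ref, shorter), chainId(ref))
  expect_equal(sum(msa@aln["sh01A", ] == "-"), 3)
  expect_equal(msa@aln["sh01A", 1:11],
               strsplit(substr(chainSeq(ref), 1, 11), "")[[1]],
               ignore_attr = TRUE)
  # known correspondences: rigid copies align column-for-column
  moved <- move_chain(ref, id = "mv01A")
  msa2 <- buildStarMsa(list(ref, moved, shorter), chainId(ref))
  expect_equal(unname(msa2@index["mv01A", ]), 1:14)
  expect_error(buildStarMsa(list(), "x"), "empty cluster")
})

test_that("sum-of-pairs scores match hand arithmetic", {
  b62 <- drpclust:::blosum62()
  msa <- toy_msa(c(aa01A = "CWAG", aa02A = "CWAV", aa03A = "CFG-"))
  prof <- al2coScores(msa)
  raw_hand <- c(
    mean(c(b62["C", "C"], b62["C", "C"], b62["C", "C"])),
    mean(c(b62["W", "W"], b62["W", "F"], b62["W", "F"])),
    mean(c(b62["A", "A"], b62["A", "G"], b62["A", "G"])),
    b62["G", "V"])                       # gap pair excluded
  expect_equal(prof@raw, unname(raw_hand), tolerance = 1e-9)
  z <- (raw_hand - mean(raw_hand)) / sd(raw_hand)
  expect_equal(prof@normalized, unname(pmin(pmax(z, -2), 2)),
               tolerance = 1e-9)
  # conserved cysteine column scores strictly above the mixed column
  expect_gt(prof@raw[1], prof@raw[4])
})

test_that("degenerate columns and zero variance are handled", {
  # a column with fewer than 2 residues takes the minimum raw score
  msa <- toy_msa(c(aa01A = "CWA", aa02A = "CW-", aa03A = "C--"))
  prof <- al2coScores(msa)
  expect_equal(prof@raw[3], min(prof@raw[1:2]))
  # identical composition in every column: all normalized scores zero
  msa2 <- toy_msa(c(aa01A = "CCC", aa02A = "CCC"))
  prof2 <- al2coScores(msa2)
  expect_equal(prof2@normalized, rep(0, 3))
  expect_error(al2coScores(toy_msa(c(aa01A = "CW"))), "2 rows")
})

test_that("normalized scores center at zero before clamping", {
  set.seed(71)
  for (rep in 1:5) {
    rows <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "W", "V"), 12, replace = TRUE),
            collapse = ""), character(1))
    names(rows) <- sprintf("aa%02dA", 1:4)
    prof <- al2coScores(toy_msa(rows))
    z <- (prof@raw - mean(prof@raw)) / sd(prof@raw)
    expect_lt(abs(mean(z)), 1e-9)
  }
})

test_that("adding an identical row preserves the raw score ordering", {
  msa <- toy_msa(c(aa01A = "CWAGH", aa02A = "CFAVH", aa03A = "CWGVY"))
  prof1 <- al2coScores(msa)
  msa2 <- toy_msa(c(aa01A = "CWAGH", aa02A = "CFAVH", aa03A = "CWGVY",
                    aa04A = "CWGVY"))
  prof2 <- al2coScores(msa2)
  for (i in 1:4) for (j in (i + 1):5) {
    if (prof1@raw[i] > prof1@raw[j] + 1e-12)
      expect_gte(prof2@raw[i], prof2@raw[j] - 1e-12)
  }
})

test_that("the color scale runs from blue through grey to yellow", {
  expect_equal(scoreToRgb(-2)[1, ], c(r = 0L, g = 0L, b = 255L))
  expect_equal(scoreToRgb(2)[1, ], c(r = 255L, g = 255L, b = 0L))
  expect_equal(scoreToRgb(0)[1, ], c(r = 128L, g = 128L, b = 128L))
  # out-of-range scores clamp to the ends
  expect_equal(scoreToRgb(-5), scoreToRgb(-2))
  # monotone: higher scores are never bluer
  s <- seq(-2, 2, by = 0.05)
  m <- scoreToRgb(s)
  expect_true(all(diff(m[, "r"]) >= 0))
  expect_true(all(diff(m[, "g"]) >= 0))
  expect_true(all(diff(m[, "b"]) <= 0))
})

test_that("coloring scripts are deterministic with one command per residue", {
  ca <- cbind(c(0, 3.8, 7.6), 0, c(0, 1, 0))
  members <- list(mk_chain(ca, id = "aa01A", seq = "CWA"),
                  mk_chain(ca, id = "aa02A", seq = "CFA"))
  msa <- buildStarMsa(members, "aa01A")
  prof <- al2coScores(msa)
  script <- emitColoringScript(members, prof, msa)
  lines <- strsplit(script, "\n")[[1]]
  expect_length(grep("^color drp_aa0", lines), 6)   # 2 members x 3 columns
  expect_identical(script, emitColoringScript(members, prof, msa))

  # most conserved column carries the most yellow color
  tb <- conservationTable(members, prof, msa)
  best <- tb[which.max(tb$normalized_score), ]
  expect_equal(best$r, max(tb$r))
})
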