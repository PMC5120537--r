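test_that("family generation is deterministic down to the PDB bytes", {
  sp <- familySpec("hp", "beta_hairpin", 3, 18L, 2L, noise_sigma = 0.4,
                   id_prefix = "hp", seed = 77)
  f1 <- generateFamily(sp)
  f2 <- generateFamily(sp)
  expect_identical(lapply(f1, pdbText), lapply(f2, pdbText))
  # a different seed moves the coordinates
  sp2 <- sp; sp2$seed <- 78L
  expect_false(identical(pdbText(generateFamily(sp2)[[1]]), pdbText(f1[[1]])))
})

test_that("noise-free members overlap perfectly despite rigid motions", {
  fam <- generateFamily(familySpec("hp", "beta_hairpin", 4, 20L, 2L,
                                   noise_sigma = 0, id_prefix = "hp",
                                   seed = 13))
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- alignPair(fam[[i]], fam[[j]])
    expect_equal(nativeOverlap(aln, 20, 20, "longer"), 1.0)
  }
})

test_that("members at 0.3 Angstrom noise stay above 0.9 overlap", {
  fam <- generateFamily(familySpec("hp", "beta_hairpin", 4, 20L, 2L,
                                   noise_sigma = 0.3, id_prefix = "hp",
                                   seed = 13))
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- alignPair(fam[[i]], fam[[j]])
    expect_gte(nativeOverlap(aln, 20, 20, "longer"), 0.9)
  }
})

test_that("bonded S-gamma pairs sit at the canonical bond length", {
  fam <- generateFamily(familySpec("kn", "knottin_core", 2, 24L, 3L,
                                   noise_sigma = 0, id_prefix = "kn",
                                   seed = 13))
  ch <- fam[[1]]
  b <- disulfides(ch)
  expect_equal(nrow(b), 3)
  for (r in seq_len(nrow(b))) {
    d <- sqrt(sum((sgCoords(ch)[b$i[r], ] - sgCoords(ch)[b$j[r], ])^2))
    expect_equal(d, 2.05, tolerance = 1e-6)
  }
  # strand interiors keep canonical C-alpha spacing; turns stay compact
  ca <- caCoords(ch)
  steps <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_lt(max(abs(steps[c(1:4, 8:11)] - 3.8)), 0.05)
  expect_true(all(steps > 1.5 & steps < 5.5))
})

test_that("impossible bond layouts are rejected", {
  expect_error(
    generateFamily(familySpec("hp", "beta_hairpin", 1, 20L, 2L,
                              bond_layout = rbind(c(1L, 9L)),
                              id_prefix = "hp", seed = 1)),
    "impossible")
  # a layout inside the variable loop is rejected up front
  expect_error(
    generateFamily(familySpec("kn", "knottin_core", 1, 26L, 1L,
                              bond_layout = rbind(c(15L, 20L)),
                              id_prefix = "kn", seed = 1)),
    "loop")
})

test_that("the default benchmark has labeled families plus decoys", {
  bm <- defaultBenchmark(seed = 2, n_members = 4)
  expect_length(bm$chains, 6 * 4 + 3)
  expect_length(bm$truth, 24)
  expect_setequal(bm$decoys, c("dx01A", "dx02A", "dy01A"))
  expect_equal(sum(bm$folds == "g.3"), 8)
  expect_setequal(unique(bm$truth),
                  c("hairpin_small", "hairpin_large", "helix_loop_helix",
                    "circular_loop", "knottin"))
  # knottin loop variants share one label but differ in loop length
  expect_equal(unname(bm$truth[c("ka01A", "kb01A")]), rep("knottin", 2))
  ka <- bm$chains[["ka01A"]]; kb <- bm$chains[["kb01A"]]
  ov <- nativeOverlap(alignPair(ka, kb), nResidues(ka), nResidues(kb),
                      "longer")
  expect_lt(ov, 0.7)
  expect_lt(disulfideDistance(ka, kb)$score, 2.0)
})

test_that("benchmark files are accepted unchanged by the structure reader", {
  bm <- defaultBenchmark(seed = 2, n_members = 2)
  dir <- tempfile()
  expect_no_warning(writeBenchmark(bm, dir))
  expect_no_warning(chains <- readPeptideChains(dir))
  expect_setequal(names(chains), names(bm$chains))
  for (id in c("hs01A", "ka01A", "dy01A")) {
    expect_equal(chainSeq(chains[[id]]), chainSeq(bm$chains[[id]]))
    expect_equal(nrow(disulfides(chains[[id]])),
                 nrow(disulfides(bm$chains[[id]])))
    expect_lt(max(abs(caCoords(chains[[id]]) - caCoords(bm$chains[[id]]))),
              1e-3)
  }
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE)
  expect_equal(nrow(truth), length(bm$chains))
  expect_equal(sum(truth$family == "decoy"), 3)
})

test_that("clustering accuracy degrades with generator noise", {
  specs <- function(sig) list(
    familySpec("hairpin_large", "beta_hairpin", 4, 38L, 3L,
               noise_sigma = sig, id_prefix = "hl", fold = "b.2", seed = 1L),
    familySpec("helix_loop_helix", "helix_loop_helix", 4, 28L, 2L,
               noise_sigma = sig, id_prefix = "hh", fold = "a.1", seed = 1L),
    familySpec("circular_loop", "circular_loop", 4, 12L, 1L,
               noise_sigma = sig, id_prefix = "cl", fold = "g.9", seed = 1L))
  ari_at <- function(sig) {
    bm <- generateBenchmark(specs(sig), seed = 9, withDecoys = FALSE,
                            validate = FALSE)
    res <- runInitialClustering(bm$chains, pipelineConfig())
    pred <- rep(NA_character_, length(bm$truth))
    names(pred) <- names(bm$truth)
    mem <- clusterMembers(res)
    for (k in seq_along(mem)) pred[mem[[k]]] <- as.character(k)
    mclust::adjustedRandIndex(bm$truth, pred[names(bm$truth)])
  }
  a_low <- ari_at(0.3); a_high <- ari_at(2.0)
  expect_equal(a_low, 1.0)
  expect_gte(a_low, a_high)
  expect_lt(a_high, 1.0)
})
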