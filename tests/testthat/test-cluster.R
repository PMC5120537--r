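sim_matrix <- function(ids, pairs) {
  n <- length(ids)
  v <- diag(n); dimnames(v) <- list(ids, ids)
  for (p in pairs) v[p[[1]], p[[2]]] <- v[p[[2]], p[[1]]] <- p[[3]]
  new("PairMatrix", values = v, kind = "similarity")
}

test_that("a hand-executed example clusters as expected", {
  pm <- sim_matrix(c("A", "B", "C"),
                   list(list("A", "B", 0.9), list("A", "C", 0.2),
                        list("B", "C", 0.2)))
  res <- averageLinkage(pm, 0.7)
  expect_equal(canonical_partition(clusterMembers(res$partition)),
               list(c("A", "B"), "C"))
  expect_equal(res$trace$value, 0.9)
  # every similarity below the cutoff: all singletons
  pm2 <- sim_matrix(c("A", "B", "C"),
                    list(list("A", "B", 0.5), list("A", "C", 0.2),
                         list("B", "C", 0.2)))
  res2 <- averageLinkage(pm2, 0.7)
  expect_equal(clusterSizes(res2$partition), c(1L, 1L, 1L))
  # a merge at exactly the cutoff is allowed
  res3 <- averageLinkage(sim_matrix(c("A", "B"), list(list("A", "B", 0.7))),
                         0.7)
  expect_equal(clusterSizes(res3$partition), 2L)
})

test_that("random matrices match the brute-force oracle", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    pm <- random_similarity_matrix(n)
    cutoff <- runif(1, 0.3, 0.8)
    ours <- canonical_partition(clusterMembers(averageLinkage(pm, cutoff)$partition))
    oracle <- bf_average_linkage(pairValues(pm), "similarity", cutoff)
    expect_equal(ours, oracle)
    # distance mode against the same oracle on 1 - s
    vd <- 1 - pairValues(pm); diag(vd) <- 0
    pmd <- new("PairMatrix", values = vd, kind = "distance")
    ours_d <- canonical_partition(clusterMembers(averageLinkage(pmd, 1 - cutoff)$partition))
    expect_equal(ours_d, oracle)
  }
})

test_that("partitions agree with hclust/cutree average linkage", {
  set.seed(43)
  for (rep in 1:10) {
    pm <- random_similarity_matrix(7)
    v <- pairValues(pm)
    cutoff <- 0.6
    ours <- canonical_partition(clusterMembers(averageLinkage(pm, cutoff)$partition))
    hc <- stats::hclust(stats::as.dist(1 - v), method = "average")
    grp <- stats::cutree(hc, h = 1 - cutoff)
    oracle <- canonical_partition(unname(split(names(grp), grp)))
    expect_equal(ours, oracle)
  }
})

test_that("the partition is invariant under input label order", {
  set.seed(47)
  pm <- random_similarity_matrix(8)
  ref <- canonical_partition(clusterMembers(averageLinkage(pm, 0.6)$partition))
  for (rep in 1:5) {
    perm <- sample(8)
    v <- pairValues(pm)[perm, perm]
    pmx <- new("PairMatrix", values = v, kind = "similarity")
    got <- canonical_partition(clusterMembers(averageLinkage(pmx, 0.6)$partition))
    expect_equal(got, ref)
  }
})

test_that("lowering a similarity cutoff never increases the cluster count", {
  set.seed(53)
  for (rep in 1:5) {
    pm <- random_similarity_matrix(8)
    counts <- vapply(seq(0.9, 0.5, by = -0.1), function(cut)
      length(clusterMembers(averageLinkage(pm, cut)$partition)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("linkage traces are monotone", {
  set.seed(59)
  for (rep in 1:5) {
    pm <- random_similarity_matrix(8)
    tr <- averageLinkage(pm, 0)$trace      # force full merge sequence
    if (nrow(tr) > 1) expect_true(all(diff(tr$value) <= 1e-12))
    vd <- 1 - pairValues(pm); diag(vd) <- 0
    trd <- averageLinkage(new("PairMatrix", values = vd, kind = "distance"),
                          2)$trace
    if (nrow(trd) > 1) expect_true(all(diff(trd$value) >= -1e-12))
  }
})

test_that("matrix building evaluates each unordered pair once and caches", {
  fam <- hairpin_family(5, n_res = 16, sigma = 0.3, seed = 61)
  calls <- new.env(); calls$n <- 0L
  metric <- function(a, b) {
    calls$n <- calls$n + 1L
    nativeOverlap(alignPair(a, b), nResidues(a), nResidues(b), "longer")
  }
  f <- tempfile(fileext = ".tsv")
  pm <- buildPairMatrix(fam, metric, "similarity", cacheFile = f)
  expect_equal(calls$n, 10L)                 # 5 choose 2
  expect_true(file.exists(f))
  bytes1 <- readLines(f)

  # reload: no further metric evaluations, identical matrix
  pm2 <- buildPairMatrix(fam, metric, "similarity", cacheFile = f)
  expect_equal(calls$n, 10L)
  expect_equal(pairValues(pm2), round(pairValues(pm), 6))

  # rebuild from scratch: byte-identical cache file
  unlink(f)
  buildPairMatrix(fam, metric, "similarity", cacheFile = f)
  expect_identical(readLines(f), bytes1)

  # identical chains give off-diagonal 1.0
  triplet <- list(fam[[1]],
                  methods::initialize(fam[[1]], chainId = "zz01A"),
                  methods::initialize(fam[[1]], chainId = "zz02A"))
  pm3 <- buildPairMatrix(triplet, metric, "similarity")
  expect_true(all(pairValues(pm3) == 1))
})
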