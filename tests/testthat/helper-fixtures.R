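# Shared fixture builders and independent oracles.

# Minimal PeptideChain from raw coordinates.
mk_chain <- function(ca, id = "tst1A", seq = NULL, bonds = NULL, sg = NULL,
                     n_bonds_any = NULL) {
  n <- nrow(ca)
  if (is.null(seq)) seq <- paste(rep("A", n), collapse = "")
  letters1 <- strsplit(seq, "")[[1]]
  if (is.null(sg)) sg <- matrix(NA_real_, n, 3)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0),
                        provenance = character(0))
  if (is.null(n_bonds_any)) n_bonds_any <- nrow(bonds)
  new("PeptideChain", chainId = id, sequence = seq,
      resNames = drpclust:::aa1_to_3(letters1),
      resIds = as.character(seq_len(n)), ca = ca, sg = sg, bonds = bonds,
      nBondsAny = as.integer(n_bonds_any), modelUsed = 1L)
}

# A random proper rotation built independently of the package (QR).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion to every coordinate of a chain.
move_chain <- function(chain, R = rand_rotation(), tr = rnorm(3, sd = 10),
                       id = chainId(chain)) {
  ca <- caCoords(chain); sg <- sgCoords(chain)
  mv <- function(m) {
    out <- t(R %*% t(m)) + matrix(tr, nrow(m), 3, byrow = TRUE)
    out[!is.finite(m)] <- NA_real_
    out
  }
  methods::initialize(chain, chainId = id, ca = mv(ca), sg = mv(sg))
}

canonical_partition <- function(clusters) {
  cl <- unname(lapply(clusters, function(m) sort(unname(m))))
  cl[order(vapply(cl, `[`, character(1), 1))]
}

# Independent brute-force average-linkage clustering (naive accumulation,
# no incremental updates), used as the oracle for averageLinkage().
bf_average_linkage <- function(v, kind, cutoff) {
  cl <- as.list(rownames(v))
  repeat {
    k <- length(cl)
    if (k < 2) break
    best <- NULL; bestval <- NA_real_
    for (x in 1:(k - 1)) for (y in (x + 1):k) {
      s <- 0; cnt <- 0
      for (i in cl[[x]]) for (j in cl[[y]]) { s <- s + v[i, j]; cnt <- cnt + 1 }
      avg <- s / cnt
      better <- if (is.null(best)) TRUE
                else if (kind == "similarity") avg > bestval else avg < bestval
      if (better) { best <- c(x, y); bestval <- avg }
    }
    ok <- if (kind == "similarity") bestval >= cutoff else bestval <= cutoff
    if (!ok) break
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  canonical_partition(cl)
}

random_similarity_matrix <- function(n) {
  ids <- sprintf("s%02d", seq_len(n))
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2)
  v[upper.tri(v)] <- vals
  v <- v + t(v)
  diag(v) <- 1
  new("PairMatrix", values = v, kind = "similarity")
}

# Independent disulfide-mapping scorer: superposition through bio3d::fit.xyz
# instead of the package's Kabsch implementation.
bf_score_mapping <- function(mapping, a, b, aggregation = "mean") {
  ba <- disulfides(a); bb <- disulfides(b)
  bp <- mapping$bondPairs
  ia <- integer(0); ib <- integer(0)
  for (k in seq_len(nrow(bp))) {
    pa <- c(ba$i[bp[k, 1]], ba$j[bp[k, 1]])
    pb <- c(bb$i[bp[k, 2]], bb$j[bp[k, 2]])
    if (mapping$flip[k]) pb <- rev(pb)
    ia <- c(ia, pa); ib <- c(ib, pb)
  }
  m2 <- length(ia)
  mobile <- rbind(caCoords(a)[ia, ], sgCoords(a)[ia, ])
  fixed <- rbind(caCoords(b)[ib, ], sgCoords(b)[ib, ])
  moved <- bio3d::fit.xyz(fixed = as.vector(t(fixed)),
                          mobile = as.vector(t(mobile)),
                          fixed.inds = atom2xyz(seq_len(m2)),
                          mobile.inds = atom2xyz(seq_len(m2)))
  moved <- matrix(moved, ncol = 3, byrow = TRUE)
  d <- sqrt(rowSums((moved - fixed)^2))
  switch(aggregation, mean = mean(d), sum = sum(d), rms = sqrt(mean(d^2)))
}

atom2xyz <- function(i) as.vector(t(cbind(3 * i - 2, 3 * i - 1, 3 * i)))

# Quick hairpin family for alignment tests.
hairpin_family <- function(n_members = 3, n_res = 20, sigma = 0.3, seed = 11) {
  generateFamily(familySpec("hp", "beta_hairpin", n_members, n_res, 2L,
                            noise_sigma = sigma, id_prefix = "hp",
                            seed = seed))
}

partition_of <- function(...) rankPartition(list(...))
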