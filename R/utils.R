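# Internal helpers shared across modules.

# 3-letter <-> 1-letter residue codes ('X' for anything unknown).
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

aa3_to_1 <- function(res3) {
  out <- .aa3to1[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1_to_3 <- function(res1) {
  out <- .aa1to3[res1]
  out[is.na(out)] <- "UNK"
  unname(out)
}

# Evaluate expr with a fixed, platform-independent RNG state, restoring the
# caller's state afterwards. All stochastic code in the package goes through
# this so results are identical across platforms and sessions.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (here used on non-negative values only), so RGB
# components are platform-independent (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Euclidean norms of matrix rows.
row_norms <- function(m) sqrt(rowSums(m * m))

# BLOSUM62 substitution matrix (cached after first use).
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

#' @useDynLib drpclust, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd median rnorm runif
#' @importFrom utils head write.table read.table
NULL
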