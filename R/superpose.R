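#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing the
#' RMSD between \code{R \%*\% a + t} and \code{b} over paired points.
#' Reflections are never returned. Degenerate inputs are handled: a single
#' point gives a pure translation, and two points give the minimal rotation
#' about the axis perpendicular to the two inter-point vectors.
#'
#' @param a,b numeric n x 3 matrices of paired coordinates (same n, n >= 1).
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom) of the superposed points.
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' fit <- kabschSuperpose(pts, pts)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("point sets must be n x 3 numeric matrices")
  n <- nrow(a)
  if (n == 0L) stop("cannot superpose empty point sets")
  if (nrow(b) != n) stop("point sets must have equal length")

  ca <- colMeans(a); cb <- colMeans(b)
  if (n == 1L) {
    R <- diag(3)
  } else {
    A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
    if (n == 2L) {
      R <- .minimal_rotation(A[2, ] - A[1, ], B[2, ] - B[1, ])
    } else {
      H <- crossprod(A, B)           # 3x3 covariance
      s <- svd(H)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    }
  }
  t <- cb - as.vector(R %*% ca)
  moved <- t(R %*% t(a)) + matrix(t, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

# Minimal-angle rotation taking unit direction of v onto unit direction of w
# (Rodrigues formula); identity when either vector vanishes.
.minimal_rotation <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv < 1e-12 || nw < 1e-12) return(diag(3))
  v <- v / nv; w <- w / nw
  axis <- c(v[2] * w[3] - v[3] * w[2],
            v[3] * w[1] - v[1] * w[3],
            v[1] * w[2] - v[2] * w[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(v * w)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to v
    p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * v) * v
    axis <- axis / sqrt(sum(axis^2))
    K <- .skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- .skew(axis)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

.skew <- function(u) {
  matrix(c(0, u[3], -u[2],
           -u[3], 0, u[1],
           u[2], -u[1], 0), 3, 3)
}

# Apply a rigid transform (list with rotation, translation) to an n x 3 matrix.
apply_transform <- function(fit, pts) {
  t(fit$rotation %*% t(rbind(pts))) +
    matrix(fit$translation, nrow(rbind(pts)), 3, byrow = TRUE)
}
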