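#' Optimal rigid-body superposition of paired coordinates
#'
#' Least-squares superposition of two paired C-alpha coordinate sets by
#' the Kabsch algorithm (SVD of the cross-covariance with a reflection
#' guard), returning the proper rotation and translation that map `coords_b`
#' onto `coords_a` with minimal RMSD.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices with paired rows,
#'   n >= 3.
#' @return A list of class `superposition` with elements `rotation` (3 x 3
#'   proper rotation), `translation` (length-3 vector), `rmsd` (Angstrom)
#'   and `n` (number of pairs). The transform maps a point `x` of B to
#'   `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3L ||
      ncol(coords_b) != 3L)
    stop("'coords_a' and 'coords_b' must be paired n x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3L) stop("at least 3 paired points are required")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)                      # 3x3 cross-covariance
  sv <- svd(H)
  # collinear/degenerate point sets give a rank-deficient covariance and
  # an unstable rotation about the degenerate axis
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    warning("degenerate (collinear) point set; rotation is unstable")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(ca - R %*% cb)
  moved <- B %*% t(R)
  rmsd <- sqrt(sum((A - moved)^2) / n)
  structure(list(rotation = R, translation = trans, rmsd = rmsd, n = n),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param sp A `superposition` from [kabsch_superpose].
#' @param coords n x 3 coordinate matrix (frame of the second argument of
#'   [kabsch_superpose]).
#' @return Transformed n x 3 matrix in the frame of the first argument.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition of %d pairs: RMSD %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

# fast all-against-all Euclidean distances between rows of A and B
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# random proper rotation (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
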