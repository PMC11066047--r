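## Least-squares rigid superposition (Kabsch algorithm).

#' Kabsch superposition of paired coordinate sets
#'
#' Closed-form least-squares rigid superposition of \code{coordsA} onto
#' \code{coordsB} over proper rotations (reflections are excluded by the
#' determinant correction). Points are paired by row order.
#'
#' The fitted transform of a point matrix \code{X} is
#' \code{sweep(X, 2, centroidA) \%*\% rotation + centroidB} (row-vector
#' convention); applying it to \code{coordsA} attains the returned RMSD.
#'
#' @param coordsA,coordsB Numeric \code{N x 3} matrices (Angstrom),
#'   \code{N >= 3}, equal dimensions.
#' @return List with \code{rotation} (3 x 3 proper rotation),
#'   \code{translation} (length-3; \code{centroidB - centroidA \%*\%
#'   rotation}), and \code{rmsd} (Angstrom).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- kabschSuperpose(a, a)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
    coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
    if (!all(dim(coordsA) == dim(coordsB)))
        stop("coordinate sets must have identical dimensions")
    n <- nrow(coordsA)
    if (n < 3L || ncol(coordsA) != 3L)
        stop("need at least 3 paired 3-D points")
    if (any(!is.finite(coordsA)) || any(!is.finite(coordsB)))
        stop("coordinates must be finite")
    cenA <- colMeans(coordsA); cenB <- colMeans(coordsB)
    A <- sweep(coordsA, 2L, cenA); B <- sweep(coordsB, 2L, cenB)
    ## degenerate (collinear/coincident) sets have no unique rotation
    if (sum(svd(A)$d > 1e-8 * max(1, max(abs(A)))) < 2L)
        stop("degenerate coordinate set: points are collinear")
    sv <- svd(crossprod(A, B))            # A^T B = U D V^T
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    fitted <- A %*% R
    rmsd <- sqrt(sum((fitted - B)^2) / n)
    list(rotation = R, translation = as.numeric(cenB - cenA %*% R),
         rmsd = rmsd)
}
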