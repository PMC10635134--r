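## Rigid-body geometry: superposition, RMSD, transforms, rotation sampling.

#' Apply a rigid transform to coordinates or a structure
#'
#' @param transform A [RigidTransform].
#' @param x n x 3 coordinate matrix or a [Structure].
#' @return Object of the same kind with transformed coordinates.
#' @export
applyTransform <- function(transform, x) {
    stopifnot(is(transform, "RigidTransform"))
    if (is(x, "Structure")) {
        coords(x) <- applyTransform(transform, coords(x))
        return(x)
    }
    x <- as.matrix(x)
    sweep(x %*% t(transform@rotation), 2, transform@translation, `+`)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first} then
#' \code{second}.
#' @param second,first [RigidTransform]s.
#' @return A [RigidTransform].
#' @export
composeTransforms <- function(second, first) {
    RigidTransform(second@rotation %*% first@rotation,
                   as.numeric(second@rotation %*% first@translation) +
                       second@translation)
}

#' Rotation matrix from a rotation vector (axis * angle)
#'
#' Rodrigues form; the zero vector gives the identity.
#' @param v length-3 numeric rotation vector (radians).
#' @return 3x3 proper rotation matrix.
#' @export
rotationFromVector <- function(v) {
    theta <- sqrt(sum(v^2))
    if (theta < 1e-12) return(diag(3))
    k <- v / theta
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Uniform random proper rotation
#'
#' Drawn via a normalized Gaussian quaternion (Haar-uniform over SO(3));
#' consumes 4 values from the current RNG stream.
#' @return 3x3 proper rotation matrix.
#' @export
randomRotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
        1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)),
        3, 3)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' \code{mobile} onto \code{reference}.  The determinant of the rotation is
#' corrected to +1, so a mirror image is never matched by an improper
#' rotation and retains a positive residual RMSD.
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3.
#' @return list with \code{transform} (a [RigidTransform]) and \code{rmsd}
#'   (Angstrom, after fitting).
#' @export
superpose <- function(mobile, reference) {
    mobile <- as.matrix(mobile); reference <- as.matrix(reference)
    if (nrow(mobile) != nrow(reference))
        stop("superpose: point counts differ (", nrow(mobile), " vs ",
             nrow(reference), ")")
    if (nrow(mobile) < 3L)
        stop("superpose: need at least 3 points")
    cm <- colMeans(mobile); cr <- colMeans(reference)
    P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
    s <- svd(crossprod(P, Q))            # H = P'Q = U D V'
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    tr <- RigidTransform(R, cr - as.numeric(R %*% cm))
    fitted <- applyTransform(tr, mobile)
    list(transform = tr, rmsd = rmsdNoFit(fitted, reference))
}

#' RMSD without superposition
#'
#' Root-mean-square deviation of paired coordinates as given; no fitting.
#' @param a,b n x 3 coordinate matrices, equal n >= 1.
#' @return RMSD in Angstrom.
#' @export
rmsdNoFit <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (nrow(a) != nrow(b))
        stop("rmsdNoFit: point counts differ (", nrow(a), " vs ", nrow(b), ")")
    if (nrow(a) < 1L) stop("rmsdNoFit: empty point sets")
    sqrt(mean(rowSums((a - b)^2)))
}

## evaluate an expression under a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}
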