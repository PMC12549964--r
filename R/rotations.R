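## Uniform SO(3) sampling, quaternion algebra and the analytic
## relative-angle distribution that explains orientation-error saturation.
##
## Quaternion convention throughout the package: numeric vectors (w, x, y, z)
## with the scalar part first; sets of rotations are n x 4 matrices, one
## quaternion per row. q and -q encode the same rotation and every angle
## computation is invariant under that sign flip.

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## global RNG state is restored afterwards, so no hidden state leaks.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Construct and validate a unit quaternion
#'
#' Normalizes (w, x, y, z) to unit length. The zero quaternion is rejected.
#'
#' @param w,x,y,z quaternion components (scalar part first).
#' @return numeric(4) unit quaternion.
#' @examples
#' quaternion(1, 0, 0, 0)            # identity rotation
#' quaternion(1, 1, 0, 0)            # normalized automatically
#' @export
quaternion <- function(w, x = 0, y = 0, z = 0) {
  if (length(w) == 4L && missing(x)) {
    q <- as.numeric(w)
  } else {
    q <- c(w, x, y, z)
  }
  nrm <- sqrt(sum(q^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("cannot normalize a (near-)zero quaternion")
  q / nrm
}

## internal: strict unit check used by angle computations
assertUnitQuat <- function(q, tol = 1e-6) {
  if (length(q) != 4L)
    stop("a quaternion must have 4 components (w, x, y, z)")
  if (abs(sqrt(sum(q^2)) - 1) > tol)
    stop("quaternion is not unit length beyond tolerance")
  invisible(q)
}

#' Sample rotations Haar-uniformly on SO(3)
#'
#' Draws unit quaternions by normalizing 4D standard Gaussian vectors, which
#' yields the unique rotation-invariant (Haar) distribution on SO(3).
#' Reproducible: a fixed seed yields an identical sequence; the caller's
#' global RNG state is left untouched.
#'
#' @param n number of rotations.
#' @param seed integer seed, or NULL to consume the current RNG stream.
#' @return n x 4 matrix of unit quaternions, one (w, x, y, z) row each.
#' @examples
#' q <- sampleUniformRotations(5, seed = 1)
#' rowSums(q^2)  # all 1
#' @export
sampleUniformRotations <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  q <- withSeed(seed, matrix(stats::rnorm(4 * n), ncol = 4))
  q / sqrt(rowSums(q^2))
}

#' Quaternion product
#'
#' Hamilton product q1 * q2, vectorized over rows when matrices are given.
#'
#' @param q1,q2 quaternions (length-4 vectors or n x 4 matrices).
#' @return quaternion(s) of the broadcast shape.
#' @export
quatMultiply <- function(q1, q2) {
  if (is.null(dim(q1))) q1 <- matrix(q1, ncol = 4)
  if (is.null(dim(q2))) q2 <- matrix(q2, ncol = 4)
  w <- q1[, 1] * q2[, 1] - q1[, 2] * q2[, 2] -
       q1[, 3] * q2[, 3] - q1[, 4] * q2[, 4]
  x <- q1[, 1] * q2[, 2] + q1[, 2] * q2[, 1] +
       q1[, 3] * q2[, 4] - q1[, 4] * q2[, 3]
  y <- q1[, 1] * q2[, 3] - q1[, 2] * q2[, 4] +
       q1[, 3] * q2[, 1] + q1[, 4] * q2[, 2]
  z <- q1[, 1] * q2[, 4] + q1[, 2] * q2[, 3] -
       q1[, 3] * q2[, 2] + q1[, 4] * q2[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q quaternion(s).
#' @return conjugate quaternion(s).
#' @export
quatConjugate <- function(q) {
  if (is.null(dim(q))) q * c(1, -1, -1, -1)
  else q %*% diag(c(1, -1, -1, -1))
}

#' Rotation matrix of a unit quaternion
#' @param q numeric(4) unit quaternion.
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
quatToMatrix <- function(q) {
  assertUnitQuat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate 3-vectors by a unit quaternion
#' @param v numeric(3) or N x 3 matrix of row vectors.
#' @param q numeric(4) unit quaternion.
#' @return rotated vectors of the same shape.
#' @export
quatRotate <- function(v, q) {
  R <- quatToMatrix(q)
  if (is.null(dim(v))) as.numeric(R %*% v)
  else v %*% t(R)
}

#' Relative orientation angle between two rotations
#'
#' The minimal single-axis angle theta mapping one orientation onto the
#' other: theta = 2 arccos(|Re(Ri Rj^-1)|). The absolute value makes the
#' result invariant under the q <-> -q double cover and confines it to
#' [0, pi]; the arccos argument is clamped to [-1, 1] to absorb
#' floating-point drift. Symmetric in its arguments. Vectorized: matrices
#' of quaternion rows give elementwise angles.
#'
#' @param Ri,Rj unit quaternions (length-4 vectors or n x 4 matrices).
#' @return angle(s) in radians, in [0, pi].
#' @examples
#' relativeAngle(quaternion(1, 0, 0, 0), quaternion(1, 0, 0, 1))  # pi/2
#' @export
relativeAngle <- function(Ri, Rj) {
  vec <- is.null(dim(Ri)) && is.null(dim(Rj))
  if (is.null(dim(Ri))) Ri <- matrix(Ri, ncol = 4)
  if (is.null(dim(Rj))) Rj <- matrix(Rj, ncol = 4)
  nrmI <- sqrt(rowSums(Ri^2)); nrmJ <- sqrt(rowSums(Rj^2))
  if (max(abs(c(nrmI, nrmJ) - 1)) > 1e-6)
    stop("relativeAngle requires unit quaternions")
  ## Re(Ri * conj(Rj)) is the dot product of the quaternion 4-vectors
  a <- abs(rowSums(Ri * Rj))
  theta <- 2 * acos(pmin(1, a))
  if (vec) theta[1] else theta
}

#' Density of the relative angle between uniform random rotations
#'
#' For two independent Haar-uniform rotations the relative angle theta has
#' the normalized density p(theta) = (2/pi) sin^2(theta/2) on [0, pi]. The
#' common unnormalized textbook form (1/2) sin^2(theta/2) differs by the
#' constant factor \code{angleUnnormalizedFactor} = pi/4.
#'
#' @param theta angle(s) in radians, each in [0, pi].
#' @return density value(s).
#' @export
anglePdf <- function(theta) {
  if (any(theta < 0 | theta > pi))
    stop("theta must lie in [0, pi]")
  (2 / pi) * sin(theta / 2)^2
}

#' Ratio of the unnormalized (1/2 sin^2(theta/2)) to the normalized form
#' @export
angleUnnormalizedFactor <- pi / 4

#' CDF of the relative-angle distribution
#'
#' F(theta) = (theta - sin(theta)) / pi on [0, pi].
#'
#' @param theta angle(s) in radians, each in [0, pi].
#' @return cumulative probability value(s).
#' @export
angleCdf <- function(theta) {
  if (any(theta < 0 | theta > pi))
    stop("theta must lie in [0, pi]")
  (theta - sin(theta)) / pi
}

#' Mean and median of the uniform-rotation relative-angle distribution
#'
#' The mean is closed form, pi/2 + 2/pi (about 2.2074 rad); the median
#' solves F(theta) = 1/2, i.e. theta - sin(theta) = pi/2, found by a
#' bracketing root-finder to 1e-10. These are the saturation values a
#' retrieval method degrades to when orientations are effectively random.
#'
#' @return list with components \code{mean} and \code{median}, radians.
#' @examples
#' angleDistributionStats()$mean   # 2.2074
#' @export
angleDistributionStats <- function() {
  med <- stats::uniroot(function(t) angleCdf(t) - 0.5,
                        interval = c(1e-9, pi - 1e-9),
                        tol = 1e-10)$root
  list(mean = pi / 2 + 2 / pi, median = med)
}
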