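# Geometric primitives: centers, minimum distances, Kabsch superposition
# and rigid transforms.

#' Coordinate matrix of an atom table
#'
#' @param x an atom table (data.frame with x, y, z), a ChainRecord, a Ligand
#'   or a numeric matrix (returned as-is).
#' @param heavyOnly drop hydrogens (default TRUE for atom tables).
#' @return n x 3 numeric matrix.
#' @export
coordsOf <- function(x, heavyOnly = TRUE) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  if (is(x, "ChainRecord") || is(x, "Ligand") || is(x, "PDBStructure"))
    x <- atoms(x)
  stopifnot(is.data.frame(x))
  if (heavyOnly && "isHydrogen" %in% names(x)) x <- x[!x$isHydrogen, ]
  cbind(x = x$x, y = x$y, z = x$z)
}

#' Geometric center of a set of atoms
#'
#' Unweighted mean of the coordinates (a geometry center, not a center of
#' mass).  Hydrogens are excluded when an atom table is given.
#'
#' @param x atoms as in [coordsOf()].
#' @return length-3 numeric vector (Angstrom).
#' @examples
#' geometricCenter(rbind(c(0, 0, 0), c(2, 0, 0)))  # (1, 0, 0)
#' @export
geometricCenter <- function(x) {
  m <- coordsOf(x)
  if (nrow(m) == 0) stop("geometricCenter: no atoms")
  colMeans(m)
}

#' Minimum distance from a point to a set of atoms
#'
#' @param point length-3 numeric vector.
#' @param x atoms as in [coordsOf()].
#' @return minimum Euclidean distance (Angstrom).
#' @export
minDistance <- function(point, x) {
  m <- coordsOf(x)
  if (nrow(m) == 0) stop("minDistance: no atoms")
  stopifnot(length(point) == 3, all(is.finite(point)))
  sqrt(min(rowSums(sweep(m, 2, point)^2)))
}

# All pairwise distances between two coordinate matrices (n x m).
.crossDist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric vector.
#' @return a [RigidTransform-class] object.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Kabsch superposition of two point sets
#'
#' Least-squares rigid superposition of \code{moving} onto \code{fixed}
#' (SVD-based, proper rotation enforced, so no reflection can be returned).
#'
#' @param moving,fixed n x 3 coordinate matrices (same n, n >= 3,
#'   non-collinear).
#' @return list with \code{transform} (a [RigidTransform-class] mapping moving
#'   into the fixed frame) and \code{rmsd} over the transformed pairs.
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' kabschSuperpose(p, p)$rmsd  # 0
#' @export
kabschSuperpose <- function(moving, fixed) {
  moving <- coordsOf(moving); fixed <- coordsOf(fixed)
  n <- nrow(moving)
  if (n != nrow(fixed)) stop("kabschSuperpose: point counts differ")
  if (n < 3) stop("kabschSuperpose: need at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Pm <- sweep(moving, 2, cm); Pf <- sweep(fixed, 2, cf)
  H <- crossprod(Pm, Pf)                     # 3x3 covariance
  sv <- svd(H)
  # collinear sets leave the rotation about the common axis undetermined
  scale <- sqrt(sum(Pm^2) / n + sum(Pf^2) / n)
  if (scale == 0 || sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-9)
    stop("kabschSuperpose: degenerate (collinear or coincident) geometry")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cf - R %*% cm)
  moved <- tcrossprod(Pm, R)                 # Pm %*% t(R)
  rmsd <- sqrt(sum((moved - Pf)^2) / n)
  list(transform = rigidTransform(R, t), rmsd = rmsd)
}

#' Apply a rigid transform
#'
#' Rotates then translates coordinates; for atom tables and Ligand objects all
#' non-coordinate fields are preserved.
#'
#' @param transform a [RigidTransform-class].
#' @param x coordinate matrix, atom table, or Ligand.
#' @return object of the same kind with transformed coordinates.
#' @export
applyTransform <- function(transform, x) {
  stopifnot(is(transform, "RigidTransform"))
  if (is(x, "Ligand")) {
    x@atoms <- applyTransform(transform, x@atoms)
    return(x)
  }
  if (is.data.frame(x)) {
    m <- tcrossprod(cbind(x$x, x$y, x$z), transform@rotation)
    m <- sweep(m, 2, transform@translation, "+")
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    return(x)
  }
  sweep(tcrossprod(x, transform@rotation), 2, transform@translation, "+")
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(b, a)} is the transform equivalent to applying
#' \code{a} first, then \code{b}.
#'
#' @param b,a [RigidTransform-class] objects.
#' @return the composed [RigidTransform-class].
#' @export
composeTransforms <- function(b, a) {
  rigidTransform(b@rotation %*% a@rotation,
                 as.numeric(b@rotation %*% a@translation) + b@translation)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return its inverse.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

# Seeded uniform random rotation (quaternion method); assumes the caller has
# set the RNG state.
.randomRotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
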