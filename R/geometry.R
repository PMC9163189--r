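## Rigid-body geometry helpers: quaternions (scalar-first), rotations,
## Euler angles, Kabsch superposition.

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' Scalar-first convention `c(w, x, y, z)`.  The quaternion is normalized
#' before conversion, so optimizer iterates need not stay exactly on the
#' unit sphere.
#'
#' @param q numeric length-4 quaternion.
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Uniform random unit quaternions
#'
#' Marsaglia/Shoemake construction: uniform on S^3, hence uniform over
#' SO(3) after the double cover.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix, rows are scalar-first unit quaternions.
#' @export
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
}

#' Quaternion from z-y-z Euler angles (degrees)
#' @param a,b,g Euler angles in degrees.
#' @return scalar-first unit quaternion.
#' @export
euler_to_quat <- function(a, b, g) {
  a <- a * pi / 180; b <- b * pi / 180; g <- g * pi / 180
  ## R = Rz(a) Ry(b) Rz(g)
  qa <- c(cos(a / 2), 0, 0, sin(a / 2))
  qb <- c(cos(b / 2), 0, sin(b / 2), 0)
  qg <- c(cos(g / 2), 0, 0, sin(g / 2))
  quat_multiply(quat_multiply(qa, qb), qg)
}

quat_multiply <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation mapping `x` onto `y` after removing
#' centroids.  Improper solutions are excluded (determinant forced to +1).
#'
#' @param x,y n x 3 coordinate matrices with matched rows.
#' @param weights optional per-row weights.
#' @return list with `rotation`, `translation` (applied as
#'   `x %*% t(rotation) + translation`), and `rmsd`.
#' @export
kabsch <- function(x, y, weights = NULL) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  w <- weights / sum(weights)
  cx <- colSums(x * w); cy <- colSums(y * w)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  h <- t(x0 * w) %*% y0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xr <- x0 %*% t(rot)
  rmsd <- sqrt(sum(weights * rowSums((xr - y0)^2)) / sum(weights))
  list(rotation = rot, translation = cy - as.vector(rot %*% cx), rmsd = rmsd)
}

## All pairwise distances between two coordinate sets (vectorized).
cross_distances <- function(xa, xb) {
  ## returns |A| x |B| matrix
  sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb), 0))
}
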