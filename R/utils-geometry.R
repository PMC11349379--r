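## Quaternion and deterministic-sampling helpers shared by the fitting and
## synthetic-data code. Quaternions are length-4 numeric (w, x, y, z), unit
## norm, scalar-first.

#' Quaternion to rotation matrix
#'
#' @param q numeric(4), unit quaternion (w, x, y, z).
#' @return 3x3 proper rotation matrix.
#' @keywords internal
quatToMatrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Angular distance between two rotations, in degrees
#' @keywords internal
quatAngle <- function(q1, q2) {
  d <- abs(sum(q1 * q2) / sqrt(sum(q1^2) * sum(q2^2)))
  2 * acos(min(1, d)) * 180 / pi
}

#' Axis-angle to quaternion
#' @keywords internal
axisAngleQuat <- function(axis, angleDeg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 360
  c(cos(a), sin(a) * axis)
}

#' Quaternion product (composition of rotations; q1 applied after q2)
#' @keywords internal
quatMultiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Map three unit-interval coordinates to a uniform quaternion
#'
#' Shoemake's subgroup construction: with (u1, u2, u3) uniform on [0,1)^3 the
#' result is uniform on SO(3). Used with a Halton sequence it yields a
#' deterministic quasi-uniform rotation library.
#' @keywords internal
shoemakeQuat <- function(u1, u2, u3) {
  s1 <- sqrt(1 - u1); s2 <- sqrt(u1)
  c(s1 * sin(2 * pi * u2), s1 * cos(2 * pi * u2),
    s2 * sin(2 * pi * u3), s2 * cos(2 * pi * u3))
}

#' Halton low-discrepancy sequence
#'
#' @param n number of points.
#' @param base integer base (use distinct primes per dimension).
#' @param offset skip the first `offset` terms.
#' @return numeric(n) in (0, 1).
#' @keywords internal
haltonSeq <- function(n, base, offset = 0L) {
  idx <- seq_len(n) + offset
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    f <- 1
    r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    out[k] <- r
  }
  out
}

#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Rotation matrix for 180 degrees about an axis through a point
#' @keywords internal
c2Operator <- function(axis = c(0, 0, 1), center = c(0, 0, 0)) {
  R <- quatToMatrix(axisAngleQuat(axis, 180))
  list(R = R, center = center,
       apply = function(X) sweep(sweep(X, 2, center) %*% t(R), 2, center, "+"))
}

## Pairwise squared-distance helper: rows of A vs rows of B.
crossDist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  outer(a2, b2, "+") - 2 * tcrossprod(A, B)
}

crossDist <- function(A, B) sqrt(pmax(crossDist2(A, B), 0))
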