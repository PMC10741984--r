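# Small 3-vector / rotation helpers used throughout. All vectors are plain
# numeric length-3; rotations are 3x3 matrices (world <- local).

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

skew3 <- function(v) {
  matrix(c(0, v[3L], -v[2L],
           -v[3L], 0, v[1L],
           v[2L], -v[1L], 0), 3L, 3L)
}

# Rodrigues rotation about a unit axis.
rot_axis_angle <- function(axis, theta) {
  ct <- cos(theta); st <- sin(theta)
  K <- skew3(axis)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(axis)
}

is_num3 <- function(v) is.numeric(v) && length(v) == 3L && all(is.finite(v))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closest points of two lines p1 + s*d1 and p2 + t*d2 (d unit not required).
# Returns midpoint, gap, and the two parameters.
line_line_closest <- function(p1, d1, p2, d2) {
  r <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); c2 <- sum(d2 * d2)
  d <- sum(d1 * r);  e <- sum(d2 * r)
  den <- a * c2 - b * b
  if (abs(den) < 1e-14 * a * c2 || den == 0) {
    stop("lines are parallel; no unique closest point")
  }
  s <- (b * e - c2 * d) / den
  t <- (a * e - b * d) / den
  q1 <- p1 + s * d1
  q2 <- p2 + t * d2
  list(point = 0.5 * (q1 + q2), gap = norm3(q1 - q2), s = s, t = t)
}
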