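# Rank analysis of the double-support force balance. With the six sole
# moment components neglected, the six force components still cannot be
# solved from the six balance equations: the coefficient matrix is always
# rank 5, because forces transmitted along the line joining the two contact
# points are indistinguishable in their resultant effect. This is the
# rank-deficiency the DDCS construction removes.

#' Coefficient matrix of the axis-aligned force-balance system
#'
#' The 6x6 matrix of the double-support balance equations (forces only,
#' contact moments neglected) for the special placement where the line
#' joining the two contact points is parallel to a coordinate axis; `a`,
#' `b`, `c`, `d` are the placement scalars. Unknown order is
#' `(FLX, FLY, FLZ, FRX, FRY, FRZ)`; equation order is force X, Y, Z then
#' moment X, Y, Z.
#'
#' @param a,b,c,d placement scalars, m.
#' @return A 6x6 numeric matrix.
#' @export
force_balance_matrix <- function(a, b, c, d) {
  rbind(c(1, 0, 0, 1, 0, 0),
        c(0, 1, 0, 0, 1, 0),
        c(0, 0, 1, 0, 0, 1),
        c(0, c, b, 0, c, -a),
        c(c, 0, -d, c, 0, -d),
        c(-b, d, 0, a, d, 0))
}

#' Coefficient matrix for arbitrary contact-point placement
#'
#' General form of the same balance system for contact points at arbitrary
#' world positions `pL`, `pR`: force rows `[I I]`, moment rows
#' `[ [pL]x [pR]x ]`. Its null space is spanned by equal-and-opposite forces
#' along the line joining the two points, so the rank is 5 whenever the
#' points are distinct -- for every placement, axis-aligned or not.
#'
#' @param pL,pR contact point positions, length-3, m.
#' @return A 6x6 numeric matrix.
#' @export
placement_balance_matrix <- function(pL, pR) {
  rbind(cbind(diag(3L), diag(3L)),
        cbind(skew3(pL), skew3(pR)))
}

#' Numeric rank via singular values
#'
#' Standard criterion: number of singular values exceeding
#' `max(dim(A)) * eps * max(singular value)`.
#'
#' @param A a numeric matrix.
#' @param tol optional explicit tolerance.
#' @return Integer rank.
#' @export
numeric_rank <- function(A, tol = NULL) {
  sv <- svd(A, nu = 0L, nv = 0L)$d
  tol <- tol %||% (max(dim(A)) * .Machine$double.eps * max(sv, 0))
  sum(sv > tol)
}

#' Rank invariance under rotation of the contact placement
#'
#' Homogeneous transformations do not change the rank of the balance
#' system: assembling the coefficient matrix for a generic (rotated) pair of
#' contact points and for the same pair rotated so their connecting line is
#' axis-aligned yields equal ranks.
#'
#' @param pL,pR contact point positions, length-3.
#' @param rotation a 3x3 rotation applied to both points for the second
#'   assembly.
#' @return A list with `rank_A` and `rank_Aprime`.
#' @export
rank_invariance <- function(pL, pR, rotation) {
  A <- placement_balance_matrix(pL, pR)
  Ap <- placement_balance_matrix(as.numeric(rotation %*% pL),
                                 as.numeric(rotation %*% pR))
  list(rank_A = numeric_rank(A), rank_Aprime = numeric_rank(Ap))
}
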