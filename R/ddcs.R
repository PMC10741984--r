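# The dynamic decoupled coordinate system (DDCS): couple the two centres of
# pressure through the central axis, build the per-sample frame whose X axis
# joins them, and solve the decoupled five-equation force balance.

#' Double-support contact geometry
#'
#' Collects the world-frame ingredients of the double-support problem: the
#' heel and toe points of the left foot (A, B) and right foot (C, D), a point
#' P on the central axis of the inertial wrench, and the unit force
#' direction. The left COP is `M = A + a * unit(AB)` and the right COP is
#' `N = C + b * unit(CD)`, with `a` measured from the heel toward the toe.
#'
#' @param kin segment kinematics.
#' @param caw central-axis reduction of the aggregate inertial wrench.
#' @return An object of class `"contact_geometry"`.
#' @export
contact_geometry <- function(kin, caw) {
  L <- kin$feet$left; R <- kin$feet$right
  structure(list(A = L$heel, B = L$toe, C = R$heel, D = R$toe,
                 P = caw$ref_point + caw$axis_point,
                 F_dir = unit3(caw$force),
                 lf_left = L$lf, lf_right = R$lf,
                 uAB = unit3(L$toe - L$heel), uCD = unit3(R$toe - R$heel)),
            class = "contact_geometry")
}

#' COP coupling: right-foot parameter b as a function of a
#'
#' Force balance requires the two COPs and the central axis to be coplanar:
#' the plane through P spanned by PM and the force direction must contain N.
#' With `n = PM x F` this gives the closed form
#' `b = -(n . PC) / (n . unit(CD))`, which is the unique root of the
#' coplanarity residual `(PM x PN) . F = 0` along the right foot's heel-toe
#' line.
#'
#' @param a left COP position along the heel-toe segment, m.
#' @param geom a [contact_geometry()].
#' @return `b`, the right COP position from the right heel, m.
#' @export
coupled_b <- function(a, geom) {
  M <- geom$A + a * geom$uAB
  n <- cross3(M - geom$P, geom$F_dir)
  den <- sum(n * geom$uCD)
  if (abs(den) < 1e-12 * (norm3(n) + 1e-300)) {
    stop("degenerate geometry: right foot line parallel to the constraint plane")
  }
  -sum(n * (geom$C - geom$P)) / den
}

#' Build the dynamic decoupled coordinate system for a candidate a
#'
#' Places the frame origin O at the intersection of line MN (through the two
#' COPs) and the central axis -- which exist by construction of `b`; the
#' closest-point gap between the two lines is checked against 1e-8 m and a
#' larger gap signals an upstream coupling error. The X axis runs along OM
#' (so both COPs lie on it), Y is perpendicular to the plane of P, M, N, and
#' Z completes the right-handed triad. The lever arms are `l = |OM|` and
#' `r = -(N - O) . X` (positive when O lies between the COPs).
#'
#' @param geom a [contact_geometry()].
#' @param a left COP parameter, m.
#' @param b right COP parameter, m; computed via [coupled_b()] when `NULL`.
#' @return An object of class `"ddcs_frame"`: `origin`, `rotation` (3x3,
#'   world <- DDCS, columns X, Y, Z), `l`, `r`, `M`, `N`, `a`, `b`.
#' @export
ddcs_frame <- function(geom, a, b = NULL) {
  b <- b %||% coupled_b(a, geom)
  M <- geom$A + a * geom$uAB
  N <- geom$C + b * geom$uCD
  MN <- N - M
  dMN <- norm3(MN)
  if (dMN < 1e-12) stop("coincident COPs: M = N, DDCS undefined")
  cl <- line_line_closest(M, MN, geom$P, geom$F_dir)
  if (cl$gap >= 1e-8) {
    stop("geometry inconsistency: line MN and central axis do not intersect (gap ",
         format(cl$gap), " m)")
  }
  O <- cl$point
  OM <- M - O
  X <- if (norm3(OM) > 1e-12) unit3(OM) else unit3(-MN)
  OP <- geom$P - O
  ycr <- cross3(OM, OP)
  if (norm3(ycr) < 1e-12) {
    # P on the X axis: fall back to the force direction to span the plane
    ycr <- cross3(X, geom$F_dir)
    if (norm3(ycr) < 1e-12) stop("P on X-axis and force along X: Y undefined")
  }
  Y <- unit3(ycr)
  Z <- cross3(X, Y)
  l <- sum((M - O) * X)
  r <- -sum((N - O) * X)
  rotation <- unname(cbind(X, Y, Z))
  structure(list(origin = O, rotation = rotation, l = l, r = r,
                 M = M, N = N, a = a, b = b),
            class = "ddcs_frame")
}

# Express a world wrench (about its own ref point) about the DDCS origin in
# DDCS axes. Returns list(force, moment), each length-3.
wrench_in_ddcs <- function(frame, w) {
  Rt <- t(frame$rotation)
  M_O <- w$moment + cross3(w$ref_point - frame$origin, w$force)
  list(force = as.numeric(Rt %*% w$force),
       moment = as.numeric(Rt %*% M_O))
}

#' Solve the decoupled double-support force balance
#'
#' Transforms the negative aggregate inertial wrench into the DDCS about O,
#' retains five components (all three forces; moments about Y and Z) as the
#' right-hand side `FD`, and solves the square system for
#' `x = (FX, FLY, FLZ, FRY, FRZ)`:
#' `FX = FXD`, `FLY + FRY = FYD`, `FLZ + FRZ = FZD`,
#' `-l FLZ + r FRZ = MYD`, `l FLY - r FRY = MZD`.
#' The X moment about O (along the COP-COP axis) has no solvable counterpart
#' and is dropped after the transform; its magnitude is recorded per sample
#' as a model-error diagnostic.
#'
#' @param frame a [ddcs_frame()].
#' @param w the aggregate inertial wrench about `O0` (world frame).
#' @return An object of class `"decoupled_system"` with fields `frame`,
#'   `A_matrix` (5x5), `FD`, `x`, `dropped_MXD`.
#' @export
solve_decoupled <- function(frame, w) {
  l <- frame$l; r <- frame$r
  # |l + r| = |MN|: the system is singular exactly when the COPs coincide
  if (abs(l + r) <= 1e-9) stop("coincident COPs: l + r = 0, singular system")
  wd <- wrench_in_ddcs(frame, w)
  FD <- -c(wd$force, wd$moment[2L], wd$moment[3L])
  dropped <- -wd$moment[1L]
  FX <- FD[1L]
  FLY <- (r * FD[2L] + FD[5L]) / (l + r)
  FRY <- (l * FD[2L] - FD[5L]) / (l + r)
  FLZ <- (r * FD[3L] - FD[4L]) / (l + r)
  FRZ <- (l * FD[3L] + FD[4L]) / (l + r)
  A <- rbind(c(1, 0, 0, 0, 0),
             c(0, 1, 0, 1, 0),
             c(0, 0, 1, 0, 1),
             c(0, 0, -l, 0, r),
             c(0, l, 0, -r, 0))
  x <- c(FX = FX, FLY = FLY, FLZ = FLZ, FRY = FRY, FRZ = FRZ)
  structure(list(frame = frame, A_matrix = A, FD = FD, x = x,
                 dropped_MXD = dropped),
            class = "decoupled_system")
}

#' Split the axial force between the feet
#'
#' The decoupled solve leaves the force along the COP-COP axis as a single
#' resultant `FX`; the split fraction `k` assigns `FLX = k FX` to the left
#' foot and `FRX = (1 - k) FX` to the right. `k` is unconstrained by default
#' (the closed-form energy minimiser assumes an unconstrained quadratic).
#'
#' @param sys a `"decoupled_system"`.
#' @param k split fraction, dimensionless.
#' @return A list with per-foot entries `left`/`right`, each holding
#'   `force_ddcs`, `force_world` and `cop` (world application point).
#' @export
split_axial <- function(sys, k) {
  x <- sys$x
  R <- sys$frame$rotation
  FL_d <- c(k * x[["FX"]], x[["FLY"]], x[["FLZ"]])
  FR_d <- c((1 - k) * x[["FX"]], x[["FRY"]], x[["FRZ"]])
  list(left = list(force_ddcs = FL_d,
                   force_world = as.numeric(R %*% FL_d),
                   cop = sys$frame$M),
       right = list(force_ddcs = FR_d,
                    force_world = as.numeric(R %*% FR_d),
                    cop = sys$frame$N))
}
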