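# Support-phase classification from the pierce point ("subpoint") of the
# inertial-wrench central axis, and the exact closed-form single-support
# contact solution.

# Boundary-inclusive even-odd point-in-polygon with a tolerance band around
# the edges (points within `tol` of any edge count as inside). `xy` is an
# n x 2 matrix of vertices in order.
point_in_polygon_2d <- function(p, xy, tol = 1e-3) {
  n <- nrow(xy)
  # distance to edges first: resolves the boundary rule
  for (i in seq_len(n)) {
    a <- xy[i, ]; b <- xy[i %% n + 1L, ]
    ab <- b - a
    L2 <- sum(ab * ab)
    t <- if (L2 > 0) max(0, min(1, sum((p - a) * ab) / L2)) else 0
    d <- p - (a + t * ab)
    if (sum(d * d) <= tol * tol) return(TRUE)
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((xy[i, 2L] > p[2L]) != (xy[j, 2L] > p[2L])) {
      xint <- xy[i, 1L] + (p[2L] - xy[i, 2L]) / (xy[j, 2L] - xy[i, 2L]) *
        (xy[j, 1L] - xy[i, 1L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Classify the support phase of one sample
#'
#' Intersects the central axis of the whole-body inertial wrench with the
#' ground plane z = 0 and tests the resulting pierce point against each
#' foot's world-frame contour. If the pierce point lies inside exactly one
#' contour the sample is a single-support phase of that foot (the pierce
#' point is then that foot's centre of pressure); otherwise the sample is
#' treated as double support. A pierce point inside neither contour and not
#' between the two feet raises a diagnostic warning flag rather than an
#' error, so whole trajectories remain processable.
#'
#' The contour test is boundary-inclusive (even-odd rule with a 1 mm
#' tolerance band around the edges), because misclassification right at
#' phase transitions is the method's dominant failure mode.
#'
#' @param caw the inertial wrench reduced to its central axis
#'   ([central_axis_reduction()]).
#' @param kin segment kinematics from [forward_kinematics()].
#' @param edge_tol edge tolerance band, m.
#' @return An object of class `"support_state"`: fields `phase`
#'   (`"left_single"`, `"right_single"` or `"double"`), `pierce_point`
#'   (3-vector on z = 0), `inside` (named logical per foot) and `warning`
#'   (logical: pierce point away from both feet).
#' @export
classify_support <- function(caw, kin, edge_tol = 1e-3) {
  F <- caw$force
  if (abs(F[3L]) < 1e-9) {
    stop("no pierce point: central axis parallel to the ground plane")
  }
  P0 <- caw$ref_point + caw$axis_point
  s <- -P0[3L] / F[3L]
  pierce <- P0 + s * F

  inside <- vapply(kin$feet, function(f) {
    point_in_polygon_2d(pierce[1:2], f$contour[, 1:2, drop = FALSE], tol = edge_tol)
  }, TRUE)

  warning_flag <- FALSE
  phase <- if (inside[["left"]] && !inside[["right"]]) "left_single"
    else if (inside[["right"]] && !inside[["left"]]) "right_single"
    else "double"
  if (!any(inside)) {
    cl <- colMeans(kin$feet$left$contour[, 1:2, drop = FALSE])
    cr <- colMeans(kin$feet$right$contour[, 1:2, drop = FALSE])
    u <- cr - cl
    tpar <- sum((pierce[1:2] - cl) * u) / sum(u * u)
    if (!is.finite(tpar) || tpar < -0.05 || tpar > 1.05) warning_flag <- TRUE
  }
  structure(list(phase = phase, pierce_point = pierce, inside = inside,
                 warning = warning_flag),
            class = "support_state")
}

#' Closed-form contact solution in single support
#'
#' In a single-support phase the estimator is exact and closed-form: the
#' supporting foot's contact force is equal and opposite to the aggregate
#' inertial force, applied at the pierce point of the central axis (which is
#' the centre of pressure), and the swing foot's contact wrench is
#' identically zero. The two sole-plane moment components are zero by
#' construction; the residual couple along the force direction is the
#' neglected free moment.
#'
#' @param w the aggregate inertial wrench about `O0`.
#' @param caw its central-axis reduction.
#' @param state a `"support_state"` with a single-support phase.
#' @param kin segment kinematics (used to express the COP position along the
#'   supporting foot's heel-toe segment).
#' @return A `"contact_solution"` (see [estimate_cfm()] for the fields).
#' @export
single_support_solution <- function(w, caw, state, kin) {
  if (!state$phase %in% c("left_single", "right_single")) {
    stop("single_support_solution called in a non-single-support phase")
  }
  side <- if (state$phase == "left_single") "left" else "right"
  foot <- kin$feet[[side]]
  force <- -w$force
  u <- unit3(foot$toe - foot$heel)
  a <- sum((state$pierce_point - foot$heel) * u)

  zero <- list(force_world = c(0, 0, 0), force_ddcs = c(NA_real_, NA_real_, NA_real_),
               cop = c(NA_real_, NA_real_, NA_real_))
  active <- list(force_world = force, force_ddcs = c(NA_real_, NA_real_, NA_real_),
                 cop = state$pierce_point)
  feet <- if (side == "left") list(left = active, right = zero)
          else list(left = zero, right = active)
  new_contact_solution(t = kin$t, phase = state$phase,
                       a = if (side == "left") a else NA_real_,
                       b = if (side == "right") a else NA_real_,
                       k = NA_real_, energy = NA_real_,
                       left = feet$left, right = feet$right,
                       joint_moments = NULL,
                       dropped_MXD = NA_real_,
                       warning = state$warning)
}

new_contact_solution <- function(t, phase, a, b, k, energy, left, right,
                                 joint_moments, dropped_MXD, warning,
                                 search = NULL) {
  structure(list(t = t, phase = phase, a = a, b = b, k = k, energy = energy,
                 left = left, right = right, joint_moments = joint_moments,
                 dropped_MXD = dropped_MXD, warning = isTRUE(warning),
                 search = search),
            class = "contact_solution")
}

#' @export
print.contact_solution <- function(x, ...) {
  cat("Contact solution @ t =", format(x$t), "s  phase:", x$phase, "\n")
  cat("  left  force (world): ", paste(format(x$left$force_world, digits = 5),
                                       collapse = " "), "N\n")
  cat("  right force (world): ", paste(format(x$right$force_world, digits = 5),
                                       collapse = " "), "N\n")
  if (!is.na(x$k)) {
    cat("  a =", format(x$a), " b =", format(x$b), " k =", format(x$k),
        " E =", format(x$energy), "\n")
  }
  invisible(x)
}
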