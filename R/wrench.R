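#' Construct a wrench (force + moment about a reference point)
#'
#' A wrench is the standard rigid-body load descriptor: a resultant force and
#' a resultant moment expressed about a stated reference point, all in world
#' coordinates. Two wrenches are *equipollent* when they produce the same
#' moment about every point.
#'
#' @param force numeric length-3, N.
#' @param moment numeric length-3, N m, about `ref_point`.
#' @param ref_point numeric length-3, m; point the moment is taken about.
#' @return An object of class `"wrench"`.
#' @seealso [transfer_wrench()], [central_axis_reduction()]
#' @export
wrench <- function(force, moment = c(0, 0, 0), ref_point = c(0, 0, 0)) {
  stopifnot(is_num3(force), is_num3(moment), is_num3(ref_point))
  structure(list(force = as.numeric(force), moment = as.numeric(moment),
                 ref_point = as.numeric(ref_point)),
            class = "wrench")
}

#' Re-express a wrench about a new reference point
#'
#' The force is unchanged; the moment picks up the lever-arm term
#' `(old_ref - new_ref) x F`.
#'
#' @param w a [wrench()].
#' @param new_point numeric length-3, m.
#' @return A `"wrench"` about `new_point`.
#' @export
transfer_wrench <- function(w, new_point) {
  stopifnot(inherits(w, "wrench"), is_num3(new_point))
  wrench(w$force,
         w$moment + cross3(w$ref_point - new_point, w$force),
         new_point)
}

#' Aggregate the whole-body inertial (D'Alembert) wrench
#'
#' Sums every segment's gravity-plus-inertia force `m_i (g - a_i)` applied at
#' its centre of mass and the rotational inertia couple
#' `-(I w_dot + w x I w)` (world-frame inertia tensor), into a single wrench
#' about the reference point `O0` carried by the model's origin segment. Under
#' D'Alembert's principle the true ground contact wrench is exactly the
#' negative of this aggregate.
#'
#' @param model a [body_model].
#' @param kin segment kinematics from [forward_kinematics()].
#' @return A `"wrench"` about the world position of `O0`.
#' @export
aggregate_inertial_wrench <- function(model, kin) {
  g <- model$gravity
  O0 <- kin$origin_point
  F_tot <- c(0, 0, 0)
  M_tot <- c(0, 0, 0)
  for (s in kin$segments) {
    seg <- model$segments[[s$name]]
    if (seg$mass > 0) {
      Fi <- seg$mass * (g - s$com_acc)
      F_tot <- F_tot + Fi
      M_tot <- M_tot + cross3(s$com_pos - O0, Fi)
    }
    Iw <- s$rotation %*% seg$inertia %*% t(s$rotation)
    Ti <- -(Iw %*% s$ang_acc + cross3(s$ang_vel, as.numeric(Iw %*% s$ang_vel)))
    M_tot <- M_tot + as.numeric(Ti)
  }
  wrench(F_tot, M_tot, O0)
}

#' Reduce a wrench to its central (screw) axis
#'
#' Poinsot reduction: every wrench with nonzero force is equipollent to the
#' same force acting along a unique line (the central axis) plus a couple
#' collinear with the force. The couple is the projection of the moment onto
#' the force direction, `T = ((F . M)/|F|^2) F`, and the axis passes through
#' `ref_point + p` with perpendicular offset `p = (F x M)/|F|^2`.
#'
#' @param w a [wrench()].
#' @param tol minimum |force| (N) below which the axis is undefined.
#' @return An object of class `"central_axis_wrench"` with fields `force`,
#'   `couple` (collinear with `force`), `axis_point` (the offset `p` from the
#'   wrench's reference point) and `ref_point`.
#' @export
central_axis_reduction <- function(w, tol = 1e-9) {
  stopifnot(inherits(w, "wrench"))
  F <- w$force
  f2 <- sum(F * F)
  if (sqrt(f2) < tol) {
    stop("pure couple: |force| below tolerance, central axis undefined")
  }
  couple <- (sum(F * w$moment) / f2) * F
  p <- cross3(F, w$moment) / f2
  structure(list(force = F, couple = couple, axis_point = p,
                 ref_point = w$ref_point),
            class = "central_axis_wrench")
}

# Moment of a central-axis wrench about an arbitrary probe point (test hook:
# must agree with the original wrench's moment about the same point).
caw_moment_about <- function(caw, point) {
  on_axis <- caw$ref_point + caw$axis_point
  caw$couple + cross3(on_axis - point, caw$force)
}
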