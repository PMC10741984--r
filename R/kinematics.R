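#' Construct a motion sample
#'
#' One time-stamped state of the whole body: floating-base pose (translation
#' plus intrinsic X-Y-Z rotation angles) and the actuated joint angles, with
#' their first and second time derivatives. Missing derivatives default to
#' zero (a static pose).
#'
#' @param t time, s.
#' @param base_position,base_velocity,base_acceleration numeric length-3, m,
#'   m/s, m/s^2.
#' @param base_orientation,base_ang_velocity,base_ang_acceleration numeric
#'   length-3: intrinsic X-Y-Z rotation angles (rad) and their rates.
#' @param theta,theta_dot,theta_ddot named or ordered numeric vectors over the
#'   model's actuated DOFs (rad, rad/s, rad/s^2).
#' @return An object of class `"motion_sample"`.
#' @export
motion_sample <- function(t = 0,
                          base_position = c(0, 0, 0),
                          base_orientation = c(0, 0, 0),
                          theta = numeric(0),
                          theta_dot = NULL, theta_ddot = NULL,
                          base_velocity = c(0, 0, 0),
                          base_ang_velocity = c(0, 0, 0),
                          base_acceleration = c(0, 0, 0),
                          base_ang_acceleration = c(0, 0, 0)) {
  theta <- as.numeric(theta)
  n <- length(theta)
  theta_dot <- theta_dot %||% numeric(n)
  theta_ddot <- theta_ddot %||% numeric(n)
  if (length(theta_dot) != n || length(theta_ddot) != n) {
    stop("theta, theta_dot and theta_ddot must have the same length")
  }
  structure(list(t = t,
                 q = c(as.numeric(base_position), as.numeric(base_orientation), theta),
                 qd = c(as.numeric(base_velocity), as.numeric(base_ang_velocity),
                        as.numeric(theta_dot)),
                 qdd = c(as.numeric(base_acceleration), as.numeric(base_ang_acceleration),
                         as.numeric(theta_ddot))),
            class = "motion_sample")
}

# Sequential revolute axes: propagate rotation, angular velocity and angular
# acceleration through an ordered list of axes fixed in the parent chain.
seq_revolute <- function(axes, th, thd, thdd, R_parent, w_parent, al_parent) {
  R_pref <- diag(3L)
  w <- w_parent; al <- al_parent
  axes_w <- vector("list", length(axes))
  for (j in seq_along(axes)) {
    a_w <- as.numeric(R_parent %*% (R_pref %*% axes[[j]]))
    al <- al + thdd[j] * a_w + thd[j] * cross3(w, a_w)
    w <- w + thd[j] * a_w
    axes_w[[j]] <- a_w
    R_pref <- R_pref %*% rot_axis_angle(axes[[j]], th[j])
  }
  list(R = R_parent %*% R_pref, w = w, al = al, axes_w = axes_w)
}

#' World-frame segment kinematics for one motion sample
#'
#' Propagates poses, velocities and accelerations through the segment tree
#' (root first), returning for every segment its world rotation, frame-origin
#' position, com position/velocity/acceleration, angular velocity and angular
#' acceleration, plus per-DOF world joint axes and joint centres (used by the
#' inverse dynamics), the world position of the wrench reference point `O0`,
#' and the world-frame heel/toe points and contours of both feet.
#'
#' @param model a [body_model].
#' @param sample a [motion_sample()], or a list with elements `q`, `qd`, `qdd`
#'   ordered as `c(base coordinates, actuated DOFs)`.
#' @return An object of class `"segment_kinematics"`.
#' @export
forward_kinematics <- function(model, sample) {
  q <- sample$q; qd <- sample$qd; qdd <- sample$qdd
  n_exp <- 6L + length(model$dof_names)
  if (length(q) != n_exp) {
    stop("DOF mismatch: sample has ", length(q) - 6L, " actuated DOFs, model has ",
         length(model$dof_names))
  }
  qd <- qd %||% numeric(n_exp); qdd <- qdd %||% numeric(n_exp)

  out <- list()
  i_dof <- 7L
  world_axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (seg in model$segments) {
    nm <- seg$name
    if (is.na(seg$parent)) {
      rot <- seq_revolute(world_axes, q[4:6], qd[4:6], qdd[4:6],
                          diag(3L), c(0, 0, 0), c(0, 0, 0))
      pos <- q[1:3]; vel <- qd[1:3]; acc <- qdd[1:3]
      dof_axes <- list()
    } else {
      par <- out[[seg$parent]]
      nd <- length(seg$joint_axes)
      idx <- if (nd) i_dof:(i_dof + nd - 1L) else integer(0)
      i_dof <- i_dof + nd
      ro <- as.numeric(par$rotation %*% seg$joint_origin)
      pos <- par$position + ro
      vel <- par$vel + cross3(par$ang_vel, ro)
      acc <- par$acc + cross3(par$ang_acc, ro) +
        cross3(par$ang_vel, cross3(par$ang_vel, ro))
      rot <- seq_revolute(seg$joint_axes, q[idx], qd[idx], qdd[idx],
                          par$rotation, par$ang_vel, par$ang_acc)
      dof_axes <- rot$axes_w
    }
    r <- as.numeric(rot$R %*% seg$com)
    out[[nm]] <- list(name = nm, rotation = rot$R, position = pos,
                      vel = vel, acc = acc,
                      ang_vel = rot$w, ang_acc = rot$al,
                      com_pos = pos + r,
                      com_vel = vel + cross3(rot$w, r),
                      com_acc = acc + cross3(rot$al, r) +
                        cross3(rot$w, cross3(rot$w, r)),
                      dof_axes = dof_axes, dof_names = seg$dof_names)
  }

  feet <- lapply(model$feet, function(f) {
    s <- out[[f$segment]]
    to_world <- function(p) s$position + as.numeric(s$rotation %*% p)
    contour_w <- t(apply(f$contour, 1L, to_world))
    list(side = f$side, segment = f$segment,
         heel = to_world(f$heel), toe = to_world(f$toe),
         contour = contour_w, lf = f$lf)
  })

  structure(list(t = sample$t %||% NA_real_, segments = out,
                 origin_point = out[[model$origin_segment]]$position,
                 feet = feet),
            class = "segment_kinematics")
}
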