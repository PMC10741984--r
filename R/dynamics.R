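# Inverse dynamics: actuated joint moments for given kinematics and contact
# forces, as a recursive Newton-Euler backward pass over the segment tree
# with D'Alembert segment wrenches. For fixed kinematics the joint-moment
# vector is an affine function of the applied contact forces -- the property
# the closed-form split-fraction minimisation rests on.

# Precompute everything that does not depend on the contact forces and
# return a fast evaluator: contacts -> named joint-moment vector.
# contacts: list with optional $left/$right, each list(point, force), world.
make_moment_evaluator <- function(model, kin) {
  seg_names <- names(model$segments)
  children <- lapply(setNames(seg_names, seg_names), function(x) character(0))
  for (s in model$segments) {
    if (!is.na(s$parent)) children[[s$parent]] <- c(children[[s$parent]], s$name)
  }
  descendants <- list()
  for (nm in rev(seg_names)) {  # reverse topological: children first
    descendants[[nm]] <- c(nm, unlist(lapply(children[[nm]], function(ch)
      descendants[[ch]]), use.names = FALSE))
  }

  # per-segment D'Alembert wrench: force at com + rotational couple
  dal <- lapply(seg_names, function(nm) {
    seg <- model$segments[[nm]]
    s <- kin$segments[[nm]]
    Fi <- seg$mass * (model$gravity - s$com_acc)
    Iw <- s$rotation %*% seg$inertia %*% t(s$rotation)
    Ti <- -as.numeric(Iw %*% s$ang_acc) -
      cross3(s$ang_vel, as.numeric(Iw %*% s$ang_vel))
    list(F = Fi, com = s$com_pos, T = Ti)
  })
  names(dal) <- seg_names

  foot_seg <- c(left = model$feet$left$segment, right = model$feet$right$segment)

  dofs <- list()
  for (nm in seg_names) {
    s <- kin$segments[[nm]]
    if (!length(s$dof_names)) next
    sub <- descendants[[nm]]
    p <- s$position
    # static (no-contact) moment of the subtree's D'Alembert loads about p
    Msub <- c(0, 0, 0)
    for (d in dal[sub]) {
      Msub <- Msub + cross3(d$com - p, d$F) + d$T
    }
    feet_here <- names(foot_seg)[foot_seg %in% sub]
    for (j in seq_along(s$dof_names)) {
      axis <- s$dof_axes[[j]]
      dofs[[s$dof_names[[j]]]] <- list(axis = axis, p = p,
                                       T0 = -sum(axis * Msub),
                                       feet = feet_here)
    }
  }
  dofs <- dofs[model$dof_names]

  function(contacts = list()) {
    out <- numeric(length(dofs))
    for (i in seq_along(dofs)) {
      d <- dofs[[i]]
      Tc <- 0
      for (side in d$feet) {
        ct <- contacts[[side]]
        if (is.null(ct)) next
        Tc <- Tc + sum(d$axis * cross3(ct$point - d$p, ct$force))
      }
      out[i] <- d$T0 - Tc
    }
    names(out) <- names(dofs)
    out
  }
}

#' Actuated joint moments for given contacts
#'
#' For each actuated DOF j, the joint moment is the negative projection onto
#' the joint axis of the total moment, about the joint centre, of all
#' D'Alembert (gravity + inertia) wrenches and contact forces acting on the
#' distal subtree -- the backward pass of a recursive Newton-Euler scheme.
#' Contact loads are pure forces at the COPs (sole moments are neglected
#' throughout), so no contact couple enters the recursion.
#'
#' @param model a [body_model].
#' @param kin segment kinematics from [forward_kinematics()].
#' @param contacts list with optional elements `left` and `right`, each a
#'   list with `point` (world application point, m) and `force` (world, N).
#' @return Named numeric vector of joint moments, N m, over
#'   `model$dof_names`.
#' @export
joint_moments <- function(model, kin, contacts = list()) {
  for (ct in contacts) {
    if (!is.null(ct) && (!all(is.finite(ct$point)) || !all(is.finite(ct$force)))) {
      stop("non-finite contact application point or force")
    }
  }
  make_moment_evaluator(model, kin)(contacts)
}
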