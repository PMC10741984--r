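# The minimum-energy hypothesis: among all contact distributions consistent
# with the decoupled balance, pick the one minimising a stiffness-weighted
# sum of squared joint moments E = sum_i f_i T_i^2. Joints are grouped into
# four classes; the weight of hip flexion/extension is fixed at 1 and the
# remaining factors [q0, q1, q2] (hip ab/adduction, knee, ankle) are
# inversely proportional to the joint stiffnesses.

#' Joint weight factors for the energy objective
#'
#' @param q0 weight for hip abduction/adduction (default 1.0).
#' @param q1 weight for knee flexion/extension (default 2.1).
#' @param q2 weight for ankle flexion/extension (default 0.1).
#' @param hip_fe reference weight for hip flexion/extension (1 by
#'   convention; only the ratios matter -- scaling all factors by a positive
#'   constant leaves every minimiser unchanged).
#' @param ... additional named class weights (e.g. `other = 1`).
#' @return A named numeric vector of class `"energy_model"` mapping joint
#'   class to weight.
#' @export
energy_factors <- function(q0 = 1.0, q1 = 2.1, q2 = 0.1, hip_fe = 1.0, ...) {
  f <- c(hip_fe = hip_fe, hip_aa = q0, knee = q1, ankle = q2, ...)
  if (any(!is.finite(f)) || any(f <= 0)) stop("all weight factors must be > 0")
  structure(f, class = "energy_model")
}

# per-DOF weights for a model
dof_factors <- function(model, em) {
  f <- unclass(em)[model$dof_classes]
  if (anyNA(f)) {
    stop("missing joint-class factor for class(es): ",
         paste(unique(model$dof_classes[is.na(f)]), collapse = ", "))
  }
  setNames(as.numeric(f), model$dof_names)
}

#' Weighted joint-energy objective
#'
#' `E = sum_i f_i T_i^2` over the actuated DOFs, with `f_i` looked up from
#' the DOF's joint class.
#'
#' @param moments named joint-moment vector (N m) over `model$dof_names`.
#' @param model a [body_model].
#' @param em an [energy_factors()] object.
#' @return The scalar objective value.
#' @export
joint_energy <- function(moments, model, em = energy_factors()) {
  f <- dof_factors(model, em)
  sum(f * moments[names(f)]^2)
}

# Everything about one motion sample that the double-support machinery
# needs: kinematics, aggregate wrench, central axis, support state, and
# (when double) the contact geometry and a fast joint-moment evaluator.
sample_context <- function(model, sample, edge_tol = 1e-3) {
  kin <- forward_kinematics(model, sample)
  w <- aggregate_inertial_wrench(model, kin)
  caw <- central_axis_reduction(w)
  state <- classify_support(caw, kin, edge_tol = edge_tol)
  ctx <- list(kin = kin, w = w, caw = caw, state = state,
              evaluator = make_moment_evaluator(model, kin))
  if (state$phase == "double") ctx$geom <- contact_geometry(kin, caw)
  ctx
}

# Contacts (world application point + force per foot) for a candidate (a, k).
contacts_for <- function(ctx, a, k, b = NULL) {
  frame <- ddcs_frame(ctx$geom, a, b)
  sys <- solve_decoupled(frame, ctx$w)
  sp <- split_axial(sys, k)
  list(left = list(point = sp$left$cop, force = sp$left$force_world),
       right = list(point = sp$right$cop, force = sp$right$force_world),
       sys = sys, split = sp)
}

#' Feasible range of the left COP parameter
#'
#' Scans `a` over `[0, lf_left]` at `grid_step` and masks the grid points
#' whose coupled right-foot parameter `b(a)` falls outside `[0, lf_right]`
#' (or where the coupling is degenerate). Both COPs must lie on their
#' heel-toe segments.
#'
#' @param geom a [contact_geometry()].
#' @param grid_step scan step, m.
#' @return An object of class `"feasible_range"`: `a_grid`, `b_grid`,
#'   `mask`, and the mask extremes `a1`, `a2`.
#' @export
feasible_a_range <- function(geom, grid_step) {
  a_grid <- seq(0, geom$lf_left, by = grid_step)
  if (a_grid[length(a_grid)] < geom$lf_left - 1e-12) {
    a_grid <- c(a_grid, geom$lf_left)
  }
  b_grid <- vapply(a_grid, function(a) {
    tryCatch(coupled_b(a, geom), error = function(e) NA_real_)
  }, 0)
  mask <- is.finite(b_grid) & b_grid >= 0 & b_grid <= geom$lf_right
  if (!any(mask)) stop("no feasible COP pairing: empty feasible range for a")
  structure(list(a_grid = a_grid, b_grid = b_grid, mask = mask,
                 a1 = min(a_grid[mask]), a2 = max(a_grid[mask])),
            class = "feasible_range")
}

# Per-sample, per-grid-point precomputation for the double-support
# optimisation. Because T is affine in the contact forces and the contacts
# are affine in k for fixed a, T(k) = t0 + k t1 with t0 = T(k=0) and
# t1 = T(k=1) - t0; the energy quadratic's coefficients are then
# e0 = sum f t1^2, e1 = 2 sum f t0 t1, e2 = sum f t0^2, accumulated per
# joint class so that any factor combination can be evaluated cheaply
# (this is what makes the 2500-point calibration grid tractable).
precompute_double <- function(model, ctx, grid_step) {
  fr <- feasible_a_range(ctx$geom, grid_step)
  idx <- which(fr$mask)
  classes <- unique(model$dof_classes)
  cls_of <- factor(model$dof_classes, levels = classes)
  nA <- length(idx)
  U <- V <- W <- matrix(0, nA, length(classes), dimnames = list(NULL, classes))
  T0m <- T1m <- matrix(NA_real_, nA, length(model$dof_names),
                       dimnames = list(NULL, model$dof_names))
  FL0 <- FL1 <- FR0 <- FR1 <- matrix(NA_real_, nA, 3L)
  copL <- copR <- matrix(NA_real_, nA, 3L)
  meta <- matrix(NA_real_, nA, 4L,
                 dimnames = list(NULL, c("a", "b", "dropped_MXD", "lr")))
  ok <- logical(nA)
  for (ii in seq_len(nA)) {
    a <- fr$a_grid[idx[ii]]; b <- fr$b_grid[idx[ii]]
    res <- tryCatch({
      frame <- ddcs_frame(ctx$geom, a, b)
      sys <- solve_decoupled(frame, ctx$w)
      s0 <- split_axial(sys, 0)
      s1 <- split_axial(sys, 1)
      t0 <- ctx$evaluator(list(left = list(point = s0$left$cop, force = s0$left$force_world),
                               right = list(point = s0$right$cop, force = s0$right$force_world)))
      tk1 <- ctx$evaluator(list(left = list(point = s1$left$cop, force = s1$left$force_world),
                                right = list(point = s1$right$cop, force = s1$right$force_world)))
      list(sys = sys, s0 = s0, s1 = s1, t0 = t0, t1 = tk1 - t0)
    }, error = function(e) NULL)
    if (is.null(res)) next
    ok[ii] <- TRUE
    t0 <- res$t0; t1 <- res$t1
    U[ii, ] <- tapply(t1 * t1, cls_of, sum, default = 0)[classes]
    V[ii, ] <- tapply(t0 * t1, cls_of, sum, default = 0)[classes]
    W[ii, ] <- tapply(t0 * t0, cls_of, sum, default = 0)[classes]
    T0m[ii, ] <- t0; T1m[ii, ] <- t1
    FL0[ii, ] <- res$s0$left$force_world
    FL1[ii, ] <- res$s1$left$force_world - res$s0$left$force_world
    FR0[ii, ] <- res$s0$right$force_world
    FR1[ii, ] <- res$s1$right$force_world - res$s0$right$force_world
    copL[ii, ] <- res$s0$left$cop; copR[ii, ] <- res$s0$right$cop
    meta[ii, ] <- c(a, b, res$sys$dropped_MXD, res$sys$frame$l + res$sys$frame$r)
  }
  if (!any(ok)) stop("estimation failure: no valid DDCS at any feasible a")
  keep <- which(ok)
  list(range = fr, classes = classes,
       U = U[keep, , drop = FALSE], V = V[keep, , drop = FALSE],
       W = W[keep, , drop = FALSE],
       T0 = T0m[keep, , drop = FALSE], T1 = T1m[keep, , drop = FALSE],
       FL0 = FL0[keep, , drop = FALSE], FL1 = FL1[keep, , drop = FALSE],
       FR0 = FR0[keep, , drop = FALSE], FR1 = FR1[keep, , drop = FALSE],
       copL = copL[keep, , drop = FALSE], copR = copR[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

# Closed-form inner minimisation over k for every precomputed a, then the
# grid argmin over a. Ties in E (within 1e-9 relative) break toward smaller
# a, then smaller |k - 1/2|, so output is deterministic.
# Returns list(i, a, b, k, E, e0, e1, e2, n_skipped) or NULL if all a skipped.
traverse_minimum <- function(pre, f_cls, clamp_k = FALSE) {
  e0 <- drop(pre$U %*% f_cls)
  e1 <- 2 * drop(pre$V %*% f_cls)
  e2 <- drop(pre$W %*% f_cls)
  valid <- e0 > 1e-12
  if (!any(valid)) return(NULL)
  k <- rep(NA_real_, length(e0))
  k[valid] <- -e1[valid] / (2 * e0[valid])
  if (clamp_k) k[valid] <- pmin(1, pmax(0, k[valid]))
  E <- e0 * k^2 + e1 * k + e2
  E[!valid] <- Inf
  Emin <- min(E)
  thr <- Emin + 1e-9 * abs(Emin) + 1e-300
  cand <- which(E <= thr)
  a <- pre$meta[cand, "a"]
  cand <- cand[order(a, abs(k[cand] - 0.5))]
  i <- cand[[1L]]
  list(i = i, a = unname(pre$meta[i, "a"]), b = unname(pre$meta[i, "b"]),
       k = k[i], E = E[i],
       e0 = e0[i], e1 = e1[i], e2 = e2[i], n_skipped = sum(!valid))
}

#' Estimate the contact solution for a single motion sample
#'
#' Single-support samples short-circuit to the exact closed-form solution
#' ([single_support_solution()]); no optimisation is invoked. For
#' double-support samples the traversal runs over the feasible grid of the
#' left COP parameter `a`: at each `a` the decoupled system is solved, the
#' energy `E(k)` -- exactly quadratic in the split fraction `k` because the
#' joint moments are affine in the contacts -- is minimised in closed form at
#' `k* = -e1 / (2 e0)`, and the global minimiser over the grid is returned.
#' Grid points with `e0 <= 1e-12` (flat or concave direction) are skipped
#' with a diagnostic; if every point is skipped the sample is an estimation
#' failure.
#'
#' @param model a [body_model].
#' @param sample a [motion_sample()].
#' @param em an [energy_factors()] object.
#' @param grid_step traversal step for `a`, m; defaults to `lf / 200`.
#' @param clamp_k clamp the split fraction into `[0, 1]`.
#' @param edge_tol contour edge tolerance for support classification, m.
#' @return A `"contact_solution"`.
#' @export
optimize_sample <- function(model, sample, em = energy_factors(),
                            grid_step = NULL, clamp_k = FALSE,
                            edge_tol = 1e-3) {
  ctx <- sample_context(model, sample, edge_tol = edge_tol)
  grid_step <- grid_step %||% (model$feet$left$lf / 200)
  f <- dof_factors(model, em)
  if (ctx$state$phase != "double") {
    sol <- single_support_solution(ctx$w, ctx$caw, ctx$state, ctx$kin)
    side <- if (ctx$state$phase == "left_single") "left" else "right"
    tm <- ctx$evaluator(setNames(list(list(point = sol[[side]]$cop,
                                           force = sol[[side]]$force_world)), side))
    sol$joint_moments <- tm
    sol$energy <- sum(f * tm^2)
    return(sol)
  }
  pre <- precompute_double(model, ctx, grid_step)
  f_cls <- unclass(em)[pre$classes]
  best <- traverse_minimum(pre, f_cls, clamp_k = clamp_k)
  if (is.null(best)) {
    stop("estimation failure: energy flat in k (e0 <= 1e-12) at every feasible a")
  }
  i <- best$i; k <- best$k
  tm <- pre$T0[i, ] + k * pre$T1[i, ]
  new_contact_solution(
    t = ctx$kin$t, phase = "double", a = best$a, b = best$b, k = k,
    energy = best$E,
    left = list(force_world = pre$FL0[i, ] + k * pre$FL1[i, ],
                force_ddcs = c(NA_real_, NA_real_, NA_real_),
                cop = pre$copL[i, ]),
    right = list(force_world = pre$FR0[i, ] + k * pre$FR1[i, ],
                 force_ddcs = c(NA_real_, NA_real_, NA_real_),
                 cop = pre$copR[i, ]),
    joint_moments = tm,
    dropped_MXD = unname(pre$meta[i, "dropped_MXD"]),
    warning = ctx$state$warning,
    search = c(a = unname(best$a), k = unname(k)))
}

#' Brute-force reference minimiser over (a, k)
#'
#' Independent cross-check for the traversal + closed-form estimator: scans
#' `a` on its own (typically finer) grid and, at each `a`, minimises the
#' energy by direct evaluation -- solve the decoupled system, split, run the
#' inverse dynamics, evaluate `E` -- using Brent's method in `k`, with no
#' quadratic assumption anywhere. Also used to synthesise "energy-minimal"
#' ground truth.
#'
#' @param model,sample,em,edge_tol as in [optimize_sample()].
#' @param a_step scan step for `a`, m.
#' @param k_interval search interval for `k`.
#' @param k_tol Brent tolerance on `k`.
#' @return A list with `a`, `b`, `k`, `E`.
#' @export
exhaustive_minimum <- function(model, sample, em = energy_factors(),
                               a_step = NULL, k_interval = c(-10, 11),
                               k_tol = 1e-7, edge_tol = 1e-3) {
  ctx <- sample_context(model, sample, edge_tol = edge_tol)
  if (ctx$state$phase != "double") stop("exhaustive_minimum requires double support")
  a_step <- a_step %||% (model$feet$left$lf / 800)
  f <- dof_factors(model, em)
  fr <- feasible_a_range(ctx$geom, a_step)
  best <- NULL
  for (i in which(fr$mask)) {
    a <- fr$a_grid[i]; b <- fr$b_grid[i]
    Ek <- function(k) {
      ct <- contacts_for(ctx, a, k, b)
      tm <- ctx$evaluator(ct[c("left", "right")])
      sum(f * tm^2)
    }
    opt <- tryCatch(stats::optimize(Ek, interval = k_interval, tol = k_tol),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$E) {
      best <- list(a = a, b = b, k = opt$minimum, E = opt$objective)
    }
  }
  if (is.null(best)) stop("no feasible (a, k) found")
  best
}
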