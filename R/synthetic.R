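# Synthetic anthropometric models, kinematically consistent walking
# trajectories and ground-truth contact wrenches. Everything is seeded and
# analytic: joint-angle trajectories are smooth low-order waves with exact
# first and second derivatives, so the rigid-body kinematics are internally
# consistent by construction. The gait is exercise-grade, not biofidelic --
# it exists so that every stage of the estimator can be tested without any
# external dataset.

# Winter-style anthropometric constants (fractions of body height / mass),
# rounded; the torso entry absorbs the head so the 12 segments sum to 1.
.mass_fractions <- c(pelvis = 0.142, torso = 0.436,
                     upper_arm = 0.028, forearm = 0.022,
                     thigh = 0.100, shank = 0.0465, foot = 0.0145)
.length_fractions <- c(thigh = 0.245, shank = 0.246, foot = 0.152,
                       ankle_height = 0.039, hip_offset = 0.095,
                       foot_halfwidth = 0.029)

rod_inertia <- function(m, L) {
  It <- m * L^2 / 12
  diag(c(It, It, 0.1 * It + 1e-6), 3L)
}

#' Generate an anthropometric body-model configuration
#'
#' Builds a 12-segment model -- pelvis, torso (head included), and left/right
#' upper arm, forearm, thigh, shank and foot -- scaled from standard
#' segment-mass and segment-length fractions of total mass and height. The
#' arms are welded (no DOFs); each leg has a 2-DOF hip
#' (flexion/extension about Y, then abduction/adduction about X), a 1-DOF
#' knee and a 1-DOF ankle, for 8 actuated DOFs. Each foot carries a 6-point
#' sole contour around its heel-toe segment.
#'
#' @param height standing height, m (0.5 to 2.5).
#' @param mass total mass, kg (10 to 200).
#' @return A model configuration list accepted by [load_body_model()].
#' @export
generate_model <- function(height = 1.75, mass = 70) {
  if (height < 0.5 || height > 2.5) stop("implausible height: ", height, " m")
  if (mass < 10 || mass > 200) stop("implausible mass: ", mass, " kg")
  H <- height
  mf <- .mass_fractions * mass
  lf_ <- .length_fractions * H
  Lt <- lf_[["thigh"]]; Ls <- lf_[["shank"]]; lf_foot <- lf_[["foot"]]
  ha <- lf_[["ankle_height"]]; hip_y <- lf_[["hip_offset"]]
  w <- lf_[["foot_halfwidth"]]

  leg <- function(side) {
    sgn <- if (side == "l") 1 else -1
    hx <- -0.25 * lf_foot; tx <- 0.75 * lf_foot
    m <- 0.015
    list(
      list(name = paste0("thigh_", side), parent = "pelvis",
           joint_origin = c(0, sgn * hip_y, 0),
           joint_axes = list(c(0, 1, 0), c(1, 0, 0)),
           dof_names = paste0(c("hip_fe_", "hip_aa_"), side),
           joint_classes = c("hip_fe", "hip_aa"),
           mass = mf[["thigh"]], com = c(0, 0, -0.433 * Lt),
           inertia = rod_inertia(mf[["thigh"]], Lt), length = Lt),
      list(name = paste0("shank_", side), parent = paste0("thigh_", side),
           joint_origin = c(0, 0, -Lt), joint_axes = list(c(0, 1, 0)),
           dof_names = paste0("knee_", side), joint_classes = "knee",
           mass = mf[["shank"]], com = c(0, 0, -0.433 * Ls),
           inertia = rod_inertia(mf[["shank"]], Ls), length = Ls),
      list(name = paste0("foot_", side), parent = paste0("shank_", side),
           joint_origin = c(0, 0, -Ls), joint_axes = list(c(0, 1, 0)),
           dof_names = paste0("ankle_", side), joint_classes = "ankle",
           mass = mf[["foot"]], com = c(0.25 * lf_foot, 0, -0.5 * ha),
           inertia = rod_inertia(mf[["foot"]], lf_foot), length = lf_foot))
  }
  arm <- function(side) {
    sgn <- if (side == "l") 1 else -1
    Lu <- 0.186 * H; Lfa <- 0.16 * H
    list(
      list(name = paste0("upper_arm_", side), parent = "torso",
           joint_origin = c(0, sgn * 0.129 * H, 0.24 * H),
           mass = mf[["upper_arm"]], com = c(0, 0, -0.436 * Lu),
           inertia = rod_inertia(mf[["upper_arm"]], Lu), length = Lu),
      list(name = paste0("forearm_", side), parent = paste0("upper_arm_", side),
           joint_origin = c(0, 0, -Lu),
           mass = mf[["forearm"]], com = c(0, 0, -0.43 * Lfa),
           inertia = rod_inertia(mf[["forearm"]], Lfa), length = Lfa))
  }
  foot_contour <- function() {
    hx <- -0.25 * lf_foot; tx <- 0.75 * lf_foot; m <- 0.015
    mid <- 0.5 * (hx + tx)
    rbind(c(hx - m, w, -ha), c(mid, w, -ha), c(tx + m, w, -ha),
          c(tx + m, -w, -ha), c(mid, -w, -ha), c(hx - m, -w, -ha))
  }
  segments <- c(
    list(list(name = "pelvis", parent = NA,
              mass = mf[["pelvis"]], com = c(0, 0, 0.02 * H),
              inertia = rod_inertia(mf[["pelvis"]], 0.1 * H), length = 0.1 * H),
         list(name = "torso", parent = "pelvis", joint_origin = c(0, 0, 0.06 * H),
              mass = mf[["torso"]], com = c(0, 0, 0.18 * H),
              inertia = rod_inertia(mf[["torso"]], 0.45 * H), length = 0.45 * H)),
    arm("l"), arm("r"), leg("l"), leg("r"))
  feet <- list(
    list(side = "left", segment = "foot_l",
         heel = c(-0.25 * lf_foot, 0, -ha), toe = c(0.75 * lf_foot, 0, -ha),
         contour = foot_contour()),
    list(side = "right", segment = "foot_r",
         heel = c(-0.25 * lf_foot, 0, -ha), toe = c(0.75 * lf_foot, 0, -ha),
         contour = foot_contour()))
  list(segments = segments, feet = feet, gravity = c(0, 0, -9.81),
       origin_segment = "pelvis",
       meta = list(height = H, mass = mass))
}

#' Gait generation parameters
#'
#' Defaults are the package's standing study conditions: a slow, deliberate
#' walk (stride period 6 s) whose inertial excursions stay comfortably
#' inside the synthetic foot contours, total double-support fraction 0.20 of
#' the cycle (two double-support episodes per stride), step length 0.12 m,
#' and no cadence jitter.
#'
#' @param stride_period stride (full cycle) period, s.
#' @param double_support total fraction of the cycle spent in double
#'   support, in (0, 0.5).
#' @param step_length fore-aft foot excursion, m.
#' @param knee_lift peak swing knee flexion, rad.
#' @param bob vertical pelvis oscillation amplitude, m.
#' @param dt sample interval, s.
#' @param n_cycles number of strides.
#' @param cadence_noise amplitude of the seeded periodic phase jitter
#'   (dimensionless, 0 = none).
#' @param seed integer seed for the jitter phase.
#' @return A validated list of class `"gait_params"`.
#' @export
gait_params <- function(stride_period = 6, double_support = 0.2,
                        step_length = 0.12, knee_lift = 0.5, bob = 0.004,
                        dt = 0.1, n_cycles = 2, cadence_noise = 0,
                        seed = 1L) {
  stopifnot(stride_period > 0, dt > 0, n_cycles > 0,
            double_support > 0, double_support < 0.5,
            step_length > 0, knee_lift >= 0, cadence_noise >= 0)
  structure(list(stride_period = stride_period, double_support = double_support,
                 step_length = step_length, knee_lift = knee_lift, bob = bob,
                 dt = dt, n_cycles = n_cycles, cadence_noise = cadence_noise,
                 seed = as.integer(seed)),
            class = "gait_params")
}

# evaluate f = A*sin(2*pi*phi + off) (and cos variant) with derivatives,
# given phi, phi', phi'' vectors
wave_sin <- function(A, phi, phid, phidd, off = 0) {
  x <- 2 * pi * phi + off
  xd <- 2 * pi * phid; xdd <- 2 * pi * phidd
  list(v = A * sin(x), d1 = A * cos(x) * xd,
       d2 = A * (-sin(x) * xd^2 + cos(x) * xdd))
}
wave_cos <- function(A, phi, phid, phidd, off = 0, mult = 1) {
  x <- mult * (2 * pi * phi) + off
  xd <- mult * 2 * pi * phid; xdd <- mult * 2 * pi * phidd
  list(v = A * cos(x), d1 = -A * sin(x) * xd,
       d2 = A * (-cos(x) * xd^2 - sin(x) * xdd))
}
wave_neg <- function(a) list(v = -a$v, d1 = -a$d1, d2 = -a$d2)
wave_add <- function(a, b, const = 0) {
  list(v = a$v + b$v + const, d1 = a$d1 + b$d1, d2 = a$d2 + b$d2)
}
# s = tanh(lambda * c)/tanh(lambda) applied to a wave c
wave_tanh <- function(cw, lambda) {
  u <- lambda * cw$v
  se2 <- 1 / cosh(u)^2
  th <- tanh(lambda)
  list(v = tanh(u) / th,
       d1 = lambda * se2 * cw$d1 / th,
       d2 = lambda * (se2 * cw$d2 - 2 * lambda * tanh(u) * se2 * cw$d1^2) / th)
}
# theta = -asin(y/L) applied to a wave y
wave_nasin <- function(yw, L) {
  den <- L^2 - yw$v^2
  list(v = -asin(yw$v / L),
       d1 = -yw$d1 / sqrt(den),
       d2 = -(yw$d2 * den + yw$v * yw$d1^2) / den^1.5)
}
# z = sqrt(L^2 - y^2): vertical hip-to-ankle drop of a leg tilted to keep
# its foot on a fixed lateral track while the pelvis sways by y
wave_leg_drop <- function(yw, L) {
  v <- sqrt(L^2 - yw$v^2)
  d1 <- -yw$v * yw$d1 / v
  list(v = v, d1 = d1,
       d2 = -(yw$d1^2 + yw$v * yw$d2) / v - yw$v^2 * yw$d1^2 / v^3)
}

# Design the lateral sway: choose the tanh flattening lambda and the
# centre-of-mass amplitude so that the predicted ground pierce point (a
# quasi-static ZMP model, com_y - (z/g) com_y'') spends the requested
# single-support fraction inside each foot's lateral contour band.
design_sway <- function(p_s, y_c, w_eff, z_bar, g, Tper) {
  phi <- seq(0, 1, length.out = 4001L)[-1L]
  frac_inside <- function(lambda) {
    cw <- list(v = cos(2 * pi * phi),
               d1 = -sin(2 * pi * phi) * (2 * pi / Tper),
               d2 = -cos(2 * pi * phi) * (2 * pi / Tper)^2)
    s <- wave_tanh(cw, lambda)
    shape <- s$v - (z_bar / g) * s$d2
    Ac <- y_c / max(shape)
    y <- Ac * shape
    mean(y >= y_c - w_eff & y <= y_c + w_eff)
  }
  obj <- function(lambda) (frac_inside(lambda) - p_s)^2
  opt <- stats::optimize(obj, c(0.05, 8))
  lambda <- opt$minimum
  if (sqrt(opt$objective) > 0.03) {
    warning("sway design residual ", format(sqrt(opt$objective)),
            ": requested double-support fraction may be missed")
  }
  cw <- list(v = cos(2 * pi * phi),
             d1 = -sin(2 * pi * phi) * (2 * pi / Tper),
             d2 = -cos(2 * pi * phi) * (2 * pi / Tper)^2)
  s <- wave_tanh(cw, lambda)
  Ac <- y_c / max(s$v - (z_bar / g) * s$d2)
  list(lambda = lambda, A_com = Ac)
}

#' Generate a synthetic walking trajectory
#'
#' Produces a motion table of smooth, strictly periodic joint-angle
#' trajectories with analytically consistent velocities and accelerations.
#' The pelvis sways laterally with a flattened (tanh-shaped) wave tuned so
#' the inertial wrench's ground pierce point dwells inside each foot's
#' contour for the requested single-support fraction; the hips
#' counter-rotate in ab/adduction to keep the feet on their tracks, the
#' legs swing fore-aft with the requested step length, swing knees flex to
#' clear the ground, and the ankles keep the soles level. Each foot's sole
#' reaches the ground plane at its mid-stance. Deterministic for a fixed
#' seed; the seed only enters through the optional cadence jitter phase.
#'
#' @param model a [body_model] produced from [generate_model()] (the DOF
#'   names `hip_fe_*`, `hip_aa_*`, `knee_*`, `ankle_*` are expected).
#' @param params a [gait_params()] list.
#' @return A motion `data.frame` (see [read_motion()] for the layout) with
#'   attributes `seed` and `design` (the realised wave parameters and the
#'   designed support windows).
#' @export
generate_gait <- function(model, params = gait_params()) {
  model <- load_body_model(model)
  p <- params
  need <- c(paste0(c("hip_fe_", "hip_aa_", "knee_", "ankle_"), "l"),
            paste0(c("hip_fe_", "hip_aa_", "knee_", "ankle_"), "r"))
  if (!all(need %in% model$dof_names)) {
    stop("generate_gait requires the standard leg DOF names; got: ",
         paste(model$dof_names, collapse = ", "))
  }
  H <- model$segments$thigh_l$length / .length_fractions[["thigh"]]
  Lt <- model$segments$thigh_l$length
  Ls <- model$segments$shank_l$length
  ha <- .length_fractions[["ankle_height"]] * H
  L_leg <- Lt + Ls
  y_c <- .length_fractions[["hip_offset"]] * H
  w_eff <- .length_fractions[["foot_halfwidth"]] * H + 1e-3
  g <- abs(model$gravity[3L])
  Tper <- p$stride_period
  p_s <- (1 - p$double_support) / 2

  # centre-of-mass gain and height from a static probe of the actual model
  probe <- function(dy) {
    th <- setNames(numeric(length(model$dof_names)), model$dof_names)
    th[c("hip_aa_l", "hip_aa_r")] <- -asin(dy / L_leg)
    s <- motion_sample(base_position = c(0, dy, L_leg + ha), theta = th)
    kin <- forward_kinematics(model, s)
    m <- vapply(model$segments, `[[`, 0, "mass")
    com <- colSums(do.call(rbind, lapply(kin$segments, `[[`, "com_pos")) * m) / sum(m)
    com
  }
  com0 <- probe(0); com1 <- probe(0.01)
  gain <- (com1[2L] - com0[2L]) / 0.01
  z_bar <- com0[3L]

  sw <- design_sway(p_s, y_c, w_eff, z_bar, g, Tper)
  A_base <- sw$A_com / gain

  t <- seq(0, p$n_cycles * Tper, by = p$dt)
  psi <- if (p$cadence_noise > 0) {
    with_seed(p$seed, stats::runif(1, 0, 2 * pi))
  } else 0
  jit <- wave_sin(p$cadence_noise, t / Tper, 1 / Tper, 0, off = psi)
  phi <- t / Tper + jit$v
  phid <- 1 / Tper + jit$d1
  phidd <- jit$d2

  thA <- asin(min(0.99, p$step_length / (2 * L_leg)))
  hip_fe_l <- wave_sin(thA, phi, phid, phidd)
  hip_fe_r <- wave_sin(thA, phi, phid, phidd, off = pi)
  knee_l <- wave_add(wave_neg(wave_cos(p$knee_lift / 2, phi, phid, phidd)),
                     list(v = 0, d1 = 0, d2 = 0), const = p$knee_lift / 2)
  knee_r <- wave_add(wave_cos(p$knee_lift / 2, phi, phid, phidd),
                     list(v = 0, d1 = 0, d2 = 0), const = p$knee_lift / 2)
  sway <- wave_tanh(wave_cos(1, phi, phid, phidd), sw$lambda)
  base_y <- list(v = A_base * sway$v, d1 = A_base * sway$d1, d2 = A_base * sway$d2)
  hip_aa <- wave_nasin(base_y, L_leg)
  ankle_l <- wave_neg(wave_add(hip_fe_l, knee_l))
  ankle_r <- wave_neg(wave_add(hip_fe_r, knee_r))
  # pelvis height follows the sway-tilted leg so the stance sole reaches
  # the ground at mid-stance; the bob term vanishes there
  base_z <- wave_add(wave_leg_drop(base_y, L_leg),
                     wave_cos(p$bob, phi, phid, phidd, mult = 2),
                     const = ha - p$bob)
  zero <- list(v = rep(0, length(t)), d1 = rep(0, length(t)), d2 = rep(0, length(t)))

  cols <- list(base_x = zero, base_y = base_y, base_z = base_z,
               base_rx = zero, base_ry = zero, base_rz = zero,
               hip_fe_l = hip_fe_l, hip_aa_l = hip_aa,
               knee_l = knee_l, ankle_l = ankle_l,
               hip_fe_r = hip_fe_r, hip_aa_r = hip_aa,
               knee_r = knee_r, ankle_r = ankle_r)
  out <- data.frame(time = t)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]$v
  for (nm in names(cols)) out[[paste0(nm, "_vel")]] <- cols[[nm]]$d1
  for (nm in names(cols)) out[[paste0(nm, "_acc")]] <- cols[[nm]]$d2
  attr(out, "seed") <- p$seed
  attr(out, "design") <- list(params = p, lambda = sw$lambda,
                              A_base = A_base, A_com = sw$A_com,
                              p_single = p_s,
                              left_single = c(-p_s / 2, p_s / 2),
                              right_single = c(0.5 - p_s / 2, 0.5 + p_s / 2),
                              phase = function(tt) (tt / Tper) %% 1)
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate ground-truth contact wrenches for a motion table
#'
#' Synthesises a reference contact-force table that satisfies the decoupled
#' balance equations exactly, playing the role of force-plate measurements.
#' Single-support samples carry the exact closed-form reaction. For
#' double-support samples, mode `"arbitrary"` plants smooth seeded profiles
#' of the COP parameter `a` (mapped into the per-sample feasible range) and
#' the split fraction `k`, and evaluates the contacts through the DDCS
#' solve; mode `"energy_minimal"` places `(a, k)` at the brute-force energy
#' minimum under the stated factors ([exhaustive_minimum()]), enabling
#' recovery experiments. Samples with an empty feasible range are excluded
#' with a flag.
#'
#' @param model a [body_model].
#' @param motion a motion `data.frame`.
#' @param mode `"arbitrary"` or `"energy_minimal"`.
#' @param seed seed for the planted profiles.
#' @param em factors used in `"energy_minimal"` mode.
#' @param a_step grid step for the feasible range / brute-force search, m.
#' @param edge_tol contour tolerance for classification, m.
#' @return A data.frame in the estimator's output layout plus an `excluded`
#'   flag column, with attribute `seed`.
#' @export
generate_truth <- function(model, motion, mode = c("arbitrary", "energy_minimal"),
                           seed = 1L, em = energy_factors(), a_step = NULL,
                           edge_tol = 1e-3) {
  mode <- match.arg(mode)
  model <- load_body_model(model)
  a_step <- a_step %||% (model$feet$left$lf / 200)
  samples <- motion_samples(model, motion)
  ph <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  Tp <- max(motion$time) - min(motion$time) + 1e-9

  rows <- lapply(samples, function(s) {
    res <- tryCatch({
      ctx <- sample_context(model, s, edge_tol = edge_tol)
      if (ctx$state$phase != "double") {
        sol <- single_support_solution(ctx$w, ctx$caw, ctx$state, ctx$kin)
        solution_row(s$t, sol)
      } else if (mode == "arbitrary") {
        fr <- feasible_a_range(ctx$geom, a_step)
        frac <- 0.5 + 0.4 * sin(2 * pi * s$t / Tp + ph[1L])
        a <- fr$a1 + frac * (fr$a2 - fr$a1)
        k <- 0.5 + 0.4 * sin(2 * pi * s$t / Tp + ph[2L])
        ct <- contacts_for(ctx, a, k)
        sol <- truth_solution(s$t, ctx, a, k, ct, model, em)
        solution_row(s$t, sol)
      } else {
        best <- exhaustive_minimum(model, s, em = em, a_step = a_step,
                                   edge_tol = edge_tol)
        ct <- contacts_for(ctx, best$a, best$k, best$b)
        sol <- truth_solution(s$t, ctx, best$a, best$k, ct, model, em)
        sol$energy <- best$E
        solution_row(s$t, sol)
      }
    }, error = function(e) solution_row(s$t, conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$excluded <- !is.na(out$error)
  attr(out, "seed") <- seed
  out
}

truth_solution <- function(t, ctx, a, k, ct, model, em) {
  f <- dof_factors(model, em)
  tm <- ctx$evaluator(ct[c("left", "right")])
  new_contact_solution(
    t = t, phase = "double", a = a, b = ct$sys$frame$b, k = k,
    energy = sum(f * tm^2),
    left = list(force_world = ct$left$force, force_ddcs = ct$split$left$force_ddcs,
                cop = ct$left$point),
    right = list(force_world = ct$right$force, force_ddcs = ct$split$right$force_ddcs,
                 cop = ct$right$point),
    joint_moments = tm, dropped_MXD = ct$sys$dropped_MXD,
    warning = ctx$state$warning)
}
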