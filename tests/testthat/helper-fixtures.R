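# Shared fixtures, built in code. All scenes are seeded and small.

# Smallest valid tree: a floating base plus two single-DOF foot segments.
minimal_config <- function() {
  contour <- rbind(c(-0.06, 0.04, 0), c(0.1, 0.04, 0), c(0.22, 0.04, 0),
                   c(0.22, -0.04, 0), c(0.1, -0.04, 0), c(-0.06, -0.04, 0))
  list(
    segments = list(
      list(name = "base", parent = NA, mass = 60, com = c(0, 0, 0),
           inertia = diag(1, 3), length = 0.5),
      list(name = "foot_l", parent = "base", joint_origin = c(0, 0.1, -0.9),
           joint_axes = list(c(0, 1, 0)), dof_names = "ankle_l",
           joint_classes = "ankle", mass = 1, com = c(0.05, 0, 0),
           inertia = diag(0.01, 3), length = 0.25),
      list(name = "foot_r", parent = "base", joint_origin = c(0, -0.1, -0.9),
           joint_axes = list(c(0, 1, 0)), dof_names = "ankle_r",
           joint_classes = "ankle", mass = 1, com = c(0.05, 0, 0),
           inertia = diag(0.01, 3), length = 0.25)),
    feet = list(
      list(side = "left", segment = "foot_l", heel = c(-0.05, 0, 0),
           toe = c(0.2, 0, 0), contour = contour),
      list(side = "right", segment = "foot_r", heel = c(-0.05, 0, 0),
           toe = c(0.2, 0, 0), contour = contour)),
    origin_segment = "base")
}

# Single revolute pendulum hanging from a fixed (massless) base.
pendulum_model <- function(r = 0.4, m = 2) {
  cfg <- minimal_config()
  cfg$segments[[4]] <- list(name = "rod", parent = "base",
                            joint_origin = c(0, 0, 0),
                            joint_axes = list(c(0, 1, 0)),
                            dof_names = "pivot", joint_classes = "other",
                            mass = m, com = c(0, 0, -r),
                            inertia = diag(0, 3), length = r)
  cfg$segments[[1]]$mass <- 0
  cfg$segments[[2]]$mass <- 0
  cfg$segments[[3]]$mass <- 0
  load_body_model(cfg)
}

default_model <- function(height = 1.75, mass = 70) {
  load_body_model(generate_model(height, mass))
}

default_gait <- function(model, dt = 0.1, n_cycles = 2, ...) {
  generate_gait(model, gait_params(dt = dt, n_cycles = n_cycles, ...))
}

# Collect up to n samples of a given classified phase from a motion table.
collect_samples <- function(model, motion, phase = "double", n = Inf) {
  ss <- cfmest:::motion_samples(model, motion)
  out <- list()
  for (s in ss) {
    ctx <- tryCatch(cfmest:::sample_context(model, s), error = function(e) NULL)
    if (is.null(ctx)) next
    if (ctx$state$phase == phase ||
        (phase == "single" && ctx$state$phase != "double")) {
      out[[length(out) + 1L]] <- list(sample = s, ctx = ctx)
      if (length(out) >= n) break
    }
  }
  out
}

# Hand-built double-support contact geometry (fields as contact_geometry()).
manual_geometry <- function(A, B, C, D, P, F_dir) {
  structure(list(A = A, B = B, C = C, D = D, P = P, F_dir = F_dir / sqrt(sum(F_dir^2)),
                 lf_left = sqrt(sum((B - A)^2)), lf_right = sqrt(sum((D - C)^2)),
                 uAB = (B - A) / sqrt(sum((B - A)^2)),
                 uCD = (D - C) / sqrt(sum((D - C)^2))),
            class = "contact_geometry")
}

# Random valid double-support geometry: feet flat on the ground, axis point
# above the stance area, force pointing mostly downward.
random_geometry <- function() {
  repeat {
    A <- c(stats::runif(1, -0.1, 0.1), stats::runif(1, 0.05, 0.25), 0)
    ang <- stats::runif(1, -0.5, 0.5)
    B <- A + 0.26 * c(cos(ang), sin(ang), 0)
    C <- c(stats::runif(1, -0.1, 0.1), stats::runif(1, -0.25, -0.05), 0)
    ang2 <- stats::runif(1, -0.5, 0.5)
    D <- C + 0.26 * c(cos(ang2), sin(ang2), 0)
    P <- c(stats::runif(1, -0.05, 0.15), stats::runif(1, -0.05, 0.05),
           stats::runif(1, 0.8, 1.1))
    F_dir <- c(stats::runif(1, -0.15, 0.15), stats::runif(1, -0.15, 0.15), -1)
    g <- manual_geometry(A, B, C, D, P, F_dir)
    b <- tryCatch(coupled_b(0.13, g), error = function(e) NA_real_)
    if (is.finite(b) && b > 0.02 && b < g$lf_right - 0.02) return(g)
  }
}
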