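test_that("wrench transfer is consistent and round-trips", {
  set.seed(11)
  w <- wrench(stats::rnorm(3), stats::rnorm(3), stats::rnorm(3))
  p <- stats::rnorm(3)
  w2 <- transfer_wrench(w, p)
  expect_equal(w2$force, w$force)
  w3 <- transfer_wrench(w2, w$ref_point)
  expect_equal(w3$moment, w$moment, tolerance = 1e-12)
})

test_that("a static pose yields the pure weight wrench", {
  model <- default_model(1.75, 70)
  # static double stance: all coordinates and rates zero, pelvis at leg height
  s <- motion_sample(base_position = c(0, 0, 0.95),
                     theta = numeric(8))
  kin <- forward_kinematics(model, s)
  w <- aggregate_inertial_wrench(model, kin)
  expect_equal(w$force, c(0, 0, -70 * 9.81), tolerance = 1e-12)
})

test_that("a point mass at the reference point produces zero moment", {
  cfg <- minimal_config()
  cfg$segments[[1]]$com <- c(0, 0, 0)
  cfg$segments[[1]]$inertia <- diag(0, 3)
  cfg$segments[[2]]$mass <- 0
  cfg$segments[[3]]$mass <- 0
  model <- load_body_model(cfg)
  kin <- forward_kinematics(model, motion_sample(theta = c(0.3, -0.2)))
  w <- aggregate_inertial_wrench(model, kin)
  expect_equal(w$moment, c(0, 0, 0), tolerance = 1e-12)
})

test_that("aggregate wrench matches a particle-cloud discretisation oracle", {
  # two-link pendulum of uniform rods under prescribed motion; the oracle
  # discretises each rod into 1e4 point masses and differentiates their FK
  # positions in time, never touching the analytic acceleration propagation
  L1 <- 0.5; L2 <- 0.4; m1 <- 3; m2 <- 2
  cfg <- list(
    segments = list(
      list(name = "base", parent = NA, mass = 0),
      list(name = "link1", parent = "base", joint_origin = c(0, 0, 0),
           joint_axes = list(c(0, 1, 0)), dof_names = "j1",
           mass = m1, com = c(0, 0, -L1 / 2),
           inertia = diag(c(m1 * L1^2 / 12, m1 * L1^2 / 12, 0), 3), length = L1),
      list(name = "link2", parent = "link1", joint_origin = c(0, 0, -L1),
           joint_axes = list(c(0, 1, 0)), dof_names = "j2",
           mass = m2, com = c(0, 0, -L2 / 2),
           inertia = diag(c(m2 * L2^2 / 12, m2 * L2^2 / 12, 0), 3), length = L2),
      list(name = "foot_l", parent = "base", joint_origin = c(0, 0.1, -1),
           mass = 0),
      list(name = "foot_r", parent = "base", joint_origin = c(0, -0.1, -1),
           mass = 0)),
    feet = list(
      list(side = "left", segment = "foot_l", heel = c(-0.05, 0, 0),
           toe = c(0.2, 0, 0),
           contour = rbind(c(-0.06, 0.04, 0), c(0.08, 0.04, 0), c(0.21, 0.04, 0),
                           c(0.21, -0.04, 0), c(0.08, -0.04, 0), c(-0.06, -0.04, 0))),
      list(side = "right", segment = "foot_r", heel = c(-0.05, 0, 0),
           toe = c(0.2, 0, 0),
           contour = rbind(c(-0.06, 0.04, 0), c(0.08, 0.04, 0), c(0.21, 0.04, 0),
                           c(0.21, -0.04, 0), c(0.08, -0.04, 0), c(-0.06, -0.04, 0)))),
    origin_segment = "base")
  model <- load_body_model(cfg)
  qf <- function(t) motion_sample(t,
    theta = c(0.4 * sin(1.3 * t), -0.6 * cos(0.9 * t)),
    theta_dot = c(0.4 * 1.3 * cos(1.3 * t), 0.6 * 0.9 * sin(0.9 * t)),
    theta_ddot = c(-0.4 * 1.3^2 * sin(1.3 * t), 0.6 * 0.9^2 * cos(0.9 * t)))
  t0 <- 0.8; h <- 1e-3
  kin <- forward_kinematics(model, qf(t0))
  w <- aggregate_inertial_wrench(model, kin)

  # particle cloud: positions only, via poses at t0 and t0 +/- h
  np <- 1e4
  zs <- (seq_len(np) - 0.5) / np
  cloud <- function(kin_t) {
    p1 <- kin_t$segments$link1
    p2 <- kin_t$segments$link2
    rbind(t(p1$position + p1$rotation %*% rbind(0, 0, -zs * L1)),
          t(p2$position + p2$rotation %*% rbind(0, 0, -zs * L2)))
  }
  P0 <- cloud(kin); Pp <- cloud(forward_kinematics(model, qf(t0 + h)))
  Pm <- cloud(forward_kinematics(model, qf(t0 - h)))
  acc <- (Pp - 2 * P0 + Pm) / h^2
  mp <- c(rep(m1 / np, np), rep(m2 / np, np))
  g <- c(0, 0, -9.81)
  Fi <- sweep(-acc, 2, g, `+`) * mp          # m * (g - a)
  F_o <- colSums(Fi)
  O0 <- kin$origin_point
  M_o <- colSums(cbind(
    (P0[, 2] - O0[2]) * Fi[, 3] - (P0[, 3] - O0[3]) * Fi[, 2],
    (P0[, 3] - O0[3]) * Fi[, 1] - (P0[, 1] - O0[1]) * Fi[, 3],
    (P0[, 1] - O0[1]) * Fi[, 2] - (P0[, 2] - O0[2]) * Fi[, 1]))
  expect_equal(w$force, F_o, tolerance = 1e-3)
  expect_equal(w$moment, M_o, tolerance = 1e-3)
})

test_that("aggregation is additive over disjoint segment subsets", {
  cfg <- generate_model(1.8, 80)
  upper <- c("pelvis", "torso", "upper_arm_l", "upper_arm_r", "forearm_l", "forearm_r")
  zero_out <- function(cfg, keep) {
    cfg$segments <- lapply(cfg$segments, function(s) {
      if (!s$name %in% keep) { s$mass <- 0; s$inertia <- diag(0, 3) }
      s
    })
    cfg
  }
  all_names <- vapply(cfg$segments, `[[`, "", "name")
  m_full <- load_body_model(cfg)
  m_up <- load_body_model(zero_out(cfg, upper))
  m_low <- load_body_model(zero_out(cfg, setdiff(all_names, upper)))
  th <- seq(-0.3, 0.4, length.out = 8)
  s <- motion_sample(base_position = c(0, 0, 0.95), theta = th,
                     theta_dot = seq(0.5, -0.2, length.out = 8),
                     theta_ddot = seq(-1, 1, length.out = 8))
  w_full <- aggregate_inertial_wrench(m_full, forward_kinematics(m_full, s))
  w_up <- aggregate_inertial_wrench(m_up, forward_kinematics(m_up, s))
  w_low <- aggregate_inertial_wrench(m_low, forward_kinematics(m_low, s))
  expect_equal(w_full$force, w_up$force + w_low$force, tolerance = 1e-12)
  expect_equal(w_full$moment, w_up$moment + w_low$moment, tolerance = 1e-12)
})

test_that("central-axis reduction handles parallel and perpendicular moments", {
  F <- c(0, 0, -500)
  caw <- central_axis_reduction(wrench(F, c(0, 0, 30)))
  expect_equal(caw$axis_point, c(0, 0, 0))
  expect_equal(caw$couple, c(0, 0, 30))

  caw <- central_axis_reduction(wrench(F, c(20, 0, 0)))
  expect_equal(caw$couple, c(0, 0, 0))
  expect_equal(caw$axis_point, c(0, -500 * 20, 0) / sum(F^2))
  expect_error(central_axis_reduction(wrench(c(0, 0, 0), c(1, 0, 0))),
               "pure couple")
})

test_that("central-axis reduction is equipollent to the original wrench", {
  set.seed(21)
  for (rep in 1:20) {
    w <- wrench(stats::rnorm(3, sd = 100), stats::rnorm(3, sd = 50),
                stats::rnorm(3))
    caw <- central_axis_reduction(w)
    # collinearity of the couple
    expect_lt(norm(cfmest:::cross3(caw$couple, caw$force), "2"),
              1e-9 * (norm(caw$couple, "2") * norm(caw$force, "2") + 1e-30))
    # p is perpendicular to F
    expect_lt(abs(sum(caw$axis_point * caw$force)),
              1e-9 * norm(caw$force, "2"))
    for (j in 1:20) {
      probe <- stats::rnorm(3)
      m_orig <- transfer_wrench(w, probe)$moment
      m_caw <- cfmest:::caw_moment_about(caw, probe)
      expect_equal(m_caw, m_orig, tolerance = 1e-12)
    }
  }
})
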