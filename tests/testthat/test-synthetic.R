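test_that("generated models conserve mass and scale proportionally", {
  cfg <- generate_model(1.75, 70)
  model <- load_body_model(cfg)
  expect_equal(total_mass(model), 70, tolerance = 1e-12)
  expect_equal(nrow(model$feet$left$contour), 6L)
  expect_equal(nrow(model$feet$right$contour), 6L)
  cfg2 <- generate_model(1.75, 140)
  m1 <- vapply(cfg$segments, `[[`, 0, "mass")
  m2 <- vapply(cfg2$segments, `[[`, 0, "mass")
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  expect_error(generate_model(3.1, 70), "implausible height")
  expect_error(generate_model(1.75, 500), "implausible mass")
})

test_that("model configs round-trip through JSON and the loader", {
  cfg <- generate_model(1.68, 62)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(cfg, path)
  model <- load_body_model(path)
  expect_equal(total_mass(model), 62, tolerance = 1e-9)
  expect_length(model$dof_names, 8L)
  ref <- load_body_model(cfg)
  expect_equal(model$segments$thigh_l$inertia, ref$segments$thigh_l$inertia,
               tolerance = 1e-12)
})

test_that("gait trajectories are periodic and seed-deterministic", {
  model <- default_model()
  p <- gait_params(n_cycles = 2, dt = 0.1, cadence_noise = 0.01, seed = 7)
  m1 <- generate_gait(model, p)
  m2 <- generate_gait(model, p)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- generate_gait(model, gait_params(n_cycles = 2, dt = 0.1,
                                         cadence_noise = 0.01, seed = 8))
  expect_false(identical(m1$hip_fe_l, m3$hip_fe_l))
  # periodicity theta(t + T) = theta(t), jitter included (periodic by design)
  Tn <- p$stride_period / p$dt
  ang_cols <- setdiff(names(m1), "time")
  for (col in ang_cols) {
    expect_equal(m1[[col]][seq_len(Tn)], m1[[col]][seq_len(Tn) + Tn],
                 tolerance = 1e-12)
  }
})

test_that("each sole reaches the ground during its stance window", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.05, n_cycles = 1)
  design <- attr(motion, "design")
  phases <- design$phase(motion$time)
  ss <- cfmest:::motion_samples(model, motion)
  sole_z <- function(s, side) {
    kin <- forward_kinematics(model, s)
    min(kin$feet[[side]]$heel[3], kin$feet[[side]]$toe[3])
  }
  zl <- vapply(ss[phases < 0.05 | phases > 0.95], sole_z, 0, side = "left")
  zr <- vapply(ss[abs(phases - 0.5) < 0.05], sole_z, 0, side = "right")
  expect_lt(min(abs(zl)), 0.01)
  expect_lt(min(abs(zr)), 0.01)
})

test_that("classified double-support fraction tracks the requested value", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.05, n_cycles = 2)
  ss <- cfmest:::motion_samples(model, motion)
  ph <- vapply(ss, function(s) {
    ctx <- tryCatch(cfmest:::sample_context(model, s), error = function(e) NULL)
    if (is.null(ctx)) NA_character_ else ctx$state$phase
  }, "")
  frac <- mean(ph == "double", na.rm = TRUE)
  expect_lt(abs(frac - 0.2), 0.05)
})

test_that("truth tables satisfy the estimator's balance invariants", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.15)
  truth <- generate_truth(model, motion, mode = "arbitrary", seed = 3,
                          a_step = model$feet$left$lf / 50)
  expect_equal(nrow(truth), nrow(motion))
  expect_false(any(truth$excluded))
  ss <- cfmest:::motion_samples(model, motion)
  for (i in seq_along(ss)) {
    ctx <- cfmest:::sample_context(model, ss[[i]])
    tot <- c(truth$flx[i] + truth$frx[i], truth$fly[i] + truth$fry[i],
             truth$flz[i] + truth$frz[i])
    expect_equal(tot, -ctx$w$force, tolerance = 1e-10)
    if (truth$phase[i] != "double") {
      # single-support truth is the exact reaction at the pierce point
      side_cols <- if (truth$phase[i] == "left_single") c("flx", "fly", "flz")
                   else c("frx", "fry", "frz")
      expect_equal(as.numeric(truth[i, side_cols]), -ctx$w$force,
                   tolerance = 1e-12)
      expect_equal(as.numeric(truth[i, c("frx", "fry", "frz")]) +
                   as.numeric(truth[i, c("flx", "fly", "flz")]),
                   -ctx$w$force, tolerance = 1e-12)
    } else {
      # planted a within the foot, coupled b consistent
      expect_gte(truth$a[i], 0); expect_lte(truth$a[i], model$feet$left$lf)
      expect_gte(truth$b[i], 0); expect_lte(truth$b[i], model$feet$right$lf)
    }
  }
  # determinism of the planted profiles
  truth2 <- generate_truth(model, motion, mode = "arbitrary", seed = 3,
                           a_step = model$feet$left$lf / 50)
  expect_identical(truth, truth2)
})

test_that("energy-minimal truth is recovered by the estimator", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.1, n_cycles = 1)
  ss <- cfmest:::motion_samples(model, motion)
  step <- model$feet$left$lf / 50
  sc <- collect_samples(model, motion, "double", n = 3)
  for (item in sc) {
    # truth planted at the brute-force minimum on the estimator's own grid
    ex <- exhaustive_minimum(model, item$sample, a_step = step)
    sol <- optimize_sample(model, item$sample, grid_step = step)
    expect_lt(abs(sol$a - ex$a), step + 1e-12)
    expect_lt(abs(sol$k - ex$k), 1e-4)
  }
})
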