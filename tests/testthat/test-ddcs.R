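test_that("COP coupling is symmetric for a mirror-symmetric stance", {
  lf <- 0.26
  geom <- manual_geometry(A = c(-0.05, 0.15, 0), B = c(-0.05 + lf, 0.15, 0),
                          C = c(-0.05, -0.15, 0), D = c(-0.05 + lf, -0.15, 0),
                          P = c(-0.05 + lf / 2, 0, 1), F_dir = c(0, 0, -1))
  expect_equal(coupled_b(lf / 2, geom), lf / 2, tolerance = 1e-12)
  geom0 <- geom; geom0$P <- c(-0.05, 0, 1)
  expect_equal(coupled_b(0, geom0), 0, tolerance = 1e-12)
})

test_that("coupled_b equals the bisection root of the coplanarity residual", {
  set.seed(41)
  for (rep in 1:25) {
    geom <- random_geometry()
    a <- stats::runif(1, 0.05, geom$lf_left - 0.05)
    b <- coupled_b(a, geom)
    M <- geom$A + a * geom$uAB
    resid <- function(bb) {
      N <- geom$C + bb * geom$uCD
      sum(cfmest:::cross3(M - geom$P, N - geom$P) * geom$F_dir)
    }
    # coplanarity residual vanishes at the returned b
    scale <- norm(M - geom$P, "2") * norm(geom$D - geom$C, "2")
    expect_lt(abs(resid(b)) / scale, 1e-10)
    # independent 1-D bisection over b
    lo <- b - 0.5; hi <- b + 0.5
    if (resid(lo) * resid(hi) < 0) {
      root <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
      expect_lt(abs(root - b), 1e-8)
    }
  }
  # degenerate: right foot line inside the constraint plane
  geom <- manual_geometry(A = c(0, 0.15, 0), B = c(0.26, 0.15, 0),
                          C = c(0, 0.15, 0) + c(0, -0.3, 0),
                          D = c(0.26, 0.15, 0) + c(0, -0.3, 0),
                          P = c(0.13, 0.15, 1), F_dir = c(0, 0, -1))
  # choose a so that plane(P, M, F) contains the x direction => n // y,
  # and CD // x lies in the plane
  expect_error(coupled_b(0.13, geom), "degenerate")
})

test_that("DDCS axes are orthonormal and place both COPs on the X axis", {
  set.seed(42)
  for (rep in 1:200) {
    geom <- random_geometry()
    a <- stats::runif(1, 0.05, geom$lf_left - 0.05)
    b <- coupled_b(a, geom)
    if (b < 0 || b > geom$lf_right) next
    fr <- ddcs_frame(geom, a, b)
    R <- fr$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    # M and N have zero Y and Z coordinates in the frame
    Md <- as.numeric(t(R) %*% (fr$M - fr$origin))
    Nd <- as.numeric(t(R) %*% (fr$N - fr$origin))
    expect_equal(Md[2:3], c(0, 0), tolerance = 1e-9)
    expect_equal(Nd[2:3], c(0, 0), tolerance = 1e-9)
    expect_equal(Md[1], fr$l, tolerance = 1e-12)
    expect_equal(Nd[1], -fr$r, tolerance = 1e-12)
  }
})

test_that("frame origin matches a dense-sampling closest-point oracle", {
  set.seed(43)
  for (rep in 1:5) {
    geom <- random_geometry()
    a <- stats::runif(1, 0.05, geom$lf_left - 0.05)
    b <- coupled_b(a, geom)
    if (b < 0 || b > geom$lf_right) next
    fr <- ddcs_frame(geom, a, b)
    M <- fr$M; N <- fr$N
    # brute force: sample both line parameters densely, minimise distance^2
    s_grid <- seq(-1, 2, length.out = 3001)
    best <- c(Inf, NA)
    axis_pt <- function(t) geom$P + t * geom$F_dir
    for (s in s_grid) {
      pmn <- M + s * (N - M)
      # distance from pmn to the axis (closed form along the axis)
      t_opt <- sum((pmn - geom$P) * geom$F_dir)
      d2 <- sum((pmn - axis_pt(t_opt))^2)
      if (d2 < best[1]) best <- c(d2, s)
    }
    O_oracle <- M + best[2] * (N - M)
    # oracle resolution: one s-grid step along MN
    expect_lt(norm(fr$origin - O_oracle, "2"), 1e-3 * norm(N - M, "2") + 1e-6)
  }
})

test_that("decoupled solve satisfies its equations and the pseudo-inverse", {
  set.seed(44)
  for (rep in 1:25) {
    geom <- random_geometry()
    a <- stats::runif(1, 0.05, geom$lf_left - 0.05)
    b <- coupled_b(a, geom)
    if (b < 0 || b > geom$lf_right) next
    # a wrench whose central axis is the geometry's axis: force along F_dir
    # through P, plus a collinear couple
    Fmag <- stats::runif(1, 400, 900)
    F <- -Fmag * geom$F_dir * sign(-geom$F_dir[3])  # downward inertial force
    O0 <- c(0, 0, 1)
    w <- wrench(F, cfmest:::cross3(geom$P - O0, F) + stats::runif(1, -5, 5) * F / Fmag,
                O0)
    fr <- ddcs_frame(geom, a, b)
    sys <- solve_decoupled(fr, w)
    x5 <- c(sys$x[["FX"]], sys$x[["FLY"]], sys$x[["FLZ"]],
            sys$x[["FRY"]], sys$x[["FRZ"]])
    expect_lt(norm(sys$A_matrix %*% x5 - sys$FD, "2"),
              1e-10 * (norm(sys$FD, "2") + 1e-12))
    expect_equal(x5, solve(sys$A_matrix, sys$FD), tolerance = 1e-9)
  }
})

test_that("symmetric lever arms split shared components evenly", {
  fr <- structure(list(origin = c(0, 0, 0), rotation = diag(3),
                       l = 0.1, r = 0.1,
                       M = c(0.1, 0, 0), N = c(-0.1, 0, 0), a = 0.1, b = 0.1),
                  class = "ddcs_frame")
  # inertial wrench with moment chosen so MYD = MZD = 0 about the origin
  w <- wrench(c(-30, -40, -500), c(0, 0, 0), c(0, 0, 0))
  sys <- solve_decoupled(fr, w)
  expect_equal(sys$x[["FLY"]], sys$x[["FRY"]])
  expect_equal(sys$x[["FLZ"]], sys$x[["FRZ"]])
  expect_equal(sys$x[["FLZ"]] + sys$x[["FRZ"]], 500)
  # homogeneous input
  sys0 <- solve_decoupled(fr, wrench(c(0, 0, 0) + 1e-30, c(0, 0, 0), c(0, 0, 0)))
  expect_equal(max(abs(sys0$x)), 0, tolerance = 1e-25)
  # coincident COPs
  fr_bad <- fr; fr_bad$l <- 0; fr_bad$r <- 0
  expect_error(solve_decoupled(fr_bad, w), "singular")
})

test_that("any split fraction preserves the total force balance", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.12)
  doubles <- collect_samples(model, motion, "double", n = 4)
  expect_gt(length(doubles), 0)
  for (sc in doubles) {
    ctx <- sc$ctx
    fr0 <- feasible_a_range(ctx$geom, model$feet$left$lf / 50)
    a <- fr0$a_grid[which(fr0$mask)[ceiling(sum(fr0$mask) / 2)]]
    frame <- ddcs_frame(ctx$geom, a)
    sys <- solve_decoupled(frame, ctx$w)
    for (k in c(0, 0.5, 1, -0.7, 1.9)) {
      sp <- split_axial(sys, k)
      tot <- sp$left$force_world + sp$right$force_world
      expect_equal(tot, -ctx$w$force, tolerance = 1e-10)
      expect_equal(sp$left$force_ddcs[1] + sp$right$force_ddcs[1],
                   sys$x[["FX"]], tolerance = 1e-12)
    }
    sp <- split_axial(sys, 1)
    expect_equal(sp$right$force_ddcs[1], 0)
    sp <- split_axial(sys, 0.5)
    expect_equal(sp$left$force_ddcs[1], sp$right$force_ddcs[1])
  }
})

test_that("retained DDCS components balance; residual confined to the X moment", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.12)
  doubles <- collect_samples(model, motion, "double", n = 6)
  for (sc in doubles) {
    ctx <- sc$ctx
    sol <- optimize_sample(model, sc$sample, grid_step = model$feet$left$lf / 50)
    frame <- ddcs_frame(ctx$geom, sol$a, sol$b)
    wd <- cfmest:::wrench_in_ddcs(frame, ctx$w)
    # contact wrench about O in DDCS
    Rt <- t(frame$rotation)
    cF <- as.numeric(Rt %*% (sol$left$force_world + sol$right$force_world))
    cM <- as.numeric(Rt %*% (
      cfmest:::cross3(sol$left$cop - frame$origin, sol$left$force_world) +
      cfmest:::cross3(sol$right$cop - frame$origin, sol$right$force_world)))
    scale <- norm(ctx$w$force, "2")
    expect_lt(max(abs(cF + wd$force)), 1e-9 * scale)
    expect_lt(abs(cM[2] + wd$moment[2]), 1e-9 * scale)
    expect_lt(abs(cM[3] + wd$moment[3]), 1e-9 * scale)
    # the only unbalanced piece is the dropped X moment
    expect_equal(cM[1], 0, tolerance = 1e-9 * scale)
    expect_equal(wd$moment[1], -sol$dropped_MXD, tolerance = 1e-12)
  }
})

test_that("b(a) is continuous on the feasible interval", {
  model <- default_model()
  motion <- default_gait(model, dt = 0.12)
  sc <- collect_samples(model, motion, "double", n = 1)[[1]]
  geom <- sc$ctx$geom
  coarse <- feasible_a_range(geom, geom$lf_left / 50)
  fine <- feasible_a_range(geom, geom$lf_left / 500)
  bf <- fine$b_grid[fine$mask]
  steps <- abs(diff(bf))
  # no jumps: every refinement step stays on the scale of the typical step
  expect_lt(max(steps), 20 * stats::median(steps) + 1e-9)
  # coarse extremes agree with the fine scan within one coarse step
  expect_lt(abs(coarse$a1 - fine$a1), geom$lf_left / 50 + 1e-12)
  expect_lt(abs(coarse$a2 - fine$a2), geom$lf_left / 50 + 1e-12)
})

test_that("the whole construction is covariant under a scene rotation", {
  set.seed(45)
  geom <- random_geometry()
  a <- 0.12
  b <- coupled_b(a, geom)
  O0 <- c(0.02, 0.01, 0.95)
  F <- -600 * geom$F_dir * sign(-geom$F_dir[3])
  w <- wrench(F, cfmest:::cross3(geom$P - O0, F) + 2 * F / norm(F, "2"), O0)
  fr1 <- ddcs_frame(geom, a, b)
  sys1 <- solve_decoupled(fr1, w)
  sp1 <- split_axial(sys1, 0.3)

  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  rot <- function(v) as.numeric(R %*% v)
  geom2 <- manual_geometry(rot(geom$A), rot(geom$B), rot(geom$C), rot(geom$D),
                           rot(geom$P), rot(geom$F_dir))
  w2 <- wrench(rot(w$force), rot(w$moment), rot(w$ref_point))
  expect_equal(coupled_b(a, geom2), b, tolerance = 1e-10)
  fr2 <- ddcs_frame(geom2, a, b)
  sys2 <- solve_decoupled(fr2, w2)
  sp2 <- split_axial(sys2, 0.3)
  expect_equal(fr2$origin, rot(fr1$origin), tolerance = 1e-8)
  expect_equal(fr2$l, fr1$l, tolerance = 1e-9)
  expect_equal(fr2$r, fr1$r, tolerance = 1e-9)
  # DDCS components unchanged; world forces rotate
  expect_equal(unname(sys2$x), unname(sys1$x), tolerance = 1e-8)
  expect_equal(sp2$left$force_world, rot(sp1$left$force_world), tolerance = 1e-7)
})
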