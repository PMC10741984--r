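#' Calibrate the joint weight factors against reference contact forces
#'
#' Traverses a flat grid of the knee and ankle factors `(q1, q2)` -- the hip
#' flexion/extension weight is the fixed reference and `q0` (hip
#' ab/adduction) is held at its default, since scaling all factors by a
#' positive constant leaves every energy minimiser, hence every estimated
#' contact force, unchanged -- and returns the combination whose estimated
#' forces are closest (mean squared error over the six force components) to
#' the reference table. Only double-support samples enter the objective:
#' single support is closed-form and carries no factor information.
#'
#' The default grid is the feasible region (0, 5] at step 0.1, i.e.
#' 50 x 50 = 2500 combinations. The per-sample energy quadratic is
#' precomputed per joint class once, so the whole grid costs little more
#' than a single estimator run; each grid point's result is exactly what
#' [estimate_cfm()] would return for those factors (same grid, same
#' tie-breaks).
#'
#' @param model a [body_model].
#' @param motion a motion `data.frame` or path.
#' @param reference a reference contact-force table aligned sample-by-sample
#'   with `motion` (the estimator's output layout; e.g. from
#'   [generate_truth()] or [write_cfm()]/[read_cfm()]).
#' @param q1_grid,q2_grid factor grids; defaults `seq(0.1, 5, by = 0.1)`.
#' @param q0 fixed hip-ab/adduction factor.
#' @param grid_step COP traversal step, m (as in [estimate_cfm()]).
#' @param edge_tol contour tolerance, m.
#' @return An object of class `"cfm_calibration"`: `factors` (named
#'   `q0, q1, q2`), `objective` (N^2), `grid` (objective matrix
#'   q1 x q2), `n_samples` (double-support samples used).
#' @export
calibrate_factors <- function(model, motion, reference,
                              q1_grid = seq(0.1, 5, by = 0.1),
                              q2_grid = seq(0.1, 5, by = 0.1),
                              q0 = 1.0, grid_step = NULL, edge_tol = 1e-3) {
  model <- load_body_model(model)
  if (is.character(motion)) motion <- read_motion(motion)
  if (!length(q1_grid) || !length(q2_grid)) stop("empty factor grid")
  grid_step <- grid_step %||% (model$feet$left$lf / 200)
  samples <- motion_samples(model, motion)
  if (nrow(reference) != length(samples) ||
      max(abs(vapply(samples, `[[`, 0, "t") - reference$time)) > 1e-9) {
    stop("misaligned tables: reference must match the motion sample-by-sample")
  }

  pres <- list(); refs <- list()
  for (i in seq_along(samples)) {
    ctx <- tryCatch(sample_context(model, samples[[i]], edge_tol = edge_tol),
                    error = function(e) NULL)
    if (is.null(ctx) || ctx$state$phase != "double") next
    if (isTRUE(reference$excluded[i])) next
    pre <- tryCatch(precompute_double(model, ctx, grid_step),
                    error = function(e) NULL)
    if (is.null(pre)) next
    pres[[length(pres) + 1L]] <- pre
    refs[[length(refs) + 1L]] <-
      as.numeric(reference[i, c("flx", "fly", "flz", "frx", "fry", "frz")])
  }
  if (!length(pres)) stop("no usable double-support samples for calibration")

  classes <- pres[[1L]]$classes
  obj_grid <- matrix(NA_real_, length(q1_grid), length(q2_grid),
                     dimnames = list(format(q1_grid), format(q2_grid)))
  best <- NULL
  for (i1 in seq_along(q1_grid)) {
    for (i2 in seq_along(q2_grid)) {
      em <- energy_factors(q0 = q0, q1 = q1_grid[i1], q2 = q2_grid[i2])
      f_cls <- unclass(em)[classes]
      sse <- 0; nuse <- 0L
      for (j in seq_along(pres)) {
        b <- traverse_minimum(pres[[j]], f_cls)
        if (is.null(b)) next
        k <- b$k; i <- b$i
        est <- c(pres[[j]]$FL0[i, ] + k * pres[[j]]$FL1[i, ],
                 pres[[j]]$FR0[i, ] + k * pres[[j]]$FR1[i, ])
        sse <- sse + sum((est - refs[[j]])^2)
        nuse <- nuse + 1L
      }
      obj <- if (nuse) sse / (6 * nuse) else Inf
      obj_grid[i1, i2] <- obj
      if (is.null(best) || obj < best$objective) {
        best <- list(objective = obj, q1 = q1_grid[i1], q2 = q2_grid[i2])
      }
    }
  }
  structure(list(factors = c(q0 = q0, q1 = best$q1, q2 = best$q2),
                 objective = best$objective, grid = obj_grid,
                 n_samples = length(pres),
                 q1_grid = q1_grid, q2_grid = q2_grid),
            class = "cfm_calibration")
}

#' @export
print.cfm_calibration <- function(x, ...) {
  cat("Joint weight factor calibration over", length(x$q1_grid), "x",
      length(x$q2_grid), "grid,", x$n_samples, "double-support samples\n")
  cat("  best [q0, q1, q2] =", paste(format(x$factors), collapse = ", "), "\n")
  cat("  objective (mean squared force error):", format(x$objective), "N^2\n")
  invisible(x)
}

#' @export
coef.cfm_calibration <- function(object, ...) object$factors

#' @export
plot.cfm_calibration <- function(x, ...) {
  graphics::image(x$q1_grid, x$q2_grid, log10(x$grid + .Machine$double.eps),
                  xlab = "q1 (knee)", ylab = "q2 (ankle)",
                  main = "log10 calibration objective", ...)
  graphics::points(x$factors[["q1"]], x$factors[["q2"]], pch = 4, cex = 2)
  invisible(x)
}
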