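#' Estimate ground contact forces and moments along a trajectory
#'
#' The main fitting interface. For every sample of the motion table the
#' whole-body inertial wrench is aggregated and reduced to its central axis;
#' the support phase is classified from the axis' ground pierce point;
#' single-support samples get the exact closed-form reaction, and
#' double-support samples are resolved by the DDCS decomposition plus the
#' minimum-energy traversal over the two remaining parameters `(a, k)` (see
#' [optimize_sample()]). Per-sample failures are recorded in the `error`
#' column and processing continues; output is deterministic given inputs
#' and options.
#'
#' @param model a [body_model] or a path/config accepted by
#'   [load_body_model()].
#' @param motion a motion `data.frame` (see [read_motion()]) or a file path.
#' @param factors joint weight factors, an [energy_factors()] object.
#' @param grid_step traversal step for the COP parameter `a`, m; default
#'   `lf / 200`.
#' @param clamp_k clamp the axial split fraction into `[0, 1]`.
#' @param edge_tol foot-contour edge tolerance for support classification, m.
#' @return An object of class `"cfm_fit"`: a list with `table` (one row per
#'   sample: time, phase, warning flag, `a`, `b`, `k`, energy `E`, the
#'   dropped X-moment diagnostic, six contact force/moment components per
#'   foot in the world frame -- the sole moments are zero by the method's
#'   construction -- COP world coordinates, and an `error` column), plus the
#'   model, factors and options used.
#' @examples
#' cfg <- generate_model(1.75, 70)
#' model <- load_body_model(cfg)
#' motion <- generate_gait(model, gait_params(n_cycles = 1, dt = 0.25))
#' fit <- estimate_cfm(model, motion)
#' summary(fit)
#' @export
estimate_cfm <- function(model, motion, factors = energy_factors(),
                         grid_step = NULL, clamp_k = FALSE, edge_tol = 1e-3) {
  cl <- match.call()
  model <- load_body_model(model)
  if (is.character(motion)) motion <- read_motion(motion)
  samples <- motion_samples(model, motion)
  grid_step <- grid_step %||% (model$feet$left$lf / 200)

  rows <- lapply(samples, function(s) {
    sol <- tryCatch(
      optimize_sample(model, s, em = factors, grid_step = grid_step,
                      clamp_k = clamp_k, edge_tol = edge_tol),
      error = function(e) conditionMessage(e))
    solution_row(s$t, sol)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, model = model, factors = factors,
                 grid_step = grid_step, clamp_k = clamp_k,
                 edge_tol = edge_tol, call = cl),
            class = "cfm_fit")
}

solution_row <- function(t, sol) {
  if (is.character(sol)) {
    return(data.frame(time = t, phase = NA_character_, warn = NA,
                      a = NA_real_, b = NA_real_, k = NA_real_, E = NA_real_,
                      dropped_MXD = NA_real_,
                      flx = NA_real_, fly = NA_real_, flz = NA_real_,
                      mlx = NA_real_, mly = NA_real_, mlz = NA_real_,
                      frx = NA_real_, fry = NA_real_, frz = NA_real_,
                      mrx = NA_real_, mry = NA_real_, mrz = NA_real_,
                      copl_x = NA_real_, copl_y = NA_real_, copl_z = NA_real_,
                      copr_x = NA_real_, copr_y = NA_real_, copr_z = NA_real_,
                      error = sol, stringsAsFactors = FALSE))
  }
  fl <- sol$left$force_world; fr <- sol$right$force_world
  cl <- sol$left$cop; cr <- sol$right$cop
  data.frame(time = t, phase = sol$phase, warn = sol$warning,
             a = sol$a, b = sol$b, k = sol$k, E = sol$energy,
             dropped_MXD = sol$dropped_MXD,
             flx = fl[1L], fly = fl[2L], flz = fl[3L],
             mlx = 0, mly = 0, mlz = 0,
             frx = fr[1L], fry = fr[2L], frz = fr[3L],
             mrx = 0, mry = 0, mrz = 0,
             copl_x = cl[1L], copl_y = cl[2L], copl_z = cl[3L],
             copr_x = cr[1L], copr_y = cr[2L], copr_z = cr[3L],
             error = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.cfm_fit <- function(x, ...) {
  tab <- x$table
  cat("Contact force/moment estimate:", nrow(tab), "samples\n")
  ph <- table(factor(tab$phase, levels = c("left_single", "right_single", "double")))
  cat("  phases: ", paste(names(ph), ph, sep = " = ", collapse = ", "), "\n")
  cat("  failures:", sum(!is.na(tab$error)), " warnings:", sum(tab$warn, na.rm = TRUE), "\n")
  cat("  factors: ", paste(names(x$factors), format(unclass(x$factors)),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cfm_fit <- function(object, ...) {
  tab <- object$table
  ok <- is.na(tab$error)
  dd <- tab$phase == "double" & ok
  out <- list(
    n = nrow(tab), n_failed = sum(!ok),
    n_double = sum(dd, na.rm = TRUE),
    n_single = sum(ok) - sum(dd, na.rm = TRUE),
    peak_vertical = c(left = max(tab$flz, na.rm = TRUE),
                      right = max(tab$frz, na.rm = TRUE)),
    mean_E_double = mean(tab$E[dd], na.rm = TRUE),
    mean_abs_dropped_MXD = mean(abs(tab$dropped_MXD[dd]), na.rm = TRUE),
    k_range = range(tab$k[dd], na.rm = TRUE))
  class(out) <- "summary.cfm_fit"
  out
}

#' @export
print.summary.cfm_fit <- function(x, ...) {
  cat("CFM estimate over", x$n, "samples (", x$n_single, "single,",
      x$n_double, "double,", x$n_failed, "failed )\n")
  cat("  peak vertical force  L/R:", format(x$peak_vertical[1L], digits = 5), "/",
      format(x$peak_vertical[2L], digits = 5), "N\n")
  if (x$n_double > 0) {
    cat("  mean double-support energy E:", format(x$mean_E_double, digits = 5), "\n")
    cat("  mean |dropped X-moment|:", format(x$mean_abs_dropped_MXD, digits = 4),
        "N m\n")
    cat("  split fraction k range:", paste(format(x$k_range, digits = 4),
                                           collapse = " .. "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cfm_fit <- function(x, ...) x$table

#' @export
plot.cfm_fit <- function(x, components = c("flz", "frz"), ...) {
  tab <- x$table
  cols <- grDevices::hcl.colors(max(2L, length(components)), "Dark 2")
  ylim <- range(unlist(tab[components]), 0, na.rm = TRUE)
  graphics::plot(tab$time, tab[[components[1L]]], type = "l", col = cols[1L],
                 xlab = "time [s]", ylab = "force [N]", ylim = ylim, ...)
  for (i in seq_along(components)[-1L]) {
    graphics::lines(tab$time, tab[[components[i]]], col = cols[i])
  }
  graphics::legend("topright", legend = components, col = cols[seq_along(components)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Residuals of an estimate against a reference contact-force table
#'
#' @param object a `"cfm_fit"`.
#' @param reference a reference table with the estimator's output layout
#'   (at least `time` and the six force columns).
#' @param ... unused.
#' @return A data.frame of per-sample force residuals (estimate - reference).
#' @export
residuals.cfm_fit <- function(object, reference, ...) {
  tab <- object$table
  check_aligned(tab, reference)
  comps <- c("flx", "fly", "flz", "frx", "fry", "frz")
  out <- tab[comps] - reference[comps]
  out$time <- tab$time
  out[c("time", comps)]
}

check_aligned <- function(tab, reference) {
  if (nrow(tab) != nrow(reference) ||
      max(abs(tab$time - reference$time)) > 1e-9) {
    stop("misaligned tables: reference must match the motion sample-by-sample")
  }
  invisible(TRUE)
}

#' Write / read an estimator output table
#' @param x a `"cfm_fit"` or its table.
#' @param path CSV path.
#' @return `path` (write) or a data.frame (read), invisibly for write.
#' @export
write_cfm <- function(x, path) {
  tab <- if (inherits(x, "cfm_fit")) x$table else x
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cfm
#' @export
read_cfm <- function(path) {
  utils::read.csv(path, check.names = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Unknown-count bookkeeping of the double-support problem
#'
#' Structural description of how the parameterisation collapses: the raw
#' double-support contact wrench has 12 components (6 forces + 6 moments);
#' dropping the sole moments and coupling the two COPs through the central
#' axis leaves 7 scalar unknowns (the COP parameter `a` plus six force
#' components); the DDCS solve then determines five force components, so the
#' optimizer's search space is exactly `(a, k)`.
#'
#' @return A list with `raw`, `after_cop_reduction` (names and count), and
#'   `search_space`.
#' @export
unknown_structure <- function() {
  force_comps <- c("FLX", "FLY", "FLZ", "FRX", "FRY", "FRZ")
  list(raw = 12L,
       after_cop_reduction = list(names = c("a", force_comps),
                                  count = 1L + length(force_comps)),
       search_space = c("a", "k"))
}
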