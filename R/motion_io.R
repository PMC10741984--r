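# Motion-table I/O. The canonical interchange format is CSV: first column
# `time` (s, strictly increasing), then the six floating-base coordinates
# (base_x, base_y, base_z in m; base_rx, base_ry, base_rz in rad) and one
# column per actuated DOF (rad). Optional `<name>_vel` / `<name>_acc`
# columns carry first/second derivatives; when absent they are filled by
# Savitzky-Golay smoothing differentiation. OpenSim-style .mot/.sto headers
# (`nRows`, `nColumns`, ..., `endheader`) are skipped on read.

#' Read a motion table
#'
#' @param path CSV or OpenSim-style `.mot`/`.sto` file.
#' @param dialect `"auto"` (by extension), `"csv"` or `"mot"`.
#' @param degrees if `TRUE`, angle columns (everything except `time` and the
#'   base translations) are converted from degrees to radians on import.
#' @param fill_derivatives fill missing `_vel`/`_acc` columns by
#'   Savitzky-Golay differentiation (window `sg_window`, order `sg_order`).
#'   Near the series edges the filter falls back to its asymmetric
#'   end-point weights, which are exact for polynomials up to `sg_order`.
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order.
#' @return A `data.frame` sorted by time, with derivative columns present
#'   for every coordinate.
#' @export
read_motion <- function(path, dialect = c("auto", "csv", "mot"),
                        degrees = FALSE, fill_derivatives = TRUE,
                        sg_window = 7L, sg_order = 3L) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(mot|sto)$", path, ignore.case = TRUE)) "mot" else "csv"
  }
  if (dialect == "mot") {
    lines <- readLines(path)
    hdr_end <- grep("^\\s*endheader\\s*$", lines, ignore.case = TRUE)
    skip <- if (length(hdr_end)) hdr_end[[1L]] else 0L
    tab <- utils::read.table(text = lines[(skip + 1L):length(lines)],
                             header = TRUE, check.names = FALSE)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  }
  if (!"time" %in% names(tab)) stop("motion table must have a 'time' column")
  for (j in seq_along(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v)) {
      stop("parse error: non-numeric cell in column '", names(tab)[j],
           "', line ", which(is.na(v))[1L] + 1L)
    }
    tab[[j]] <- v
  }
  if (is.unsorted(tab$time)) tab <- tab[order(tab$time), , drop = FALSE]
  if (any(diff(tab$time) <= 0)) stop("non-monotone time column")
  if (degrees) {
    ang <- setdiff(names(tab), c("time", "base_x", "base_y", "base_z",
                                 paste0(c("base_x", "base_y", "base_z"),
                                        rep(c("_vel", "_acc"), each = 3L))))
    for (col in ang) tab[[col]] <- tab[[col]] * pi / 180
  }
  if (fill_derivatives) {
    tab <- fill_motion_derivatives(tab, sg_window = sg_window, sg_order = sg_order)
  }
  tab
}

#' Write a motion table to CSV
#' @param motion a motion `data.frame`.
#' @param path output path.
#' @param seed optional integer recorded as a `# seed:` comment header.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path, seed = attr(motion, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(motion, con, row.names = FALSE)
  invisible(path)
}

# Savitzky-Golay differentiation of a uniformly sampled column.
sg_deriv <- function(x, dt, m, window = 7L, order = 3L) {
  n <- length(x)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window < order + 1L || n < 3L) {
    # series too short for the filter: low-order finite differences
    if (m == 1L) {
      d <- c(diff(x)[1L], (x[-(1:2)] - x[1:(n - 2L)]) / 2, diff(x)[n - 1L]) / dt
      return(if (n >= 2L) d else rep(0, n))
    }
    d2 <- rep(0, n)
    if (n >= 3L) d2[2:(n - 1L)] <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) / dt^2
    if (n >= 3L) { d2[1L] <- d2[2L]; d2[n] <- d2[n - 1L] }
    return(d2)
  }
  if (window %% 2L == 0L) window <- window - 1L
  signal::sgolayfilt(x, p = order, n = window, m = m) / dt^m
}

fill_motion_derivatives <- function(tab, sg_window = 7L, sg_order = 3L) {
  t <- tab$time
  dts <- diff(t)
  dt <- stats::median(dts)
  uniform <- length(dts) == 0L || max(abs(dts - dt)) < 1e-6 * dt
  base <- setdiff(names(tab), "time")
  coords <- base[!grepl("_(vel|acc)$", base)]
  for (col in coords) {
    vcol <- paste0(col, "_vel"); acol <- paste0(col, "_acc")
    if (!vcol %in% names(tab)) {
      if (!uniform) stop("cannot differentiate a non-uniformly sampled table; ",
                         "provide _vel/_acc columns")
      tab[[vcol]] <- sg_deriv(tab[[col]], dt, 1L, sg_window, sg_order)
    }
    if (!acol %in% names(tab)) {
      if (!uniform) stop("cannot differentiate a non-uniformly sampled table; ",
                         "provide _vel/_acc columns")
      tab[[acol]] <- sg_deriv(tab[[col]], dt, 2L, sg_window, sg_order)
    }
  }
  tab
}

# Turn a motion table into per-row motion samples ordered as the model
# expects. Unknown columns are warned about (once) and ignored.
motion_samples <- function(model, motion) {
  coords <- c(model$base_names, model$dof_names)
  missing <- setdiff(coords, names(motion))
  if (length(missing)) {
    stop("motion table is missing coordinate column(s): ",
         paste(missing, collapse = ", "))
  }
  known <- c("time", coords, paste0(coords, "_vel"), paste0(coords, "_acc"))
  extra <- setdiff(names(motion), known)
  if (length(extra)) {
    warning("ignoring unknown motion column(s): ", paste(extra, collapse = ", "))
  }
  motion <- fill_motion_derivatives(motion)
  Q <- as.matrix(motion[coords])
  Qd <- as.matrix(motion[paste0(coords, "_vel")])
  Qdd <- as.matrix(motion[paste0(coords, "_acc")])
  lapply(seq_len(nrow(motion)), function(i) {
    list(t = motion$time[i], q = Q[i, ], qd = Qd[i, ], qdd = Qdd[i, ])
  })
}
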