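#' Articulated body model
#'
#' A `body_model` is a tree of rigid segments rooted at a floating base, plus
#' two foot definitions, a gravity vector, and the name of the segment that
#' carries the wrench reference point `O0`. Each segment has a mass, a centre
#' of mass and an inertia tensor (about the com, in the segment frame), and an
#' ordered list of revolute joint axes connecting it to its parent; multi-DOF
#' joints (e.g. a 2-DOF hip) are ordered sequences of revolute axes.
#'
#' The world frame is right-handed and Z-up; the ground plane is z = 0 and
#' gravity defaults to (0, 0, -9.81) m/s^2. The floating base contributes six
#' unactuated coordinates named `base_x`, `base_y`, `base_z` (translation, m)
#' and `base_rx`, `base_ry`, `base_rz` (intrinsic X-Y-Z rotations, rad).
#'
#' @param config a list with elements `segments` (list of segment specs),
#'   `feet` (list of two foot specs with sides `"left"` and `"right"`),
#'   optional `gravity` and `origin_segment`. See the packaged example
#'   produced by [generate_model()] for the schema.
#' @return An object of class `"body_model"`.
#' @seealso [load_body_model()], [forward_kinematics()], [generate_model()]
#' @export
body_model <- function(config) {
  stopifnot(is.list(config), !is.null(config$segments), !is.null(config$feet))
  segs <- lapply(config$segments, normalize_segment)
  names(segs) <- vapply(segs, `[[`, "", "name")
  if (anyDuplicated(names(segs))) stop("validation error: duplicate segment names")

  roots <- names(segs)[vapply(segs, function(s) is.na(s$parent), TRUE)]
  if (length(roots) != 1L) {
    stop("validation error: segment graph must have exactly one floating base, found ",
         length(roots))
  }
  # cycle / dangling-parent check and topological order
  order <- character(0)
  state <- setNames(rep(0L, length(segs)), names(segs))  # 0 new, 1 visiting, 2 done
  visit <- function(nm) {
    if (state[[nm]] == 1L) stop("validation error: cycle in segment graph at '", nm, "'")
    if (state[[nm]] == 2L) return(invisible())
    state[[nm]] <<- 1L
    p <- segs[[nm]]$parent
    if (!is.na(p)) {
      if (!p %in% names(segs)) {
        stop("validation error: parent '", p, "' of segment '", nm, "' does not exist")
      }
      visit(p)
    }
    state[[nm]] <<- 2L
    order <<- c(order, nm)
  }
  for (nm in names(segs)) visit(nm)
  segs <- segs[order]

  feet <- config$feet
  if (!is.null(names(feet)) && all(c("left", "right") %in% names(feet))) {
    feet <- list(feet$left, feet$right)
  }
  feet <- lapply(feet, normalize_foot)
  sides <- vapply(feet, `[[`, "", "side")
  if (!setequal(sides, c("left", "right"))) {
    stop("validation error: exactly one left and one right foot required")
  }
  names(feet) <- sides
  feet <- feet[c("left", "right")]
  for (f in feet) {
    if (!f$segment %in% names(segs)) {
      stop("validation error: foot segment '", f$segment, "' does not exist")
    }
  }

  origin_segment <- config$origin_segment %||% order[[1L]]
  if (!origin_segment %in% names(segs)) {
    stop("validation error: origin_segment '", origin_segment, "' does not exist")
  }
  gravity <- as.numeric(config$gravity %||% c(0, 0, -9.81))
  stopifnot(is_num3(gravity))

  dof_names <- unlist(lapply(segs, `[[`, "dof_names"), use.names = FALSE)
  if (anyDuplicated(dof_names)) stop("validation error: duplicate DOF names")
  classes <- unlist(lapply(segs, `[[`, "joint_classes"), use.names = FALSE)

  structure(list(segments = segs, feet = feet, gravity = gravity,
                 origin_segment = origin_segment,
                 dof_names = dof_names,
                 dof_classes = setNames(classes, dof_names),
                 base_names = c("base_x", "base_y", "base_z",
                                "base_rx", "base_ry", "base_rz")),
            class = "body_model")
}

normalize_segment <- function(s) {
  stopifnot(!is.null(s$name))
  parent <- s$parent %||% NA_character_
  if (length(parent) == 0L || identical(parent, "")) parent <- NA_character_
  if (!is.na(parent) && identical(parent, s$name)) {
    stop("validation error: cycle: segment '", s$name, "' is its own parent")
  }
  axes <- s$joint_axes %||% list()
  if (is.matrix(axes)) axes <- lapply(seq_len(nrow(axes)), function(i) axes[i, ])
  axes <- lapply(axes, as.numeric)
  for (a in axes) {
    if (!is_num3(a) || abs(norm3(a) - 1) > 1e-8) {
      stop("validation error: non-unit joint axis in segment '", s$name, "'")
    }
  }
  ndof <- length(axes)
  dof_names <- as.character(s$dof_names %||%
    (if (ndof) paste0(s$name, "_q", seq_len(ndof)) else character(0)))
  classes <- as.character(s$joint_classes %||% rep("other", ndof))
  if (length(dof_names) != ndof || length(classes) != ndof) {
    stop("validation error: dof_names/joint_classes length mismatch in '", s$name, "'")
  }
  mass <- as.numeric(s$mass %||% 0)
  if (mass < 0) stop("validation error: negative mass in segment '", s$name, "'")
  inertia <- s$inertia %||% diag(0, 3L)
  if (!is.matrix(inertia)) {
    inertia <- if (length(inertia) == 3L) diag(as.numeric(inertia), 3L)
               else matrix(as.numeric(unlist(inertia)), 3L, 3L)
  }
  inertia <- (inertia + t(inertia)) / 2
  if (min(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("validation error: inertia not positive semidefinite in '", s$name, "'")
  }
  list(name = s$name, parent = parent,
       joint_origin = as.numeric(s$joint_origin %||% c(0, 0, 0)),
       joint_axes = axes, dof_names = dof_names, joint_classes = classes,
       mass = mass, com = as.numeric(s$com %||% c(0, 0, 0)),
       inertia = inertia, length = as.numeric(s$length %||% 0))
}

normalize_foot <- function(f) {
  stopifnot(!is.null(f$side), !is.null(f$segment))
  heel <- as.numeric(f$heel); toe <- as.numeric(f$toe)
  stopifnot(is_num3(heel), is_num3(toe))
  lf <- norm3(toe - heel)
  if (lf <= 0) stop("validation error: foot length |toe - heel| must be > 0")
  contour <- f$contour
  if (!is.matrix(contour)) contour <- do.call(rbind, lapply(contour, as.numeric))
  if (nrow(contour) < 3L) stop("validation error: foot contour needs >= 3 points")
  check_contour(contour, heel, toe, f$side)
  list(side = f$side, segment = f$segment, heel = heel, toe = toe,
       contour = contour, lf = lf)
}

# Contour must be a simple polygon (in its sole plane) containing the
# heel-toe segment. Checked in the contour's own 2-D plane coordinates.
check_contour <- function(contour, heel, toe, side) {
  n <- nrow(contour)
  xy <- contour[, 1:2, drop = FALSE]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    r <- q1 - p1
    t <- (r[1L] * d2[2L] - r[2L] * d2[1L]) / den
    u <- (r[1L] * d1[2L] - r[2L] * d1[1L]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (seg_int(xy[i, ], xy[i %% n + 1L, ], xy[j, ], xy[j %% n + 1L, ])) {
        stop("validation error: self-intersecting foot contour (", side, ")")
      }
    }
  }
  for (p in list(heel[1:2], toe[1:2], (heel[1:2] + toe[1:2]) / 2)) {
    if (!point_in_polygon_2d(p, xy, tol = 1e-9)) {
      stop("validation error: foot contour must contain the heel-toe segment (",
           side, ")")
    }
  }
}

#' Load a body model from a configuration file or list
#'
#' Accepts a JSON file, a YAML file (extension `.yml`/`.yaml`, requires the
#' `yaml` package), or an already-parsed list. Units are SI throughout and
#' angles are radians.
#'
#' @param config_source path to a JSON/YAML model file, or a list.
#' @return A validated [body_model].
#' @export
load_body_model <- function(config_source) {
  if (inherits(config_source, "body_model")) return(config_source)
  cfg <- if (is.character(config_source)) {
    if (grepl("\\.ya?ml$", config_source, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML model files requires the 'yaml' package")
      }
      yaml::read_yaml(config_source)
    } else {
      jsonlite::read_json(config_source, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
    }
  } else {
    config_source
  }
  body_model(cfg)
}

#' Write a body model configuration to JSON
#'
#' @param config a model configuration list (e.g. from [generate_model()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.body_model <- function(x, ...) {
  cat("Articulated body model\n")
  cat("  segments:", length(x$segments),
      " total mass:", format(total_mass(x)), "kg\n")
  cat("  actuated DOFs:", length(x$dof_names), "\n")
  cat("  origin segment (O0):", x$origin_segment, "\n")
  cat("  foot lengths (L/R):", format(x$feet$left$lf), "/",
      format(x$feet$right$lf), "m\n")
  invisible(x)
}

#' Total mass of a body model
#' @param model a [body_model].
#' @return Sum of segment masses, kg.
#' @export
total_mass <- function(model) {
  sum(vapply(model$segments, `[[`, 0, "mass"))
}
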