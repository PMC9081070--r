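#' Crystal specification
#'
#' Describes the CZT crystal slab. The coordinate convention is right-handed
#' with depth \eqn{z \in [0, thickness]}: the continuous cathode (the
#' source-facing side) sits at \eqn{z = 0} and the pixelated anode plane at
#' \eqn{z = thickness}. The lateral origin is at the centre of the selected
#' anode pad. `bias_voltage` is the magnitude of the potential difference
#' applied over the crystal; internally the cathode is held at
#' \code{-bias_voltage} and the anodes at 0 V so that electrons drift toward
#' the anode plane.
#'
#' @param width_x,width_y Lateral crystal dimensions (mm).
#' @param thickness Crystal depth (mm), cathode to anode plane.
#' @param bias_voltage Magnitude of the applied bias (V).
#' @param permittivity_rel Relative permittivity (dimensionless); carried for
#'   completeness, the solvers assume negligible space charge so it never
#'   enters the discrete systems.
#' @return An object of class `crystal_spec`.
#' @export
#' @examples
#' crystal_spec()  # the 39 x 39 x 5 mm, 600 V default module
crystal_spec <- function(width_x = 39, width_y = 39, thickness = 5,
                         bias_voltage = 600, permittivity_rel = 10.9) {
  stopifnot(width_x > 0, width_y > 0, thickness > 0,
            bias_voltage > 0, permittivity_rel > 0)
  structure(list(width_x = width_x, width_y = width_y, thickness = thickness,
                 bias_voltage = bias_voltage,
                 permittivity_rel = permittivity_rel),
            class = "crystal_spec")
}

#' Anode array specification
#'
#' @param n_x,n_y Number of anode elements per lateral axis.
#' @param pitch Anode pitch (mm).
#' @param pad_size Side of the square contact pad (mm); must be < pitch.
#' @return An object of class `anode_array_spec`.
#' @export
anode_array_spec <- function(n_x = 16, n_y = 16, pitch = 2.46,
                             pad_size = 1.86) {
  stopifnot(n_x >= 1, n_y >= 1, pitch > 0, pad_size > 0, pad_size <= pitch)
  structure(list(n_x = n_x, n_y = n_y, pitch = pitch, pad_size = pad_size),
            class = "anode_array_spec")
}

#' Collimator specification
#'
#' Presets for the parallel-hole collimators with holes matched one-to-one
#' onto the anode array, plus the open-field cover. Circular holes are
#' modelled as circles of the stated hole width (diameter) centred on the
#' anode cell.
#'
#' @param name One of `"LEHR"`, `"MEGP"`, `"OPEN"` for the shipped presets,
#'   or any label when the remaining fields are given explicitly.
#' @param hole_length,wall_thickness,hole_width Dimensions (mm).
#' @param material Absorber material label.
#' @param hole_shape `"square"`, `"circular"` or `"none"`.
#' @param eps_pen Septal penetration factor in `[0,1]` used by the synthetic
#'   listmode generator and by [collimator_transmission()]: the relative
#'   interaction density over the septa. May be a single number or a function
#'   of energy (keV).
#' @return An object of class `collimator_spec`.
#' @export
#' @examples
#' collimator_spec("MEGP")
#' collimator_spec("OPEN")
collimator_spec <- function(name = c("LEHR", "MEGP", "OPEN"),
                            hole_length = NULL, wall_thickness = NULL,
                            hole_width = NULL, material = NULL,
                            hole_shape = NULL, eps_pen = 0) {
  presets <- list(
    LEHR = list(hole_length = 22.6, wall_thickness = 0.23, hole_width = 2.23,
                material = "lead", hole_shape = "square"),
    MEGP = list(hole_length = 11.5, wall_thickness = 0.96, hole_width = 1.50,
                material = "lead", hole_shape = "circular"),
    OPEN = list(hole_length = 0, wall_thickness = 0, hole_width = Inf,
                material = "none", hole_shape = "none"))
  if (length(name) > 1L || name %in% names(presets)) {
    name <- match.arg(name)
    p <- presets[[name]]
  } else {
    p <- list(hole_length = hole_length, wall_thickness = wall_thickness,
              hole_width = hole_width, material = material,
              hole_shape = hole_shape)
    if (any(vapply(p, is.null, logical(1))))
      stop("custom collimator requires all dimension fields")
  }
  if (!is.null(hole_length)) p$hole_length <- hole_length
  if (!is.null(wall_thickness)) p$wall_thickness <- wall_thickness
  if (!is.null(hole_width)) p$hole_width <- hole_width
  if (!is.null(hole_shape)) p$hole_shape <- hole_shape
  structure(c(list(name = name), p, list(eps_pen = eps_pen)),
            class = "collimator_spec")
}

#' Centre positions of the anode pads
#'
#' Lateral pad-centre coordinates in the crystal frame (origin at the crystal
#' centre), ordered column-major (x fastest).
#'
#' @param anodes An [anode_array_spec()].
#' @return A matrix with `n_x * n_y` rows and columns `x`, `y` (mm).
#' @export
anode_centers <- function(anodes) {
  cx <- (seq_len(anodes$n_x) - (anodes$n_x + 1) / 2) * anodes$pitch
  cy <- (seq_len(anodes$n_y) - (anodes$n_y + 1) / 2) * anodes$pitch
  cbind(x = rep(cx, times = anodes$n_y), y = rep(cy, each = anodes$n_x))
}

# step must divide `len` exactly (no silent snapping); returns interval count
.exact_divide <- function(len, step, what) {
  m <- len / step
  if (abs(m - round(m)) > 1e-9 * max(1, m))
    stop(sprintf("step %g mm is not commensurate with %s %g mm", step, what, len))
  as.integer(round(m))
}

#' Build the discretised sub-volume around the selected anode
#'
#' Constructs a vertex-centred Cartesian lattice over an
#' `neighbourhood x neighbourhood` patch of anode cells centred on the
#' selected (central) anode, with inclusive endpoints. The lateral step must
#' divide the pitch exactly (no silent snapping); the axial node count is
#' rounded so the axial step matches `step` to within half a node. Anode-plane
#' nodes are labelled by pad membership: a node belongs to a pad when its
#' lateral distance from the pad centre is at most `pad_size/2` in both axes
#' (closed set), otherwise it is a gap node.
#'
#' @param crystal A [crystal_spec()].
#' @param anodes An [anode_array_spec()].
#' @param neighbourhood Odd number of anode cells per lateral axis (default 5).
#' @param step Target node spacing (mm). Must divide the pitch exactly.
#' @return An object of class `grid3d` with fields `x`, `y`, `z` (node
#'   coordinates, mm), `hx`, `hy`, `hz` (spacings), `anode_label` (nx-by-ny
#'   integer matrix over the anode plane: 0 = gap, `k` = pad of anode `k`),
#'   `central_anode` (label of the selected anode), `pad_centers` (per-label
#'   lateral centres), `symmetry_planes` (the lateral mid-planes `x = 0`,
#'   `y = 0`), and the originating specs.
#' @export
#' @examples
#' g <- build_grid(crystal_spec(), anode_array_spec(), 5, 0.41)
#' dim(g$anode_label)
build_grid <- function(crystal, anodes, neighbourhood = 5, step = 0.41) {
  stopifnot(inherits(crystal, "crystal_spec"),
            inherits(anodes, "anode_array_spec"))
  if (neighbourhood %% 2 != 1) stop("neighbourhood must be odd")
  if (neighbourhood * anodes$pitch > crystal$width_x + 1e-9 ||
      neighbourhood * anodes$pitch > crystal$width_y + 1e-9)
    stop("neighbourhood exceeds the crystal extent")
  m <- .exact_divide(anodes$pitch, step, "pitch")
  nz_int <- round(crystal$thickness / step)
  if (nz_int < 1 || abs(crystal$thickness - nz_int * step) > step / 2)
    stop(sprintf("step %g mm is not commensurate with thickness %g mm",
                 step, crystal$thickness))
  hz <- crystal$thickness / nz_int
  n_int <- neighbourhood * m           # lateral intervals
  half <- n_int * step / 2
  x <- seq(-half, half, length.out = n_int + 1L)
  z <- seq(0, crystal$thickness, length.out = nz_int + 1L)

  # pad centres of the neighbourhood, labelled 1..neighbourhood^2,
  # central anode at the origin
  off <- (seq_len(neighbourhood) - (neighbourhood + 1) / 2) * anodes$pitch
  pad_centers <- cbind(x = rep(off, times = neighbourhood),
                       y = rep(off, each = neighbourhood))
  central <- which(pad_centers[, 1] == 0 & pad_centers[, 2] == 0)

  lab <- matrix(0L, n_int + 1L, n_int + 1L)
  half_pad <- anodes$pad_size / 2 + 1e-9
  for (k in seq_len(nrow(pad_centers))) {
    ix <- which(abs(x - pad_centers[k, 1]) <= half_pad)
    iy <- which(abs(x - pad_centers[k, 2]) <= half_pad)
    lab[ix, iy] <- as.integer(k)
  }

  structure(list(x = x, y = x, z = z, hx = step, hy = step, hz = hz,
                 anode_label = lab, central_anode = as.integer(central),
                 pad_centers = pad_centers,
                 neighbourhood = as.integer(neighbourhood),
                 symmetry_planes = list(c("x", 0), c("y", 0)),
                 crystal = crystal, anodes = anodes, reduced = FALSE),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d nodes (h = %.4g/%.4g/%.4g mm)%s\n",
              length(x$x), length(x$y), length(x$z), x$hx, x$hy, x$hz,
              if (isTRUE(x$reduced)) ", quarter-reduced" else ""))
  cat(sprintf("  anode plane: %d pads, central anode #%d\n",
              max(x$anode_label), x$central_anode))
  invisible(x)
}

#' Reduce a grid to one quadrant using the lateral mirror symmetries
#'
#' The central anode's two lateral mid-planes (`x = 0`, `y = 0`) are symmetry
#' planes of every field solved around it; only the `x >= 0, y >= 0` quadrant
#' is retained and zero normal gradients are applied across the shared
#' planes when solving. Requires a node on each plane (a node count odd per
#' lateral axis) and electrode labels symmetric under both reflections.
#'
#' @param grid A full `grid3d` from [build_grid()].
#' @return A list with `grid` (the reduced `grid3d`) and `unfold`, a function
#'   mapping a reduced 3-D value array back onto the full grid by reflection.
#' @export
symmetry_reduce <- function(grid) {
  stopifnot(inherits(grid, "grid3d"), !isTRUE(grid$reduced))
  nx <- length(grid$x)
  i0 <- which(abs(grid$x) < 1e-12)
  if (length(i0) != 1L)
    stop("symmetry plane falls between nodes: choose a step with an even pitch/step ratio")
  lab <- grid$anode_label
  flipped_x <- lab[nx:1, , drop = FALSE]
  flipped_y <- lab[, nx:1, drop = FALSE]
  # compare pad geometry, not label identity: reflected pads must exist with
  # mirrored centres
  refl_ok <- function(flip, axis) {
    a <- lab > 0L
    b <- flip > 0L
    if (!identical(a, b)) return(FALSE)
    idx <- which(a)
    c1 <- grid$pad_centers[lab[idx], , drop = FALSE]
    c2 <- grid$pad_centers[flip[idx], , drop = FALSE]
    c2[, axis] <- -c2[, axis]
    max(abs(c1 - c2)) < 1e-9
  }
  if (!refl_ok(flipped_x, 1) || !refl_ok(flipped_y, 2))
    stop("electrode labels are not symmetric under the lateral reflections; reduction refused")

  keep <- i0:nx
  red <- grid
  red$x <- grid$x[keep]
  red$y <- grid$y[keep]
  red$anode_label <- lab[keep, keep, drop = FALSE]
  red$reduced <- TRUE
  red$reduce_index <- keep
  nr <- length(keep)
  unfold <- function(values) {
    stopifnot(length(dim(values)) == 3L,
              dim(values)[1] == nr, dim(values)[2] == nr)
    nzv <- dim(values)[3]
    full <- array(NA_real_, c(nx, nx, nzv))
    full[keep, keep, ] <- values
    full[(i0 - 1):1, keep, ] <- values[2:nr, , , drop = FALSE]
    full[, (i0 - 1):1, ] <- full[, (i0 + 1):nx, , drop = FALSE]
    full
  }
  list(grid = red, unfold = unfold)
}

#' Hole cross-section membership for collimator shadowing
#'
#' Tests whether lateral positions fall inside the (projected) open aperture
#' of the collimator hole of the anode cell containing them. Square holes are
#' centred squares of side `hole_width`; circular holes are centred circles
#' of diameter `hole_width`; the open cover accepts everything.
#'
#' @param xy Two-column matrix of lateral positions (mm, crystal frame).
#' @param collimator A [collimator_spec()].
#' @param anodes An [anode_array_spec()].
#' @return Logical vector.
#' @export
in_hole_aperture <- function(xy, collimator, anodes) {
  xy <- matrix(xy, ncol = 2)
  if (collimator$hole_shape == "none") return(rep(TRUE, nrow(xy)))
  # offset within the containing anode cell, in [-pitch/2, pitch/2)
  u <- xy - round(xy / anodes$pitch) * anodes$pitch
  if (collimator$hole_shape == "square") {
    abs(u[, 1]) <= collimator$hole_width / 2 &
      abs(u[, 2]) <= collimator$hole_width / 2
  } else {
    u[, 1]^2 + u[, 2]^2 <= (collimator$hole_width / 2)^2
  }
}

#' Read a geometry configuration file
#'
#' Structured-text (YAML) configuration with `crystal`, `anodes` and
#' `collimator` blocks; missing fields fall back to the shipped defaults
#' (the hand-held camera module and its collimator set).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `crystal`, `anodes`, `collimator`.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  crystal <- do.call(crystal_spec, cfg$crystal %||% list())
  anodes <- do.call(anode_array_spec, cfg$anodes %||% list())
  collimator <- if (is.null(cfg$collimator)) collimator_spec("OPEN")
                else do.call(collimator_spec, cfg$collimator)
  list(crystal = crystal, anodes = anodes, collimator = collimator)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
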