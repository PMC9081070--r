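#' Scalar field on a grid
#'
#' Thin container tying a 3-D value array to its `grid3d`.
#'
#' @param grid A `grid3d`.
#' @param values 3-D numeric array matching the grid's node counts.
#' @param unit Unit label (e.g. `"V"`, `""`).
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values, unit = "") {
  stopifnot(inherits(grid, "grid3d"))
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  if (!identical(dim(values), as.integer(dims)))
    stop("value array shape does not match the grid")
  if (!all(is.finite(values))) stop("field values must be finite")
  structure(list(grid = grid, values = values, unit = unit),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s, range [%.4g, %.4g] %s\n",
              paste(dim(x$values), collapse = " x "),
              min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' Field-solver configuration
#'
#' Selects the boundary-condition alternatives for the electric potential
#' (A1 uniform field; A2 Laplace with zero normal gradient on the inter-anode
#' gaps; A3 a convex combination of A1 and A2) and the weighting potential
#' (B1 zero normal gradient on the gaps; B2 inverse-distance weighted
#' Dirichlet gap values). A2 is only used as the second ingredient of A3.
#'
#' @param electric_alternative `"A1"`, `"A2"` or `"A3"`.
#' @param a3_weight Convex weight on the A1 solution for A3, in `[0,1]`.
#' @param weighting_alternative `"B1"` or `"B2"`.
#' @param b2_power Inverse-distance weighting exponent (> 0); larger values
#'   steepen the lateral transition of the weighting potential.
#' @param b2_scale Fraction of the gap, measured from the selected pad's edge
#'   toward the neighbouring pad edge, at which the weighting potential is
#'   forced to zero; in `(0, 1]`. Controls the width of the anode's sensitive
#'   area.
#' @return Object of class `field_config`.
#' @export
field_config <- function(electric_alternative = c("A1", "A2", "A3"),
                         a3_weight = 0.5,
                         weighting_alternative = c("B1", "B2"),
                         b2_power = 2, b2_scale = 1) {
  electric_alternative <- match.arg(electric_alternative)
  weighting_alternative <- match.arg(weighting_alternative)
  stopifnot(a3_weight >= 0, a3_weight <= 1, b2_power > 0,
            b2_scale > 0, b2_scale <= 1)
  structure(list(electric_alternative = electric_alternative,
                 a3_weight = a3_weight,
                 weighting_alternative = weighting_alternative,
                 b2_power = b2_power, b2_scale = b2_scale),
            class = "field_config")
}

.grid_dims <- function(grid) c(length(grid$x), length(grid$y), length(grid$z))

# Dirichlet masks/values for the electric potential: cathode at -bias,
# anode pads at 0, gaps and lateral faces insulating (handled as Neumann).
.electric_dirichlet <- function(grid, crystal) {
  dims <- .grid_dims(grid)
  dir <- array(FALSE, dims); val <- array(0, dims)
  dir[, , 1L] <- TRUE
  val[, , 1L] <- -crystal$bias_voltage
  pads <- grid$anode_label > 0L
  dir[, , dims[3]][pads] <- TRUE
  list(dirichlet = dir, values = val)
}

#' Solve the electric potential
#'
#' Alternative A1 returns the uniform-field potential, linear in depth from
#' \code{-bias} at the cathode to 0 at the anode plane. A2 solves the Laplace
#' equation (space charge taken as zero) with Dirichlet electrodes and zero
#' normal gradient on the inter-anode gaps and lateral faces. A3 returns
#' \code{a3_weight * A1 + (1 - a3_weight) * A2}.
#'
#' @param grid A `grid3d`.
#' @param crystal A [crystal_spec()]; supplies the bias magnitude.
#' @param cfg A [field_config()].
#' @return A `scalar_field` in volts.
#' @export
solve_electric_potential <- function(grid, crystal, cfg = field_config()) {
  dims <- .grid_dims(grid)
  a1 <- function() {
    L <- crystal$thickness
    phi_z <- crystal$bias_voltage * (grid$z / L - 1)
    scalar_field(grid, array(rep(phi_z, each = dims[1] * dims[2]), dims), "V")
  }
  a2 <- function() {
    bc <- .electric_dirichlet(grid, crystal)
    lp <- .laplace_terms(dims, c(grid$hx, grid$hy, grid$hz))
    u <- .solve_lattice(dims, bc$dirichlet, bc$values, lp$terms, lp$diag,
                        array(0, dims), "electric potential")
    scalar_field(grid, u, "V")
  }
  switch(cfg$electric_alternative,
         A1 = a1(),
         A2 = a2(),
         A3 = {
           fa <- a1(); fb <- a2()
           scalar_field(grid, cfg$a3_weight * fa$values +
                          (1 - cfg$a3_weight) * fb$values, "V")
         })
}

# distance from lateral points to the closed square pad of given centre
.pad_distance <- function(x, y, cx, cy, half_pad) {
  dx <- pmax(0, abs(x - cx) - half_pad)
  dy <- pmax(0, abs(y - cy) - half_pad)
  sqrt(dx^2 + dy^2)
}

# Inverse-distance-weighted Dirichlet values on anode-plane gap nodes for
# alternative B2: weights d^(-power) over all pads (value 1 on pad k, 0
# elsewhere), then a linear rescale along the gap driving the value to zero
# at fraction `scale` of the way from pad k's edge to the nearest other pad.
.b2_gap_values <- function(grid, anode_k, power, scale) {
  gap <- which(grid$anode_label == 0L, arr.ind = TRUE)
  if (nrow(gap) == 0L) return(list(index = gap, values = numeric(0)))
  gx <- grid$x[gap[, 1]]; gy <- grid$y[gap[, 2]]
  pc <- grid$pad_centers
  half_pad <- grid$anodes$pad_size / 2
  eps <- 1e-6 * min(grid$hx, grid$hy)
  wsum <- rep(0, nrow(gap)); wk <- rep(0, nrow(gap))
  dmin_other <- rep(Inf, nrow(gap)); dk <- rep(Inf, nrow(gap))
  for (i in seq_len(nrow(pc))) {
    d <- .pad_distance(gx, gy, pc[i, 1], pc[i, 2], half_pad)
    w <- (d + eps)^(-power)
    wsum <- wsum + w
    if (i == anode_k) { wk <- w; dk <- d }
    else dmin_other <- pmin(dmin_other, d)
  }
  u <- wk / wsum
  tfrac <- dk / (dk + dmin_other)
  vals <- u * pmax(0, 1 - tfrac / scale)
  list(index = gap, values = vals)
}

#' Solve the Shockley-Ramo weighting potential
#'
#' Laplace solution with the selected electrode at unity and all other
#' electrodes at zero. `anode_k` selects a pad by its label in
#' `grid$anode_label`; `anode_k = 0` selects the cathode (useful for
#' partition-of-unity checks). Alternative B1 applies a zero normal gradient
#' on the inter-anode gap nodes; B2 prescribes Dirichlet gap values from the
#' inverse-distance-weighted construction parameterised by `b2_power` and
#' `b2_scale`.
#'
#' @param grid A `grid3d`.
#' @param anode_k Pad label (defaults to the grid's central anode), or 0 for
#'   the cathode.
#' @param cfg A [field_config()].
#' @return A `scalar_field`, dimensionless in `[0, 1]`.
#' @export
solve_weighting_potential <- function(grid, anode_k = grid$central_anode,
                                      cfg = field_config()) {
  dims <- .grid_dims(grid)
  if (anode_k != 0 && !(anode_k %in% grid$anode_label))
    stop("anode_k is not a pad label of this grid")
  dir <- array(FALSE, dims); val <- array(0, dims)
  dir[, , 1L] <- TRUE
  val[, , 1L] <- if (anode_k == 0) 1 else 0
  pads <- grid$anode_label > 0L
  top_dir <- dir[, , dims[3]]; top_val <- val[, , dims[3]]
  top_dir[pads] <- TRUE
  top_val[pads] <- 0
  if (anode_k != 0) top_val[grid$anode_label == anode_k] <- 1
  if (cfg$weighting_alternative == "B2") {
    b2 <- .b2_gap_values(grid, anode_k, cfg$b2_power, cfg$b2_scale)
    if (nrow(b2$index)) {
      gv <- if (anode_k == 0) 0 * b2$values else b2$values
      top_dir[b2$index] <- TRUE
      top_val[b2$index] <- gv
    }
  }
  dir[, , dims[3]] <- top_dir
  val[, , dims[3]] <- top_val
  lp <- .laplace_terms(dims, c(grid$hx, grid$hy, grid$hz))
  u <- .solve_lattice(dims, dir, val, lp$terms, lp$diag, array(0, dims),
                      "weighting potential")
  u <- pmin(pmax(u, 0), 1)
  scalar_field(grid, array(u, dims), "")
}

#' Gradient of a scalar field
#'
#' Central differences in the interior (second-order), one-sided differences
#' at the boundary nodes.
#'
#' @param field A `scalar_field`.
#' @return Object of class `vector_field`: list with 3-D arrays `x`, `y`,
#'   `z`, per mm of the field's unit.
#' @export
field_gradient <- function(field) {
  g <- field$grid
  v <- field$values
  dims <- dim(v)
  d1 <- function(arr, axis, h) {
    n <- dims[axis]
    out <- array(0, dims)
    if (n < 2L) return(out)
    idx <- function(rng) {
      ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      ix[[axis]] <- rng
      arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    }
    oidx <- function(rng, value) {
      ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      ix[[axis]] <- rng
      out[ix[[1]], ix[[2]], ix[[3]]] <<- value
    }
    if (n > 2L)
      oidx(2:(n - 1L), (idx(3:n) - idx(1:(n - 2L))) / (2 * h))
    oidx(1L, (idx(2L) - idx(1L)) / h)
    oidx(n, (idx(n) - idx(n - 1L)) / h)
    out
  }
  structure(list(grid = g,
                 x = d1(v, 1L, g$hx),
                 y = d1(v, 2L, g$hy),
                 z = d1(v, 3L, g$hz)),
            class = "vector_field")
}
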