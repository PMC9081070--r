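#' Charge-carrier transport parameters
#'
#' Mobility and lifetime for one carrier species. The diffusion constant
#' follows the Einstein relation \eqn{D = \mu k_B T / q} at 293 K unless
#' given explicitly; it can be set to zero to disable diffusion (used by the
#' Hecht consistency control).
#'
#' @param mobility Mobility (cm^2 V^-1 s^-1), > 0.
#' @param lifetime Lifetime (us), > 0.
#' @param carrier `"electron"` or `"hole"`. Electrons drift toward the anode
#'   plane, holes toward the cathode.
#' @param diffusion Diffusion constant (cm^2 s^-1); `NULL` (default) applies
#'   the Einstein relation, 0 disables diffusion.
#' @return Object of class `carrier_params`.
#' @export
#' @examples
#' carrier_params(1000, 3)            # typical CZT electrons
#' carrier_params(80, 0.5, "hole")    # poor hole transport
carrier_params <- function(mobility, lifetime,
                           carrier = c("electron", "hole"),
                           diffusion = NULL) {
  carrier <- match.arg(carrier)
  stopifnot(mobility > 0, lifetime > 0)
  kT_q <- 8.617333e-5 * 293  # thermal voltage at 293 K, volts
  if (is.null(diffusion)) diffusion <- mobility * kT_q
  stopifnot(diffusion >= 0)
  structure(list(mobility = mobility, lifetime = lifetime,
                 carrier = carrier, diffusion = diffusion),
            class = "carrier_params")
}

# unit conversions: mobility cm^2/(V s) -> mm^2/(V us); diffusion cm^2/s ->
# mm^2/us. Both are a factor 1e-4.
.mu_mm <- function(carrier) carrier$mobility * 1e-4
.D_mm <- function(carrier) carrier$diffusion * 1e-4

#' Adjoint source term
#'
#' The source of the adjoint transport problem,
#' \eqn{G^+ = \mu \nabla\varphi \cdot \nabla\varphi_k}, evaluated per node.
#' Units: 1/us with potentials in volts, lengths in mm and the mobility
#' converted internally.
#'
#' @param e_grad `vector_field` gradient of the electric potential (V/mm).
#' @param w_grad `vector_field` gradient of the weighting potential (1/mm).
#' @param mobility Carrier mobility (cm^2 V^-1 s^-1).
#' @return A `scalar_field` (1/us).
#' @export
adjoint_source <- function(e_grad, w_grad, mobility) {
  if (!identical(dim(e_grad$x), dim(w_grad$x)))
    stop("gradient fields live on different grids")
  mu <- mobility * 1e-4
  g <- mu * (e_grad$x * w_grad$x + e_grad$y * w_grad$y + e_grad$z * w_grad$z)
  scalar_field(e_grad$grid, g, "1/us")
}

# Electrode mask for charge transport: x(+) = 0 on ohmic surfaces (cathode
# plane and anode pads); gaps and lateral faces are insulating. Without
# diffusion the absorbing condition is only meaningful on the carrier's
# collecting side (pure drift never carries charge into the other
# electrode, and the adjoint characteristics only enter there), so the
# opposite electrode is released in that case.
.transport_dirichlet <- function(grid, carrier = NULL, D = 1) {
  dims <- .grid_dims(grid)
  dir <- array(FALSE, dims)
  with_cathode <- D > 0 || is.null(carrier) || carrier$carrier == "hole"
  with_anode <- D > 0 || is.null(carrier) || carrier$carrier == "electron"
  if (with_cathode) dir[, , 1L] <- TRUE
  if (with_anode) {
    top <- dir[, , dims[3]]
    top[grid$anode_label > 0L] <- TRUE
    dir[, , dims[3]] <- top
  }
  dir
}

# Null drift components pointing out of the domain at insulating
# (non-Dirichlet) boundary nodes: charge there is pinned by the surface, and
# a charge that does not move induces no signal. Applied to the advection
# velocity and, through it, to the adjoint source, in both the adjoint
# solver and the direct oracle.
.blocked_velocity <- function(grid, vel, dir) {
  dims <- .grid_dims(grid)
  for (axis in 1:3) {
    idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    lo <- idx; lo[[axis]] <- 1L
    hi <- idx; hi[[axis]] <- dims[axis]
    v <- vel[[axis]]
    vs <- v[lo[[1]], lo[[2]], lo[[3]]]
    ds <- dir[lo[[1]], lo[[2]], lo[[3]]]
    vs[!ds & vs < 0] <- 0
    v[lo[[1]], lo[[2]], lo[[3]]] <- vs
    vs <- v[hi[[1]], hi[[2]], hi[[3]]]
    ds <- dir[hi[[1]], hi[[2]], hi[[3]]]
    vs[!ds & vs > 0] <- 0
    v[hi[[1]], hi[[2]], hi[[3]]] <- vs
    vel[[axis]] <- v
  }
  vel
}

#' Solve the steady-state adjoint transport problem for the CIE
#'
#' Solves \eqn{0 = \pm\mu\nabla\varphi\cdot\nabla x^+ + \nabla\cdot(D\nabla
#' x^+) + G^+ - x^+/\tau} (advection sign positive for electrons, negative
#' for holes) with \eqn{x^+ = 0} on the electrode (ohmic) surfaces and zero
#' normal gradient on the insulating gap and lateral surfaces. The solution
#' equals the charge-induction efficiency \eqn{\eta_{x,k}(\mathbf r)} for
#' every starting position in a single solve. First-order upwinding is used
#' for the advection term; the upwind direction follows the adjoint
#' characteristics, which run against the carrier drift.
#'
#' @param grid A `grid3d`.
#' @param phi Electric potential `scalar_field` (V).
#' @param phi_k Weighting potential `scalar_field`.
#' @param carrier A [carrier_params()].
#' @return A `scalar_field` with the per-node CIE contribution of this
#'   carrier, clamped into `[0, 1]` (negative values beyond -1e-6 raise an
#'   error).
#' @export
solve_adjoint_cie <- function(grid, phi, phi_k, carrier) {
  dims <- .grid_dims(grid)
  hs <- c(grid$hx, grid$hy, grid$hz)
  gphi <- field_gradient(phi)
  gk <- field_gradient(phi_k)
  mu <- .mu_mm(carrier)
  D <- .D_mm(carrier)
  tau <- carrier$lifetime
  sgn <- if (carrier$carrier == "electron") +1 else -1
  dir <- .transport_dirichlet(grid, carrier, D)
  # carrier drift velocity, mm/us (electrons +mu grad(phi), holes -mu),
  # with outward components nulled where the surface pins the charge
  vel <- .blocked_velocity(grid,
                           list(sgn * mu * gphi$x, sgn * mu * gphi$y,
                                sgn * mu * gphi$z), dir)
  # source from the effective velocity: G+ = mu grad(phi) . grad(phi_k)
  # in the interior, zero where the drift is blocked
  G <- sgn * (vel[[1]] * gk$x + vel[[2]] * gk$y + vel[[3]] * gk$z)

  N <- prod(dims)
  terms <- list()
  diag <- rep(1 / tau, N)
  for (axis in 1:3) {
    h <- hs[axis]
    nb_m <- .shifted_index(dims, axis, -1L)
    nb_p <- .shifted_index(dims, axis, +1L)
    v <- as.numeric(vel[[axis]])
    # upwind along the adjoint characteristics: velocity component v > 0
    # couples to the +1 neighbour, v < 0 to the -1 neighbour
    cp <- ifelse(v > 0, -v / h, 0)
    cm <- ifelse(v < 0, v / h, 0)
    terms[[length(terms) + 1L]] <-
      list(nb = nb_p, coef = cp, boundary = "drop",
           opposite = nb_m, diag_pair = -cp)
    terms[[length(terms) + 1L]] <-
      list(nb = nb_m, coef = cm, boundary = "drop",
           opposite = nb_p, diag_pair = -cm)
    if (D > 0) {
      cd <- rep(-D / h^2, N)
      terms[[length(terms) + 1L]] <-
        list(nb = nb_m, coef = cd, boundary = "reflect", opposite = nb_p,
             diag_pair = rep(0, N))
      terms[[length(terms) + 1L]] <-
        list(nb = nb_p, coef = cd, boundary = "reflect", opposite = nb_m,
             diag_pair = rep(0, N))
      diag <- diag + 2 * D / h^2
    }
  }
  u <- .solve_lattice(dims, dir, array(0, dims), terms, diag, G,
                      "adjoint transport")
  # With a non-negative source (monopolar induction, e.g. parallel plate)
  # the upwinded M-matrix guarantees a non-negative solution, so negatives
  # beyond round-off indicate a scheme violation. Multi-electrode
  # geometries have sign-changing sources (carriers collected by a
  # neighbouring pad induce net negative charge on the selected anode);
  # those physical negative transients are clamped to the CIE bounds.
  if (min(G) >= -1e-12 && min(u) < -1e-6)
    stop(sprintf("adjoint solution has negative values (min %.3g): scheme violation",
                 min(u)))
  u[u < 0] <- 0
  scalar_field(grid, array(pmin(u, 1), dims), "")
}

#' Direct time-stepping CIE oracle
#'
#' Brute-force reference for [solve_adjoint_cie()]: injects a point-like unit
#' charge at `r0`, steps the carrier continuity equation forward in time with
#' an explicit upwind finite-difference scheme (conservative flux form), and
#' accumulates the Shockley-Ramo induced charge
#' \eqn{\int\!\!\int x\,\mu\nabla\varphi\cdot\nabla\varphi_k\, d\Omega\,dt}.
#' Intended for validation on small grids only; never used in production
#' paths.
#'
#' @param r0 Numeric length-3 starting position (mm, grid frame); snapped to
#'   the nearest node.
#' @param phi,phi_k Potential `scalar_field`s.
#' @param carrier A [carrier_params()].
#' @param dt Time step (us); default 40\% of the stability limit. A value
#'   above the explicit stability (CFL) limit raises an error.
#' @param t_end Integration end (us); default runs until the surviving
#'   charge fraction falls below 1e-10 (capped at 60 lifetimes).
#' @return The CIE (scalar) at `r0`.
#' @export
direct_cie_oracle <- function(r0, phi, phi_k, carrier, dt = NULL,
                              t_end = NULL) {
  grid <- phi$grid
  dims <- .grid_dims(grid)
  hs <- c(grid$hx, grid$hy, grid$hz)
  gphi <- field_gradient(phi)
  gk <- field_gradient(phi_k)
  mu <- .mu_mm(carrier)
  D <- .D_mm(carrier)
  tau <- carrier$lifetime
  sgn <- if (carrier$carrier == "electron") +1 else -1
  dir <- .transport_dirichlet(grid, carrier, D)
  vel <- .blocked_velocity(grid,
                           list(sgn * mu * gphi$x, sgn * mu * gphi$y,
                                sgn * mu * gphi$z), dir)
  G <- sgn * (vel[[1]] * gk$x + vel[[2]] * gk$y + vel[[3]] * gk$z)

  vmax <- max(abs(vel[[1]]) / hs[1] + abs(vel[[2]]) / hs[2] +
                abs(vel[[3]]) / hs[3])
  dmax <- if (D > 0) 2 * D * sum(1 / hs^2) else 0
  limit <- 1 / max(vmax + dmax, 1 / tau)
  if (is.null(dt)) dt <- 0.4 * limit
  if (dt > limit)
    stop(sprintf("dt = %g us violates the explicit stability limit %g us",
                 dt, limit))
  if (is.null(t_end)) t_end <- 60 * tau

  ii <- c(which.min(abs(grid$x - r0[1])), which.min(abs(grid$y - r0[2])),
          which.min(abs(grid$z - r0[3])))
  if (dir[ii[1], ii[2], ii[3]]) return(0)

  x <- array(0, dims)
  x[ii[1], ii[2], ii[3]] <- 1          # cell masses; total mass 1
  shift <- function(arr, axis, by) {
    out <- array(0, dims)
    n <- dims[axis]
    src <- dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    if (by > 0) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1L) }
    else { dst[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    out
  }
  eta <- 0
  t <- 0
  repeat {
    eta <- eta + dt * sum(x * G)
    dx <- -x / tau
    for (axis in 1:3) {
      h <- hs[axis]
      v <- vel[[axis]]
      vf_p <- 0.5 * (v + shift(v, axis, -1L))  # face i+1/2 velocity
      # flux through the i+1/2 face, upwinded on the face velocity
      Fp <- ifelse(vf_p > 0, vf_p * x, vf_p * shift(x, axis, -1L))
      # outer faces are insulating: no advective flux
      edge <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      edge[[axis]] <- dims[axis]
      Fp[edge[[1]], edge[[2]], edge[[3]]] <- 0
      Fm <- shift(Fp, axis, +1L)
      dx <- dx - (Fp - Fm) / h
      if (D > 0) {
        xm <- shift(x, axis, +1L); xp <- shift(x, axis, -1L)
        lo <- edge; lo[[axis]] <- 1L
        # reflected ghosts (zero normal gradient) at the outer faces
        xm[lo[[1]], lo[[2]], lo[[3]]] <-
          shift(x, axis, -1L)[lo[[1]], lo[[2]], lo[[3]]]
        xp[edge[[1]], edge[[2]], edge[[3]]] <-
          shift(x, axis, +1L)[edge[[1]], edge[[2]], edge[[3]]]
        dx <- dx + D * (xp - 2 * x + xm) / h^2
      }
    }
    x <- x + dt * dx
    x[dir] <- 0                        # absorbing electrode surfaces
    t <- t + dt
    if (sum(x) < 1e-10 || t >= t_end) break
  }
  eta
}

#' Hecht charge-collection efficiency
#'
#' Closed-form CIE versus depth for the parallel-plate detector with a
#' uniform field and no diffusion:
#' \deqn{\eta(z) = \frac{\lambda_e}{L}\left(1 - e^{-(L-z)/\lambda_e}\right) +
#'   \frac{\lambda_h}{L}\left(1 - e^{-z/\lambda_h}\right),}
#' with drift lengths \eqn{\lambda = \mu\tau E} and `z` measured from the
#' cathode. The hole term is omitted when `mu_tau_h` is `NULL`.
#'
#' @param z Depth(s) from the cathode (mm).
#' @param thickness Crystal thickness L (mm).
#' @param mu_tau_e Electron mobility-lifetime product (cm^2/V).
#' @param mu_tau_h Hole mobility-lifetime product (cm^2/V) or `NULL`.
#' @param field Field magnitude (V/mm).
#' @return CIE value(s) in `[0, 1]`.
#' @export
#' @examples
#' hecht_cie(0, 5, 1e-3, NULL, 120)  # lambda_e = 12 mm
hecht_cie <- function(z, thickness, mu_tau_e, mu_tau_h = NULL, field) {
  lam_e <- mu_tau_e * 100 * field  # cm^2/V -> mm^2/V, times V/mm
  if (lam_e <= 0) stop("non-positive electron drift length")
  eta <- (lam_e / thickness) * (1 - exp(-(thickness - z) / lam_e))
  if (!is.null(mu_tau_h)) {
    lam_h <- mu_tau_h * 100 * field
    if (lam_h <= 0) stop("non-positive hole drift length")
    eta <- eta + (lam_h / thickness) * (1 - exp(-z / lam_h))
  }
  eta
}

#' Combine carrier components into a CIE map
#'
#' C1 uses the electron contribution alone; C2 adds the hole contribution.
#' The result is clamped into `[0, 1]` and wrapped with coordinates and
#' generation metadata.
#'
#' @param eta_e Electron `scalar_field` from [solve_adjoint_cie()].
#' @param eta_h Hole `scalar_field`, required for `mode = "C2"`.
#' @param mode `"C1"` (electrons only) or `"C2"` (electrons and holes).
#' @param field_config,carriers Metadata recorded on the map.
#' @return Object of class `cie_map`: `values` (3-D array), `x`, `y`, `z`
#'   coordinates (mm, origin at the joint anode pad centre laterally, cathode
#'   at z = 0), `signal_mode`, `r_joint`, `meta`.
#' @export
combine_components <- function(eta_e, eta_h = NULL, mode = c("C1", "C2"),
                               field_config = NULL, carriers = NULL) {
  mode <- match.arg(mode)
  if (mode == "C2" && is.null(eta_h))
    stop("mode C2 requires the hole component")
  vals <- eta_e$values
  if (mode == "C2") {
    if (!identical(dim(eta_h$values), dim(vals)))
      stop("electron and hole fields live on different grids")
    vals <- vals + eta_h$values
  }
  vals <- pmin(pmax(vals, 0), 1)
  g <- eta_e$grid
  structure(list(values = vals, x = g$x, y = g$y, z = g$z,
                 signal_mode = mode, r_joint = c(0, 0),
                 meta = list(field_config = field_config,
                             carriers = carriers)),
            class = "cie_map")
}

#' @export
print.cie_map <- function(x, ...) {
  cat(sprintf("<cie_map> %d x %d x %d (%s), eta in [%.3f, %.3f]\n",
              length(x$x), length(x$y), length(x$z), x$signal_mode,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Plot a CIE map cross-section
#'
#' Grey-scale image of the x-z mid-plane (y = centre), anode plane at the
#' top.
#'
#' @param x A `cie_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cie_map <- function(x, ...) {
  jy <- which.min(abs(x$y - stats::median(x$y)))
  graphics::image(x$x, x$z, x$values[, jy, ], xlab = "x (mm)",
                  ylab = "depth z (mm)", main = "CIE, y mid-plane",
                  col = grey.colors(64, 0, 1), ...)
  invisible(x)
}

.cie_magic <- charToRaw("CZTCIE1\n")

#' Write / read a CIE map container
#'
#' Versioned binary container: an 8-byte magic string, a format version,
#' the axis lengths, the axis coordinates, the value array (column-major,
#' little-endian 64-bit floats) and a length-prefixed JSON metadata block.
#' The round trip is bit-exact.
#'
#' @param map A `cie_map`.
#' @param path File path.
#' @return `read_cie` returns the `cie_map`; with `metadata_only = TRUE`
#'   only the recorded parameters (no array) are loaded.
#' @export
write_cie <- function(map, path) {
  stopifnot(inherits(map, "cie_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.cie_magic, con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(as.integer(c(length(map$x), length(map$y), length(map$z))), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(map$x), con, size = 8L, endian = "little")
  writeBin(as.numeric(map$y), con, size = 8L, endian = "little")
  writeBin(as.numeric(map$z), con, size = 8L, endian = "little")
  writeBin(as.numeric(map$values), con, size = 8L, endian = "little")
  meta <- jsonlite::toJSON(list(signal_mode = map$signal_mode,
                                r_joint = map$r_joint, meta = map$meta),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  mraw <- charToRaw(as.character(meta))
  writeBin(length(mraw), con, size = 4L, endian = "little")
  writeBin(mraw, con)
  invisible(path)
}

#' @rdname write_cie
#' @param metadata_only Skip loading the value array.
#' @export
read_cie <- function(path, metadata_only = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, .cie_magic))
    stop("not a CIE container (bad magic header)", call. = FALSE)
  ver <- readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(ver, 1L)) stop(sprintf("unsupported CIE format version %d", ver))
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (length(dims) < 3L || any(dims <= 0L)) stop("truncated CIE file")
  x <- readBin(con, "numeric", n = dims[1], size = 8L, endian = "little")
  y <- readBin(con, "numeric", n = dims[2], size = 8L, endian = "little")
  z <- readBin(con, "numeric", n = dims[3], size = 8L, endian = "little")
  if (metadata_only) {
    seek(con, where = prod(dims) * 8, origin = "current")
    vals <- NULL
  } else {
    vraw <- readBin(con, "numeric", n = prod(dims), size = 8L,
                    endian = "little")
    if (length(vraw) != prod(dims)) stop("truncated CIE file")
    vals <- array(vraw, dims)
  }
  mlen <- readBin(con, "integer", size = 4L, endian = "little")
  mraw <- readBin(con, "raw", n = mlen)
  if (length(mraw) != mlen) stop("truncated CIE file")
  meta <- jsonlite::fromJSON(rawToChar(mraw), simplifyVector = TRUE)
  structure(list(values = vals, x = x, y = y, z = z,
                 signal_mode = meta$signal_mode,
                 r_joint = as.numeric(meta$r_joint), meta = meta$meta),
            class = "cie_map")
}

#' Generate a joint CIE map for the central anode
#'
#' End-to-end pipeline: build the grid (optionally quarter-reduced through
#' the lateral mirror symmetries), solve the electric and weighting
#' potentials under the chosen boundary-condition alternatives, run the
#' steady-state adjoint transport solve per carrier and combine the
#' components. The returned map always covers the full (unfolded)
#' neighbourhood.
#'
#' @param crystal A [crystal_spec()].
#' @param anodes An [anode_array_spec()].
#' @param cfg A [field_config()].
#' @param electron A [carrier_params()] for electrons.
#' @param hole A [carrier_params()] for holes (required for `mode = "C2"`).
#' @param mode `"C1"` or `"C2"`.
#' @param neighbourhood,step Grid parameters, see [build_grid()].
#' @param reduce Use quarter-symmetry reduction (default `TRUE`; requires an
#'   even pitch/step ratio).
#' @return A `cie_map`.
#' @export
generate_cie_map <- function(crystal, anodes, cfg = field_config(),
                             electron = carrier_params(1000, 3),
                             hole = NULL, mode = c("C1", "C2"),
                             neighbourhood = 5, step = 0.41,
                             reduce = TRUE) {
  mode <- match.arg(mode)
  full <- build_grid(crystal, anodes, neighbourhood, step)
  if (reduce) {
    sr <- symmetry_reduce(full)
    g <- sr$grid
  } else {
    g <- full
  }
  phi <- solve_electric_potential(g, crystal, cfg)
  phik <- solve_weighting_potential(g, g$central_anode, cfg)
  eta_e <- solve_adjoint_cie(g, phi, phik, electron)
  eta_h <- NULL
  if (mode == "C2") {
    if (is.null(hole)) stop("mode C2 requires hole carrier parameters")
    eta_h <- solve_adjoint_cie(g, phi, phik, hole)
  }
  if (reduce) {
    ev <- scalar_field(full, sr$unfold(eta_e$values))
    hv <- if (!is.null(eta_h)) scalar_field(full, sr$unfold(eta_h$values))
    combine_components(ev, hv, mode, cfg,
                       list(electron = electron, hole = hole))
  } else {
    combine_components(eta_e, eta_h, mode, cfg,
                       list(electron = electron, hole = hole))
  }
}
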