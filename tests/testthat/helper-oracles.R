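# Brute-force dense solver for the discrete Laplace system: independent
# naive-loop assembly of the same 7-point stencil (Dirichlet nodes pinned,
# zero-normal-gradient boundaries via ghost reflection). Used as an oracle
# for the sparse field solvers on tiny grids only.
dense_laplace_oracle <- function(grid, dirichlet, dirvals) {
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  hs <- c(grid$hx, grid$hy, grid$hz)
  N <- nx * ny * nz
  id <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  A <- matrix(0, N, N)
  b <- numeric(N)
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    n <- id(i, j, k)
    if (dirichlet[i, j, k]) {
      A[n, n] <- 1
      b[n] <- dirvals[i, j, k]
      next
    }
    nb <- list(
      c(if (i > 1) i - 1 else i + 1, j, k, 1),
      c(if (i < nx) i + 1 else i - 1, j, k, 1),
      c(i, if (j > 1) j - 1 else j + 1, k, 2),
      c(i, if (j < ny) j + 1 else j - 1, k, 2),
      c(i, j, if (k > 1) k - 1 else k + 1, 3),
      c(i, j, if (k < nz) k + 1 else k - 1, 3))
    for (m in nb) {
      c2 <- 1 / hs[m[4]]^2
      A[n, id(m[1], m[2], m[3])] <- A[n, id(m[1], m[2], m[3])] + c2
      A[n, n] <- A[n, n] - c2
    }
  }
  array(solve(A, b), c(nx, ny, nz))
}

# electric-potential Dirichlet data as the solvers define it
electric_bc <- function(grid, crystal) {
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  dir <- array(FALSE, dims); val <- array(0, dims)
  dir[, , 1] <- TRUE
  val[, , 1] <- -crystal$bias_voltage
  top <- dir[, , dims[3]]
  top[grid$anode_label > 0] <- TRUE
  dir[, , dims[3]] <- top
  list(dir = dir, val = val)
}

# weighting-potential Dirichlet data (B1: gaps free)
weighting_bc <- function(grid, anode_k) {
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  dir <- array(FALSE, dims); val <- array(0, dims)
  dir[, , 1] <- TRUE
  top_d <- dir[, , dims[3]]; top_v <- val[, , dims[3]]
  top_d[grid$anode_label > 0] <- TRUE
  top_v[grid$anode_label == anode_k] <- 1
  dir[, , dims[3]] <- top_d
  val[, , dims[3]] <- top_v
  list(dir = dir, val = val)
}

# parallel-plate fixture: full-area single anode, thin lateral extent
pp_setup <- function(step = 0.25, thickness = 5, width = NULL, bias = 600,
                     alt = "A1") {
  if (is.null(width)) width <- 4 * step
  cr <- crystal_spec(width, width, thickness, bias)
  an <- anode_array_spec(1, 1, pitch = width, pad_size = width)
  g <- build_grid(cr, an, 1, step)
  cfg <- field_config(alt)
  list(crystal = cr, anodes = an, grid = g, cfg = cfg,
       phi = solve_electric_potential(g, cr, cfg),
       phik = solve_weighting_potential(g, g$central_anode, cfg))
}

# small 3x3-anode neighbourhood fixture (<= 21^3 nodes)
toy_setup <- function(step = 0.5, weighting = "B1") {
  cr <- crystal_spec(6, 6, 5, 600)
  an <- anode_array_spec(3, 3, pitch = 2, pad_size = 1.5)
  g <- build_grid(cr, an, 3, step)
  cfg <- field_config("A1", weighting_alternative = weighting)
  list(crystal = cr, anodes = an, grid = g, cfg = cfg,
       phi = solve_electric_potential(g, cr, cfg),
       phik = solve_weighting_potential(g, g$central_anode, cfg))
}

# synthetic CIE map with prescribed values on a given lattice
synthetic_cie <- function(values, x, y, z, mode = "C1") {
  structure(list(values = values, x = x, y = y, z = z, signal_mode = mode,
                 r_joint = c(0, 0), meta = list()),
            class = "cie_map")
}

# constant-eta joint map covering +/- `reach` anode cells laterally
const_cie <- function(eta0 = 0.8, reach = 1.5, pitch = 2.46, thickness = 5,
                      n = 9) {
  x <- seq(-reach * pitch, reach * pitch, length.out = n)
  z <- seq(0, thickness, length.out = 5)
  synthetic_cie(array(eta0, c(n, n, 5)), x, x, z)
}

# synthetic three-line initial spectrum: narrow peaks at scale * E plus a
# flat low-energy tail fragment per line
three_line_spectrum <- function(scale = 0.8, peaks = c(55, 112.9, 208.4),
                                heights = c(800, 600, 400)) {
  ax <- energy_axis()
  cnt <- numeric(ax$n)
  for (i in seq_along(peaks)) {
    mu <- scale * peaks[i]
    prof <- heights[i] * exp(-0.5 * ((ax$centers - mu) / 1.2)^2)
    tail_sel <- ax$centers > 42 & ax$centers < mu - 5
    cnt <- cnt + prof
    cnt[tail_sel] <- cnt[tail_sel] + 0.03 * heights[i]
  }
  spectrum(cnt)
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected) /
                            pmax(abs(expected), 1e-12)), tol)
}
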