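test_that("adjoint source reduces to the closed form for uniform fields", {
  st <- pp_setup(step = 0.5)
  gphi <- field_gradient(st$phi)
  gk <- field_gradient(st$phik)
  G <- adjoint_source(gphi, gk, 1000)
  # mu E / L with mu = 0.1 mm^2/(V us), E = 120 V/mm, L = 5 mm
  expect_equal(max(abs(G$values - 0.1 * 120 / 5)), 0, tolerance = 1e-12)
  # constant weighting potential: zero source
  dims <- dim(st$phik$values)
  gk0 <- field_gradient(scalar_field(st$grid, array(0.3, dims)))
  expect_equal(max(abs(adjoint_source(gphi, gk0, 1000)$values)), 0)
  # hand-evaluated dot product on prescribed linear fields
  g <- st$grid
  fa <- scalar_field(g, array(rep(2 * g$z, each = dims[1] * dims[2]), dims))
  fb <- outer(outer(3 * g$x, 0 * g$y, `+`), 0.5 * g$z, `+`)
  fbf <- scalar_field(g, fb)
  G2 <- adjoint_source(field_gradient(fa), field_gradient(fbf), 1000)
  expect_equal(max(abs(G2$values - 0.1 * (2 * 0.5))), 0, tolerance = 1e-12)
  # grid mismatch is rejected
  st2 <- pp_setup(step = 1)
  expect_error(adjoint_source(gphi, field_gradient(st2$phik), 1000),
               "different grids")
})

test_that("Hecht closed form matches its limits and a hand evaluation", {
  expect_equal(hecht_cie(c(0, 2.5, 5), 5, 1e6, 1e6, 120), rep(1, 3),
               tolerance = 1e-6)
  expect_equal(hecht_cie(5, 5, 1e-3, NULL, 120), 0)
  # lambda_e = 12 mm at mu tau = 1e-3 cm^2/V and 120 V/mm
  expect_equal(hecht_cie(0, 5, 1e-3, NULL, 120),
               2.4 * (1 - exp(-5 / 12)))
  expect_error(hecht_cie(0, 5, -1, NULL, 120), "non-positive")
})

test_that("diffusion-free parallel-plate adjoint solution is Hecht", {
  cr <- crystal_spec(0.2, 0.2, 5, 600)
  an <- anode_array_spec(1, 1, pitch = 0.2, pad_size = 0.2)
  g <- build_grid(cr, an, 1, 0.05)
  cfg <- field_config("A1")
  phi <- solve_electric_potential(g, cr, cfg)
  phik <- solve_weighting_potential(g, g$central_anode, cfg)
  el <- carrier_params(1000, 1, diffusion = 0)   # mu tau = 1e-3 cm^2/V
  eta <- solve_adjoint_cie(g, phi, phik, el)
  href <- hecht_cie(g$z, 5, 1e-3, NULL, 120)
  idx <- seq_len(length(g$z) - 1L)      # exclude the shared zero at z = L
  expect_rel_equal(eta$values[3, 3, idx], href[idx], 0.01)
  # electrons-only profile decreases monotonically toward the anode
  expect_true(all(diff(eta$values[3, 3, ]) < 0))
})

test_that("a vanishing source yields a vanishing CIE", {
  st <- pp_setup(step = 0.5)
  dims <- dim(st$phik$values)
  flat <- scalar_field(st$grid, array(0.4, dims))
  eta <- solve_adjoint_cie(st$grid, st$phi, flat, carrier_params(1000, 3))
  expect_equal(max(abs(eta$values)), 0)
})

test_that("longer lifetimes never decrease the CIE", {
  st <- pp_setup(step = 0.5)
  e1 <- solve_adjoint_cie(st$grid, st$phi, st$phik, carrier_params(1000, 1))
  e2 <- solve_adjoint_cie(st$grid, st$phi, st$phik, carrier_params(1000, 4))
  expect_true(all(e2$values - e1$values >= -1e-9))
})

test_that("direct oracle reproduces full collection and surface limits", {
  st <- pp_setup(step = 0.5)
  # effectively infinite lifetimes: electrons and holes together collect
  # the full signal anywhere
  el <- carrier_params(1000, 1e4, "electron", diffusion = 0)
  ho <- carrier_params(80, 1e5, "hole", diffusion = 0)
  r0 <- c(0, 0, 1.5)
  eta <- direct_cie_oracle(r0, st$phi, st$phik, el, dt = 0.002) +
    direct_cie_oracle(r0, st$phi, st$phik, ho, dt = 0.02)
  expect_equal(eta, 1, tolerance = 0.01)
  # charge created on the collecting anode surface induces nothing
  expect_equal(direct_cie_oracle(c(0, 0, 5), st$phi, st$phik,
                                 carrier_params(1000, 3)), 0)
  # CFL guard
  expect_error(direct_cie_oracle(r0, st$phi, st$phik,
                                 carrier_params(1000, 3), dt = 10), "stability")
  # mid-depth agreement with the Hecht configuration
  elh <- carrier_params(1000, 1, diffusion = 0)
  d <- direct_cie_oracle(c(0, 0, 2.5), st$phi, st$phik, elh, dt = 0.002)
  expect_equal(d, hecht_cie(2.5, 5, 1e-3, NULL, 120), tolerance = 0.02)
})

test_that("adjoint solution equals the direct time-stepping oracle", {
  st <- toy_setup(step = 0.5)    # 13 x 13 x 11 nodes
  el <- carrier_params(1000, 0.5)
  eta <- solve_adjoint_cie(st$grid, st$phi, st$phik, el)
  g <- st$grid
  pts <- list(c(0, 0, 1), c(0.5, 0, 2.5), c(0, 0.5, 3.5), c(0.5, 0.5, 4),
              c(0, 0, 0.5))
  for (p in pts) {
    d <- direct_cie_oracle(p, st$phi, st$phik, el, dt = 0.001)
    a <- eta$values[which(g$x == p[1]), which(g$y == p[2]),
                    which(g$z == p[3])]
    expect_rel_equal(d, a, 0.02)
  }
})

test_that("carrier components combine per signal mode", {
  st <- pp_setup(step = 0.25)
  el <- carrier_params(1000, 1, diffusion = 0)
  ho <- carrier_params(80, 2, "hole", diffusion = 0)
  ee <- solve_adjoint_cie(st$grid, st$phi, st$phik, el)
  eh <- solve_adjoint_cie(st$grid, st$phi, st$phik, ho)
  c1 <- combine_components(ee, NULL, "C1")
  expect_identical(c1$values, ee$values)
  zero <- scalar_field(st$grid, array(0, dim(ee$values)))
  expect_equal(combine_components(ee, zero, "C2")$values, c1$values)
  c2 <- combine_components(ee, eh, "C2")
  # the hole term lifts the CIE near the anode (Hecht algebra)
  nz <- length(st$grid$z)
  expect_gt(c2$values[2, 2, nz - 1], c1$values[2, 2, nz - 1])
  # and the lift matches the Hecht hole term on this geometry
  lam_h <- 80e-4 * 2 * 120   # mm
  zh <- st$grid$z[nz - 1]
  expect_equal(c2$values[2, 2, nz - 1] - c1$values[2, 2, nz - 1],
               (lam_h / 5) * (1 - exp(-zh / lam_h)),
               tolerance = 0.1)
  expect_error(combine_components(ee, NULL, "C2"), "hole")
})

test_that("joint maps are bounded and quarter-symmetric", {
  cie <- generate_cie_map(crystal_spec(), anode_array_spec(),
                          field_config("A1", weighting_alternative = "B1"),
                          electron = carrier_params(1000, 3),
                          neighbourhood = 3, step = 0.41)
  v <- cie$values
  expect_true(all(v >= 0 & v <= 1))
  expect_lt(max(abs(v - v[dim(v)[1]:1, , ])), 1e-9)
  expect_lt(max(abs(v - v[, dim(v)[2]:1, ])), 1e-9)
})

test_that("CIE containers round-trip bit-exactly", {
  cie <- generate_cie_map(crystal_spec(), anode_array_spec(),
                          field_config("A1"),
                          electron = carrier_params(1000, 3),
                          neighbourhood = 3, step = 0.82, reduce = FALSE)
  path <- tempfile(fileext = ".cie")
  write_cie(cie, path)
  back <- read_cie(path)
  expect_identical(back$values, cie$values)
  expect_identical(back$x, cie$x)
  expect_identical(back$z, cie$z)
  expect_identical(back$signal_mode, cie$signal_mode)
  meta <- read_cie(path, metadata_only = TRUE)
  expect_null(meta$values)
  expect_identical(meta$signal_mode, cie$signal_mode)
  expect_equal(meta$meta$carriers$electron$mobility, 1000)
  # corrupted magic header is a typed failure
  bad <- tempfile()
  raw <- readBin(path, "raw", file.size(path))
  raw[1:4] <- as.raw(0)
  writeBin(raw, bad)
  expect_error(read_cie(bad), "magic")
})
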