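test_that("CIE evaluation interpolates and translates correctly", {
  # small synthetic joint map linear in x so midpoints are exact means
  x <- seq(-3.69, 3.69, by = 1.23)
  z <- seq(0, 5, by = 1.25)
  vals <- array(0, c(length(x), length(x), length(z)))
  for (i in seq_along(x)) vals[i, , ] <- 0.1 + 0.05 * (i - 1)
  cie <- synthetic_cie(vals, x, x, z)
  model <- detector_model(cie, anode_array_spec(), crystal_spec(),
                          threshold = 40)
  k_joint <- which(model$centers[, 1] == -1.23 & model$centers[, 2] == -1.23)
  # node identity at the joint anode
  p <- c(-1.23 + x[2], -1.23 + x[3], z[2])
  expect_equal(eval_cie(model, k_joint, p), vals[2, 3, 2])
  # translation: a neighbour anode sees the shifted position
  k_nb <- which(model$centers[, 1] == -1.23 + 2.46 &
                  model$centers[, 2] == -1.23)
  expect_equal(eval_cie(model, k_nb, c(p[1] + 2.46, p[2], p[3])),
               vals[2, 3, 2])
  # midpoint between two nodes differing linearly along x
  pm <- c(-1.23 + (x[2] + x[3]) / 2, -1.23 + x[3], z[2])
  expect_equal(eval_cie(model, k_joint, pm),
               (vals[2, 3, 2] + vals[3, 3, 2]) / 2)
  # out of lateral extent is a defined zero
  expect_equal(eval_cie(model, k_joint, c(30, 0, 2)), 0)
})

test_that("history responses follow the weighted-sum rule", {
  model <- detector_model(const_cie(0.8), anode_array_spec(), crystal_spec())
  h1 <- data.frame(x = 0, y = 0, z = 2, energy = 100, weight = 1)
  r <- respond_history(model, h1)
  near <- which(abs(model$centers[, 1]) < 2 & abs(model$centers[, 2]) < 2)
  expect_equal(r[near], rep(80, length(near)))
  expect_equal(respond_history(model, h1[0, ]), numeric(256))
  # two events over adjacent anodes, hand evaluation with constant eta
  h2 <- data.frame(x = c(-1.23, 1.23), y = c(-1.23, -1.23), z = c(1, 1),
                   energy = c(100, 50), weight = 1)
  r2 <- respond_history(model, h2)
  k1 <- which(model$centers[, 1] == -1.23 & model$centers[, 2] == -1.23)
  expect_equal(r2[k1], 0.8 * 150)  # both events within the joint-map reach
})

test_that("winner selection takes the maximum with a deterministic tie-break", {
  e <- numeric(256); e[10] <- 50; e[30] <- 30
  w <- select_winner(e, 40)
  expect_equal(w$anode, 10L)
  expect_equal(w$energy, 50)
  expect_null(select_winner(numeric(256) + 10, 40))
  tie <- numeric(256); tie[c(7, 19)] <- 60
  expect_equal(select_winner(tie, 40)$anode, 7L)
})

test_that("spectrum accumulation conserves weighted counts", {
  model <- detector_model(const_cie(0.9), anode_array_spec(), crystal_spec())
  src <- source_spec(lines = cbind(energy = 140.5, intensity = 1),
                     class_fractions = c(geometric_primary = 1,
                                         phantom_scatter = 0, penetration = 0,
                                         collimator_scatter = 0,
                                         collimator_xray = 0, other = 0),
                     p_photo = 1, p_rayleigh = 0)
  lm <- generate_listmode(src, crystal_spec(), anode_array_spec(),
                          collimator_spec("OPEN"), 2000, seed = 2)
  tab <- accumulate_spectra(model, lm)
  # constant eta: all counts in the bin of 0.9 * 140.5 keV
  b <- floor(0.9 * 140.5 / 0.1) + 1
  expect_equal(sum(tab$counts), 2000)
  expect_equal(sum(tab$counts[, b]), 2000)
  # weighted histories contribute their weights
  lm$events$weight <- rep(c(1, 0.25), length.out = nrow(lm$events))
  tab2 <- accumulate_spectra(model, lm)
  expect_equal(sum(tab2$counts), sum(rep(c(1, 0.25), length.out = 2000)),
               tolerance = 1e-9)
})

test_that("energy calibration re-bins counts conservatively", {
  ax <- energy_axis()
  cnt <- numeric(ax$n); cnt[500] <- 100             # bin 500 = [49.9, 50.0)
  s <- spectrum(cnt)
  id <- apply_calibration(s, energy_calibration(0, 1))
  expect_identical(as.numeric(id), cnt)
  dbl <- apply_calibration(s, energy_calibration(0, 2))
  expect_equal(sum(dbl), 100)
  expect_equal(sum(as.numeric(dbl)[999:1000]), 100)  # [99.8, 100.0) keV
  shift <- apply_calibration(s, energy_calibration(3.77, 1.13))
  expect_equal(sum(shift), 100)
  com_in <- sum(ax$centers * cnt) / sum(cnt)
  com_out <- sum(ax$centers * as.numeric(shift)) / sum(shift)
  expect_equal(com_out, 3.77 + 1.13 * com_in, tolerance = 1e-3)
})

test_that("resolution smoothing has the requested width and conserves counts", {
  ax <- energy_axis()
  cnt <- numeric(ax$n); cnt[1500] <- 1000   # spike at 149.95 keV
  s <- spectrum(cnt)
  expect_identical(as.numeric(apply_resolution(s, resolution_model(0, 0))),
                   cnt)
  res <- resolution_model(5.64, 0.00751)
  sm <- apply_resolution(s, res)
  expect_equal(sum(sm), 1000, tolerance = 1e-9)
  want <- 5.64 + 0.00751 * ax$centers[1500]
  v <- as.numeric(sm)
  half <- max(v) / 2
  above <- which(v >= half)
  lo <- min(above); hi <- max(above)
  # interpolated half-maximum crossings
  fl <- ax$centers[lo - 1] + (half - v[lo - 1]) / (v[lo] - v[lo - 1]) * 0.1
  fh <- ax$centers[hi] + (v[hi] - half) / (v[hi] - v[hi + 1]) * 0.1
  expect_lt(abs((fh - fl) - want), 0.05)
  expect_error(apply_resolution(s, resolution_model(-200, 0.1)), "negative")
})

test_that("calibration solves the fixed point and inverts linear distortions", {
  res <- resolution_model(5.64, 0.00751)
  aligned <- three_line_spectrum(scale = 1)
  cal0 <- calibrate(aligned, c(55, 112.9, 208.4), res)
  expect_lt(abs(cal0$a0), 0.1)
  expect_lt(abs(cal0$a1 - 1), 1e-3)
  shrunk <- three_line_spectrum(scale = 0.8)
  cal <- calibrate(shrunk, c(55, 112.9, 208.4), res)
  expect_equal(cal$a1, 1.25, tolerance = 0.01)
  corrected <- apply_resolution(apply_calibration(shrunk, cal), res)
  for (p in c(55, 112.9, 208.4))
    expect_lt(abs(find_peak_centroid(corrected, p, res$b0 + res$b1 * p) - p),
              0.1)
  # single-peak calibration fixes a0 at zero
  one <- three_line_spectrum(scale = 0.9, peaks = 122, heights = 500)
  cal1 <- calibrate(one, 122, res)
  expect_equal(cal1$a0, 0)
  expect_equal(cal1$a1, 1 / 0.9, tolerance = 0.01)
  expect_error(calibrate(spectrum(numeric(2500) + 1e-12), 55, res), "55")
})

test_that("anode selections sum spectra as expected", {
  counts <- matrix(0, 256, 2500)
  counts[, 100] <- seq_len(256)
  tab <- cztcam:::.spectrum_table(counts, meta = list(activity = 1,
                                                      duration = 1))
  full <- sum_spectra(tab, "all")
  expect_equal(sum(full), sum(seq_len(256)))
  sel <- central_anode_selection(anode_array_spec(), 1L)
  expect_equal(length(sel), 196L)          # 16^2 - 14^2 = 60 edge anodes
  cen <- sum_spectra(tab, "central14")
  expect_equal(sum(cen), sum(sel))
  single <- sum_spectra(tab, 42L)
  expect_equal(as.numeric(single)[100], 42)
  expect_equal(sum(sum_spectra(tab, integer(0))), 0)
})

test_that("images integrate windows consistently", {
  model <- detector_model(const_cie(0.8, reach = 0.4), anode_array_spec(),
                          crystal_spec())
  src <- source_spec(lines = cbind(energy = 140.5, intensity = 1),
                     extent = 1,
                     class_fractions = c(geometric_primary = 1,
                                         phantom_scatter = 0, penetration = 0,
                                         collimator_scatter = 0,
                                         collimator_xray = 0, other = 0),
                     p_photo = 1, p_rayleigh = 0)
  lm <- generate_listmode(src, crystal_spec(), anode_array_spec(),
                          collimator_spec("LEHR"), 3000, seed = 4)
  tab <- accumulate_spectra(model, lm)
  win <- energy_window("tc", 100, 130)
  img <- form_image(tab, win)
  s <- sum_spectra(tab, "all")
  selbins <- energy_axis()$centers >= 100 & energy_axis()$centers < 130
  expect_equal(sum(img), sum(as.numeric(s)[selbins]))
  # a point-like source centred on the array lights the four central pixels
  expect_true(which.max(img) %in% c(8 + 7 * 16, 9 + 7 * 16, 8 + 8 * 16,
                                    9 + 8 * 16))
  expect_equal(sum(form_image(tab, energy_window("empty", 240, 249))), 0)
})

test_that("component spectra partition the total", {
  model <- detector_model(const_cie(0.8), anode_array_spec(), crystal_spec())
  lm <- generate_listmode(source_spec(), crystal_spec(), anode_array_spec(),
                          collimator_spec("MEGP"), 3000, seed = 6)
  tab <- accumulate_spectra(model, lm)
  total <- as.numeric(sum_spectra(tab, "all"))
  for (split in c("emission_energy", "transport_class")) {
    comps <- component_spectra(model, lm, split)
    stacked <- Reduce(`+`, lapply(comps, as.numeric))
    expect_equal(stacked, total, tolerance = 1e-9)
  }
  # single-line source yields exactly one emission component
  src1 <- source_spec(lines = cbind(energy = 140.5, intensity = 1))
  lm1 <- generate_listmode(src1, crystal_spec(), anode_array_spec(),
                           collimator_spec("OPEN"), 500, seed = 8)
  comps1 <- component_spectra(model, lm1, "emission_energy")
  expect_equal(length(comps1), 1L)
})

test_that("sensitivity arithmetic and curve fitting recover truth", {
  counts <- matrix(0, 256, 2500)
  counts[1, 1000] <- 1000
  tab <- cztcam:::.spectrum_table(counts, meta = list(activity = 10,
                                                      duration = 100))
  win <- energy_window("w", 99, 101)
  expect_equal(sensitivity(tab, win), 1.0)
  tab$meta$activity <- NULL
  expect_error(sensitivity(tab, win), "metadata")
  d <- c(0, 10, 25, 50, 75, 100, 130)
  s <- 2 + 5 * exp(-0.03 * d)
  fit <- fit_sensitivity_curve(d, s)
  expect_rel_equal(fit, c(2, 5, 0.03), 1e-6)
  flat <- fit_sensitivity_curve(d, rep(4.2, 7))
  expect_equal(unname(flat["c2"]), 0)
  expect_equal(unname(flat["c0"]), 4.2)
  expect_error(fit_sensitivity_curve(c(0, 10, 20), c(1, 2, 3)))
})

test_that("shorter electron lifetimes deepen the low-energy tail", {
  cr <- crystal_spec(); an <- anode_array_spec()
  src <- source_spec(lines = cbind(energy = 140.5, intensity = 1),
                     class_fractions = c(geometric_primary = 1,
                                         phantom_scatter = 0, penetration = 0,
                                         collimator_scatter = 0,
                                         collimator_xray = 0, other = 0),
                     p_photo = 1, p_rayleigh = 0)
  lm <- generate_listmode(src, cr, an, collimator_spec("MEGP"), 4000,
                          seed = 10)
  frac_below <- function(tau) {
    cie <- generate_cie_map(cr, an, field_config("A1"),
                            electron = carrier_params(1000, tau),
                            neighbourhood = 3, step = 0.41)
    model <- detector_model(cie, an, cr)
    s <- as.numeric(sum_spectra(accumulate_spectra(model, lm), "all"))
    # counts below a fixed window under the 140.5 keV photopeak
    sum(s[energy_axis()$centers < 100]) / sum(s)
  }
  expect_gt(frac_below(0.8), frac_below(5))
})

test_that("spectrum tables round-trip through the camera text format", {
  counts <- matrix(rpois(256 * 2500, 0.01), 256, 2500)
  tab <- cztcam:::.spectrum_table(counts, meta = list(activity = 12.5,
                                                      duration = 60,
                                                      distance = 48))
  path <- tempfile(fileext = ".tsv")
  write_spectrum_table(tab, path)
  back <- read_spectrum_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$meta$activity, 12.5)
  expect_equal(back$meta$distance, 48)
})
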