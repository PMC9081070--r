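test_that("the agreement score matches hand-evaluated cases", {
  ax <- energy_axis()
  win <- energy_window("w", 100, 100.2)   # exactly two bins
  ref <- numeric(ax$n); sim <- numeric(ax$n)
  sel <- which(ax$centers >= 100 & ax$centers < 100.2)
  expect_length(sel, 2L)
  sim[sel] <- c(1, 2); ref[sel] <- c(2, 2)
  p <- spectrum_pair(sim, ref, win, "fixed_unity")
  expect_equal(agreement(p)$D, 1 / 16)    # ((1-2)^2 + 0) / (2+2)^2
  # identical spectra at unit scale score zero
  expect_equal(agreement(spectrum_pair(ref, ref, win, "fixed_unity"))$D, 0)
  # a perfect rescale with free f is exact
  p2 <- spectrum_pair(2 * ref, ref, win, "free")
  a2 <- agreement(p2)
  expect_equal(a2$f, 0.5)
  expect_equal(a2$D, 0)
  # undefined with an empty reference
  expect_error(agreement(spectrum_pair(sim, numeric(ax$n), win, "free")),
               "zero reference")
})

test_that("the free scale factor never scores worse than unity", {
  ax <- energy_axis()
  win <- energy_window("w", 50, 150)
  set.seed(31)
  for (i in 1:20) {
    base <- pmax(0, sin(ax$centers / 40) + rnorm(ax$n, 0, 0.2))
    sim <- pmax(0, base * runif(1, 0.5, 2) + rnorm(ax$n, 0, 0.1))
    d_free <- agreement(spectrum_pair(sim, base, win, "free"))$D
    d_unit <- agreement(spectrum_pair(sim, base, win, "fixed_unity"))$D
    expect_lte(d_free, d_unit + 1e-12)
  }
})

test_that("total agreement is an additive, permutation-invariant sum", {
  ax <- energy_axis()
  win <- energy_window("w", 50, 150)
  set.seed(32)
  mk <- function() {
    r <- pmax(0, rnorm(ax$n, 5, 1))
    spectrum_pair(r * 1.1, r, win, "fixed_unity")
  }
  ps <- list(mk(), mk(), mk())
  expect_equal(total_agreement(list()), 0)
  expect_equal(total_agreement(ps[1]), agreement(ps[[1]])$D)
  expect_equal(total_agreement(ps),
               sum(vapply(ps, function(p) agreement(p)$D, numeric(1))))
  expect_equal(total_agreement(ps), total_agreement(rev(ps)))
})

test_that("comparison windows span the emissions and the operating range", {
  res <- resolution_model(5.64, 0.00751)
  w <- comparison_window(c(54.6, 55.8, 112.9, 208.4), 40, res)
  expect_equal(w$low, 40)     # emission minus margin falls below the cutoff
  expect_equal(w$high, min(250, 208.4 + 3 * (5.64 + 0.00751 * 208.4)),
               tolerance = 1e-9)
  w1 <- comparison_window(122, 40, res)
  expect_lt(w1$low, 122)
  expect_gt(w1$high, 122)
  expect_error(comparison_window(30, 40, res), "empty")
})

test_that("bounded Nelder-Mead minimises and respects its box", {
  fn <- function(x) sum((x - c(2, -1))^2)
  opt <- nelder_mead(fn, c(0, 0), tol = 1e-8, maxeval = 400)
  expect_equal(opt$par, c(2, -1), tolerance = 1e-3)
  optb <- nelder_mead(fn, c(0, 0), lower = c(0, 0), upper = c(1, 1),
                      tol = 1e-8, maxeval = 400)
  expect_equal(optb$par, c(1, 0), tolerance = 1e-3)
  expect_true(all(optb$trace$X1 >= 0 & optb$trace$X1 <= 1))
  expect_true(all(optb$trace$X2 >= 0 & optb$trace$X2 <= 1))
  # cross-check against the reference implementation on the smooth problem
  ref <- stats::optim(c(0, 0), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-10))
  expect_equal(opt$value, ref$value, tolerance = 1e-4)
})

test_that("the inner loop recovers known resolution parameters", {
  set.seed(41)
  initial <- three_line_spectrum(scale = 0.82,
                                 heights = c(900, 700, 600))
  truth <- resolution_model(6.8, 0.011)
  peaks <- c(55, 112.9, 208.4)
  cal_star <- calibrate(initial, peaks, truth)
  ref <- apply_resolution(apply_calibration(initial, cal_star), truth)
  win <- comparison_window(peaks, 40)
  builder <- function(b0, b1) {
    res <- resolution_model(b0, b1)
    cal <- calibrate(initial, peaks, res)
    sim <- apply_resolution(apply_calibration(initial, cal), res)
    list(spectrum_pair(sim, ref, win, "fixed_unity"))
  }
  inner <- optimize_resolution(builder, tol = 1e-4, maxeval = 200)
  expect_lt(abs(inner$b0 - truth$b0) / truth$b0, 0.05)
  expect_lt(abs(inner$b1 - truth$b1) / truth$b1, 0.05)
  # the returned objective equals the recomputed score at the optimum
  expect_equal(inner$D_tot_opt,
               total_agreement(builder(inner$b0, inner$b1)),
               tolerance = 1e-10)
  # starting at the optimum converges immediately to the same score
  at_opt <- optimize_resolution(builder,
                                init = resolution_model(truth$b0, truth$b1),
                                tol = 1e-3, maxeval = 60)
  expect_lte(at_opt$D_tot_opt, 1e-10)
})

test_that("tuning configurations enumerate the design space", {
  cfgs <- all_tuning_configurations()
  expect_length(cfgs, 8L)
  expect_setequal(vapply(cfgs, function(c) c$label, character(1)),
                  c("A1-B1-C1", "A1-B1-C2", "A1-B2-C1", "A1-B2-C2",
                    "A3-B1-C1", "A3-B1-C2", "A3-B2-C1", "A3-B2-C2"))
  c0 <- tuning_configuration("A1", "B1", "C1")
  expect_named(c0$params, c("mu_e", "tau_e"))
  c1 <- tuning_configuration("A3", "B2", "C2")
  expect_named(c1$params, c("mu_e", "tau_e", "a3_weight", "b2_power",
                            "b2_scale", "mutau_h"))
  expect_true(all(c1$lower <= c1$params & c1$params <= c1$upper))
})

test_that("outer-loop candidates stay inside the declared bounds", {
  cr <- crystal_spec(); an <- anode_array_spec()
  src <- source_spec(lines = cbind(energy = c(112.9, 208.4),
                                   intensity = c(1, 1)))
  lm <- generate_listmode(src, cr, an, collimator_spec("MEGP"), 1500,
                          seed = 21)
  config <- tuning_configuration("A1", "B1", "C1",
                                 init = c(mu_e = 1000, tau_e = 2),
                                 lower = c(mu_e = 800, tau_e = 1),
                                 upper = c(mu_e = 1300, tau_e = 4))
  win <- comparison_window(c(112.9, 208.4), 40)
  peaks <- c(112.9, 208.4)
  setup0 <- tuning_setup(cr, an, list(lm), refs = list(spectrum(rep(1, 2500))),
                         windows = list(win), f_modes = "fixed_unity",
                         peaks = peaks, step = 0.41)
  initial <- cztcam:::.initial_spectra(setup0, config, config$params)
  res_star <- resolution_model(6, 0.009)
  cal_star <- calibrate(initial[[1]], peaks, res_star)
  refs <- list(apply_resolution(apply_calibration(initial[[1]], cal_star),
                                res_star))
  setup <- tuning_setup(cr, an, list(lm), refs = refs, windows = list(win),
                        f_modes = "fixed_unity", peaks = peaks, step = 0.41,
                        recalibrate_refs = FALSE)
  out <- optimize_cie(setup, config, outer_maxeval = 6, inner_maxeval = 20)
  expect_s3_class(out, "tuning_result")
  expect_true(is.finite(out$D_tot_opt))
  expect_true(all(out$trace$X1 >= 800 & out$trace$X1 <= 1300))
  expect_true(all(out$trace$X2 >= 1 & out$trace$X2 <= 4))
  expect_true(all(out$params >= config$lower & out$params <= config$upper))
})

test_that("run_tuning ranks configurations by optimised agreement", {
  cr <- crystal_spec(); an <- anode_array_spec()
  src <- source_spec(lines = cbind(energy = c(112.9, 208.4),
                                   intensity = c(1, 1)))
  lm <- generate_listmode(src, cr, an, collimator_spec("MEGP"), 800,
                          seed = 22)
  peaks <- c(112.9, 208.4)
  win <- comparison_window(peaks, 40)
  cfg_gen <- tuning_configuration("A1", "B1", "C1")
  setup0 <- tuning_setup(cr, an, list(lm), refs = list(spectrum(rep(1, 2500))),
                         windows = list(win), f_modes = "fixed_unity",
                         peaks = peaks, step = 0.41)
  initial <- cztcam:::.initial_spectra(setup0, cfg_gen, cfg_gen$params)
  res_star <- resolution_model(6, 0.009)
  cal_star <- calibrate(initial[[1]], peaks, res_star)
  refs <- list(apply_resolution(apply_calibration(initial[[1]], cal_star),
                                res_star))
  setup <- tuning_setup(cr, an, list(lm), refs = refs, windows = list(win),
                        f_modes = "fixed_unity", peaks = peaks, step = 0.41,
                        recalibrate_refs = FALSE)
  configs <- list(tuning_configuration("A1", "B1", "C1"),
                  tuning_configuration("A1", "B2", "C1"))
  ranked <- run_tuning(setup, configs, outer_maxeval = 3, inner_maxeval = 10)
  scores <- vapply(ranked, function(r) r$D_tot_opt, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_identical(attr(ranked, "winner"), ranked[[1]]$config$label)
  # a single configuration wins by construction
  one <- run_tuning(setup, configs[1], outer_maxeval = 2, inner_maxeval = 8)
  expect_identical(attr(one, "winner"), "A1-B1-C1")
})
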