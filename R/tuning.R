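#' Simulated/reference spectrum pair
#'
#' One pair entering the agreement score: a simulated and a reference
#' spectrum on the common axis, the comparison window, and the scale-factor
#' mode. For collimated acquisitions the scale factor is fixed at unity; for
#' open-field acquisitions it is a free parameter, chosen as the
#' least-squares optimum inside the agreement functional.
#'
#' @param sim,ref `spectrum` objects (or plain 2500-vectors).
#' @param window An [energy_window()].
#' @param f_mode `"fixed_unity"` or `"free"`.
#' @return Object of class `spectrum_pair`.
#' @export
spectrum_pair <- function(sim, ref, window,
                          f_mode = c("fixed_unity", "free")) {
  f_mode <- match.arg(f_mode)
  stopifnot(length(sim) == 2500L, length(ref) == 2500L,
            inherits(window, "energy_window"))
  structure(list(sim = as.numeric(sim), ref = as.numeric(ref),
                 window = window, f_mode = f_mode),
            class = "spectrum_pair")
}

#' Spectrum agreement score
#'
#' \deqn{D_j = \frac{\sum_{E \in W_j} (f_j S_{sim}(E) - S_{ref}(E))^2}
#'   {\left(\sum_{E \in W_j} S_{ref}(E)\right)^2}.}
#' With `f_mode = "free"`, \eqn{f_j = \sum S_{sim}S_{ref} / \sum S_{sim}^2}
#' over the window (the least-squares optimum) is applied first; with
#' `"fixed_unity"`, \eqn{f_j = 1}.
#'
#' @param pair A [spectrum_pair()].
#' @return List with `D` and the applied `f`.
#' @export
agreement <- function(pair) {
  ax <- energy_axis()
  sel <- ax$centers >= pair$window$low & ax$centers < pair$window$high
  if (!any(sel)) stop("comparison window outside the energy axis")
  s <- pair$sim[sel]; r <- pair$ref[sel]
  denom <- sum(r)^2
  if (denom <= 0) stop("zero reference total in the comparison window")
  f <- 1
  if (pair$f_mode == "free") {
    ss <- sum(s^2)
    f <- if (ss > 0) sum(s * r) / ss else 1
  }
  list(D = sum((f * s - r)^2) / denom, f = f)
}

#' Total agreement over spectrum pairs
#'
#' \eqn{D_{tot} = \sum_j D_j}.
#'
#' @param pairs List of [spectrum_pair()]s.
#' @return Numeric total (0 for an empty list).
#' @export
total_agreement <- function(pairs) {
  if (!length(pairs)) return(0)
  sum(vapply(pairs, function(p) agreement(p)$D, numeric(1)))
}

#' Comparison window for a radionuclide
#'
#' Covers the emission range and the detector's operating range:
#' `[max(threshold, E_min - 3 FWHM(E_min)), min(250, E_max + 3 FWHM(E_max))]`
#' with the FWHM from the supplied resolution model.
#'
#' @param lines Emission energies (keV).
#' @param threshold Detector low-energy cutoff (keV).
#' @param res A [resolution_model()].
#' @return An [energy_window()].
#' @export
comparison_window <- function(lines, threshold = 40,
                              res = resolution_model()) {
  stopifnot(length(lines) >= 1)
  fw <- function(E) res$b0 + res$b1 * E
  if (max(lines) < threshold)
    stop("empty comparison window: all emissions fall below the detector threshold")
  lo <- max(threshold, min(lines) - 3 * fw(min(lines)))
  hi <- min(250, max(lines) + 3 * fw(max(lines)))
  if (lo >= hi) stop("empty comparison window")
  energy_window(sprintf("%.0f-%.0f keV", lo, hi), lo, hi)
}

#' Optimise the energy-resolution parameters (inner loop)
#'
#' Downhill-simplex minimisation of the total agreement as a function of
#' `(b0, b1)`, starting from the stated initial estimates. `pairs_builder`
#' must rebuild the spectrum pairs (re-determining the calibration and
#' re-applying calibration and resolution to the fixed initial spectra) for
#' each candidate.
#'
#' @param pairs_builder Function `(b0, b1) -> list of spectrum_pair`.
#' @param init A [resolution_model()] start (defaults to b0 = 5.64 keV,
#'   b1 = 0.00751).
#' @param tol,maxeval Simplex convergence controls (relative diameter and
#'   evaluation budget, per start).
#' @param n_starts Number of deterministic starts: the stated initial
#'   estimates, then multiplicative spreads (x1.2, x3) and (x0.7, x0.3) of
#'   them. The constant and slope terms trade off against each other over
#'   the count-dominant part of the spectrum, and a single simplex can
#'   collapse onto the `b1 = 0` boundary of that ridge.
#' @return List `b0`, `b1`, `D_tot_opt`, `trace`.
#' @export
optimize_resolution <- function(pairs_builder, init = resolution_model(),
                                tol = 1e-3, maxeval = 200, n_starts = 1) {
  # optimise in (b0, b1 * 250 keV): both coordinates then carry comparable
  # magnitudes (the slope term's contribution across the axis), which keeps
  # the simplex well conditioned
  sc <- 250
  fn <- function(p) {
    if (p[1] < 0 || p[2] < 0) return(Inf)
    tryCatch(total_agreement(pairs_builder(p[1], p[2] / sc)),
             error = function(e) Inf)
  }
  z0 <- c(init$b0, init$b1 * sc)
  starts <- list(z0, z0 * c(1.2, 3), z0 * c(0.7, 0.3))[seq_len(max(1, n_starts))]
  runs <- lapply(starts, function(z)
    nelder_mead(fn, z, lower = c(0, 0), tol = tol, maxeval = maxeval))
  opt <- runs[[which.min(vapply(runs, function(r) r$value, numeric(1)))]]
  opt$trace <- do.call(rbind, lapply(runs, function(r) r$trace))
  if (!is.finite(opt$value))
    stop("all resolution-parameter evaluations failed")
  list(b0 = opt$par[1], b1 = opt$par[2] / sc, D_tot_opt = opt$value,
       trace = opt$trace)
}

#' CIE tuning configuration
#'
#' One of the eight combinations of electric-potential alternative (A1, A3),
#' weighting-potential alternative (B1, B2) and signal-generation mode
#' (C1 electrons only, C2 electrons and holes), together with the
#' configuration's tunable CIE parameters and their bounds. Effective
#' parameter counts: A3 adds `a3_weight`; B2 adds `b2_power` and `b2_scale`;
#' C1 carries `mu_e` (cm^2/Vs) and `tau_e` (us); C2 adds the hole
#' mobility-lifetime product `mutau_h` (cm^2/V) with the hole mobility fixed
#' at 80 cm^2/Vs.
#'
#' @param electric `"A1"` or `"A3"`.
#' @param weighting `"B1"` or `"B2"`.
#' @param signal `"C1"` or `"C2"`.
#' @param init Named numeric vector overriding default initial parameter
#'   values.
#' @param lower,upper Named numeric vectors overriding default bounds.
#' @return Object of class `tuning_configuration` with `params` (named
#'   inits), `lower`, `upper`.
#' @export
tuning_configuration <- function(electric = c("A1", "A3"),
                                 weighting = c("B1", "B2"),
                                 signal = c("C1", "C2"),
                                 init = NULL, lower = NULL, upper = NULL) {
  electric <- match.arg(electric)
  weighting <- match.arg(weighting)
  signal <- match.arg(signal)
  p <- c(mu_e = 1000, tau_e = 3)
  lo <- c(mu_e = 300, tau_e = 0.3)
  hi <- c(mu_e = 3000, tau_e = 30)
  if (electric == "A3") {
    p <- c(p, a3_weight = 0.5); lo <- c(lo, a3_weight = 0)
    hi <- c(hi, a3_weight = 1)
  }
  if (weighting == "B2") {
    p <- c(p, b2_power = 2, b2_scale = 1)
    lo <- c(lo, b2_power = 0.5, b2_scale = 0.3)
    hi <- c(hi, b2_power = 8, b2_scale = 1)
  }
  if (signal == "C2") {
    p <- c(p, mutau_h = 5e-5); lo <- c(lo, mutau_h = 1e-6)
    hi <- c(hi, mutau_h = 1e-3)
  }
  ov <- function(x, o) { if (!is.null(o)) x[names(o)] <- o; x }
  structure(list(electric = electric, weighting = weighting, signal = signal,
                 params = ov(p, init), lower = ov(lo, lower),
                 upper = ov(hi, upper),
                 label = paste(electric, weighting, signal, sep = "-")),
            class = "tuning_configuration")
}

#' All eight tuning configurations
#'
#' The cross product \{A1, A3\} x \{B1, B2\} x \{C1, C2\} (the pure Laplace
#' electric alternative is only used inside A3, not on its own).
#' @return List of [tuning_configuration()]s.
#' @export
all_tuning_configurations <- function() {
  out <- list()
  for (a in c("A1", "A3")) for (b in c("B1", "B2")) for (s in c("C1", "C2"))
    out[[paste(a, b, s, sep = "-")]] <- tuning_configuration(a, b, s)
  out
}

# carriers + field config from a configuration's parameter vector
.config_realise <- function(config, params) {
  cfg <- field_config(
    electric_alternative = if (config$electric == "A3") "A3" else "A1",
    a3_weight = if (config$electric == "A3") unname(params["a3_weight"]) else 0.5,
    weighting_alternative = config$weighting,
    b2_power = if (config$weighting == "B2") unname(params["b2_power"]) else 2,
    b2_scale = if (config$weighting == "B2") unname(params["b2_scale"]) else 1)
  electron <- carrier_params(unname(params["mu_e"]), unname(params["tau_e"]))
  hole <- NULL
  if (config$signal == "C2") {
    mu_h <- 80  # hole mobility fixed at a literature-style default, cm^2/Vs
    tau_h_us <- unname(params["mutau_h"]) / mu_h * 1e6  # (cm^2/V)/(cm^2/Vs) -> s -> us
    hole <- carrier_params(mu_h, tau_h_us, "hole")
  }
  list(field = cfg, electron = electron, hole = hole)
}

#' Tuning problem setup
#'
#' Bundles everything the nested optimisation needs: geometry, grid
#' resolution, the listmode set and reference spectrum per pair, windows and
#' scale-factor modes, the calibration peaks and the designated calibration
#' pair.
#'
#' @param crystal,anodes Geometry specs.
#' @param listmodes List of `listmode` objects, one per
#'   radionuclide-collimator pair.
#' @param refs List of reference `spectrum` objects (summed central block),
#'   same length/order.
#' @param windows List of [energy_window()]s per pair.
#' @param f_modes Character vector (`"fixed_unity"`/`"free"`) per pair.
#' @param peaks Photopeak energies (keV) used for the energy calibration.
#' @param calibration_pair Index of the pair whose simulation determines the
#'   (shared) energy calibration.
#' @param threshold Detector low-energy cutoff (keV).
#' @param neighbourhood,step,reduce CIE grid controls, see
#'   [generate_cie_map()].
#' @param selection Anode selection summed for comparison (default the
#'   central 14 x 14 block).
#' @param recalibrate_refs Re-calibrate the reference spectra once so their
#'   photopeaks sit at the true energies before comparison.
#' @return Object of class `tuning_setup`.
#' @export
tuning_setup <- function(crystal, anodes, listmodes, refs, windows, f_modes,
                         peaks, calibration_pair = 1L, threshold = 40,
                         neighbourhood = 5, step = 0.41, reduce = TRUE,
                         selection = "central14", recalibrate_refs = TRUE) {
  stopifnot(length(listmodes) == length(refs),
            length(refs) == length(windows),
            length(windows) == length(f_modes))
  structure(list(crystal = crystal, anodes = anodes, listmodes = listmodes,
                 refs = refs, windows = windows, f_modes = f_modes,
                 peaks = peaks, calibration_pair = calibration_pair,
                 threshold = threshold, neighbourhood = neighbourhood,
                 step = step, reduce = reduce, selection = selection,
                 recalibrate_refs = recalibrate_refs),
            class = "tuning_setup")
}

# initial summed spectra for a CIE parameter candidate, scaled to each
# reference's activity x duration
.initial_spectra <- function(setup, config, params) {
  rc <- .config_realise(config, params)
  cie <- generate_cie_map(setup$crystal, setup$anodes, rc$field,
                          electron = rc$electron, hole = rc$hole,
                          mode = config$signal,
                          neighbourhood = setup$neighbourhood,
                          step = setup$step, reduce = setup$reduce)
  model <- detector_model(cie, setup$anodes, setup$crystal,
                          threshold = setup$threshold)
  lapply(seq_along(setup$listmodes), function(j) {
    tab <- accumulate_spectra(model, setup$listmodes[[j]])
    s <- sum_spectra(tab, setup$selection, setup$anodes)
    ref_meta <- attr(setup$refs[[j]], "meta")
    sm <- attr(s, "meta")
    if (!is.null(ref_meta$activity) && !is.null(sm$activity)) {
      sc <- (ref_meta$activity * ref_meta$duration) /
        (sm$activity * sm$duration)
      s <- spectrum(as.numeric(s) * sc, meta = sm)
    }
    s
  })
}

# reference spectra with their own photopeak alignment applied
.prepared_refs <- function(setup, res) {
  if (!setup$recalibrate_refs) return(setup$refs)
  lapply(setup$refs, function(r) {
    cal <- tryCatch(calibrate(r, setup$peaks, resolution_model(0, 0)),
                    error = function(e) energy_calibration(0, 1))
    apply_calibration(r, cal)
  })
}

# build spectrum pairs for candidate resolution parameters, given fixed
# initial spectra: shared calibration from the designated pair, then
# calibration + resolution on every simulated spectrum
.pairs_builder <- function(setup, initial, refs_prepared) {
  # one cold-start calibration per CIE candidate anchors the peak
  # identification; per-resolution candidates then refine from it
  cal0 <- tryCatch(calibrate(initial[[setup$calibration_pair]], setup$peaks,
                             resolution_model()),
                   error = function(e) NULL)
  function(b0, b1) {
    res <- resolution_model(b0, b1)
    # one least-squares refinement of the anchor per candidate: the
    # calibration tracks the candidate resolution smoothly
    cal <- calibrate(initial[[setup$calibration_pair]], setup$peaks, res,
                     init = cal0, max_iter = 1L)
    lapply(seq_along(initial), function(j) {
      sim <- apply_resolution(apply_calibration(initial[[j]], cal), res)
      spectrum_pair(sim, refs_prepared[[j]], setup$windows[[j]],
                    setup$f_modes[[j]])
    })
  }
}

#' Optimise the CIE parameters of one configuration (outer loop)
#'
#' For each outer simplex candidate: regenerate the CIE map, rebuild the
#' initial spectra, and run the inner resolution optimisation (which
#' re-determines the shared energy calibration per candidate); the inner
#' optimum `D_tot_opt` is the outer objective. Candidates are clamped into
#' the declared bounds; a CIE generation failure scores `+Inf` and the
#' optimisation continues. Every evaluated candidate is logged.
#'
#' @param setup A [tuning_setup()].
#' @param config A [tuning_configuration()].
#' @param outer_maxeval,outer_tol Outer simplex budget (per start) and
#'   tolerance.
#' @param inner_maxeval,inner_tol Inner simplex budget and tolerance.
#' @param n_starts Number of deterministic simplex starts: the first at the
#'   configuration's initial parameters, the others shifted by -0.25 and
#'   +0.25 in the normalised parameter space. The outer surface can hold
#'   shallow secondary basins (long-lifetime CIE maps are nearly flat and
#'   score similarly after re-calibration), which a single simplex rarely
#'   escapes.
#' @return Object of class `tuning_result`: `config`, `params` (optimal CIE
#'   parameters), `b0`, `b1`, `calibration`, `D_tot_opt`, `trace`.
#' @export
optimize_cie <- function(setup, config, outer_maxeval = 40, outer_tol = 1e-3,
                         inner_maxeval = 60, inner_tol = 1e-3,
                         n_starts = 3) {
  refs_prepared <- .prepared_refs(setup, resolution_model())
  inner_of <- function(params) {
    initial <- .initial_spectra(setup, config, params)
    optimize_resolution(.pairs_builder(setup, initial, refs_prepared),
                        tol = inner_tol, maxeval = inner_maxeval)
  }
  # The outer parameters span orders of magnitude (mobilities ~1e3,
  # lifetimes ~1, hole mu-tau ~1e-5), so the simplex works in a
  # bounds-normalised space: logarithmic for strictly positive ranges,
  # linear otherwise. Initial steps of 0.2 in that space explore factors
  # of ~2 per parameter.
  lo <- config$lower; hi <- config$upper
  uselog <- lo > 0
  to_z <- function(p) ifelse(uselog, log(p / lo) / log(hi / lo),
                             (p - lo) / (hi - lo))
  from_z <- function(z) ifelse(uselog, lo * (hi / lo)^z, lo + z * (hi - lo))
  fn <- function(z) {
    p <- from_z(z)
    names(p) <- names(config$params)
    tryCatch(inner_of(p)$D_tot_opt, error = function(e) Inf)
  }
  z0 <- to_z(config$params)
  shifts <- c(0, -0.25, 0.25, -0.5, 0.5)[seq_len(max(1, n_starts))]
  runs <- lapply(shifts, function(sh)
    nelder_mead(fn, pmin(pmax(z0 + sh, 0.02), 0.98), lower = 0, upper = 1,
                step = 0.2, tol = outer_tol, maxeval = outer_maxeval))
  opt <- runs[[which.min(vapply(runs, function(r) r$value, numeric(1)))]]
  opt$trace <- do.call(rbind, lapply(runs, function(r) r$trace))
  best <- from_z(opt$par)
  names(best) <- names(config$params)
  opt$trace[seq_along(best)] <- as.data.frame(
    t(apply(as.matrix(opt$trace[seq_along(best)]), 1L, from_z)))
  inner <- tryCatch(inner_of(best), error = function(e) NULL)
  if (is.null(inner))
    return(structure(list(config = config, params = best, b0 = NA, b1 = NA,
                          calibration = NULL, D_tot_opt = Inf,
                          trace = opt$trace, error = "CIE generation failed"),
                     class = "tuning_result"))
  initial <- .initial_spectra(setup, config, best)
  cal <- calibrate(initial[[setup$calibration_pair]], setup$peaks,
                   resolution_model(inner$b0, inner$b1))
  structure(list(config = config, params = best, b0 = inner$b0,
                 b1 = inner$b1, calibration = cal,
                 D_tot_opt = inner$D_tot_opt, trace = opt$trace,
                 error = NULL),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s: D_tot_opt = %.4g\n", x$config$label,
              x$D_tot_opt))
  cat("  CIE params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                             collapse = ", "), "\n")
  if (!is.null(x$calibration))
    cat(sprintf("  resolution b0=%.4g keV b1=%.4g; calibration a0=%.4g a1=%.4g\n",
                x$b0, x$b1, x$calibration$a0, x$calibration$a1))
  if (!is.null(x$error)) cat("  error:", x$error, "\n")
  invisible(x)
}

#' Run the tuning over a set of configurations
#'
#' Executes [optimize_cie()] per configuration and ranks the results by
#' `D_tot_opt` (ascending); failed configurations rank last with their
#' error recorded.
#'
#' @param setup A [tuning_setup()].
#' @param configs List of [tuning_configuration()]s (default all eight).
#' @param ... Budgets passed to [optimize_cie()].
#' @return List of `tuning_result`s, best first, with attribute `winner`.
#' @export
run_tuning <- function(setup, configs = all_tuning_configurations(), ...) {
  results <- lapply(configs, function(cf)
    tryCatch(optimize_cie(setup, cf, ...),
             error = function(e)
               structure(list(config = cf, params = cf$params, b0 = NA,
                              b1 = NA, calibration = NULL, D_tot_opt = Inf,
                              trace = NULL,
                              error = conditionMessage(e)),
                         class = "tuning_result")))
  ord <- order(vapply(results, function(r) r$D_tot_opt, numeric(1)))
  out <- results[ord]
  attr(out, "winner") <- out[[1]]$config$label
  out
}
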