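#' Energy axis of the camera spectra
#'
#' 2500 equally spaced bins from 0 to 250 keV, 0.1 keV wide.
#' @return List with `n`, `width` (keV), `edges` (length 2501), `centers`.
#' @export
energy_axis <- function() {
  n <- 2500L; w <- 0.1
  list(n = n, width = w, edges = seq(0, 250, by = w),
       centers = seq(w / 2, 250 - w / 2, by = w))
}

#' Energy window
#'
#' @param label Window label.
#' @param low,high Window bounds (keV), `low < high`. Counts are integrated
#'   over bins whose centres fall in `[low, high)`.
#' @return Object of class `energy_window`.
#' @export
energy_window <- function(label, low, high) {
  stopifnot(low < high)
  structure(list(label = label, low = low, high = high),
            class = "energy_window")
}

#' Standard Lu-177 energy windows
#'
#' The 55 keV (49.7-59.7), 113 keV (100.5-120.8) and 208 keV (193.8-216.7)
#' windows.
#' @return Named list of [energy_window()]s.
#' @export
lu177_windows <- function() {
  list(`55keV` = energy_window("55keV", 49.7, 59.7),
       `113keV` = energy_window("113keV", 100.5, 120.8),
       `208keV` = energy_window("208keV", 193.8, 216.7))
}

#' Linear energy calibration
#'
#' \eqn{E_{corr} = a_0 + a_1 E_{init}}.
#' @param a0 Offset (keV).
#' @param a1 Gain (> 0, dimensionless).
#' @return Object of class `energy_calibration`.
#' @export
energy_calibration <- function(a0 = 0, a1 = 1) {
  stopifnot(a1 > 0)
  structure(list(a0 = a0, a1 = a1), class = "energy_calibration")
}

#' Energy-resolution model
#'
#' Gaussian smoothing with energy-dependent width
#' \eqn{FWHM(E) = b_0 + b_1 E}; must stay positive over the operating range.
#' The default values are the initial estimates used for model tuning.
#'
#' @param b0 Constant term (keV).
#' @param b1 Slope (dimensionless).
#' @return Object of class `resolution_model`.
#' @export
resolution_model <- function(b0 = 5.64, b1 = 0.00751) {
  structure(list(b0 = b0, b1 = b1), class = "resolution_model")
}

#' Detector model
#'
#' A 16 x 16 (by default) array of identical anode elements, each carrying a
#' translated copy of one joint CIE map (the map computed for a central
#' anode), a fixed energy axis and a low-energy threshold below which a
#' history records no count.
#'
#' @param cie A `cie_map` (joint map, lateral origin at the joint pad
#'   centre).
#' @param anodes An [anode_array_spec()].
#' @param crystal A [crystal_spec()].
#' @param threshold Low-energy cutoff (keV) applied to the winning anode's
#'   summed response.
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(cie, anodes = anode_array_spec(),
                           crystal = crystal_spec(), threshold = 40) {
  stopifnot(inherits(cie, "cie_map"))
  centers <- anode_centers(anodes)
  # lateral reach of the joint map, in whole anode cells
  reach <- floor((max(cie$x) + anodes$pitch / 2 - 1e-9) / anodes$pitch)
  structure(list(cie = cie, anodes = anodes, crystal = crystal,
                 centers = centers, threshold = threshold,
                 reach = as.integer(max(reach, 0L)), axis = energy_axis()),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> %d x %d anodes, pitch %.3g mm, threshold %g keV\n",
              x$anodes$n_x, x$anodes$n_y, x$anodes$pitch, x$threshold))
  print(x$cie)
  invisible(x)
}

#' Evaluate the CIE of an anode at arbitrary points
#'
#' Translates points into the joint map's frame
#' (\eqn{\eta_k(\mathbf r) = \eta_{joint}(\mathbf r - (\mathbf r_k -
#' \mathbf r_{joint}))}) and tri-linearly interpolates; points beyond the
#' joint map's lateral extent return 0 (an anode more than the neighbourhood
#' half-width away is insensitive).
#'
#' @param model A [detector_model()].
#' @param anode_k Anode index (1-based, column-major over the array).
#' @param points Length-3 vector or n x 3 matrix (mm, crystal frame, z from
#'   the cathode).
#' @return CIE value(s).
#' @export
eval_cie <- function(model, anode_k, points) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else points
  rk <- model$centers[anode_k, ]
  loc <- cbind(pts[, 1] - (rk[1] - model$cie$r_joint[1]),
               pts[, 2] - (rk[2] - model$cie$r_joint[2]), pts[, 3])
  .trilinear(model$cie$x, model$cie$y, model$cie$z, model$cie$values, loc, 0)
}

#' Per-anode energy response of one photon history
#'
#' \eqn{E_{out,k} = \sum_{i \in H} \eta_k(\mathbf r_i) E_i} over the
#' history's interaction events, for every anode element.
#'
#' @param model A [detector_model()].
#' @param history Data frame of events with columns `x`, `y`, `z`, `energy`
#'   (one history's rows of a `listmode` event table).
#' @return Numeric vector, one summed response (keV) per anode.
#' @export
respond_history <- function(model, history) {
  n_an <- nrow(model$centers)
  out <- numeric(n_an)
  if (!nrow(history)) return(out)
  pts <- cbind(history$x, history$y, history$z)
  for (k in seq_len(n_an))
    out[k] <- sum(eval_cie(model, k, pts) * history$energy)
  out
}

#' Select the winning anode
#'
#' The anode with the largest summed response wins the history; exact ties
#' go to the lowest anode index. A winner below the threshold yields no
#' count.
#'
#' @param e_out Per-anode response vector (keV).
#' @param threshold Low-energy cutoff (keV).
#' @return List `(anode, energy)` or `NULL` when undetected.
#' @export
select_winner <- function(e_out, threshold = 40) {
  k <- which.max(e_out)   # which.max returns the first (lowest) maximiser
  if (!length(k) || e_out[k] < threshold) return(NULL)
  list(anode = k, energy = e_out[k])
}

# Vectorised winner selection for a whole listmode: returns one row per
# detected history (anode, energy, weight, line, class).
.detect_events <- function(model, lm) {
  ev <- lm$events
  h <- classify_history(lm)
  empty <- data.table::data.table(history_id = integer(0), anode = integer(0),
                                  energy = numeric(0), weight = numeric(0),
                                  line = numeric(0), class = character(0))
  if (!nrow(ev)) return(empty)
  an <- model$anodes
  nx <- an$n_x; ny <- an$n_y
  # nearest anode cell of each event
  ix <- pmin(pmax(round(ev$x / an$pitch + (nx + 1) / 2), 1L), nx)
  iy <- pmin(pmax(round(ev$y / an$pitch + (ny + 1) / 2), 1L), ny)
  reach <- model$reach
  cie <- model$cie
  parts <- vector("list", (2L * reach + 1L)^2)
  pi_ <- 0L
  for (dx in -reach:reach) for (dy in -reach:reach) {
    kx <- ix + dx; ky <- iy + dy
    ok <- kx >= 1L & kx <= nx & ky >= 1L & ky <= ny
    if (!any(ok)) next
    kk <- kx[ok] + (ky[ok] - 1L) * nx
    ctr <- model$centers[kk, , drop = FALSE]
    loc <- cbind(ev$x[ok] - (ctr[, 1] - cie$r_joint[1]),
                 ev$y[ok] - (ctr[, 2] - cie$r_joint[2]), ev$z[ok])
    eta <- .trilinear(cie$x, cie$y, cie$z, cie$values, loc, 0)
    contrib <- eta * ev$energy[ok]
    nz <- contrib != 0
    if (!any(nz)) next
    pi_ <- pi_ + 1L
    parts[[pi_]] <- data.table::data.table(
      history_id = ev$history_id[ok][nz], anode = kk[nz], e = contrib[nz])
  }
  if (pi_ == 0L) return(empty)
  dt <- data.table::rbindlist(parts[seq_len(pi_)])
  e <- anode <- history_id <- NULL  # NSE notes
  dt <- dt[, list(e = sum(e)), by = c("history_id", "anode")]
  data.table::setorderv(dt, c("history_id", "e", "anode"),
                        order = c(1L, -1L, 1L))
  win <- dt[!duplicated(dt$history_id)]
  win <- win[win$e >= model$threshold]
  hi <- match(win$history_id, h$history_id)
  wt <- ev$weight[match(win$history_id, ev$history_id)]
  data.table::data.table(history_id = win$history_id, anode = win$anode,
                         energy = win$e, weight = wt,
                         line = h$line[hi], class = h$class[hi])
}

.spectrum_table <- function(counts, meta = list()) {
  structure(list(counts = counts, axis = energy_axis(), meta = meta),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d anodes x %d bins, %.6g counts total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Spectrum vector constructor
#'
#' A single energy spectrum on the camera axis (2500 bins of 0.1 keV).
#' @param counts Numeric vector of length 2500.
#' @param meta Acquisition metadata list (`activity`, `duration`,
#'   `distance`).
#' @return Object of class `spectrum` (numeric vector with attributes).
#' @export
spectrum <- function(counts, meta = list()) {
  ax <- energy_axis()
  stopifnot(length(counts) == ax$n, all(counts >= -1e-9))
  structure(as.numeric(counts), meta = meta, class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %.6g counts, peak bin at %.1f keV\n", sum(x),
              energy_axis()$centers[which.max(x)]))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(energy_axis()$centers, as.numeric(x), type = "l",
                 xlab = "energy (keV)", ylab = "counts", ...)
  invisible(x)
}

.bin_of <- function(E) {
  ax <- energy_axis()
  pmin(pmax(floor(E / ax$width) + 1L, 1L), ax$n)
}

#' Accumulate initial (uncalibrated) per-anode spectra
#'
#' Runs winner selection over all histories and records one count per
#' detected history (scaled by the photon weight) in the winning anode's
#' spectrum at the summed response energy.
#'
#' @param model A [detector_model()].
#' @param lm A `listmode`.
#' @return A `spectrum_table` (anodes x 2500 weighted counts) carrying the
#'   listmode acquisition metadata.
#' @export
accumulate_spectra <- function(model, lm) {
  det <- .detect_events(model, lm)
  n_an <- nrow(model$centers)
  counts <- matrix(0, n_an, model$axis$n)
  if (nrow(det)) {
    bin <- .bin_of(det$energy)
    idx <- cbind(det$anode, bin)
    agg <- stats::aggregate(det$weight,
                            by = list(a = det$anode, b = bin), FUN = sum)
    counts[cbind(agg$a, agg$b)] <- agg$x
  }
  .spectrum_table(counts, meta = list(activity = lm$header$activity,
                                      duration = lm$header$duration,
                                      distance = lm$header$distance))
}

#' Sum spectra over a selection of anodes
#'
#' @param table A `spectrum_table`.
#' @param selection `"all"`, `"central14"` (the central 14 x 14 block,
#'   excluding the 60 edge anodes of a 16 x 16 array) or an integer index
#'   vector. An empty selection yields a zero spectrum.
#' @param anodes Anode layout for the named selections.
#' @return A `spectrum`.
#' @export
sum_spectra <- function(table, selection = "all",
                        anodes = anode_array_spec()) {
  idx <- if (is.character(selection)) {
    switch(selection,
           all = seq_len(nrow(table$counts)),
           central14 = central_anode_selection(anodes, margin = 1L),
           stop("unknown selection"))
  } else as.integer(selection)
  cnt <- if (length(idx)) colSums(table$counts[idx, , drop = FALSE])
         else numeric(ncol(table$counts))
  spectrum(cnt, meta = table$meta)
}

#' Central anode block selection
#'
#' Indices of the anodes at least `margin` rows/columns away from the array
#' edge (margin 1 on a 16 x 16 array keeps the central 14 x 14).
#'
#' @param anodes An [anode_array_spec()].
#' @param margin Number of edge rows/columns to exclude.
#' @return Integer vector of anode indices (column-major).
#' @export
central_anode_selection <- function(anodes, margin = 1L) {
  ix <- (margin + 1L):(anodes$n_x - margin)
  iy <- (margin + 1L):(anodes$n_y - margin)
  as.integer(outer(ix, (iy - 1L) * anodes$n_x, `+`))
}

#' Apply the linear energy calibration to a spectrum
#'
#' Re-samples counts onto the fixed 0.1 keV axis under
#' \eqn{E_{corr} = a_0 + a_1 E_{init}} by fractional redistribution of each
#' source bin over the destination bins it overlaps; counts are conserved
#' for any calibration whose image stays inside the axis.
#'
#' @param x A `spectrum` or `spectrum_table`.
#' @param cal An [energy_calibration()].
#' @return Object of the same class as `x`.
#' @export
apply_calibration <- function(x, cal) UseMethod("apply_calibration")

#' @export
apply_calibration.spectrum <- function(x, cal) {
  spectrum(.recalib_vec(as.numeric(x), cal), meta = attr(x, "meta"))
}

#' @export
apply_calibration.spectrum_table <- function(x, cal) {
  out <- t(apply(x$counts, 1L, .recalib_vec, cal = cal))
  .spectrum_table(out, x$meta)
}

.recalib_vec <- function(cnt, cal) {
  if (cal$a0 == 0 && cal$a1 == 1) return(cnt)
  ax <- energy_axis()
  nz <- which(cnt != 0)
  out <- numeric(ax$n)
  if (!length(nz)) return(out)
  l <- cal$a0 + cal$a1 * ax$edges[nz]
  r <- cal$a0 + cal$a1 * ax$edges[nz + 1L]
  w <- r - l
  k0 <- floor(l / ax$width)
  span <- max(ceiling(max(r - l) / ax$width) + 1L, 1L)
  for (s in 0:span) {
    dl <- pmax(l, (k0 + s) * ax$width)
    dr <- pmin(r, (k0 + s + 1L) * ax$width)
    ov <- pmax(dr - dl, 0) / w
    dest <- k0 + s + 1L
    ok <- ov > 0 & dest >= 1L & dest <= ax$n
    if (any(ok))
      out[dest[ok]] <- out[dest[ok]] + cnt[nz[ok]] * ov[ok]
  }
  out
}

#' Apply the Gaussian energy-resolution smoothing
#'
#' Spreads each source bin's counts with a Gaussian of
#' \eqn{\sigma(E) = FWHM(E)/2.3548}, \eqn{FWHM(E) = b_0 + b_1 E}, centred on
#' the bin centre, renormalised within the 0-250 keV axis so edge truncation
#' conserves counts. `b0 = b1 = 0` is the identity.
#'
#' @param x A `spectrum` or `spectrum_table`.
#' @param res A [resolution_model()].
#' @return Object of the same class as `x`.
#' @export
apply_resolution <- function(x, res) UseMethod("apply_resolution")

#' @export
apply_resolution.spectrum <- function(x, res) {
  spectrum(.smooth_vec(as.numeric(x), res), meta = attr(x, "meta"))
}

#' @export
apply_resolution.spectrum_table <- function(x, res) {
  out <- t(apply(x$counts, 1L, .smooth_vec, res = res))
  .spectrum_table(out, x$meta)
}

.smooth_vec <- function(cnt, res) {
  ax <- energy_axis()
  nz <- which(cnt != 0)
  if (!length(nz)) return(numeric(ax$n))
  E <- ax$centers[nz]
  fwhm <- res$b0 + res$b1 * E
  if (any(fwhm < 0)) stop("negative FWHM over the spectrum support")
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  out <- numeric(ax$n)
  tiny <- sig < ax$width / 100
  if (any(tiny)) out[nz[tiny]] <- out[nz[tiny]] + cnt[nz[tiny]]
  act <- which(!tiny)
  if (!length(act)) return(out)
  K <- ceiling(4 * max(sig[act]) / ax$width)
  offs <- (-K):K
  W <- exp(-0.5 * outer(ax$width / sig[act], offs)^2)
  dest <- outer(nz[act], offs, `+`)
  valid <- dest >= 1L & dest <= ax$n
  W[!valid] <- 0
  W <- W / rowSums(W)
  vals <- W * cnt[nz[act]]
  ok <- which(valid)
  out2 <- numeric(ax$n)
  acc <- rowsum(vals[ok], dest[ok])
  out2[as.integer(rownames(acc))] <- acc
  out + out2
}

# Gaussian smoothing evaluated only on a bin window (unnormalised weights;
# used for peak location, where the per-source renormalisation is a no-op
# away from the axis edges)
.smooth_window <- function(cnt, res, lo_bin, hi_bin) {
  ax <- energy_axis()
  out <- numeric(ax$n)
  fw_max <- res$b0 + res$b1 * ax$centers[hi_bin]
  K <- max(1L, ceiling(4 * (fw_max / 2.3548) / ax$width))
  src <- max(1L, lo_bin - K):min(ax$n, hi_bin + K)
  src <- src[cnt[src] != 0]
  if (!length(src)) return(out)
  sig <- (res$b0 + res$b1 * ax$centers[src]) / (2 * sqrt(2 * log(2)))
  sig <- pmax(sig, ax$width / 10)
  dest <- lo_bin:hi_bin
  D <- outer(src, dest, function(a, b) (b - a) * ax$width)
  W <- exp(-0.5 * (D / sig)^2) / sig   # sig recycles along rows (sources)
  out[dest] <- as.numeric(crossprod(W, cnt[src]))
  out
}

#' Locate a photopeak centroid
#'
#' Finds the local maximum within a search window of
#' `+/- max(2 keV, expected FWHM)` around the expected energy and refines it
#' by parabolic interpolation on the logarithm of the three surrounding
#' bins.
#'
#' @param spec A `spectrum` (or plain counts vector).
#' @param expected Expected peak energy (keV).
#' @param fwhm Expected FWHM (keV) at the peak.
#' @return Centroid energy (keV); errors when no peak is found.
#' @export
find_peak_centroid <- function(spec, expected, fwhm = 5) {
  ax <- energy_axis()
  cnt <- as.numeric(spec)
  half <- max(2, fwhm)
  sel <- which(ax$centers >= expected - half & ax$centers <= expected + half)
  if (!length(sel) || all(cnt[sel] <= 0))
    stop(sprintf("no peak found near %.1f keV", expected))
  med <- stats::median(cnt[sel])
  if (max(cnt[sel]) <= 1.2 * med + 1e-9)
    stop(sprintf("no peak found near %.1f keV (window is flat)", expected))
  i <- sel[which.max(cnt[sel])]
  if (i <= 1L || i >= ax$n) return(ax$centers[i])
  y <- cnt[(i - 1L):(i + 1L)]
  if (any(y <= 0)) return(ax$centers[i])
  ly <- log(y)
  den <- ly[1] - 2 * ly[2] + ly[3]
  if (abs(den) < 1e-12) return(ax$centers[i])
  delta <- 0.5 * (ly[1] - ly[3]) / den
  ax$centers[i] + pmin(pmax(delta, -1), 1) * ax$width
}

#' Determine the energy calibration by fixed-point iteration
#'
#' Solves for the linear calibration that places the photopeaks at their
#' true energies *after* the resolution smoothing: iteratively (i) applies
#' the current calibration and the resolution model, (ii) locates the peak
#' centroids, (iii) updates `(a0, a1)` by least squares mapping found onto
#' true energies. Converged when the largest centroid shift is below
#' 0.05 keV, or after 20 iterations. With a single peak, `a0` is fixed at 0.
#'
#' @param spec Initial (uncalibrated) `spectrum`.
#' @param peaks True photopeak energies (keV), at least one.
#' @param res A [resolution_model()] used during the iteration.
#' @param init Optional [energy_calibration()] warm start. With a warm
#'   start the peaks are assumed roughly aligned already, so the narrow
#'   search windows apply from the first iteration; this keeps repeated
#'   calibrations (e.g. across optimiser candidates) on the same peaks.
#' @param max_iter Iteration cap (default 20). `max_iter = 1` with a warm
#'   start performs a single least-squares refinement of the anchor
#'   calibration, which depends smoothly on the resolution parameters;
#'   the iterated fixed point can otherwise settle on discretely different
#'   branches for nearby resolution candidates, which poisons optimiser
#'   surfaces.
#' @return An [energy_calibration()].
#' @export
calibrate <- function(spec, peaks, res = resolution_model(), init = NULL,
                      max_iter = 20L) {
  stopifnot(length(peaks) >= 1, max_iter >= 1)
  ax <- energy_axis()
  if (is.null(init)) { a0 <- 0; a1 <- 1; cold <- TRUE }
  else { a0 <- init$a0; a1 <- init$a1; cold <- FALSE }
  for (it in seq_len(max_iter)) {
    cal <- energy_calibration(a0, a1)
    cnt <- .recalib_vec(as.numeric(spec), cal)
    # the uncalibrated photopeaks sit well below their true energies (the
    # CIE plateau is < 1), so the first pass searches a wide fractional
    # window; once roughly aligned the narrow window takes over. Smoothing
    # is evaluated only around the search windows.
    locate <- function(p, half) {
      lo <- max(1L, .bin_of(p - half)); hi <- min(ax$n, .bin_of(p + half))
      s <- .smooth_window(cnt, res, lo, hi)
      find_peak_centroid(s, p, half)
    }
    found <- vapply(peaks, function(p) {
      narrow <- max(2, res$b0 + res$b1 * p)
      wide <- max(narrow, 0.3 * p)
      if (it == 1L && cold) return(locate(p, wide))
      # peaks whose residual displacement is non-linear can drift out of
      # the narrow window; fall back to the wide fractional search, and
      # past the first iteration a vanished peak ends the fixed point
      # with the current calibration instead of aborting
      tryCatch(locate(p, narrow),
               error = function(e)
                 tryCatch(locate(p, wide), error = function(e2) NA_real_))
    }, numeric(1))
    if (anyNA(found)) break
    if (length(peaks) == 1L) {
      beta <- unname(peaks / found); alpha <- 0
    } else {
      fit <- stats::lm.fit(cbind(1, found), peaks)
      alpha <- unname(fit$coefficients[1]); beta <- unname(fit$coefficients[2])
    }
    a0n <- alpha + beta * a0
    a1n <- beta * a1
    shift <- max(abs(found - peaks))
    # Once the spectrum is roughly aligned updates must be perturbative; a
    # large jump means a window latched onto a tail feature (low-count
    # spectra), and compounding it would run away.
    if ((it > 1L || !cold) && abs(a1n / a1 - 1) > 0.3) break
    # stop on placement (all centroids within half a bin) or on parameter
    # stationarity (the least-squares compromise cannot improve further)
    stationary <- max(abs(a0n - a0), abs(a1n - a1) * 250) < 0.01
    a0 <- a0n; a1 <- a1n
    if (shift < 0.05 || stationary) break
  }
  energy_calibration(a0, a1)
}

#' Integrate a window into an image
#'
#' One pixel per anode: the summed counts of the anode's spectrum within the
#' energy window.
#'
#' @param table A `spectrum_table`.
#' @param window An [energy_window()].
#' @param anodes Anode layout giving the image shape.
#' @return Matrix `n_x` x `n_y`.
#' @export
form_image <- function(table, window, anodes = anode_array_spec()) {
  ax <- energy_axis()
  sel <- ax$centers >= window$low & ax$centers < window$high
  px <- rowSums(table$counts[, sel, drop = FALSE])
  matrix(px, anodes$n_x, anodes$n_y)
}

#' Split spectra into labelled components
#'
#' Winner selection runs once over the full histories; each detected count
#' is routed to the component given by its history's tag. The components sum
#' to the total spectrum bin by bin.
#'
#' @param model A [detector_model()].
#' @param lm A `listmode`.
#' @param splitter `"emission_energy"` or `"transport_class"`.
#' @return Named list of summed `spectrum` objects (all anodes).
#' @export
component_spectra <- function(model, lm,
                              splitter = c("emission_energy",
                                           "transport_class")) {
  splitter <- match.arg(splitter)
  det <- .detect_events(model, lm)
  key <- if (splitter == "emission_energy") format(det$line) else det$class
  ax <- energy_axis()
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    cnt <- numeric(ax$n)
    if (any(sel)) {
      acc <- rowsum(det$weight[sel], .bin_of(det$energy[sel]))
      cnt[as.integer(rownames(acc))] <- acc
    }
    out[[k]] <- spectrum(cnt, meta = list(activity = lm$header$activity,
                                          duration = lm$header$duration,
                                          distance = lm$header$distance))
  }
  out
}

#' Windowed system sensitivity
#'
#' Total windowed count rate per unit activity over the full field of view:
#' windowed counts / (duration x activity), in counts s^-1 MBq^-1.
#'
#' @param table A `spectrum_table` with `activity` (MBq) and `duration` (s)
#'   metadata.
#' @param window An [energy_window()].
#' @return Sensitivity (cps/MBq).
#' @export
sensitivity <- function(table, window) {
  meta <- table$meta
  if (is.null(meta$activity) || is.null(meta$duration))
    stop("spectrum table lacks activity/duration metadata")
  ax <- energy_axis()
  sel <- ax$centers >= window$low & ax$centers < window$high
  sum(table$counts[, sel]) / (meta$duration * meta$activity)
}

#' Fit the sensitivity-versus-distance model
#'
#' Nonlinear least squares for \eqn{s(d) = c_0 + c_1 e^{-c_2 d}} with
#' \eqn{c_2 \ge 0}. A profile search over `c2` (with `c0`, `c1` solved
#' linearly) supplies the start; `minpack.lm::nlsLM` polishes it. Degenerate
#' flat data (any `c2` fits equally) returns `c2 = 0` by the lower-bound tie
#' rule.
#'
#' @param distances Source-collimator distances (mm), at least 4.
#' @param sensitivities Matching sensitivities.
#' @return Named vector `c(c0, c1, c2)` (`c2` in 1/mm).
#' @export
fit_sensitivity_curve <- function(distances, sensitivities) {
  stopifnot(length(distances) >= 4,
            length(distances) == length(sensitivities))
  d <- as.numeric(distances); s <- as.numeric(sensitivities)
  prof <- function(c2) {
    X <- if (c2 > 0) cbind(1, exp(-c2 * d)) else matrix(1, length(d), 1)
    fit <- stats::lm.fit(X, s)
    cf <- fit$coefficients
    list(rss = sum(fit$residuals^2),
         coef = c(cf[1], if (length(cf) > 1) cf[2] else 0))
  }
  rng <- diff(range(d))
  c2_grid <- c(0, exp(seq(log(1e-4), log(10 / max(rng, 1e-9)),
                          length.out = 40)))
  rss <- vapply(c2_grid, function(c) prof(c)$rss, numeric(1))
  # lower-bound tie rule: a profile flat in c2 (c1 = 0 data) returns c2 = 0
  if (all(abs(rss - rss[1]) <= 1e-10 * max(1, abs(rss[1])))) {
    cf <- prof(0)$coef
    return(c(c0 = unname(cf[1]), c1 = 0, c2 = 0))
  }
  best <- which.min(rss)
  c2_0 <- c2_grid[best]
  cf <- prof(c2_0)$coef
  df <- data.frame(d = d, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ c0 + c1 * exp(-c2 * d), data = df,
                      start = list(c0 = unname(cf[1]), c1 = unname(cf[2]),
                                   c2 = max(c2_0, 1e-8)),
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e)
      stop(sprintf("sensitivity fit did not converge (%s); profile RSS %.4g",
                   conditionMessage(e), rss[best])))
  out <- stats::coef(fit)
  c(c0 = unname(out["c0"]), c1 = unname(out["c1"]), c2 = unname(out["c2"]))
}
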