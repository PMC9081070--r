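#' Source specification for the synthetic listmode generator
#'
#' Describes the emitter and measurement geometry emulated by
#' [generate_listmode()]. The generator is a parameterised statistical
#' stand-in for an external Monte Carlo photon-transport code: class mixture
#' fractions and the septal penetration factor are inputs, not predictions.
#'
#' @param lines Two-column matrix or data frame: emission energy (keV) and
#'   relative intensity (> 0). Default: the four prominent Lu-177 lines with
#'   equal unit intensities (yields are configuration, not constants).
#' @param distance Source-collimator distance (mm).
#' @param extent Lateral diameter of the disc source (mm).
#' @param activity Activity (MBq).
#' @param duration Acquisition duration (s).
#' @param class_fractions Named numeric vector of transport-class fractions
#'   (`geometric_primary`, `phantom_scatter`, `penetration`,
#'   `collimator_scatter`, `collimator_xray`, `other`), or a matrix with one
#'   row per emission line. Each row must sum to 1.
#' @param mu_att Linear attenuation coefficient of the crystal (1/mm): a
#'   function of energy (keV) or a single number. The default is a stylised
#'   log-log interpolation of CZT values.
#' @param p_photo Probability that an interacting photon is photo-absorbed in
#'   one event (vs opening a Compton chain): function of energy or number.
#' @param p_second Probability that a Compton-scattered photon is absorbed in
#'   a second crystal event rather than escaping.
#' @param p_rayleigh Probability of a zero-deposit elastic event preceding
#'   the chain.
#' @param xray_energy Representative collimator fluorescence energy (keV).
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(lines = cbind(energy = c(54.6, 55.8, 112.9, 208.4),
                                      intensity = c(1, 1, 1, 1)),
                        distance = 25, extent = 20, activity = 10,
                        duration = 100,
                        class_fractions = c(geometric_primary = 0.85,
                                            phantom_scatter = 0.02,
                                            penetration = 0.10,
                                            collimator_scatter = 0.02,
                                            collimator_xray = 0.01,
                                            other = 0),
                        mu_att = NULL, p_photo = NULL, p_second = 0.5,
                        p_rayleigh = 0.02, xray_energy = 75) {
  lines <- as.matrix(lines)
  colnames(lines) <- c("energy", "intensity")
  stopifnot(all(lines[, "intensity"] > 0), all(lines[, "energy"] > 0))
  classes <- c("geometric_primary", "phantom_scatter", "penetration",
               "collimator_scatter", "collimator_xray", "other")
  if (is.matrix(class_fractions)) {
    stopifnot(nrow(class_fractions) == nrow(lines),
              identical(colnames(class_fractions), classes))
    cf <- class_fractions
  } else {
    stopifnot(identical(names(class_fractions), classes))
    cf <- matrix(class_fractions, nrow(lines), length(classes),
                 byrow = TRUE, dimnames = list(NULL, classes))
  }
  if (any(abs(rowSums(cf) - 1) > 1e-9))
    stop("class mixture fractions must sum to 1 per line")
  if (any(cf < 0)) stop("class mixture fractions must be non-negative")
  if (is.null(mu_att)) mu_att <- czt_attenuation
  if (is.numeric(mu_att)) { mval <- mu_att; mu_att <- function(E) rep(mval, length(E)) }
  if (is.null(p_photo))
    p_photo <- function(E) 1 / (1 + (E / 260)^2.5)
  if (is.numeric(p_photo)) { pval <- p_photo; p_photo <- function(E) rep(pval, length(E)) }
  structure(list(lines = lines, distance = distance, extent = extent,
                 activity = activity, duration = duration,
                 class_fractions = cf, mu_att = mu_att, p_photo = p_photo,
                 p_second = p_second, p_rayleigh = p_rayleigh,
                 xray_energy = xray_energy),
            class = "source_spec")
}

#' Stylised CZT linear attenuation coefficient
#'
#' Log-log interpolation through representative values (1/mm) spanning the
#' 40-250 keV operating range; a configuration default, replaceable per
#' [source_spec()].
#'
#' @param energy Photon energy (keV).
#' @return Linear attenuation coefficient (1/mm).
#' @export
czt_attenuation <- function(energy) {
  E <- c(40, 55, 80, 113, 150, 208, 250)
  mu <- c(8.0, 3.5, 1.6, 0.90, 0.55, 0.35, 0.28)
  exp(stats::approx(log(E), log(mu), xout = log(pmin(pmax(energy, 40), 250)),
                    rule = 2)$y)
}

#' Lateral collimator transmission factor
#'
#' Relative interaction likelihood at a lateral position: 1 inside the
#' projected hole aperture of the containing anode cell, the septal
#' penetration factor `eps_pen` over the septa, and 1 everywhere for the
#' open cover.
#'
#' @param xy Two-column matrix of lateral positions (mm).
#' @param collimator A [collimator_spec()].
#' @param anodes An [anode_array_spec()].
#' @param energy Photon energy (keV), forwarded to `eps_pen` when it is a
#'   function.
#' @return Numeric factor(s) in `[0, 1]`.
#' @export
collimator_transmission <- function(xy, collimator, anodes, energy = 140) {
  xy <- matrix(xy, ncol = 2)
  if (collimator$hole_shape == "none") return(rep(1, nrow(xy)))
  eps <- collimator$eps_pen
  if (is.function(eps)) eps <- eps(energy)
  inside <- in_hole_aperture(xy, collimator, anodes)
  ifelse(inside, 1, eps)
}

#' Sample interaction depths
#'
#' Truncated exponential on `[0, thickness]` with rate `mu_att`, by inverse
#' transform on the session RNG.
#'
#' @param n Number of samples.
#' @param mu_att Attenuation coefficient (1/mm), > 0.
#' @param thickness Crystal thickness (mm).
#' @return Depths (mm) from the cathode-side entrance surface.
#' @export
sample_interaction_depth <- function(n, mu_att, thickness) {
  stopifnot(mu_att > 0, thickness > 0)
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-mu_att * thickness))) / mu_att
}

#' Sample a Compton energy split
#'
#' Samples the scattering angle from the Klein-Nishina differential cross
#' section (rejection sampling) and splits the photon energy by the Compton
#' relation. Energy is conserved exactly: `deposited + scattered = energy`.
#'
#' @param energy Incident photon energy (keV), > 0.
#' @param n Number of samples.
#' @return Data frame with columns `deposited` and `scattered` (keV).
#' @export
sample_compton_split <- function(energy, n = 1) {
  stopifnot(energy > 0)
  alpha <- energy / 510.999
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    ct <- stats::runif(m, -1, 1)
    eps <- 1 / (1 + alpha * (1 - ct))
    f <- eps^2 * (eps + 1 / eps - (1 - ct^2))
    acc <- stats::runif(m) * 2 <= f
    take <- which(acc)
    take <- take[seq_len(min(length(take), n - got))]
    out[got + seq_along(take)] <- eps[take]
    got <- got + length(take)
  }
  scattered <- energy * out
  data.frame(deposited = energy - scattered, scattered = scattered)
}

#' Compton deposited energy at a fixed angle
#'
#' Deterministic companion of [sample_compton_split()]:
#' \eqn{E_{dep} = E^2(1-\cos\theta)/(m_ec^2 + E(1-\cos\theta))}.
#'
#' @param energy Incident energy (keV).
#' @param theta Scattering angle (radians).
#' @return Deposited energy (keV).
#' @export
compton_deposit <- function(energy, theta) {
  k <- 1 - cos(theta)
  energy^2 * k / (510.999 + energy * k)
}

.lm_classes <- c("geometric_primary", "phantom_scatter", "penetration",
                 "collimator_scatter", "collimator_xray", "other")
.lm_kinds <- c("photoelectric", "compton", "rayleigh")

.empty_events <- function() {
  data.frame(history_id = integer(0), kind = character(0), x = numeric(0),
              y = numeric(0), z = numeric(0), energy = numeric(0),
              weight = numeric(0))
}
.empty_histories <- function() {
  data.frame(history_id = integer(0), line = numeric(0), class = character(0))
}

.listmode <- function(events, histories, header) {
  structure(list(events = events, histories = histories, header = header),
            class = "listmode")
}

#' @export
print.listmode <- function(x, ...) {
  cat(sprintf("<listmode> %d histories, %d events\n",
              nrow(x$histories), nrow(x$events)))
  if (nrow(x$histories)) {
    tab <- table(x$histories$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Synthesise photon-interaction histories
#'
#' Statistical stand-in for an external Monte Carlo photon-transport stage.
#' Per history: an emission line is drawn by intensity and a transport class
#' by the line's mixture; the lateral interaction position is a projected
#' source-disc sample thinned by the collimator transmission for collimated
#' primaries (and near-uniform over the field of view for penetration,
#' collimator-scatter and x-ray classes); the interaction depth follows a
#' truncated exponential at the line's attenuation coefficient; the
#' deposition chain is a single photo-absorption or a Klein-Nishina Compton
#' split with a possible second (absorbed) event or escape. Weights default
#' to 1. Output is deterministic under `seed`, which is recorded in the
#' header.
#'
#' @param source A [source_spec()].
#' @param crystal A [crystal_spec()].
#' @param anodes An [anode_array_spec()].
#' @param collimator A [collimator_spec()].
#' @param n_histories Number of decays to record (>= 0).
#' @param seed Integer RNG seed.
#' @return Object of class `listmode`: event table (`history_id`, `kind`,
#'   `x`, `y`, `z`, `energy`, `weight`), per-history table (`history_id`,
#'   `line`, `class`) and a header.
#' @export
generate_listmode <- function(source, crystal, anodes, collimator,
                              n_histories, seed = 1L) {
  stopifnot(inherits(source, "source_spec"), n_histories >= 0)
  header <- list(seed = as.integer(seed), n_histories = as.integer(n_histories),
                 activity = source$activity, duration = source$duration,
                 distance = source$distance, collimator = collimator$name)
  if (n_histories == 0)
    return(.listmode(.empty_events(), .empty_histories(), header))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  nl <- nrow(source$lines)
  line_id <- sample.int(nl, n_histories, replace = TRUE,
                        prob = source$lines[, "intensity"])
  line_E <- source$lines[line_id, "energy"]
  cls <- character(n_histories)
  for (li in seq_len(nl)) {
    sel <- line_id == li
    if (!any(sel)) next
    cls[sel] <- sample(.lm_classes, sum(sel), replace = TRUE,
                       prob = source$class_fractions[li, ])
  }

  half_x <- crystal$width_x / 2
  half_y <- crystal$width_y / 2
  r_src <- source$extent / 2
  sample_disc <- function(m) {
    r <- r_src * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }
  xy <- matrix(0, n_histories, 2)
  primary <- cls %in% c("geometric_primary", "phantom_scatter")
  np <- sum(primary)
  if (np) {
    # thin source-disc samples by the collimator transmission
    pos <- matrix(NA_real_, np, 2)
    Ep <- line_E[primary]
    todo <- seq_len(np)
    for (it in 1:200) {
      if (!length(todo)) break
      cand <- sample_disc(length(todo))
      tr <- collimator_transmission(cand, collimator, anodes, Ep[todo])
      keep <- stats::runif(length(todo)) < tr
      pos[todo[keep], ] <- cand[keep, , drop = FALSE]
      todo <- todo[!keep]
    }
    if (length(todo)) pos[todo, ] <- sample_disc(length(todo))
    xy[primary, ] <- pos
  }
  diffuse <- !primary
  nd <- sum(diffuse)
  if (nd)
    xy[diffuse, ] <- cbind(stats::runif(nd, -half_x, half_x),
                           stats::runif(nd, -half_y, half_y))

  E_in <- line_E
  deg <- cls %in% c("phantom_scatter", "collimator_scatter")
  if (any(deg))
    E_in[deg] <- vapply(line_E[deg], function(E)
      sample_compton_split(E, 1)$scattered, numeric(1))
  E_in[cls == "collimator_xray"] <- source$xray_energy

  z <- numeric(n_histories)
  for (E in unique(E_in)) {
    sel <- E_in == E
    z[sel] <- sample_interaction_depth(sum(sel), source$mu_att(E),
                                       crystal$thickness)
  }

  is_photo <- stats::runif(n_histories) < source$p_photo(E_in)
  has_ray <- stats::runif(n_histories) < source$p_rayleigh

  ev_hist <- list(); ev_kind <- list(); ev_x <- list(); ev_y <- list()
  ev_z <- list(); ev_E <- list()
  push <- function(h, kind, x, y, zz, E) {
    i <- length(ev_hist) + 1L
    ev_hist[[i]] <<- h; ev_kind[[i]] <<- rep(kind, length(h))
    ev_x[[i]] <<- x; ev_y[[i]] <<- y; ev_z[[i]] <<- zz; ev_E[[i]] <<- E
  }
  hid <- seq_len(n_histories)
  if (any(has_ray))
    push(hid[has_ray], "rayleigh", xy[has_ray, 1], xy[has_ray, 2],
         z[has_ray], rep(0, sum(has_ray)))
  ph <- is_photo
  if (any(ph))
    push(hid[ph], "photoelectric", xy[ph, 1], xy[ph, 2], z[ph], E_in[ph])
  co <- !is_photo
  if (any(co)) {
    nc <- sum(co)
    splits <- do.call(rbind, lapply(E_in[co], function(E)
      sample_compton_split(E, 1)))
    push(hid[co], "compton", xy[co, 1], xy[co, 2], z[co], splits$deposited)
    second <- stats::runif(nc) < source$p_second
    if (any(second)) {
      Es <- splits$scattered[second]
      # displaced absorption of the scattered photon
      step <- stats::rexp(sum(second), rate = source$mu_att(Es))
      dirz <- stats::runif(sum(second), -1, 1)
      az <- stats::runif(sum(second), 0, 2 * pi)
      sl <- sqrt(1 - dirz^2)
      x2 <- pmin(pmax(xy[co, 1][second] + step * sl * cos(az), -half_x), half_x)
      y2 <- pmin(pmax(xy[co, 2][second] + step * sl * sin(az), -half_y), half_y)
      z2 <- pmin(pmax(z[co][second] + step * dirz, 0), crystal$thickness)
      push(hid[co][second], "photoelectric", x2, y2, z2, Es)
    }
  }
  events <- data.frame(history_id = unlist(ev_hist),
                        kind = unlist(ev_kind),
                        x = unlist(ev_x), y = unlist(ev_y), z = unlist(ev_z),
                        energy = unlist(ev_E),
                        weight = 1)
  events <- events[order(events$history_id), , drop = FALSE]
  rownames(events) <- NULL
  histories <- data.frame(history_id = hid, line = line_E, class = cls)
  .listmode(events, histories, header)
}

#' History classification tags
#'
#' Returns the stored per-history emission energy and transport class, used
#' to split spectra into components. Unknown or missing class codes map to
#' `"other"`.
#'
#' @param lm A `listmode` object.
#' @return Data frame with `history_id`, `line` (keV), `class`.
#' @export
classify_history <- function(lm) {
  h <- lm$histories
  bad <- is.na(h$class) | !(h$class %in% .lm_classes)
  if (any(bad)) h$class[bad] <- "other"
  h
}

.lm_magic <- charToRaw("CZTLM1\n\n")

#' Write / read listmode files
#'
#' Versioned binary container with fixed-width little-endian records
#' (history id int32, event kind uint8, position 3 x float64, deposited
#' energy float64, weight float64, emission line float32, class uint8), plus
#' a plain-text TSV dialect for fixtures. `read_listmode` auto-detects the
#' format, can stream binary records in chunks through a callback, and in
#' strict mode flags event positions outside the crystal volume.
#'
#' @param lm A `listmode` object.
#' @param path File path.
#' @param format `"binary"` or `"text"`.
#' @return `read_listmode` returns the `listmode` (or, with a callback,
#'   invisibly the number of records streamed).
#' @export
write_listmode <- function(lm, path, format = c("binary", "text")) {
  format <- match.arg(format)
  ev <- lm$events
  h <- lm$histories
  cls_code <- match(h$class, .lm_classes)
  kind_code <- match(ev$kind, .lm_kinds)
  line_of <- h$line[match(ev$history_id, h$history_id)]
  cls_of <- cls_code[match(ev$history_id, h$history_id)]
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# cztcam-listmode v1",
                 sprintf("# seed: %s", lm$header$seed %||% NA),
                 sprintf("# activity_MBq: %s", lm$header$activity %||% NA),
                 sprintf("# duration_s: %s", lm$header$duration %||% NA),
                 sprintf("# distance_mm: %s", lm$header$distance %||% NA),
                 sprintf("# collimator: %s", lm$header$collimator %||% NA),
                 paste("history_id", "kind", "x", "y", "z", "energy",
                       "weight", "line", "class", sep = "\t")), con)
    df <- data.frame(ev$history_id, ev$kind, ev$x, ev$y, ev$z, ev$energy,
                     ev$weight, line_of, .lm_classes[cls_of])
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.lm_magic, con)
  writeBin(1L, con, size = 4L, endian = "little")
  hdr <- jsonlite::toJSON(lm$header, auto_unbox = TRUE, null = "null")
  hraw <- charToRaw(as.character(hdr))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(nrow(ev), con, size = 4L, endian = "little")
  if (nrow(ev)) {
    m <- nrow(ev)
    rec_size <- 4L + 1L + 5L * 8L + 4L + 1L
    M <- matrix(as.raw(0), rec_size, m)
    M[1:4, ] <- matrix(writeBin(as.integer(ev$history_id), raw(), size = 4L,
                                endian = "little"), 4L)
    M[5L, ] <- as.raw(kind_code)
    M[6:45, ] <- matrix(writeBin(as.numeric(rbind(ev$x, ev$y, ev$z,
                                                  ev$energy, ev$weight)),
                                 raw(), size = 8L, endian = "little"), 40L)
    M[46:49, ] <- matrix(writeBin(as.numeric(line_of), raw(), size = 4L,
                                  endian = "little"), 4L)
    M[50L, ] <- as.raw(cls_of)
    writeBin(as.vector(M), con)
  }
  invisible(path)
}

.read_lm_text <- function(path, strict, crystal) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getm <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  header <- list(seed = suppressWarnings(as.integer(getm("seed"))),
                 activity = suppressWarnings(as.numeric(getm("activity_MBq"))),
                 duration = suppressWarnings(as.numeric(getm("duration_s"))),
                 distance = suppressWarnings(as.numeric(getm("distance_mm"))),
                 collimator = getm("collimator"))
  if (length(body) <= 1L)
    return(.listmode(.empty_events(), .empty_histories(), header))
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  events <- data.frame(history_id = as.integer(df$history_id),
                        kind = df$kind, x = df$x, y = df$y, z = df$z,
                        energy = df$energy, weight = df$weight)
  hids <- !duplicated(df$history_id)
  histories <- data.frame(history_id = as.integer(df$history_id[hids]),
                          line = df$line[hids], class = df$class[hids])
  .validate_lm(events, strict, crystal)
  .listmode(events, histories, header)
}

#' @rdname write_listmode
#' @param callback Optional function receiving each chunk of decoded binary
#'   event records (a data frame); when given, events are not accumulated.
#' @param chunk Records per chunk for streaming reads.
#' @param strict Flag event positions outside the crystal volume as an error.
#' @param crystal Crystal bounds used by `strict` (default the standard
#'   module).
#' @export
read_listmode <- function(path, callback = NULL, chunk = 65536L,
                          strict = FALSE, crystal = crystal_spec()) {
  con <- file(path, "rb")
  probe <- readBin(con, "raw", n = 8L)
  close(con)
  if (!identical(probe, .lm_magic)) {
    if (identical(rawToChar(probe[1:1]), "#"))
      return(.read_lm_text(path, strict, crystal))
    stop("not a listmode file (bad magic header)", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 8L)
  ver <- readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(ver, 1L)) stop(sprintf("unsupported listmode version %d", ver))
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  nrec <- readBin(con, "integer", size = 4L, endian = "little")
  rec_size <- 4L + 1L + 5L * 8L + 4L + 1L
  all_chunks <- list()
  read_done <- 0L
  while (read_done < nrec) {
    m <- min(chunk, nrec - read_done)
    raw <- readBin(con, "raw", n = m * rec_size)
    if (length(raw) < m * rec_size) stop("malformed listmode record (truncated)")
    M <- matrix(raw, nrow = rec_size)
    dec_int <- function(rows) readBin(as.raw(M[rows, ]), "integer",
                                      n = m, size = 4L, endian = "little")
    dec_dbl <- function(rows) readBin(as.raw(M[rows, ]), "numeric",
                                      n = m, size = 8L, endian = "little")
    hid <- dec_int(1:4)
    kind <- as.integer(M[5L, ])
    x <- dec_dbl(6:13); y <- dec_dbl(14:21); z <- dec_dbl(22:29)
    energy <- dec_dbl(30:37); weight <- dec_dbl(38:45)
    line <- readBin(as.raw(M[46:49, ]), "numeric", n = m, size = 4L,
                    endian = "little")
    clsc <- as.integer(M[50L, ])
    if (any(kind < 1L | kind > 3L)) stop("malformed listmode record (bad kind)")
    df <- data.frame(history_id = hid, kind = .lm_kinds[kind], x = x, y = y,
                     z = z, energy = energy, weight = weight, line = line,
                     class = ifelse(clsc >= 1L & clsc <= 6L,
                                    .lm_classes[pmin(pmax(clsc, 1L), 6L)],
                                    "other"))
    if (!is.null(callback)) callback(df)
    else all_chunks[[length(all_chunks) + 1L]] <- df
    read_done <- read_done + m
  }
  if (!is.null(callback)) return(invisible(read_done))
  df <- if (length(all_chunks)) do.call(rbind, all_chunks) else
    cbind(.empty_events(), line = numeric(0), class = character(0))
  events <- df[, c("history_id", "kind", "x", "y", "z", "energy", "weight")]
  rownames(events) <- NULL
  hids <- !duplicated(df$history_id)
  histories <- data.frame(history_id = df$history_id[hids],
                          line = as.numeric(df$line[hids]),
                          class = df$class[hids])
  .validate_lm(events, strict, crystal)
  .listmode(events, histories, header)
}

.validate_lm <- function(events, strict, crystal) {
  if (!strict || !nrow(events)) return(invisible(TRUE))
  hw <- c(crystal$width_x, crystal$width_y) / 2
  bad <- abs(events$x) > hw[1] + 1e-9 | abs(events$y) > hw[2] + 1e-9 |
    events$z < -1e-9 | events$z > crystal$thickness + 1e-9
  if (any(bad))
    stop(sprintf("%d event position(s) outside the crystal volume", sum(bad)))
  invisible(TRUE)
}
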