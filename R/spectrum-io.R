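#' Write / read a table of spectra
#'
#' Plain-text mirror of the camera's table-of-spectra dump: comment header
#' lines with the acquisition metadata, then one row per anode element with
#' 2500 tab-separated counts (0-250 keV, 0.1 keV bins).
#'
#' @param table A `spectrum_table`.
#' @param path File path.
#' @return `read_spectrum_table` returns the `spectrum_table`.
#' @export
write_spectrum_table <- function(table, path) {
  stopifnot(inherits(table, "spectrum_table"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- table$meta
  writeLines(c("# cztcam-spectra v1",
               sprintf("# anodes: %d", nrow(table$counts)),
               sprintf("# activity_MBq: %s", m$activity %||% NA),
               sprintf("# duration_s: %s", m$duration %||% NA),
               sprintf("# distance_mm: %s", m$distance %||% NA)), con)
  utils::write.table(table$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path) {
  lines <- readLines(path)
  meta_l <- lines[startsWith(lines, "#")]
  getm <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta_l, value = TRUE)
    if (!length(m)) return(NULL)
    v <- suppressWarnings(as.numeric(sub(paste0("^# ", key, ": "), "", m[1])))
    if (is.na(v)) NULL else v
  }
  counts <- as.matrix(utils::read.table(
    text = lines[!startsWith(lines, "#")], sep = "\t"))
  dimnames(counts) <- NULL
  if (ncol(counts) != 2500L)
    stop("table of spectra must have 2500 energy columns")
  .spectrum_table(counts, meta = list(activity = getm("activity_MBq"),
                                      duration = getm("duration_s"),
                                      distance = getm("distance_mm")))
}
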