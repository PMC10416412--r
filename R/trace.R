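#' Digitized CTCE electropherogram
#'
#' A trace is the digitized output of one cycling-temperature capillary
#' electrophoresis run: a strictly increasing scan axis, the sample-dye
#' channel (the 6-FAM-labeled analyte, carrying the wild-type, mutant,
#' heteroduplex and single-strand peaks) and the standard-dye channel (the
#' ROX-labeled internal standard injected before the sample, whose peaks
#' anchor peak labeling).
#'
#' @param scan Strictly increasing numeric scan index/time axis (length >= 16).
#' @param sample_channel Analyte fluorescence, same length as `scan`.
#' @param standard_channel Internal-standard fluorescence, same length.
#' @param well Optional well identifier.
#' @param fragment Optional fragment/gene name.
#' @param meta Optional list of extra metadata.
#' @return An object of class `ctce_trace`.
#' @export
ctce_trace <- function(scan, sample_channel, standard_channel,
                       well = NA_character_, fragment = NA_character_,
                       meta = list()) {
  scan <- as.numeric(scan)
  sample_channel <- as.numeric(sample_channel)
  standard_channel <- as.numeric(standard_channel)
  if (length(scan) < 16L) stop("trace must have >= 16 scans", call. = FALSE)
  if (length(sample_channel) != length(scan) ||
      length(standard_channel) != length(scan)) {
    stop("channel lengths must match the scan axis", call. = FALSE)
  }
  if (is.unsorted(scan, strictly = TRUE)) {
    stop("`scan` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(scan = scan, sample_channel = sample_channel,
         standard_channel = standard_channel,
         well = well, fragment = fragment, meta = meta),
    class = "ctce_trace"
  )
}

#' @export
print.ctce_trace <- function(x, ...) {
  cat(sprintf("<ctce_trace> well %s, %d scans, sample max %.4g, standard max %.4g\n",
              x$well, length(x$scan), max(x$sample_channel),
              max(x$standard_channel)))
  invisible(x)
}

#' @export
plot.ctce_trace <- function(x, ...) {
  graphics::plot(x$scan, x$sample_channel, type = "l", col = "blue",
                 xlab = "scan", ylab = "fluorescence (a.u.)",
                 main = if (is.na(x$well)) "CTCE trace" else x$well, ...)
  graphics::lines(x$scan, x$standard_channel, col = "red")
  graphics::legend("topright", c("sample (6-FAM)", "internal standard (ROX)"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Read / write a trace CSV
#'
#' The on-disk schema is one CSV per well with columns `scan`,
#' `sample_channel`, `standard_channel`.
#'
#' @param path File path.
#' @param well,fragment Metadata attached on read.
#' @return [read_trace_csv()] returns a `ctce_trace`.
#' @export
read_trace_csv <- function(path, well = NA_character_,
                           fragment = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan", "sample_channel", "standard_channel")
  if (!all(need %in% names(d))) {
    stop(sprintf("trace file '%s' lacks columns: %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  if (is.na(well)) {
    well <- sub("\\.csv$", "", basename(path))
  }
  ctce_trace(d$scan, d$sample_channel, d$standard_channel,
             well = well, fragment = fragment)
}

#' @rdname read_trace_csv
#' @param trace A `ctce_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ctce_trace"))
  utils::write.csv(
    data.frame(scan = trace$scan,
               sample_channel = trace$sample_channel,
               standard_channel = trace$standard_channel),
    path, row.names = FALSE)
  invisible(path)
}
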