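#' Baseline-correct a trace
#'
#' Estimates each channel's baseline with a centered rolling quantile —
#' by default the 10th percentile over a window much wider than a peak, so
#' even a cluster of nearby peaks cannot lift the estimate — smooths it
#' with a running mean of the same window, clamps it at zero, and
#' subtracts it. Subtraction of a non-negative baseline never increases a
#' channel value, removes constant offsets and slow drift, and is
#' idempotent within noise tolerance on an already-flat baseline.
#'
#' @param trace A [ctce_trace()].
#' @param window Odd window length in scans; must be shorter than the trace
#'   and wide relative to the peak width (default 301).
#' @param prob Quantile used for the baseline (default 0.1).
#' @return A baseline-corrected `ctce_trace`.
#' @export
baseline_correct <- function(trace, window = 301L, prob = 0.1) {
  stopifnot(inherits(trace, "ctce_trace"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  n <- length(trace$scan)
  if (window >= n) stop("`window` must be shorter than the trace",
                        call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  one_pass <- function(x) {
    b <- rolling_quantile(x, window, prob)
    # running-mean smoothing keeps the estimate from chasing noise steps
    b <- as.numeric(stats::filter(b, rep(1 / window, window), sides = 2))
    # extend the smoothed estimate into the filter's edge margins
    ok <- which(!is.na(b))
    if (length(ok)) {
      b[seq_len(ok[1] - 1)] <- b[ok[1]]
      b[seq((ok[length(ok)] + 1), length.out = length(b) - ok[length(ok)])] <-
        b[ok[length(ok)]]
    } else {
      b[] <- 0
    }
    b <- pmax(b, 0)
    x - b
  }
  # a low-quantile baseline lags a sloped drift by (0.5 - prob) * window
  # samples; the second pass removes the near-constant residual it leaves
  correct <- function(x) one_pass(one_pass(x))
  out <- trace
  out$sample_channel <- correct(trace$sample_channel)
  out$standard_channel <- correct(trace$standard_channel)
  out$meta$baseline_corrected <- TRUE
  out
}

# Centered rolling quantile; median uses the fast C path in runmed.
rolling_quantile <- function(x, window, prob) {
  if (abs(prob - 0.5) < 1e-12) {
    return(as.numeric(stats::runmed(x, window, endrule = "constant")))
  }
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- stats::quantile(x[lo:hi], probs = prob, names = FALSE,
                              type = 7)
  }
  out
}

#' Detect peaks in one channel
#'
#' Finds local maxima whose topographic prominence (apex height above the
#' higher of the two bounding valleys toward taller terrain) exceeds a
#' threshold, with valley-to-valley integration bounds. The default
#' threshold is 5 times the robust noise level (median absolute deviation
#' of the corrected channel scaled to a Gaussian sd). Two peaks merged
#' closer than their resolution share the separating valley as a common
#' bound and are flagged `merged`, never silently dropped.
#'
#' @param trace A baseline-corrected [ctce_trace()].
#' @param min_prominence Absolute prominence threshold; `NULL` for the
#'   robust default.
#' @param channel `"sample"` or `"standard"`.
#' @return A data.frame sorted by apex: `apex`, `height`, `prominence`,
#'   `left`, `right` (bounds, scan positions), `area` (trapezoidal, clamped
#'   at 0), `merged`.
#' @export
detect_peaks <- function(trace, min_prominence = NULL,
                         channel = c("sample", "standard")) {
  stopifnot(inherits(trace, "ctce_trace"))
  channel <- match.arg(channel)
  x <- if (channel == "sample") trace$sample_channel else trace$standard_channel
  n <- length(x)
  if (is.null(min_prominence)) {
    min_prominence <- 5 * stats::mad(x)
    if (min_prominence == 0) min_prominence <- sqrt(.Machine$double.eps)
  }
  # strict-left / non-strict-right comparison picks one index per plateau
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                     x[2:(n - 1)] >= x[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(empty_peaks())
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]
  prom <- prom[keep]
  if (!length(idx)) return(empty_peaks())
  # valley-to-valley bounds between retained peaks
  k <- length(idx)
  left <- integer(k)
  right <- integer(k)
  for (j in seq_len(k)) {
    lo <- if (j == 1L) 1L else idx[j - 1L]
    hi <- if (j == k) n else idx[j + 1L]
    left[j] <- (lo:idx[j])[which.min(x[lo:idx[j]])]
    right[j] <- (idx[j]:hi)[which.min(x[idx[j]:hi])]
  }
  # merged: the shared valley stays above half the smaller apex
  merged <- logical(k)
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      v <- x[right[j]]
      if (v > 0.5 * min(x[idx[j]], x[idx[j + 1L]])) {
        merged[j] <- TRUE
        merged[j + 1L] <- TRUE
      }
    }
  }
  area <- vapply(seq_len(k), function(j) {
    rng <- left[j]:right[j]
    max(trapz(trace$scan[rng], x[rng]), 0)
  }, numeric(1))
  data.frame(apex = trace$scan[idx], height = x[idx], prominence = prom,
             left = trace$scan[left], right = trace$scan[right],
             area = area, merged = merged)
}

empty_peaks <- function() {
  data.frame(apex = numeric(0), height = numeric(0),
             prominence = numeric(0), left = numeric(0), right = numeric(0),
             area = numeric(0), merged = logical(0))
}

# Topographic prominence of the local maximum at index i.
peak_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  lv <- {
    j <- if (i > 1) which(x[1:(i - 1)] > h) else integer(0)
    lo <- if (length(j)) max(j) + 1L else 1L
    min(x[lo:i])
  }
  rv <- {
    j <- if (i < n) which(x[(i + 1):n] > h) else integer(0)
    hi <- if (length(j)) i + min(j) - 1L else n
    min(x[i:hi])
  }
  h - max(lv, rv)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Integrated peak areas of one sample
#'
#' Container for the peak areas entering the mutant-fraction calculation:
#' wild type, mutant, the two heteroduplexes, and the optional single-strand
#' peak (tracked but excluded from quantification). The denominator total is
#' the sum of the four double-stranded product areas.
#'
#' @param a_wt,a_mut,a_hd1,a_hd2 Areas, all >= 0.
#' @param a_ss Optional single-strand area (`NA` if not tracked).
#' @param absent Character vector of labels that were looked for but not
#'   found (their areas are 0 with an explicit flag).
#' @param status `"ok"` for a quantifiable sample, otherwise a missing
#'   reason such as `"no signal"`.
#' @param well Optional well id.
#' @param notes Character vector of assignment log messages.
#' @return An object of class `peak_areas`.
#' @export
peak_areas <- function(a_wt, a_mut, a_hd1, a_hd2, a_ss = NA_real_,
                       absent = character(0), status = "ok",
                       well = NA_character_, notes = character(0)) {
  for (a in list(a_wt, a_mut, a_hd1, a_hd2)) {
    stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a >= 0)
  }
  if (!is.na(a_ss)) stopifnot(a_ss >= 0)
  structure(
    list(a_wt = a_wt, a_mut = a_mut, a_hd1 = a_hd1, a_hd2 = a_hd2,
         a_ss = a_ss, absent = absent, status = status, well = well,
         notes = notes,
         denominator_total = a_wt + a_mut + a_hd1 + a_hd2),
    class = "peak_areas"
  )
}

#' @export
print.peak_areas <- function(x, ...) {
  cat(sprintf(
    "<peak_areas> wt %.5g, mut %.5g, hd1 %.5g, hd2 %.5g, ss %s [%s]\n",
    x$a_wt, x$a_mut, x$a_hd1, x$a_hd2,
    if (is.na(x$a_ss)) "-" else sprintf("%.5g", x$a_ss), x$status))
  if (x$status == "ok") {
    cat(sprintf("  mutant fraction: %.4g (denominator %.6g)\n",
                mutant_fraction(x), x$denominator_total))
  }
  invisible(x)
}

#' Expected analyte peak layout relative to the internal standard
#'
#' The internal standard is a separately labeled product injected before
#' each sample; its first peak anchors the mobility scale, and analyte
#' peaks are labeled by their offset from that anchor. The default layout
#' is derived from [trace_params()] so simulated traces and the quantifier
#' agree by construction; instrument users supply their own offsets.
#'
#' @param params A [trace_params()].
#' @param tol Assignment tolerance in scans around each expected apex.
#' @return A data.frame with columns `label`, `offset`, `tol`.
#' @export
peak_layout <- function(params = trace_params(), tol = 12) {
  labs <- c("wt", "mut", "hd1", "hd2", "ss")
  data.frame(label = labs,
             offset = as.numeric(params$apex[labs] - params$apex[["std1"]]),
             tol = tol, stringsAsFactors = FALSE)
}

#' Label detected peaks and collect their areas
#'
#' Analyte peaks are assigned to the wild-type / mutant / heteroduplex /
#' single-strand classes by mobility relative to the first internal-standard
#' apex. A class with no detected peak inside its tolerance window gets
#' area 0 and an explicit `absent` flag; if two detected peaks fall inside
#' one window the larger-area peak takes the label and the tie is logged in
#' `notes`. A trace with no analyte peaks at all is returned as a missing
#' record with status `"no signal"`; a trace with no standard peaks gets
#' status `"no standard"`.
#'
#' @param peaks Analyte-channel peak table from [detect_peaks()].
#' @param standard_peaks Standard-channel peak table.
#' @param expected_layout Layout from [peak_layout()].
#' @param well Optional well id carried into the result.
#' @return A [peak_areas()] object.
#' @export
assign_labels <- function(peaks, standard_peaks,
                          expected_layout = peak_layout(),
                          well = NA_character_) {
  if (nrow(standard_peaks) == 0) {
    return(peak_areas(0, 0, 0, 0, status = "no standard", well = well,
                      absent = expected_layout$label))
  }
  if (nrow(peaks) == 0) {
    return(peak_areas(0, 0, 0, 0, status = "no signal", well = well,
                      absent = expected_layout$label))
  }
  # anchor on the dominant standard peaks: noise blips occasionally pass
  # the prominence threshold, so "first detected" is not trustworthy
  top <- order(standard_peaks$area, decreasing = TRUE)
  top <- top[seq_len(min(2L, length(top)))]
  anchor <- min(standard_peaks$apex[top])
  got <- stats::setNames(numeric(length(expected_layout$label)),
                         expected_layout$label)
  absent <- character(0)
  notes <- character(0)
  claimed <- rep(FALSE, nrow(peaks))
  for (j in seq_len(nrow(expected_layout))) {
    lab <- expected_layout$label[j]
    target <- anchor + expected_layout$offset[j]
    hit <- which(!claimed & abs(peaks$apex - target) <= expected_layout$tol[j])
    if (!length(hit)) {
      absent <- c(absent, lab)
      next
    }
    if (length(hit) > 1L) {
      pick <- hit[which.max(peaks$area[hit])]
      notes <- c(notes, sprintf(
        "label %s: %d candidate peaks in window; kept apex %.4g (largest area)",
        lab, length(hit), peaks$apex[pick]))
    } else {
      pick <- hit
    }
    claimed[pick] <- TRUE
    got[lab] <- peaks$area[pick]
    if (isTRUE(peaks$merged[pick])) {
      notes <- c(notes, sprintf("label %s: peak merged with a neighbor", lab))
    }
  }
  if (all(c("wt", "mut", "hd1", "hd2") %in% absent)) {
    return(peak_areas(0, 0, 0, 0, status = "no signal", well = well,
                      absent = expected_layout$label, notes = notes))
  }
  peak_areas(got[["wt"]], got[["mut"]], got[["hd1"]], got[["hd2"]],
             a_ss = if ("ss" %in% names(got)) got[["ss"]] else NA_real_,
             absent = absent, status = "ok", well = well, notes = notes)
}

#' Mutant allele fraction from peak areas
#'
#' The estimator: the mutant peak area plus half of the two heteroduplex
#' peak areas (each heteroduplex molecule carries exactly one mutant
#' strand), divided by the total area of the four double-stranded product
#' peaks,
#' \deqn{\hat p = \frac{A_{mut} + (A_{hd1} + A_{hd2})/2}{A_{wt} + A_{mut} + A_{hd1} + A_{hd2}}.}
#' The single-strand and internal-standard peaks enter neither numerator
#' nor denominator: with areas (wt, mut, hd1, hd2) = (10000, 1000, 2000,
#' 2000) the fraction is 3000 / 15000 = 0.20. A zero denominator is a
#' non-quantifiable sample — an error distinct from a fraction of 0.
#'
#' @param areas A [peak_areas()] object, or `a_wt` as a number with the
#'   remaining areas given separately.
#' @param a_mut,a_hd1,a_hd2 Areas when called with numbers.
#' @return Mutant allele fraction in \[0, 1\].
#' @examples
#' mutant_fraction(10000, 1000, 2000, 2000) # 0.2
#' @export
mutant_fraction <- function(areas, a_mut = NULL, a_hd1 = NULL,
                            a_hd2 = NULL) {
  if (inherits(areas, "peak_areas")) {
    a <- c(areas$a_wt, areas$a_mut, areas$a_hd1, areas$a_hd2)
  } else {
    a <- c(areas, a_mut, a_hd1, a_hd2)
    if (length(a) != 4L) {
      stop("supply a `peak_areas` object or four areas", call. = FALSE)
    }
  }
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("areas must be finite and >= 0", call. = FALSE)
  }
  total <- sum(a)
  if (total <= 0) {
    stop("total double-stranded peak area is 0: signal not quantifiable ",
         "(distinct from a mutant fraction of 0)", call. = FALSE)
  }
  (a[2] + 0.5 * (a[3] + a[4])) / total
}

#' Quantify one trace end to end
#'
#' Baseline correction, peak detection on both channels, labeling against
#' the expected layout, and area integration.
#'
#' @param trace A [ctce_trace()].
#' @param expected_layout From [peak_layout()].
#' @param window,prob Passed to [baseline_correct()].
#' @param min_prominence Passed to [detect_peaks()].
#' @return A [peak_areas()] object (status `"ok"`, `"no signal"`, or
#'   `"no standard"`).
#' @export
quantify_trace <- function(trace, expected_layout = peak_layout(),
                           window = 301L, prob = 0.1,
                           min_prominence = NULL) {
  bc <- baseline_correct(trace, window = window, prob = prob)
  pk <- detect_peaks(bc, min_prominence = min_prominence, channel = "sample")
  st <- detect_peaks(bc, min_prominence = min_prominence,
                     channel = "standard")
  assign_labels(pk, st, expected_layout, well = trace$well)
}

#' Quantify a directory of trace CSVs against a manifest
#'
#' Reads every non-missing well's trace, quantifies it, and returns the
#' peak-area table (one row per manifest position, missing wells passed
#' through with their status).
#'
#' @param dir Directory holding `<well>.csv` traces and `manifest.csv`
#'   (from [simulate_dataset()] or equivalent instrument exports).
#' @param expected_layout From [peak_layout()].
#' @param ... Passed to [quantify_trace()].
#' @return A peak-area table data.frame: `well`, `x_um`, `y_um`, `z_um`,
#'   `a_wt`, `a_mut`, `a_hd1`, `a_hd2`, `a_ss`, `status`.
#' @export
quantify_dir <- function(dir, expected_layout = peak_layout(), ...) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) {
    stop(sprintf("no manifest.csv in '%s'", dir), call. = FALSE)
  }
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    base <- manifest[i, c("well", "x_um", "y_um", "z_um")]
    if (isTRUE(manifest$missing[i])) {
      return(cbind(base, a_wt = NA_real_, a_mut = NA_real_,
                   a_hd1 = NA_real_, a_hd2 = NA_real_, a_ss = NA_real_,
                   status = "missing"))
    }
    tr <- read_trace_csv(file.path(dir, paste0(manifest$well[i], ".csv")),
                         well = manifest$well[i])
    pa <- quantify_trace(tr, expected_layout, ...)
    cbind(base, a_wt = pa$a_wt, a_mut = pa$a_mut, a_hd1 = pa$a_hd1,
          a_hd2 = pa$a_hd2, a_ss = pa$a_ss, status = pa$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
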