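#' Parameters of the synthetic CTCE trace generator
#'
#' The generator emulates the signal quantified by the pipeline: Gaussian
#' peaks for the double-stranded PCR products (wild type `wt`, homoduplex
#' mutant `mut`, the two heteroduplexes `hd1`/`hd2`), an optional
#' single-strand peak `ss`, and a separately dyed internal-standard peak
#' pair, on top of optional low-order baseline drift and white noise.
#'
#' Peak areas follow a random-reannealing model: after the final denature /
#' reanneal step a mutant strand fraction p pairs into homoduplexes and
#' heteroduplexes, so the noise-free areas are
#' `a_mut = (p - s*p*(1-p)) * gain`, `a_wt = (1 - p - s*p*(1-p)) * gain`
#' and `a_hd1 + a_hd2 = 2*s*p*(1-p) * gain`, where `s = hd_split` is the
#' fraction of cross pairings that survive as heteroduplex signal. For any
#' `hd_split` these satisfy the quantification identity
#' `(a_mut + (a_hd1 + a_hd2)/2) / (a_wt + a_mut + a_hd1 + a_hd2) = p`
#' exactly, so a noise-free trace round-trips through the quantifier.
#'
#' @param scan_length Number of scans per trace.
#' @param apex Named numeric: apex scan position per label (`wt`, `mut`,
#'   `hd1`, `hd2`, `ss`, plus `std1`, `std2` on the standard channel).
#' @param width Named numeric Gaussian sd (scans) per label; all > 0.
#'   Adjacent apexes on a channel must be separated by at least three widths
#'   so the peaks are resolvable.
#' @param signal_gain Total double-stranded product area in
#'   fluorescence x scan units per unit of template; also the effective
#'   count n entering the Wald interval.
#' @param noise_sd Baseline white-noise standard deviation (fluorescence
#'   units); >= 0.
#' @param baseline_drift Polynomial drift coefficients over the rescaled
#'   scan axis in \[0, 1\] (constant first).
#' @param hd_split Fraction of mutant-bearing cross pairings converted to
#'   heteroduplex signal, in \[0, 1\]; 1 is full random reannealing.
#' @param hd_balance Share of the heteroduplex area in `hd1` (the rest in
#'   `hd2`); default 0.5 splits the signal equally, matching the equal
#'   half-weighting of the two heteroduplex peaks in the fraction formula.
#' @param ss_frac Single-strand peak area as a fraction of `signal_gain`
#'   (excluded from quantification); 0 disables the peak.
#' @param standard_area Area of each internal-standard peak.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(scan_length = 1200L,
                         apex = c(std1 = 150, std2 = 210, wt = 400,
                                  mut = 450, hd1 = 510, hd2 = 560, ss = 650),
                         width = c(std1 = 6, std2 = 6, wt = 6, mut = 6,
                                   hd1 = 6, hd2 = 6, ss = 6),
                         signal_gain = 15000, noise_sd = 2.5,
                         baseline_drift = c(0, 0), hd_split = 1,
                         hd_balance = 0.5, ss_frac = 0.05,
                         standard_area = 5000) {
  stopifnot(scan_length >= 16, signal_gain > 0, noise_sd >= 0,
            standard_area > 0, ss_frac >= 0)
  check_unit_scalar(hd_split, "hd_split")
  check_unit_scalar(hd_balance, "hd_balance")
  need <- c("std1", "std2", "wt", "mut", "hd1", "hd2", "ss")
  if (!all(need %in% names(apex)) || !all(need %in% names(width))) {
    stop("`apex` and `width` must name all of: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(width <= 0)) stop("all peak widths must be > 0", call. = FALSE)
  for (channel in list(c("wt", "mut", "hd1", "hd2", "ss"),
                       c("std1", "std2"))) {
    a <- apex[channel]
    w <- width[channel]
    if (is.unsorted(a, strictly = TRUE)) {
      stop("peak apexes must be strictly increasing within a channel",
           call. = FALSE)
    }
    gap <- diff(a)
    lim <- 3 * pmax(w[-length(w)], w[-1])
    if (any(gap < lim)) {
      bad <- which(gap < lim)[1]
      stop(sprintf(
        "peaks %s and %s are %.3g scans apart; unresolvable (need >= %.3g)",
        channel[bad], channel[bad + 1], gap[bad], lim[bad]), call. = FALSE)
    }
  }
  if (any(apex < 1) || any(apex > scan_length)) {
    stop("peak apexes must lie inside the scan range", call. = FALSE)
  }
  structure(
    list(scan_length = as.integer(scan_length), apex = apex, width = width,
         signal_gain = signal_gain, noise_sd = noise_sd,
         baseline_drift = as.numeric(baseline_drift), hd_split = hd_split,
         hd_balance = hd_balance, ss_frac = ss_frac,
         standard_area = standard_area),
    class = "trace_params"
  )
}

# Noise-free peak areas implied by a true mutant fraction.
true_peak_areas <- function(true_fraction, params) {
  p <- true_fraction
  hd_tot <- params$hd_split * 2 * p * (1 - p)
  c(wt = (1 - p - hd_tot / 2) * params$signal_gain,
    mut = (p - hd_tot / 2) * params$signal_gain,
    hd1 = params$hd_balance * hd_tot * params$signal_gain,
    hd2 = (1 - params$hd_balance) * hd_tot * params$signal_gain,
    ss = params$ss_frac * params$signal_gain)
}

gaussian_peak <- function(scan, apex, width, area) {
  area * stats::dnorm(scan, mean = apex, sd = width)
}

#' Simulate one CTCE trace
#'
#' Builds the sample-dye channel from the noise-free areas implied by
#' `true_fraction` (see [trace_params()]) and the standard-dye channel from
#' the internal-standard peak pair, then adds polynomial baseline drift and
#' white noise. With `noise_sd = 0` and no drift the integrated areas
#' reproduce `true_fraction` exactly through the quantification formula.
#' Two calls with the same seed and parameters produce identical traces.
#'
#' @param true_fraction Mutant allele fraction in \[0, 1\].
#' @param params A [trace_params()].
#' @param seed Optional integer seed (see [derive_seed()]).
#' @param well,fragment Metadata passed to [ctce_trace()].
#' @return A `ctce_trace`; the generating areas are kept in
#'   `$meta$true_areas` and the fraction in `$meta$true_fraction`.
#' @export
simulate_trace <- function(true_fraction, params = trace_params(),
                           seed = NULL, well = NA_character_,
                           fragment = NA_character_) {
  check_unit_scalar(true_fraction, "true_fraction")
  stopifnot(inherits(params, "trace_params"))
  scan <- seq_len(params$scan_length)
  areas <- true_peak_areas(true_fraction, params)
  smp <- numeric(params$scan_length)
  for (lab in c("wt", "mut", "hd1", "hd2", "ss")) {
    if (areas[[lab]] > 0) {
      smp <- smp + gaussian_peak(scan, params$apex[[lab]],
                                 params$width[[lab]], areas[[lab]])
    }
  }
  std <- gaussian_peak(scan, params$apex[["std1"]], params$width[["std1"]],
                       params$standard_area) +
         gaussian_peak(scan, params$apex[["std2"]], params$width[["std2"]],
                       params$standard_area)
  s01 <- (scan - 1) / (params$scan_length - 1)
  drift <- numeric(params$scan_length)
  for (k in seq_along(params$baseline_drift)) {
    drift <- drift + params$baseline_drift[k] * s01^(k - 1)
  }
  noise <- with_seed(seed, {
    matrix(stats::rnorm(2 * params$scan_length, sd = params$noise_sd),
           ncol = 2)
  })
  ctce_trace(scan, smp + drift + noise[, 1], std + drift + noise[, 2],
             well = well, fragment = fragment,
             meta = list(true_fraction = true_fraction, true_areas = areas,
                         params = params))
}

#' Bernoulli sample dropout
#'
#' Emulates grid positions that yield no data (lost tissue, no tissue at the
#' collection point, or too few cells). Masked positions are carried forward
#' as explicit missing values, never silently removed.
#'
#' @param positions Position data.frame from [enumerate_positions()] (any
#'   data.frame works; only the row count is used).
#' @param dropout_prob Per-position dropout probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Logical vector, `TRUE` where the position is missing.
#' @export
apply_dropout <- function(positions, dropout_prob, seed = NULL) {
  check_unit_scalar(dropout_prob, "dropout_prob")
  n <- nrow(positions)
  with_seed(seed, stats::runif(n) < dropout_prob)
}

#' Simulate a full LCM/CTCE data set
#'
#' Samples a ground-truth [make_clone_field()] at every layout position,
#' applies dropout, simulates one trace per surviving position (child seeds
#' derived per well from the top-level seed, so any single well can be
#' regenerated in isolation), and optionally writes everything to disk as
#' one trace CSV per well plus a `manifest.csv`.
#'
#' @param field A [make_clone_field()].
#' @param layout A [grid_layout()]; positions falling outside the field
#'   extent are an error.
#' @param params A [trace_params()].
#' @param dropout_prob Dropout probability.
#' @param seed Top-level integer seed.
#' @param dir Output directory, or `NULL` to keep traces in memory.
#' @return A list with `manifest` (data.frame: well, block, row, col,
#'   z_index, x_um, y_um, z_um, true_fraction, missing) and `traces`
#'   (named list of `ctce_trace`, `NULL` for missing wells).
#' @export
simulate_dataset <- function(field, layout, params = trace_params(),
                             dropout_prob = 0.1, seed = 1L, dir = NULL) {
  stopifnot(inherits(field, "clone_field"), inherits(layout, "grid_layout"))
  pos <- enumerate_positions(layout)
  xyz <- as.matrix(pos[, c("x_um", "y_um", "z_um")])
  if (any(xyz[, 1] > field$extent_xyz[1]) ||
      any(xyz[, 2] > field$extent_xyz[2]) ||
      any(xyz[, 3] > field$extent_xyz[3])) {
    stop("layout positions extend beyond the clone-field extent",
         call. = FALSE)
  }
  pos$true_fraction <- eval_field(field, xyz)
  pos$missing <- apply_dropout(pos, dropout_prob,
                               seed = derive_seed(seed, "dropout"))
  traces <- stats::setNames(vector("list", nrow(pos)), pos$well)
  for (i in seq_len(nrow(pos))) {
    if (pos$missing[i]) next
    traces[[i]] <- simulate_trace(
      pos$true_fraction[i], params,
      seed = derive_seed(seed, "trace", i), well = pos$well[i])
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (w in pos$well[!pos$missing]) {
      write_trace_csv(traces[[w]], file.path(dir, paste0(w, ".csv")))
    }
    utils::write.csv(pos, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = pos, traces = traces)
}
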