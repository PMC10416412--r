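flat_trace <- function(n = 600, sample = 0, standard = 0) {
  ctce_trace(seq_len(n), rep_len(sample, n), rep_len(standard, n))
}

test_that("baseline correction removes offsets and drift, never adds signal", {
  # flat zero trace is untouched
  z <- baseline_correct(flat_trace())
  expect_equal(z$sample_channel, rep(0, 600))
  # constant offset: corrected areas match the un-offset trace within 1%
  p0 <- quiet_params()
  tr <- simulate_trace(0.2, p0, seed = 1)
  off <- tr
  off$sample_channel <- off$sample_channel + 50
  off$standard_channel <- off$standard_channel + 50
  a_ref <- quantify_trace(tr)
  a_off <- quantify_trace(off)
  for (lab in c("a_wt", "a_mut", "a_hd1", "a_hd2")) {
    expect_equal(a_off[[lab]], a_ref[[lab]], tolerance = 0.01)
  }
  # pure linear drift, no peaks: residual below a noise-sd equivalent
  n <- 1200
  drift <- 40 * (seq_len(n) - 1) / (n - 1)
  d <- ctce_trace(seq_len(n), drift, drift)
  r <- baseline_correct(d)
  mid <- 350:850 # interior: clear of the centered-window edge margins
  expect_lt(max(abs(r$sample_channel[mid])), 1)
  # correction never increases a channel value
  noisy <- simulate_trace(0.2, trace_params(), seed = 3)
  bc <- baseline_correct(noisy)
  expect_true(all(bc$sample_channel <= noisy$sample_channel + 1e-12))
  expect_error(baseline_correct(tr, window = 0), "window")
  expect_error(baseline_correct(tr, window = 5000), "shorter")
})

test_that("peak detection finds every resolvable peak and nothing in noise", {
  # noise-free 5-peak trace (wt, mut, hd1, hd2, ss)
  tr <- baseline_correct(simulate_trace(0.2, quiet_params(), seed = 1))
  pk <- detect_peaks(tr, min_prominence = 1)
  expect_equal(nrow(pk), 5)
  expect_equal(pk$apex, unname(quiet_params()$apex[c("wt", "mut", "hd1",
                                                     "hd2", "ss")]),
               tolerance = 1e-8)
  expect_true(all(diff(pk$apex) > 0))
  expect_true(all(pk$left < pk$apex & pk$apex < pk$right))
  # flat trace: empty list, not an error
  expect_equal(nrow(detect_peaks(flat_trace(), min_prominence = 1)), 0)
  # standard channel carries the internal-standard pair
  st <- detect_peaks(tr, min_prominence = 1, channel = "standard")
  expect_equal(st$apex, c(150, 210), tolerance = 1e-8)
})

test_that("merged peaks share a boundary and are flagged, not dropped", {
  n <- 400
  scan <- seq_len(n)
  two <- 100 * dnorm(scan, 200, 6) + 100 * dnorm(scan, 218, 6)
  tr <- ctce_trace(scan, two, rep(0, n))
  pk <- detect_peaks(tr, min_prominence = 1)
  expect_equal(nrow(pk), 2)
  expect_true(all(pk$merged))
  expect_equal(pk$right[1], pk$left[2]) # shared valley
})

test_that("label assignment follows the internal standard and logs ties", {
  p0 <- quiet_params()
  lay <- peak_layout(p0)
  tr <- baseline_correct(simulate_trace(0.3, p0, seed = 1))
  pa <- assign_labels(detect_peaks(tr, 1), detect_peaks(tr, 1, "standard"),
                      lay)
  truth <- simulate_trace(0.3, p0, seed = 1)$meta$true_areas
  expect_equal(pa$a_wt, truth[["wt"]], tolerance = 1e-3)
  expect_equal(pa$a_hd1, truth[["hd1"]], tolerance = 1e-3)
  expect_equal(pa$status, "ok")
  # wild-type-only trace stays quantifiable with explicit zero classes
  wt <- baseline_correct(simulate_trace(0, p0, seed = 1))
  pw <- assign_labels(detect_peaks(wt, 1), detect_peaks(wt, 1, "standard"),
                      lay)
  expect_equal(pw$status, "ok")
  expect_equal(c(pw$a_mut, pw$a_hd1, pw$a_hd2), c(0, 0, 0))
  expect_setequal(pw$absent, c("mut", "hd1", "hd2"))
  expect_equal(mutant_fraction(pw), 0)
  # no analyte peaks at all: an explicit missing record
  none <- assign_labels(empty <- detect_peaks(flat_trace(), 1),
                        detect_peaks(wt, 1, "standard"), lay)
  expect_equal(none$status, "no signal")
  # no internal standard: distinct failure mode
  expect_equal(assign_labels(detect_peaks(tr, 1),
                             detect_peaks(flat_trace(), 1), lay)$status,
               "no standard")
})

test_that("mutant fraction implements the half-weighted heteroduplex rule", {
  expect_equal(mutant_fraction(10000, 1000, 2000, 2000), 0.2)
  expect_equal(mutant_fraction(123.4, 0, 0, 0), 0)
  expect_equal(mutant_fraction(0, 57, 0, 0), 1)
  expect_equal(mutant_fraction(0, 0, 31, 31), 0.5)
  expect_error(mutant_fraction(0, 0, 0, 0), "not quantifiable")
  # scale invariance
  set.seed(4)
  for (i in 1:20) {
    a <- runif(4, 0, 1000)
    k <- runif(1, 0.01, 100)
    expect_equal(mutant_fraction(a[1], a[2], a[3], a[4]),
                 mutant_fraction(k * a[1], k * a[2], k * a[3], k * a[4]))
  }
  # monotone: non-decreasing in mutant area, non-increasing in wild type
  base <- mutant_fraction(100, 20, 10, 10)
  expect_gte(mutant_fraction(100, 25, 10, 10), base)
  expect_lte(mutant_fraction(120, 20, 10, 10), base)
})

test_that("end-to-end quantification reproduces noise-free ground truth", {
  p0 <- quiet_params()
  lay <- peak_layout(p0)
  for (p in c(0, 0.01, 0.05, 0.2, 0.5, 0.8, 1)) {
    pa <- quantify_trace(simulate_trace(p, p0, seed = 1), lay)
    expect_equal(pa$status, "ok")
    expect_equal(mutant_fraction(pa), p, tolerance = 1e-3)
  }
})

test_that("trace CSVs round-trip and directories quantify against manifests", {
  dir <- withr::local_tempdir()
  tr <- simulate_trace(0.2, quiet_params(), seed = 1, well = "B1-A01-Z1")
  write_trace_csv(tr, file.path(dir, "B1-A01-Z1.csv"))
  rt <- read_trace_csv(file.path(dir, "B1-A01-Z1.csv"))
  expect_equal(rt$sample_channel, tr$sample_channel)
  expect_equal(rt$well, "B1-A01-Z1")
  f <- make_clone_field(c(1000, 800, 10), background_fraction = 0.3)
  lay <- grid_layout(n_blocks = 1, rows = 2, cols = 3, z_planes = 0)
  sim <- simulate_dataset(f, lay, quiet_params(), dropout_prob = 0.4,
                          seed = 2, dir = dir2 <- withr::local_tempdir())
  tab <- quantify_dir(dir2, peak_layout(quiet_params()))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$status == "missing", sim$manifest$missing)
  ok <- tab$status == "ok"
  expect_equal((tab$a_mut[ok] + 0.5 * (tab$a_hd1[ok] + tab$a_hd2[ok])) /
                 (tab$a_wt[ok] + tab$a_mut[ok] + tab$a_hd1[ok] +
                    tab$a_hd2[ok]),
               rep(0.3, sum(ok)), tolerance = 1e-3)
})
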