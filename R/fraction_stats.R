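#' Normal-approximation screen for a proportion
#'
#' The usual rule of thumb before a Wald interval: both expected counts
#' `n * p_hat` and `n * (1 - p_hat)` must be at least 5. Symmetric under
#' `p_hat <-> 1 - p_hat`; a wild-type-only sample (`p_hat = 0`) always
#' fails the screen. Vectorized.
#'
#' @param p_hat Proportion(s) in \[0, 1\].
#' @param n_eff Effective count(s) > 0 — here the sum of the four
#'   double-stranded peak areas (the denominator of the proportion), used
#'   as a pseudo-count without rounding.
#' @return Logical vector.
#' @export
normality_check <- function(p_hat, n_eff) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1, na.rm = TRUE),
            all(n_eff > 0, na.rm = TRUE))
  n_eff * p_hat >= 5 & n_eff * (1 - p_hat) >= 5
}

#' Two-sided standard-normal quantile for a confidence level
#'
#' `z_quantile(0.95)` is 1.959964..., the margin multiplier of the standard
#' 95% interval (the spreadsheet `norm.s.inv((1 + level) / 2)`).
#'
#' @param level Confidence level in (0.5, 1).
#' @return The standard-normal quantile at `(1 + level) / 2`.
#' @export
z_quantile <- function(level) {
  if (!is.numeric(level) || any(level <= 0.5) || any(level >= 1)) {
    stop("`level` must lie in (0.5, 1)", call. = FALSE)
  }
  stats::qnorm((1 + level) / 2)
}

#' Wald confidence interval for a proportion
#'
#' The textbook normal-approximation limits
#' \deqn{\hat p \mp z \sqrt{\hat p (1 - \hat p) / n},}
#' clipped into \[0, 1\]. Degenerate at `p_hat` of 0 or 1 (zero width).
#' Vectorized over `p_hat` / `n_eff`.
#'
#' @inheritParams normality_check
#' @param level Confidence level (default 0.95).
#' @return A two-column matrix `ci_low`, `ci_high`.
#' @examples
#' wald_ci(0.5, 100)            # about (0.402, 0.598)
#' wald_ci(0.2, 15000)[, 1] > 0 # TRUE: the interval excludes 0
#' @export
wald_ci <- function(p_hat, n_eff, level = 0.95) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1, na.rm = TRUE),
            all(n_eff > 0, na.rm = TRUE))
  z <- z_quantile(level)
  half <- z * sqrt(p_hat * (1 - p_hat) / n_eff)
  cbind(ci_low = pmax(p_hat - half, 0), ci_high = pmin(p_hat + half, 1))
}

#' Estimate mutant fractions with confidence intervals for a peak-area table
#'
#' Applies the mutant-fraction formula, the normality screen and the Wald
#' interval to every quantifiable row of a peak-area table. `n_eff` is the
#' raw area sum (fluorescence x scan units) used as a pseudo-count, exactly
#' as the denominator of the proportion; it is surfaced in the output so
#' its adequacy can be judged. Missing rows pass through with their status;
#' normality failures are reported (`normality_ok = FALSE`), not dropped —
#' a wild-type-only sample maps as fraction 0 with a degenerate \[0, 0\]
#' interval. Rows whose four areas are all zero but carry status `"ok"`
#' are demoted to status `"not quantifiable"`.
#'
#' @param peak_table Data.frame with columns `well`, `a_wt`, `a_mut`,
#'   `a_hd1`, `a_hd2` and `status` (coordinate columns `x_um`, `y_um`,
#'   `z_um` are carried through when present).
#' @param level Confidence level.
#' @return The fraction table: `well` (+ coordinates), `p_hat`, `n_eff`,
#'   `ci_low`, `ci_high`, `normality_ok`, `status`; one row per input row.
#' @export
estimate_all <- function(peak_table, level = 0.95) {
  need <- c("well", "a_wt", "a_mut", "a_hd1", "a_hd2", "status")
  missing_cols <- setdiff(need, names(peak_table))
  if (length(missing_cols)) {
    stop("peak-area table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  area_cols <- c("a_wt", "a_mut", "a_hd1", "a_hd2")
  ok <- peak_table$status == "ok"
  bad <- ok & (rowSums(is.na(peak_table[, area_cols])) > 0 |
               rowSums(peak_table[, area_cols], na.rm = TRUE) <= 0)
  if (any(bad, na.rm = TRUE)) {
    peak_table$status[which(bad)] <- "not quantifiable"
    ok <- peak_table$status == "ok"
  }
  keep <- intersect(c("well", "x_um", "y_um", "z_um"), names(peak_table))
  out <- peak_table[, keep, drop = FALSE]
  out$p_hat <- NA_real_
  out$n_eff <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  out$normality_ok <- NA
  out$status <- peak_table$status
  if (any(ok)) {
    a <- peak_table[ok, area_cols]
    n_eff <- rowSums(a)
    p_hat <- (a$a_mut + 0.5 * (a$a_hd1 + a$a_hd2)) / n_eff
    ci <- wald_ci(p_hat, n_eff, level)
    out$p_hat[ok] <- p_hat
    out$n_eff[ok] <- n_eff
    out$ci_low[ok] <- ci[, 1]
    out$ci_high[ok] <- ci[, 2]
    out$normality_ok[ok] <- normality_check(p_hat, n_eff)
  }
  rownames(out) <- NULL
  out
}
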