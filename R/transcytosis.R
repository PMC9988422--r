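#' Saturation check on a dose-uptake curve
#'
#' Receptor-mediated binding/uptake saturates: the dose-response slope
#' falls off at high ligand doses, whereas passive uptake stays linear.
#' Fits separate least-squares slopes to the doses strictly below and at or
#' above `breakpoint` and compares them through the relative slope drop
#' `1 - slope_high / slope_low`. The default breakpoint of 2400 pmol is
#' where transferrin dose-uptake curves in transwell BBB models have been
#' observed to bend; it is a parameter, not an estimate (no binding model
#' is fitted, so no Kd is produced).
#'
#' @param dose_pmol applied ligand doses, strictly increasing (pmol).
#' @param response matched uptake/transport measurements (arbitrary units,
#'   >= 0), same length as `dose_pmol`.
#' @param breakpoint dose splitting the low- and high-dose ranges (pmol).
#' @param drop_threshold relative slope drop above which the curve is
#'   called saturable (default 0.2).
#' @return Object of class `saturation_verdict`: `slope_low`, `slope_high`,
#'   `breakpoint`, `relative_slope_drop`, `verdict` (`"saturable"` or
#'   `"linear"`), `flags`.
#' @export
saturation_check <- function(dose_pmol, response, breakpoint = 2400,
                             drop_threshold = 0.2) {
  dose_pmol <- as.numeric(dose_pmol)
  response <- as.numeric(response)
  if (length(dose_pmol) != length(response)) {
    stop("dose_pmol and response must have equal length", call. = FALSE)
  }
  if (any(diff(dose_pmol) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (any(response < 0)) stop("responses must be >= 0", call. = FALSE)
  check_number(breakpoint, "breakpoint", positive = TRUE)
  low <- dose_pmol < breakpoint
  if (sum(low) < 2L || sum(!low) < 2L) {
    stop(sprintf(
      "need >= 2 doses below and >= 2 at/above the %g pmol breakpoint",
      breakpoint), call. = FALSE)
  }
  ls_slope <- function(x, y) {
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  slope_low <- ls_slope(dose_pmol[low], response[low])
  slope_high <- ls_slope(dose_pmol[!low], response[!low])
  flags <- character()
  if (all(response == 0)) flags <- c(flags, "zero_signal")
  drop <- if (slope_low > 0) 1 - slope_high / slope_low else NA_real_
  verdict <- if (!is.na(drop) && drop > drop_threshold) "saturable"
             else "linear"
  structure(
    list(slope_low = slope_low, slope_high = slope_high,
         breakpoint = breakpoint, relative_slope_drop = drop,
         drop_threshold = drop_threshold, verdict = verdict, flags = flags),
    class = "saturation_verdict"
  )
}

#' @export
print.saturation_verdict <- function(x, ...) {
  cat(sprintf(
    "Dose-uptake saturation: slopes %.4g -> %.4g beyond %g pmol (drop %s) => %s\n",
    x$slope_low, x$slope_high, x$breakpoint,
    if (is.na(x$relative_slope_drop)) "NA"
    else sprintf("%.0f%%", 100 * x$relative_slope_drop), x$verdict))
  invisible(x)
}

#' Competition test for receptor-mediated transport
#'
#' Labeled-ligand transport with and without an excess of unlabeled
#' competitor. Receptor-mediated transcytosis is competitively inhibitable,
#' so the labeled signal must fall when the competitor occupies the
#' receptor; passive transport is unchanged. Verdict: `rmt_consistent` iff
#' the with-competitor/alone mean ratio is < 1 AND the two-arm Student
#' t-test is significant at `alpha`; any ratio >= 1 is `not_rmt` regardless
#' of p.
#'
#' @param alone transported-amount replicates, labeled ligand alone (>= 2).
#' @param with_competitor transported-amount replicates with the unlabeled
#'   competitor present (>= 2).
#' @param alpha significance level (default 0.05).
#' @return Object of class `competition_verdict`: `transport_ratio`,
#'   `p_value`, `alpha`, `verdict` (`"rmt_consistent"` or `"not_rmt"`).
#' @export
competition_test <- function(alone, with_competitor, alpha = 0.05) {
  alone <- as.numeric(alone)
  with_competitor <- as.numeric(with_competitor)
  if (length(alone) < 2L || length(with_competitor) < 2L) {
    stop("need >= 2 replicates in each arm", call. = FALSE)
  }
  if (any(alone < 0) || any(with_competitor < 0)) {
    stop("transported amounts must be >= 0", call. = FALSE)
  }
  check_number(alpha, "alpha", positive = TRUE)
  if (mean(alone) <= 0) {
    stop("alone-arm mean must be > 0 to form a transport ratio",
         call. = FALSE)
  }
  tt <- student_t2(alone, with_competitor)
  ratio <- mean(with_competitor) / mean(alone)
  verdict <- if (ratio < 1 && tt$p < alpha) "rmt_consistent" else "not_rmt"
  structure(
    list(transport_ratio = ratio, p_value = tt$p, t = tt$t, alpha = alpha,
         verdict = verdict),
    class = "competition_verdict"
  )
}

#' @export
print.competition_verdict <- function(x, ...) {
  cat(sprintf(
    "Competition test: with/without ratio %.2f, p = %.3g => %s\n",
    x$transport_ratio, x$p_value, x$verdict))
  invisible(x)
}
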