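#' Efflux ratio
#'
#' `ER = Pe(B to A) / Pe(A to B)`. ER > 1 indicates net
#' basolateral-to-apical transport, the signature of an apically polarized
#' efflux pump such as P-gp or BCRP.
#'
#' @param pe_a2b apical-to-basolateral permeability (1e-6 cm/s), > 0.
#' @param pe_b2a basolateral-to-apical permeability (1e-6 cm/s), > 0.
#' @return The unitless efflux ratio.
#' @examples
#' efflux_ratio(17.6, 28.1)   # 1.60
#' @export
efflux_ratio <- function(pe_a2b, pe_b2a) {
  if (any(pe_a2b <= 0) || any(pe_b2a <= 0)) {
    stop("both permeabilities must be > 0", call. = FALSE)
  }
  pe_b2a / pe_a2b
}

#' One bidirectional experiment
#'
#' A single independent experiment's directional Pe pair, its efflux ratio
#' and (when replicate-level data allow a test) the two-tailed significance
#' of the A2B/B2A difference, marked `**` for p < 0.01, `*` for p < 0.05.
#'
#' @param experiment experiment label.
#' @param pe_a2b,pe_b2a directional permeabilities (1e-6 cm/s), > 0.
#' @param p_value optional p-value from [directional_test()]; the
#'   significance mark is derived from it.
#' @return Object of class `efflux_experiment`.
#' @export
efflux_experiment <- function(experiment, pe_a2b, pe_b2a, p_value = NULL) {
  check_number(pe_a2b, "pe_a2b", positive = TRUE)
  check_number(pe_b2a, "pe_b2a", positive = TRUE)
  if (!is.null(p_value)) {
    check_number(p_value, "p_value", nonneg = TRUE)
    stopifnot(p_value <= 1)
  }
  structure(
    list(experiment = as.character(experiment),
         pe_a2b = pe_a2b, pe_b2a = pe_b2a,
         er = efflux_ratio(pe_a2b, pe_b2a),
         p_value = p_value,
         mark = if (is.null(p_value)) "none" else p_mark(p_value)),
    class = "efflux_experiment"
  )
}

#' Aggregate efflux ratios over independent experiments
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-experiment ER values. With a single experiment the SD is undefined
#' and left absent. Values are kept at full precision; rounding (1 decimal,
#' the conventional reporting precision) happens only in report output.
#'
#' @param experiments list of [efflux_experiment()] objects (n >= 1).
#' @param substrate substrate label.
#' @param transporter transporter assigned to the substrate
#'   (e.g. `"P-gp"`, `"BCRP"`, `"Glut1"`, `"TfR"`).
#' @return Object of class `efflux_result`: `experiments`, `er_mean`,
#'   `er_sd` (NULL when n = 1), `n`.
#' @export
aggregate_er <- function(experiments, substrate = NA_character_,
                         transporter = NA_character_) {
  if (length(experiments) == 0L) {
    stop("need at least one experiment", call. = FALSE)
  }
  stopifnot(all(vapply(experiments, inherits, TRUE, "efflux_experiment")))
  ers <- vapply(experiments, `[[`, numeric(1), "er")
  structure(
    list(substrate = as.character(substrate),
         transporter = as.character(transporter),
         experiments = experiments,
         er_mean = mean(ers),
         er_sd = if (length(ers) >= 2L) stats::sd(ers) else NULL,
         n = length(ers)),
    class = "efflux_result"
  )
}

#' Efflux result from summary statistics only
#'
#' Builds an `efflux_result` from a published mean +/- SD when the
#' per-experiment Pe pairs are not available (e.g. a partner facility
#' reporting only summaries). Such records carry no experiments and no
#' classification evidence; [compare_facilities()] accepts them.
#'
#' @param substrate,transporter labels.
#' @param er_mean,er_sd,n the reported summary.
#' @return Object of class `efflux_result` with empty `experiments`.
#' @export
efflux_summary <- function(substrate, er_mean, er_sd, n,
                           transporter = NA_character_) {
  check_number(er_mean, "er_mean", positive = TRUE)
  check_number(er_sd, "er_sd", nonneg = TRUE)
  check_number(n, "n", positive = TRUE)
  structure(
    list(substrate = as.character(substrate),
         transporter = as.character(transporter),
         experiments = list(), er_mean = er_mean, er_sd = er_sd,
         n = as.integer(n)),
    class = "efflux_result"
  )
}

#' @export
print.efflux_result <- function(x, ...) {
  sd_txt <- if (is.null(x$er_sd)) "NA" else sprintf("%.1f", x$er_sd)
  cat(sprintf("%s (%s): ER = %.1f +/- %s (n = %d)\n",
              x$substrate, x$transporter, x$er_mean, sd_txt, x$n))
  invisible(x)
}

#' Directional significance test
#'
#' Two-sample equal-variance (Student) two-tailed t-test between the A2B
#' and B2A replicate values of one experiment, with the conventional
#' significance marks (`*` p < 0.05, `**` p < 0.01).
#'
#' @param a2b_replicates,b2a_replicates numeric vectors, >= 2 values each
#'   (replicate Pe values or transported amounts).
#' @return List with `t`, `p` (two-tailed) and `mark`.
#' @export
directional_test <- function(a2b_replicates, b2a_replicates) {
  res <- student_t2(a2b_replicates, b2a_replicates)
  list(t = res$t, p = res$p, mark = p_mark(res$p))
}

#' Classify whether efflux transport is functionally demonstrated
#'
#' Decision rule over an aggregated efflux result. Default policy: efflux is
#' `efflux_functional` iff the mean ER exceeds `er_threshold` (default 1)
#' AND at least `min_significant_fraction` (default 1/2) of the experiments
#' individually show `pe_b2a > pe_a2b` with a significance mark. Otherwise
#' `not_demonstrated`. The thresholds are configurable because no community
#' consensus cutoff exists for transwell BBB models.
#'
#' @param result an `efflux_result` with n >= 2 experiments.
#' @param er_threshold minimum mean ER.
#' @param min_significant_fraction minimum fraction of experiments that are
#'   individually significant in the efflux direction.
#' @return `"efflux_functional"` or `"not_demonstrated"`.
#' @export
classify_transporter <- function(result, er_threshold = 1,
                                 min_significant_fraction = 0.5) {
  stopifnot(inherits(result, "efflux_result"))
  if (result$n < 2L || length(result$experiments) < 2L) {
    stop("classification needs >= 2 experiments with per-experiment data",
         call. = FALSE)
  }
  sig_efflux <- vapply(result$experiments, function(e) {
    e$pe_b2a > e$pe_a2b && e$mark != "none"
  }, logical(1))
  ok <- result$er_mean > er_threshold &&
    mean(sig_efflux) >= min_significant_fraction
  if (ok) "efflux_functional" else "not_demonstrated"
}

#' Efflux results from a replicate-level permeability table
#'
#' Groups a table from [analyze_permeability()] by substrate and
#' experiment, averages replicate Pe within each direction, tests the
#' directional difference on the replicate values ([directional_test()]
#' where both directions have >= 2 usable replicates), and aggregates
#' per-substrate ER summaries. Flagged replicates (no usable Pe) are
#' dropped from the averages.
#'
#' @param pe_table data.frame from [analyze_permeability()].
#' @param transporters optional named character vector mapping substrate to
#'   transporter label.
#' @return Named list of `efflux_result`, one per substrate having both
#'   directions in at least one experiment.
#' @export
efflux_from_pe_table <- function(pe_table, transporters = NULL) {
  stopifnot(is.data.frame(pe_table))
  usable <- pe_table[!is.na(pe_table$pe_1e6_cm_s), , drop = FALSE]
  out <- list()
  for (s in unique(usable$substrate)) {
    sub <- usable[usable$substrate == s, , drop = FALSE]
    experiments <- list()
    for (e in unique(sub$experiment)) {
      g <- sub[sub$experiment == e, , drop = FALSE]
      a2b <- g$pe_1e6_cm_s[g$direction == "A2B"]
      b2a <- g$pe_1e6_cm_s[g$direction == "B2A"]
      if (length(a2b) == 0L || length(b2a) == 0L) next
      p <- if (length(a2b) >= 2L && length(b2a) >= 2L) {
        directional_test(a2b, b2a)$p
      } else NULL
      experiments[[length(experiments) + 1L]] <-
        efflux_experiment(e, mean(a2b), mean(b2a), p_value = p)
    }
    if (length(experiments) == 0L) next
    tr <- if (!is.null(transporters) && s %in% names(transporters)) {
      transporters[[s]]
    } else NA_character_
    out[[s]] <- aggregate_er(experiments, substrate = s, transporter = tr)
  }
  out
}
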