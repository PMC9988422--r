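#' Benchmark item identifiers
#'
#' The minimal essential benchmark items for BBB-likeness of a transwell
#' model: endothelial identity (CD31), tight-junction protein expression
#' and localization (ZO-1, claudin-5), functional tightness (permeable vs
#' non-permeable tracer), TEER, and expression plus function of the
#' transporters P-gp, BCRP, Glut1 and the transferrin receptor.
#'
#' @return Character vector of item ids.
#' @export
benchmark_items <- function() {
  c("cd31_expression",
    "zo1_expression_localization",
    "claudin5_expression_localization",
    "tightness_ly_caffeine",
    "teer_measured",
    "pgp_expression", "pgp_function",
    "bcrp_expression", "bcrp_function",
    "glut1_expression", "glut1_function",
    "tfr_expression", "tfr_function_rmt")
}

.item_row <- function(item_id, status, evidence) {
  stopifnot(status %in% c("pass", "fail", "not_assessed"))
  if (status == "pass" && (!nzchar(evidence) || is.na(evidence))) {
    stop("a pass status requires evidence", call. = FALSE)
  }
  data.frame(item_id = item_id, status = status, evidence = evidence)
}

#' Functional tight-junction check from tracer permeabilities
#'
#' A tight barrier discriminates a freely diffusing tracer (e.g. caffeine)
#' from a paracellularly excluded one (e.g. Lucifer Yellow): the item
#' passes iff the permeable tracer's mean Pe exceeds the non-permeable
#' tracer's and the difference is significant by Student's t-test at
#' `alpha`. With fewer than 2 values in either group the item is
#' `not_assessed`, never silently passed.
#'
#' @param pe_nonpermeable Pe replicates of the non-permeable tracer
#'   (1e-6 cm/s).
#' @param pe_permeable Pe replicates of the permeable tracer.
#' @param alpha significance level.
#' @return A one-row benchmark-item data.frame (`item_id`
#'   `"tightness_ly_caffeine"`).
#' @export
tightness_check <- function(pe_nonpermeable, pe_permeable, alpha = 0.05) {
  pe_nonpermeable <- as.numeric(pe_nonpermeable)
  pe_permeable <- as.numeric(pe_permeable)
  if (length(pe_nonpermeable) < 2L || length(pe_permeable) < 2L) {
    return(.item_row("tightness_ly_caffeine", "not_assessed",
                     "fewer than 2 Pe values in a tracer group"))
  }
  tt <- student_t2(pe_permeable, pe_nonpermeable)
  ok <- mean(pe_permeable) > mean(pe_nonpermeable) && tt$p < alpha
  ev <- sprintf(
    "mean Pe permeable %.1f vs non-permeable %.1f (1e-6 cm/s), p = %.3g",
    mean(pe_permeable), mean(pe_nonpermeable), tt$p)
  .item_row("tightness_ly_caffeine", if (ok) "pass" else "fail", ev)
}

.function_item <- function(item_id, efflux_results, transporter,
                           er_threshold, min_significant_fraction) {
  hits <- Filter(function(r) identical(r$transporter, transporter),
                 efflux_results)
  classifiable <- Filter(function(r) {
    r$n >= 2L && length(r$experiments) >= 2L
  }, hits)
  if (length(classifiable) == 0L) {
    return(.item_row(item_id, "not_assessed",
                     sprintf("no classifiable efflux result for %s",
                             transporter)))
  }
  cls <- vapply(classifiable, classify_transporter, "",
                er_threshold = er_threshold,
                min_significant_fraction = min_significant_fraction)
  ev <- paste(vapply(seq_along(classifiable), function(i) {
    r <- classifiable[[i]]
    sprintf("%s: ER %.1f +/- %s (n=%d) -> %s", r$substrate, r$er_mean,
            if (is.null(r$er_sd)) "NA" else sprintf("%.1f", r$er_sd),
            r$n, cls[i])
  }, ""), collapse = "; ")
  status <- if (any(cls == "efflux_functional")) "pass" else "fail"
  .item_row(item_id, status, ev)
}

#' Assemble the benchmark scorecard
#'
#' One row per benchmark item. Function items are wired to quantitative
#' results ([classify_transporter()], [tightness_check()],
#' [competition_test()]); expression/localization items rest on declared
#' qualitative wet-lab evidence (Western blot, immunostaining), recorded as
#' booleans with a provenance note. Missing inputs degrade to
#' `not_assessed` — never silently to `pass` — and no item can pass without
#' attached evidence.
#'
#' @param efflux_results list of `efflux_result` objects (any substrates).
#' @param tightness one-row data.frame from [tightness_check()], or `NULL`.
#' @param competition a `competition_verdict` from [competition_test()] for
#'   the transferrin assay, or `NULL`.
#' @param teer_values numeric TEER values (Ohm cm^2), or `NULL`. TEER is
#'   reported as measured evidence; no pass threshold is imposed.
#' @param declared_evidence named list for the expression/localization
#'   items: each element `TRUE`/`FALSE` or `list(observed =, note =)`.
#'   Names must be item ids.
#' @param er_threshold,min_significant_fraction forwarded to
#'   [classify_transporter()].
#' @return A data.frame of class `benchmark_report`: `item_id`, `status`,
#'   `evidence`.
#' @export
build_report <- function(efflux_results = list(), tightness = NULL,
                         competition = NULL, teer_values = NULL,
                         declared_evidence = list(),
                         er_threshold = 1, min_significant_fraction = 0.5) {
  rows <- list()

  declared_item <- function(item_id) {
    d <- declared_evidence[[item_id]]
    if (is.null(d)) {
      return(.item_row(item_id, "not_assessed", "no declared evidence"))
    }
    if (is.logical(d)) d <- list(observed = d, note = "user-declared")
    .item_row(item_id, if (isTRUE(d$observed)) "pass" else "fail",
              paste0("declared: ", d$note %||% "user-declared"))
  }
  for (id in c("cd31_expression", "zo1_expression_localization",
               "claudin5_expression_localization", "pgp_expression",
               "bcrp_expression", "glut1_expression", "tfr_expression")) {
    rows[[id]] <- declared_item(id)
  }

  rows[["tightness_ly_caffeine"]] <- if (is.null(tightness)) {
    .item_row("tightness_ly_caffeine", "not_assessed", "no tracer Pe data")
  } else tightness

  rows[["teer_measured"]] <- if (is.null(teer_values) ||
                                 !length(teer_values)) {
    .item_row("teer_measured", "not_assessed", "no TEER readings")
  } else {
    .item_row("teer_measured", "pass",
              sprintf("TEER measured: mean %.1f Ohm cm^2 (n=%d)",
                      mean(teer_values), length(teer_values)))
  }

  rows[["pgp_function"]] <- .function_item(
    "pgp_function", efflux_results, "P-gp",
    er_threshold, min_significant_fraction)
  rows[["bcrp_function"]] <- .function_item(
    "bcrp_function", efflux_results, "BCRP",
    er_threshold, min_significant_fraction)
  rows[["glut1_function"]] <- .function_item(
    "glut1_function", efflux_results, "Glut1",
    er_threshold, min_significant_fraction)

  rows[["tfr_function_rmt"]] <- if (is.null(competition)) {
    .item_row("tfr_function_rmt", "not_assessed", "no competition assay")
  } else {
    stopifnot(inherits(competition, "competition_verdict"))
    ev <- sprintf(
      "competition: with/without ratio %.2f, p = %.3g -> %s",
      competition$transport_ratio, competition$p_value, competition$verdict)
    .item_row("tfr_function_rmt",
              if (competition$verdict == "rmt_consistent") "pass" else "fail",
              ev)
  }

  out <- do.call(rbind, rows[benchmark_items()])
  rownames(out) <- NULL
  class(out) <- c("benchmark_report", "data.frame")
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("BBB benchmark scorecard\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-34s %-12s %s\n", x$item_id[i], x$status[i],
                strtrim(x$evidence[i], 60)))
  }
  invisible(x)
}

#' Compare efflux results between two facilities
#'
#' Default agreement rule: the `mean +/- SD` intervals of the two ER
#' summaries overlap, and — when both sides carry per-experiment data —
#' their [classify_transporter()] classifications match. Summary-only
#' records (e.g. [efflux_summary()]) are compared on interval overlap
#' alone. The rule is a convention, surfaced in the `criterion` field, not
#' a hypothesis test: published summaries rarely allow one.
#'
#' @param r1,r2 `efflux_result` records for the same substrate.
#' @param er_threshold,min_significant_fraction forwarded to
#'   [classify_transporter()] when both records have per-experiment data.
#' @return List of class `facility_comparison`: `substrate`, `agree`,
#'   `criterion`, `interval1`, `interval2`, `classifications`.
#' @export
compare_facilities <- function(r1, r2, er_threshold = 1,
                               min_significant_fraction = 0.5) {
  stopifnot(inherits(r1, "efflux_result"), inherits(r2, "efflux_result"))
  if (!identical(r1$substrate, r2$substrate)) {
    stop(sprintf("substrate mismatch: %s vs %s", r1$substrate, r2$substrate),
         call. = FALSE)
  }
  iv <- function(r) {
    sd <- r$er_sd %||% 0
    c(r$er_mean - sd, r$er_mean + sd)
  }
  i1 <- iv(r1); i2 <- iv(r2)
  overlap <- i1[1] <= i2[2] && i2[1] <= i1[2]
  both_classifiable <- length(r1$experiments) >= 2L &&
    length(r2$experiments) >= 2L
  cls <- NULL
  cls_match <- TRUE
  if (both_classifiable) {
    cls <- c(classify_transporter(r1, er_threshold, min_significant_fraction),
             classify_transporter(r2, er_threshold, min_significant_fraction))
    cls_match <- cls[1] == cls[2]
  }
  criterion <- paste0(
    "ER mean +/- SD intervals overlap",
    if (both_classifiable) " and transporter classifications match"
    else " (summary-only records: classification clause not applicable)")
  structure(
    list(substrate = r1$substrate, agree = overlap && cls_match,
         criterion = criterion, interval1 = i1, interval2 = i2,
         classifications = cls),
    class = "facility_comparison"
  )
}

#' @export
print.facility_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: [%.2f, %.2f] vs [%.2f, %.2f] -> %s\n  rule: %s\n",
    x$substrate, x$interval1[1], x$interval1[2], x$interval2[1],
    x$interval2[2], if (x$agree) "agree" else "disagree", x$criterion))
  invisible(x)
}
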