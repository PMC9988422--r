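#' Cleared (donor-equivalent) volume
#'
#' The volume of donor solution whose substrate content has appeared in the
#' receiver compartment: `receiver_conc * receiver_volume / donor_conc` (uL).
#' Because only the concentration ratio enters, any consistent concentration
#' unit may be used. Plotted against time, cleared volume grows with slope
#' PS, the permeability-surface area product of the barrier.
#'
#' @param receiver_conc receiver-compartment concentration (amount/uL).
#' @param receiver_volume receiver-compartment volume `[R]` (uL).
#' @param donor_conc donor-compartment concentration (amount/uL), > 0.
#' @return Cleared volume in uL.
#' @examples
#' cleared_volume(1, 600, 10)   # 60 uL
#' @export
cleared_volume <- function(receiver_conc, receiver_volume, donor_conc) {
  if (any(!is.finite(donor_conc)) || any(donor_conc <= 0)) {
    stop("donor_conc must be > 0", call. = FALSE)
  }
  check_number(receiver_volume, "receiver_volume", positive = TRUE)
  if (any(receiver_conc < 0)) {
    stop("receiver_conc must be >= 0", call. = FALSE)
  }
  receiver_conc * receiver_volume / donor_conc
}

#' Fit the permeability-surface area product (PS) from cleared volumes
#'
#' Ordinary least-squares slope of cleared volume (uL) against time (min)
#' with a free intercept, so an early-time lag does not bias PS; the
#' intercept is kept as a diagnostic. A non-positive slope marks the fit
#' unusable (flag `"nonpositive_slope"`) rather than erroring: downstream
#' stages refuse unusable fits explicitly.
#'
#' @param time_min sampling times in minutes (>= 2 distinct values).
#' @param cleared_uL cleared volumes at those times.
#' @param condition `"total"` (cell-bearing insert), `"membrane"` (blank
#'   insert) or `"corrected"`.
#' @return Object of class `ps_fit`: `value` (uL/min), `condition`,
#'   `intercept`, `fit_r2`, `n_points`, `usable`, `flags`.
#' @export
fit_ps <- function(time_min, cleared_uL,
                   condition = c("total", "membrane", "corrected")) {
  condition <- match.arg(condition)
  time_min <- as.numeric(time_min)
  cleared_uL <- as.numeric(cleared_uL)
  keep <- is.finite(time_min) & is.finite(cleared_uL)
  time_min <- time_min[keep]
  cleared_uL <- cleared_uL[keep]
  if (length(time_min) < 2L || length(unique(time_min)) < 2L) {
    stop("need at least 2 points with distinct times to fit PS",
         call. = FALSE)
  }
  fit <- stats::lm(cleared_uL ~ time_min)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((cleared_uL - mean(cleared_uL))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  flags <- character()
  usable <- TRUE
  if (slope <= 0) {
    flags <- c(flags, "nonpositive_slope")
    usable <- FALSE
  }
  structure(
    list(value = slope, condition = condition,
         intercept = unname(stats::coef(fit)[1]),
         fit_r2 = r2, n_points = length(time_min),
         usable = usable, flags = flags),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("PS (%s): %.4g uL/min, r2 = %.4f, n = %d%s\n",
              x$condition, x$value, x$fit_r2, x$n_points,
              if (x$usable) "" else "  [UNUSABLE]"))
  invisible(x)
}

#' Blank-membrane correction of PS
#'
#' The cell layer and the insert membrane are barriers in series, so their
#' clearances add reciprocally: `1/PS_e = 1/PS_total - 1/PS_mem`. Requires
#' `PS_total < PS_mem`; cells on a membrane cannot make the composite
#' barrier leakier than the bare membrane, so equality or reversal flags an
#' inconsistent replicate (exclude it, never clamp).
#'
#' @param ps_total `ps_fit` with condition `"total"` (cell-bearing insert).
#' @param ps_mem `ps_fit` with condition `"membrane"` (blank insert).
#' @return A `ps_fit` with condition `"corrected"` and the cell-layer PS_e.
#' @export
correct_for_membrane <- function(ps_total, ps_mem) {
  stopifnot(inherits(ps_total, "ps_fit"), inherits(ps_mem, "ps_fit"))
  if (ps_total$condition != "total" || ps_mem$condition != "membrane") {
    stop("expected condition tags `total` and `membrane`", call. = FALSE)
  }
  if (!ps_total$usable) {
    stop("PS_total fit is unusable (", paste(ps_total$flags, collapse = ","),
         ")", call. = FALSE)
  }
  if (!ps_mem$usable) {
    stop("PS_mem fit is unusable (", paste(ps_mem$flags, collapse = ","),
         ")", call. = FALSE)
  }
  if (ps_total$value >= ps_mem$value) {
    stop(sprintf(
      "inconsistent fits: PS_total (%.4g) >= PS_mem (%.4g); %s",
      ps_total$value, ps_mem$value,
      "the cell-bearing insert cannot be leakier than the blank membrane"),
      call. = FALSE)
  }
  value <- 1 / (1 / ps_total$value - 1 / ps_mem$value)
  structure(
    list(value = value, condition = "corrected", intercept = NA_real_,
         fit_r2 = NA_real_,
         n_points = min(ps_total$n_points, ps_mem$n_points),
         usable = TRUE, flags = character()),
    class = "ps_fit"
  )
}

# (uL/min)/cm^2 -> 1e-6 cm/s: 1 uL = 1e-3 cm^3 and 1 min = 60 s, so
# 1 (uL/min)/cm^2 = 1e-3/60 cm/s = (1000/60) x 1e-6 cm/s
.PE_UNIT_FACTOR <- 1000 / 60

#' Permeability coefficient from a corrected PS
#'
#' Divides PS_e by the membrane surface area and converts the result to the
#' conventional reporting unit: `pe = PS_e / S * 1000/60` in 1e-6 cm/s.
#'
#' @param ps_e usable `ps_fit`, normally condition `"corrected"`
#'   (`"total"` is accepted when membrane correction is disabled).
#' @param geometry an [insert_geometry()].
#' @param substrate,direction,experiment,replicate labels carried through to
#'   the result.
#' @return Object of class `pe_result` with `pe` in 1e-6 cm/s and
#'   `corrected` indicating whether the blank-membrane correction was
#'   applied.
#' @export
pe_from_ps <- function(ps_e, geometry, substrate = NA_character_,
                       direction = NA_character_, experiment = NA_character_,
                       replicate = NA_character_) {
  stopifnot(inherits(ps_e, "ps_fit"), inherits(geometry, "insert_geometry"))
  if (!ps_e$usable) {
    stop("PS fit is unusable (", paste(ps_e$flags, collapse = ","), ")",
         call. = FALSE)
  }
  if (ps_e$condition == "membrane") {
    stop("refusing to report Pe for a blank-membrane fit", call. = FALSE)
  }
  pe <- ps_e$value / geometry$membrane_area_cm2 * .PE_UNIT_FACTOR
  structure(
    list(substrate = substrate, direction = direction,
         experiment = experiment, replicate = replicate,
         pe = pe, corrected = ps_e$condition == "corrected"),
    class = "pe_result"
  )
}

#' @export
print.pe_result <- function(x, ...) {
  cat(sprintf("Pe %s %s: %.1f x 1e-6 cm/s (%s)\n",
              x$substrate, x$direction, report_round(x$pe),
              if (x$corrected) "membrane-corrected" else "uncorrected"))
  invisible(x)
}

# Cleared-volume series for one timecourse. With nominal donor (sink
# approximation) the cleared volume is pointwise Cr*[R]/Cd0. With measured
# donor concentrations the series is accumulated per sampling interval,
# dividing each interval's receiver increment by the interval-mean donor
# concentration — the conventional handling when the donor is sampled at
# every timepoint, and unbiased under donor depletion where the pointwise
# ratio is not.
.cleared_series <- function(tc, geometry,
                            donor_mode = c("measured", "nominal")) {
  donor_mode <- match.arg(donor_mode)
  rv <- receiver_volume(geometry, tc$direction)
  cr <- tc$samples$receiver_conc
  donor <- tc$samples$donor_conc
  if (donor_mode == "nominal" || anyNA(donor)) {
    if (!is.finite(tc$donor_initial)) {
      stop(sprintf(
        "timecourse %s %s exp %s rep %s: no measured donor_conc and no %s",
        tc$substrate, tc$direction, tc$experiment, tc$replicate,
        "nominal dosing concentration supplied"), call. = FALSE)
    }
    cleared <- cleared_volume(cr, rv, rep(tc$donor_initial, length(cr)))
  } else {
    d0 <- if (is.finite(tc$donor_initial)) tc$donor_initial else donor[1]
    d_start <- c(d0, donor[-length(donor)])
    d_bar <- (d_start + donor) / 2
    cleared <- cumsum(diff(c(0, cr)) * rv / d_bar)
  }
  data.frame(time_min = tc$samples$time_min, cleared_uL = cleared)
}

#' Permeability coefficient for one replicate, blank-corrected
#'
#' Composes the full clearance pipeline: per-timepoint cleared volume for
#' the cell insert and its matched blank, PS by slope for both, series
#' membrane correction, division by surface area. Stages report failures
#' under their own names so a bad replicate is diagnosable.
#'
#' @param tc cell-bearing [timecourse()] (`insert_condition == "cells"`).
#' @param blank matched blank-membrane timecourse, same substrate and
#'   direction; `NULL` to skip membrane correction (Pe from PS_total).
#' @param geometry an [insert_geometry()].
#' @param donor_mode `"measured"` uses the per-timepoint donor
#'   concentrations when present; `"nominal"` always uses the dosing
#'   concentration (sink approximation).
#' @return A `pe_result` (see [pe_from_ps()]).
#' @export
compute_pe <- function(tc, blank, geometry,
                       donor_mode = c("measured", "nominal")) {
  donor_mode <- match.arg(donor_mode)
  stopifnot(inherits(tc, "timecourse"))
  if (tc$insert_condition != "cells") {
    stop("`tc` must be a cell-bearing timecourse", call. = FALSE)
  }
  cs <- .cleared_series(tc, geometry, donor_mode)
  ps_total <- fit_ps(cs$time_min, cs$cleared_uL, "total")
  if (!ps_total$usable) {
    stop("fit_ps(total): non-positive clearance slope for ", tc$substrate,
         " ", tc$direction, " exp ", tc$experiment, " rep ", tc$replicate,
         call. = FALSE)
  }
  if (is.null(blank)) {
    ps_e <- ps_total
  } else {
    stopifnot(inherits(blank, "timecourse"))
    if (blank$insert_condition != "blank") {
      stop("`blank` must have insert_condition = \"blank\"", call. = FALSE)
    }
    if (blank$substrate != tc$substrate || blank$direction != tc$direction) {
      stop("blank timecourse does not match substrate/direction",
           call. = FALSE)
    }
    bs <- .cleared_series(blank, geometry, donor_mode)
    ps_mem <- fit_ps(bs$time_min, bs$cleared_uL, "membrane")
    ps_e <- correct_for_membrane(ps_total, ps_mem)
  }
  out <- pe_from_ps(ps_e, geometry, substrate = tc$substrate,
                    direction = tc$direction, experiment = tc$experiment,
                    replicate = tc$replicate)
  out$ps_total <- ps_total$value
  out$ps_mem <- if (is.null(blank)) NA_real_ else ps_mem$value
  out$ps_e <- ps_e$value
  out$fit_r2 <- ps_total$fit_r2
  out
}

#' Permeability table for a whole assay set
#'
#' Runs [compute_pe()] for every cell-bearing replicate in a set of
#' timecourses, matching blanks per (substrate, direction, experiment);
#' when an experiment has several blank replicates their fitted PS_mem
#' values are averaged before correction, and when an experiment has no
#' blank the pooled blank of the same substrate and direction is used.
#' Replicates whose correction is undefined (PS_total >= PS_mem) or whose
#' slope is non-positive are flagged and excluded from `pe`, never clamped.
#'
#' @param tcs a `timecourse_set` (or plain list of [timecourse()]).
#' @param geometry an [insert_geometry()]; defaults to the geometry attached
#'   to `tcs` by [read_timecourses()].
#' @param donor_mode see [compute_pe()].
#' @param blank_match blank-to-cell matching rule. `"experiment"` (default)
#'   pools blank fits within (substrate, experiment) across directions and
#'   replicates — the bare membrane has no sidedness, so one PS_mem serves
#'   both directions and any blank-fit bias cancels from the efflux ratio;
#'   `"direction"` matches per (substrate, direction, experiment);
#'   `"substrate"` pools all blanks of a substrate. Narrower rules fall
#'   back to broader pools when a matching blank is missing.
#' @return A data.frame, one row per cell-bearing replicate:
#'   `substrate, direction, experiment, replicate, ps_total_uL_min,
#'   ps_mem_uL_min, ps_e_uL_min, pe_1e6_cm_s, fit_r2, flags`.
#' @export
analyze_permeability <- function(tcs, geometry = NULL,
                                 donor_mode = c("measured", "nominal"),
                                 blank_match = c("experiment", "direction",
                                                 "substrate")) {
  donor_mode <- match.arg(donor_mode)
  blank_match <- match.arg(blank_match)
  geometry <- geometry %||% attr(tcs, "geometry")
  stopifnot(inherits(geometry, "insert_geometry"))
  cells <- Filter(function(tc) tc$insert_condition == "cells", tcs)
  blanks <- Filter(function(tc) tc$insert_condition == "blank", tcs)
  if (length(cells) == 0L) stop("no cell-bearing timecourses", call. = FALSE)

  blank_ps <- function(substrate, direction, experiment) {
    rules <- switch(blank_match,
      direction = list(
        function(b) b$substrate == substrate && b$direction == direction &&
          b$experiment == experiment,
        function(b) b$substrate == substrate && b$direction == direction,
        function(b) b$substrate == substrate),
      experiment = list(
        function(b) b$substrate == substrate && b$experiment == experiment,
        function(b) b$substrate == substrate),
      substrate = list(function(b) b$substrate == substrate))
    for (rule in rules) {
      matched <- Filter(rule, blanks)
      if (length(matched)) {
        vals <- vapply(matched, function(b) {
          bs <- .cleared_series(b, geometry, donor_mode)
          fit_ps(bs$time_min, bs$cleared_uL, "membrane")$value
        }, numeric(1))
        return(mean(vals))
      }
    }
    NA_real_
  }

  rows <- lapply(cells, function(tc) {
    row <- data.frame(substrate = tc$substrate, direction = tc$direction,
                      experiment = tc$experiment, replicate = tc$replicate,
                      ps_total_uL_min = NA_real_, ps_mem_uL_min = NA_real_,
                      ps_e_uL_min = NA_real_, pe_1e6_cm_s = NA_real_,
                      fit_r2 = NA_real_, flags = "")
    if ("too_few_timepoints" %in% tc$flags) {
      row$flags <- "too_few_timepoints"
      return(row)
    }
    cs <- .cleared_series(tc, geometry, donor_mode)
    ps_total <- fit_ps(cs$time_min, cs$cleared_uL, "total")
    row$ps_total_uL_min <- ps_total$value
    row$fit_r2 <- ps_total$fit_r2
    if (!ps_total$usable) {
      row$flags <- "nonpositive_slope"
      return(row)
    }
    psm <- blank_ps(tc$substrate, tc$direction, tc$experiment)
    if (is.na(psm)) {
      # no blank available: report uncorrected Pe, flagged
      pe <- pe_from_ps(ps_total, geometry)
      row$ps_e_uL_min <- ps_total$value
      row$pe_1e6_cm_s <- pe$pe
      row$flags <- "uncorrected_no_blank"
      return(row)
    }
    row$ps_mem_uL_min <- psm
    if (ps_total$value >= psm) {
      row$flags <- "ps_total_ge_ps_mem"
      return(row)
    }
    ps_mem <- structure(list(value = psm, condition = "membrane",
                             intercept = NA_real_, fit_r2 = NA_real_,
                             n_points = ps_total$n_points, usable = TRUE,
                             flags = character()), class = "ps_fit")
    ps_e <- correct_for_membrane(ps_total, ps_mem)
    row$ps_e_uL_min <- ps_e$value
    row$pe_1e6_cm_s <- pe_from_ps(ps_e, geometry)$pe
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trans-endothelial electrical resistance (TEER)
#'
#' Net resistance times membrane area:
#' `TEER (Ohm cm^2) = (coculture - blank membrane) (Ohm) * area (cm^2)`.
#' The blank-insert resistance is subtracted so only the cell layers
#' contribute.
#'
#' @param coculture_ohm resistance measured across the cell-bearing insert.
#' @param blank_ohm resistance of the bare insert membrane.
#' @param area_cm2 membrane surface area.
#' @return TEER in Ohm cm^2.
#' @examples
#' teer(100, 20, 0.33)  # 26.4
#' @export
teer <- function(coculture_ohm, blank_ohm, area_cm2) {
  check_number(coculture_ohm, "coculture_ohm", nonneg = TRUE)
  check_number(blank_ohm, "blank_ohm", nonneg = TRUE)
  check_number(area_cm2, "area_cm2", positive = TRUE)
  if (coculture_ohm < blank_ohm) {
    stop("negative net resistance: coculture resistance is below the blank",
         call. = FALSE)
  }
  (coculture_ohm - blank_ohm) * area_cm2
}
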