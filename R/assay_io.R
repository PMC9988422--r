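#' Single-replicate transport timecourse
#'
#' One replicate's donor/receiver concentration series for one substrate in
#' one transport direction, from either a cell-bearing or a blank insert.
#' Concentrations are amount per uL in any one consistent unit: the
#' cleared-volume formula uses only the receiver/donor concentration ratio,
#' so the unit cancels, but a single file must use a single unit.
#'
#' @param substrate substrate label, e.g. `"digoxin"`.
#' @param direction `"A2B"` or `"B2A"`.
#' @param experiment experiment (biological run) label.
#' @param replicate replicate label within the experiment.
#' @param insert_condition `"cells"` for a cell-bearing insert, `"blank"`
#'   for the coated membrane without cells.
#' @param time_min sampling times in minutes, strictly increasing, all > 0.
#' @param receiver_conc receiver-compartment concentrations at `time_min`.
#' @param donor_conc donor-compartment concentrations at `time_min`, or `NA`
#'   when the donor was not sampled (sink approximation: the nominal dosing
#'   concentration is used instead).
#' @param donor_initial nominal dosing concentration in the donor compartment.
#' @return An object of class `timecourse`. If fewer than two timepoints are
#'   present the object carries the flag `"too_few_timepoints"` (slope
#'   fitting will refuse it, but it is not silently dropped).
#' @export
timecourse <- function(substrate, direction, experiment, replicate,
                       insert_condition, time_min, receiver_conc,
                       donor_conc = NULL, donor_initial = NA_real_) {
  direction <- match.arg(direction, c("A2B", "B2A"))
  insert_condition <- match.arg(insert_condition, c("cells", "blank"))
  time_min <- as.numeric(time_min)
  receiver_conc <- as.numeric(receiver_conc)
  if (is.null(donor_conc)) donor_conc <- rep(NA_real_, length(time_min))
  donor_conc <- as.numeric(donor_conc)
  if (length(receiver_conc) != length(time_min) ||
      length(donor_conc) != length(time_min)) {
    stop("time_min, receiver_conc and donor_conc must have equal length",
         call. = FALSE)
  }
  ord <- order(time_min)
  time_min <- time_min[ord]
  receiver_conc <- receiver_conc[ord]
  donor_conc <- donor_conc[ord]
  if (any(time_min <= 0)) stop("sample times must be > 0", call. = FALSE)
  if (any(duplicated(time_min))) {
    stop("duplicate sample times within one timecourse", call. = FALSE)
  }
  if (any(receiver_conc < 0, na.rm = TRUE) ||
      any(donor_conc < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  flags <- character()
  if (length(time_min) < 2L) flags <- c(flags, "too_few_timepoints")
  structure(
    list(substrate = as.character(substrate),
         direction = direction,
         experiment = as.character(experiment),
         replicate = as.character(replicate),
         insert_condition = insert_condition,
         donor_initial = as.numeric(donor_initial),
         samples = data.frame(time_min = time_min,
                              receiver_conc = receiver_conc,
                              donor_conc = donor_conc),
         flags = flags),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Timecourse: %s %s exp %s rep %s [%s], %d timepoints\n",
              x$substrate, x$direction, x$experiment, x$replicate,
              x$insert_condition, nrow(x$samples)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.assay_cols <- c("substrate", "direction", "experiment", "replicate",
                 "insert_condition", "time_min", "donor_conc", "receiver_conc")

.parse_num <- function(x, col) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value in column `%s` at data row %d: \"%s\"",
                 col, bad[1], x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read bidirectional-assay timecourses from a tidy CSV
#'
#' The file must carry the exact header
#' `substrate,direction,experiment,replicate,insert_condition,time_min,donor_conc,receiver_conc`
#' with `direction` in `{A2B, B2A}` and `insert_condition` in
#' `{cells, blank}`. `donor_conc` cells may be empty; the dosing
#' concentration from `dosing` is then used at every timepoint (sink
#' approximation). Rows are grouped into one [timecourse()] per
#' (substrate, direction, experiment, replicate, insert_condition);
#' row order in the file is irrelevant, samples are sorted by time.
#'
#' @param path CSV file path.
#' @param geometry optional [insert_geometry()] attached to the returned set
#'   (attribute `geometry`) for downstream convenience.
#' @param dosing named numeric vector of nominal dosing concentrations by
#'   substrate, used where `donor_conc` is empty; or a single number applied
#'   to all substrates.
#' @return A list of `timecourse` objects (class `timecourse_set`).
#' @export
read_timecourses <- function(path, geometry = NULL, dosing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(.assay_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  bad_dir <- setdiff(unique(raw$direction), c("A2B", "B2A"))
  if (length(bad_dir)) {
    stop("invalid `direction` value(s): ", paste(bad_dir, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- setdiff(unique(raw$insert_condition), c("cells", "blank"))
  if (length(bad_cond)) {
    stop("invalid `insert_condition` value(s): ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  raw$time_min <- .parse_num(raw$time_min, "time_min")
  raw$donor_conc <- .parse_num(raw$donor_conc, "donor_conc")
  raw$receiver_conc <- .parse_num(raw$receiver_conc, "receiver_conc")
  if (anyNA(raw$time_min) || anyNA(raw$receiver_conc)) {
    col <- if (anyNA(raw$time_min)) "time_min" else "receiver_conc"
    stop(sprintf("empty cell in required column `%s` at data row %d",
                 col, which(is.na(raw[[col]]))[1]), call. = FALSE)
  }
  key <- interaction(raw$substrate, raw$direction, raw$experiment,
                     raw$replicate, raw$insert_condition, drop = TRUE)
  dup <- duplicated(data.frame(key, raw$time_min))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf(
      "duplicate record: %s %s exp %s rep %s [%s] sampled twice at t = %g min",
      raw$substrate[i], raw$direction[i], raw$experiment[i],
      raw$replicate[i], raw$insert_condition[i], raw$time_min[i]),
      call. = FALSE)
  }
  dose_for <- function(substrate) {
    if (is.null(dosing)) return(NA_real_)
    if (is.null(names(dosing))) return(as.numeric(dosing[1]))
    as.numeric(dosing[substrate] %||% NA_real_)
  }
  out <- lapply(split(raw, key), function(g) {
    timecourse(substrate = g$substrate[1], direction = g$direction[1],
               experiment = g$experiment[1], replicate = g$replicate[1],
               insert_condition = g$insert_condition[1],
               time_min = g$time_min, receiver_conc = g$receiver_conc,
               donor_conc = g$donor_conc,
               donor_initial = dose_for(g$substrate[1]))
  })
  names(out) <- NULL
  structure(out, class = "timecourse_set", geometry = geometry)
}

#' Write timecourses to the tidy assay CSV schema
#'
#' Inverse of [read_timecourses()]: write then read reproduces the set.
#'
#' @param tcs a list of [timecourse()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  if (length(tcs) == 0L) stop("nothing to write", call. = FALSE)
  rows <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(substrate = tc$substrate, direction = tc$direction,
               experiment = tc$experiment, replicate = tc$replicate,
               insert_condition = tc$insert_condition,
               time_min = tc$samples$time_min,
               donor_conc = tc$samples$donor_conc,
               receiver_conc = tc$samples$receiver_conc)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf("timecourse_set: %d timecourses, %d substrate(s)\n",
              length(x), length(unique(vapply(x, `[[`, "", "substrate")))))
  invisible(x)
}

#' Read an assay configuration file
#'
#' YAML configuration carrying insert geometry, per-substrate metadata
#' (dosing concentration, assigned transporter), the significance level,
#' donor-concentration mode and report rounding. Missing fields fall back
#' to package defaults.
#'
#' @param path YAML file path.
#' @return A list of class `assay_config` with elements `geometry`
#'   ([insert_geometry()]), `substrates` (data.frame: substrate, transporter,
#'   dosing_concentration), `alpha`, `donor_mode` (`"measured"` or
#'   `"nominal"`), `report_digits`.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  geom <- y$geometry %||% list()
  geometry <- insert_geometry(
    membrane_area_cm2 = geom$area_cm2 %||% 0.33,
    luminal_uL = geom$luminal_uL %||% 200,
    abluminal_uL = geom$abluminal_uL %||% 600)
  substrates <- NULL
  if (!is.null(y$substrates)) {
    substrates <- do.call(rbind, lapply(names(y$substrates), function(s) {
      meta <- y$substrates[[s]]
      data.frame(substrate = s,
                 transporter = meta$transporter %||% NA_character_,
                 dosing_concentration =
                   as.numeric(meta$dosing_concentration %||% NA_real_))
    }))
  }
  donor_mode <- match.arg(y$donor_mode %||% "measured",
                          c("measured", "nominal"))
  structure(
    list(geometry = geometry, substrates = substrates,
         alpha = as.numeric(y$alpha %||% 0.05),
         donor_mode = donor_mode,
         report_digits = as.integer(y$report_digits %||% 1L)),
    class = "assay_config"
  )
}

#' Write result records to CSV
#'
#' Serialises pipeline outputs so that reading the file back reproduces the
#' records field-for-field (within float round-trip). Supported inputs:
#' a plain `data.frame` (e.g. a Pe table from [analyze_permeability()]),
#' a single [efflux result][aggregate_er] or a list of them (one row per
#' experiment plus a `summary` row per substrate).
#'
#' @param records result collection, non-empty.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(records, path) {
  if (nrow(records) == 0L) stop("nothing to write", call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
write_results.efflux_result <- function(records, path) {
  write_results.list(list(records), path)
}

#' @export
write_results.list <- function(records, path) {
  if (length(records) == 0L) stop("nothing to write", call. = FALSE)
  stopifnot(all(vapply(records, inherits, TRUE, "efflux_result")))
  rows <- do.call(rbind, lapply(records, function(r) {
    ex <- do.call(rbind, lapply(r$experiments, function(e) {
      data.frame(substrate = r$substrate, transporter = r$transporter,
                 row_type = "experiment", experiment = e$experiment,
                 pe_a2b = e$pe_a2b, pe_b2a = e$pe_b2a, er = e$er,
                 p_value = e$p_value %||% NA_real_, mark = e$mark,
                 er_mean = NA_real_, er_sd = NA_real_, n = NA_integer_)
    }))
    smry <- data.frame(substrate = r$substrate, transporter = r$transporter,
                       row_type = "summary", experiment = NA_character_,
                       pe_a2b = NA_real_, pe_b2a = NA_real_, er = NA_real_,
                       p_value = NA_real_, mark = NA_character_,
                       er_mean = r$er_mean, er_sd = r$er_sd %||% NA_real_,
                       n = r$n)
    rbind(ex, smry)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read efflux results written by [write_results()]
#'
#' @param path CSV written by `write_results()` for efflux results.
#' @return A list of `efflux_result` objects.
#' @export
read_efflux_results <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$substrate), function(g) {
    ex <- g[g$row_type == "experiment", ]
    experiments <- lapply(seq_len(nrow(ex)), function(i) {
      efflux_experiment(experiment = ex$experiment[i],
                        pe_a2b = ex$pe_a2b[i], pe_b2a = ex$pe_b2a[i],
                        p_value = if (is.na(ex$p_value[i])) NULL
                                  else ex$p_value[i])
    })
    aggregate_er(experiments, substrate = g$substrate[1],
                 transporter = g$transporter[1])
  })
}
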