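#' Bundled reference efflux dataset
#'
#' Per-experiment directional permeability pairs (Pe in 1e-6 cm/s) for
#' seven transporter substrates measured in a humanized tricellular static
#' transwell BBB model, with the per-experiment significance marks as
#' published (`*` p < 0.05, `**` p < 0.01; the underlying replicate values
#' are not available, so marks are carried as printed rather than
#' recomputed). Substrate-to-transporter assignment: rhodamine 123 and
#' digoxin probe P-gp; Hoechst 33342, dantrolene and sulfasalazine (SASP)
#' probe BCRP; 2-NBDG probes Glut1; Alexa-488 transferrin probes TfR.
#'
#' @return A data.frame with columns `substrate`, `transporter`,
#'   `experiment`, `pe_a2b`, `pe_b2a`, `mark`.
#' @export
bbb_reference_pe <- function() {
  utils::read.csv(system.file("extdata", "reference_pe_pairs.csv",
                              package = "bbbench"),
                  colClasses = c(rep("character", 3), rep("numeric", 2),
                                 "character"))
}

#' Reference efflux results aggregated per substrate
#'
#' Builds [aggregate_er()] summaries from [bbb_reference_pe()], preserving
#' the published per-experiment significance marks.
#'
#' @return Named list of `efflux_result`, one per substrate.
#' @export
bbb_reference_efflux <- function() {
  df <- bbb_reference_pe()
  out <- lapply(split(df, df$substrate), function(g) {
    experiments <- lapply(seq_len(nrow(g)), function(i) {
      e <- efflux_experiment(g$experiment[i], g$pe_a2b[i], g$pe_b2a[i])
      e$mark <- g$mark[i]   # as published; replicate-level p not available
      e
    })
    aggregate_er(experiments, substrate = g$substrate[1],
                 transporter = g$transporter[1])
  })
  out[unique(df$substrate)]
}

#' Second-facility efflux summaries from the reference study
#'
#' Mean +/- SD efflux ratios reported by an independent facility running
#' the same standard operating procedure on the same model, as
#' [efflux_summary()] records (no per-experiment data were published).
#'
#' @return Named list of summary-level `efflux_result`.
#' @export
bbb_reference_facility2 <- function() {
  df <- utils::read.csv(system.file("extdata",
                                    "reference_facility2_summary.csv",
                                    package = "bbbench"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    efflux_summary(df$substrate[i], df$er_mean[i], df$er_sd[i], df$n[i],
                   transporter = df$transporter[i])
  })
  names(out) <- df$substrate
  out
}
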