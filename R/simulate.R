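#' Configuration for the transwell assay simulator
#'
#' Defines a two-compartment transwell system: a passive cell-layer
#' clearance, an optional apically polarized active (efflux) component that
#' adds to B-to-A and subtracts from A-to-B transport, an optional
#' saturation of that component with donor concentration, the bare-membrane
#' clearance of the blank insert, receptor-mediated transcytosis (RMT)
#' parameters for competition assays, and multiplicative lognormal
#' measurement noise.
#'
#' Defaults emulate a conventional 24-well transwell run: samples at
#' 15/30/45/60 min, four replicates, 10% measurement CV, a cell layer with
#' Pe around 15 x 1e-6 cm/s and a blank membrane ten times leakier than the
#' cell layer.
#'
#' @param geometry an [insert_geometry()].
#' @param ps_passive passive cell-layer clearance, uL/min.
#' @param ps_active polarized efflux increment, uL/min; effective
#'   cell-layer PS is `ps_passive - ps_active` for A2B and
#'   `ps_passive + ps_active` for B2A (must stay > 0 for A2B).
#' @param km donor concentration at half-maximal active transport
#'   (same unit as `dosing_concentration`); `NULL` for a non-saturable pump.
#' @param ps_membrane_blank clearance of the blank insert membrane, uL/min;
#'   must exceed the effective cell-layer PS (the membrane is in series
#'   with the cells and is normally much leakier).
#' @param dosing_concentration donor concentration at t = 0 (amount/uL).
#' @param sample_times sampling times in minutes, strictly increasing.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noise-free).
#' @param replicates replicates per direction per experiment.
#' @param seed integer seed governing all stochasticity.
#' @param rmt_mode `"off"` (passive transferrin leak only) or `"on"`
#'   (functional receptor-mediated transport).
#' @param rmt_capacity maximal receptor-mediated transport (response units)
#'   when `rmt_mode = "on"`.
#' @param rmt_kd ligand dose at half receptor occupancy (pmol).
#' @param rmt_passive_leak passive leak coefficient: leak = coefficient x
#'   labeled dose, added to both arms of a competition assay.
#' @param rmt_labeled_dose labeled-ligand dose (pmol).
#' @param rmt_competitor_dose unlabeled-competitor dose (pmol).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = insert_geometry(),
                              ps_passive = 0.3,
                              ps_active = 0,
                              km = NULL,
                              ps_membrane_blank = 10 * ps_passive,
                              dosing_concentration = 10,
                              sample_times = c(15, 30, 45, 60),
                              noise_cv = 0.1,
                              replicates = 4L,
                              seed = 1L,
                              rmt_mode = c("off", "on"),
                              rmt_capacity = 100,
                              rmt_kd = 200,
                              rmt_passive_leak = 0.02,
                              rmt_labeled_dose = 200,
                              rmt_competitor_dose = 200) {
  rmt_mode <- match.arg(rmt_mode)
  stopifnot(inherits(geometry, "insert_geometry"))
  check_number(ps_passive, "ps_passive", positive = TRUE)
  check_number(ps_active, "ps_active", nonneg = TRUE)
  if (!is.null(km)) check_number(km, "km", positive = TRUE)
  check_number(ps_membrane_blank, "ps_membrane_blank", positive = TRUE)
  check_number(dosing_concentration, "dosing_concentration", positive = TRUE)
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  check_number(replicates, "replicates", positive = TRUE)
  check_number(seed, "seed")
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0) ||
      any(sample_times <= 0)) {
    stop("`sample_times` must be >= 2 strictly increasing positive times",
         call. = FALSE)
  }
  if (ps_passive - ps_active <= 0) {
    stop("effective A2B cell-layer PS must be > 0: need ps_active < ps_passive",
         call. = FALSE)
  }
  if (rmt_mode == "on") {
    check_number(rmt_capacity, "rmt_capacity", positive = TRUE)
    check_number(rmt_kd, "rmt_kd", positive = TRUE)
  }
  check_number(rmt_passive_leak, "rmt_passive_leak", nonneg = TRUE)
  check_number(rmt_labeled_dose, "rmt_labeled_dose", positive = TRUE)
  check_number(rmt_competitor_dose, "rmt_competitor_dose", nonneg = TRUE)
  structure(
    list(geometry = geometry, ps_passive = ps_passive,
         ps_active = ps_active, km = km,
         ps_membrane_blank = ps_membrane_blank,
         dosing_concentration = dosing_concentration,
         sample_times = sample_times, noise_cv = noise_cv,
         replicates = as.integer(replicates), seed = as.integer(seed),
         rmt_mode = rmt_mode, rmt_capacity = rmt_capacity,
         rmt_kd = rmt_kd, rmt_passive_leak = rmt_passive_leak,
         rmt_labeled_dose = rmt_labeled_dose,
         rmt_competitor_dose = rmt_competitor_dose),
    class = "simulation_config"
  )
}

# saturable efflux increment at donor concentration c
.active_ps <- function(config, donor_conc) {
  if (is.null(config$km)) return(config$ps_active)
  config$ps_active * config$km / (config$km + donor_conc)
}

# effective cell-layer PS in a physical transport direction, at donor conc c
.ps_cell <- function(config, physical_direction, donor_conc) {
  act <- .active_ps(config, donor_conc)
  if (physical_direction == "A2B") config$ps_passive - act
  else config$ps_passive + act
}

# series combination of cell layer and insert membrane
.ps_series <- function(ps_cell, ps_mem) 1 / (1 / ps_cell + 1 / ps_mem)

#' True directional permeability and efflux ratio of a simulation config
#'
#' The ground truth the estimation pipeline should recover: the effective
#' cell-layer PS per direction (active component evaluated at the dosing
#' concentration) divided by the membrane area, in 1e-6 cm/s, and their
#' ratio `ER = PS_B2A / PS_A2B`.
#'
#' @param config a [simulation_config()].
#' @return List with `pe_a2b`, `pe_b2a` (1e-6 cm/s) and `er`.
#' @export
true_permeability <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  c0 <- config$dosing_concentration
  ps_a2b <- .ps_cell(config, "A2B", c0)
  ps_b2a <- .ps_cell(config, "B2A", c0)
  s <- config$geometry$membrane_area_cm2
  list(pe_a2b = ps_a2b / s * .PE_UNIT_FACTOR,
       pe_b2a = ps_b2a / s * .PE_UNIT_FACTOR,
       er = ps_b2a / ps_a2b)
}

# mean-one multiplicative lognormal noise factors
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

# receiver amount over time for constant forward/backward PS (closed form):
# dAr/dt = PSf*(A0-Ar)/Vd - PSb*Ar/Vr  =>  Ar(t) = a/b * (1 - exp(-b t))
# (a0 = donor amount at interval start, receiver starting empty)
.linear_receiver_amount <- function(t, ps_fwd, ps_bwd, a0, vd, vr) {
  a <- ps_fwd * a0 / vd
  b <- ps_fwd / vd + ps_bwd / vr
  a / b * (1 - exp(-b * t))
}

# Cumulative transferred amount at each sampling time under the
# insert-transfer protocol: the receiver compartment is renewed at every
# sampling time (the insert moves to a fresh well), so each interval starts
# with an empty receiver while the donor depletes cumulatively. Within an
# interval the kinetics are mass-conserving two-compartment exchange.
# Returns list(cumulative = Ar_cum(t_i), donor = Ad(t_i)).
.transfer_series <- function(times, a0, vd, vr, ps_fun) {
  n <- length(times)
  cum <- numeric(n)
  donor <- numeric(n)
  ad <- a0
  t_prev <- 0
  for (i in seq_len(n)) {
    dt <- times[i] - t_prev
    ps <- ps_fun(ad / vd)
    if (is.null(ps$deriv)) {
      ar <- .linear_receiver_amount(dt, ps$fwd, ps$bwd, ad, vd, vr)
    } else {
      sol <- deSolve::ode(c(ar = 0), c(0, dt), ps$deriv, parms = ad,
                          rtol = 1e-9, atol = 1e-12)
      ar <- sol[2, "ar"]
    }
    ad <- ad - ar
    cum[i] <- a0 - ad
    donor[i] <- ad
    t_prev <- times[i]
  }
  list(cumulative = cum, donor = donor)
}

#' Simulate one transwell assay replicate
#'
#' Mass-conserving two-compartment exchange
#' `d(receiver amount)/dt = PS_fwd * C_donor - PS_bwd * C_receiver`, with
#' the forward/backward clearances set by the assay direction, the apical
#' polarity of the efflux component and, for a cell insert, the series
#' combination with the insert membrane. The simulation follows the
#' insert-transfer protocol the clearance-slope method presumes: at every
#' sampling time the receiver compartment is renewed (the insert moves to
#' a fresh well), which maintains sink conditions; the donor is never
#' replaced and depletes over the full run. The reported receiver
#' concentration at time t is the cumulative transferred amount divided by
#' the receiver volume — the quantity whose cleared volume grows linearly
#' with slope PS. The linear (non-saturable) case is solved in closed form
#' per interval; with `km` set each interval is integrated numerically
#' (deSolve). Multiplicative lognormal noise with the configured CV is
#' applied per sampled concentration; a fixed seed makes the result
#' reproducible.
#'
#' @param config a [simulation_config()].
#' @param direction `"A2B"` or `"B2A"` (dosing side).
#' @param insert_condition `"cells"` or `"blank"`.
#' @param experiment,replicate labels for the resulting [timecourse()].
#' @param seed seed for the measurement noise; defaults to `config$seed`.
#' @return A [timecourse()] with measured donor and (cumulative) receiver
#'   concentrations at `config$sample_times`.
#' @export
simulate_assay <- function(config, direction = c("A2B", "B2A"),
                           insert_condition = c("cells", "blank"),
                           experiment = "exp1", replicate = "r1",
                           seed = config$seed) {
  direction <- match.arg(direction)
  insert_condition <- match.arg(insert_condition)
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  vd <- donor_volume(geom, direction)
  vr <- receiver_volume(geom, direction)
  c0 <- config$dosing_concentration
  a0 <- c0 * vd
  times <- config$sample_times
  opposite <- if (direction == "A2B") "B2A" else "A2B"

  ps_fun <- if (insert_condition == "blank") {
    function(cd) list(fwd = config$ps_membrane_blank,
                      bwd = config$ps_membrane_blank, deriv = NULL)
  } else if (is.null(config$km)) {
    function(cd) list(
      fwd = .ps_series(.ps_cell(config, direction, cd),
                       config$ps_membrane_blank),
      bwd = .ps_series(.ps_cell(config, opposite, cd),
                       config$ps_membrane_blank),
      deriv = NULL)
  } else {
    function(cd0) list(fwd = NA, bwd = NA, deriv = function(t, state, ad) {
      ar <- state[["ar"]]
      cd <- (ad - ar) / vd
      cr <- ar / vr
      fwd <- .ps_series(.ps_cell(config, direction, cd),
                        config$ps_membrane_blank)
      bwd <- .ps_series(.ps_cell(config, opposite, cd),
                        config$ps_membrane_blank)
      list(fwd * cd - bwd * cr)
    })
  }
  ts <- .transfer_series(times, a0, vd, vr, ps_fun)

  receiver_conc <- ts$cumulative / vr
  donor_conc <- ts$donor / vd
  set.seed(seed)
  receiver_conc <- receiver_conc * .noise_factor(length(times),
                                                 config$noise_cv)
  donor_conc <- donor_conc * .noise_factor(length(times), config$noise_cv)
  timecourse(substrate = "sim", direction = direction,
             experiment = experiment, replicate = replicate,
             insert_condition = insert_condition,
             time_min = times, receiver_conc = receiver_conc,
             donor_conc = donor_conc, donor_initial = c0)
}

#' Simulate a complete bidirectional experiment set
#'
#' Both directions x replicates x \{cells, blank\} timecourses for one or
#' more independent experiments, ready for [analyze_permeability()] /
#' [efflux_from_pe_table()], together with the ground truth from
#' [true_permeability()]. Per-assay noise seeds are derived
#' deterministically from `config$seed`, so the whole set is reproducible.
#'
#' @param config a [simulation_config()].
#' @param n_experiments number of independent experiments to simulate.
#' @param substrate substrate label stamped on the timecourses.
#' @return List with `timecourses` (a `timecourse_set`) and `truth`
#'   (`pe_a2b`, `pe_b2a`, `er`).
#' @export
simulate_bidirectional_experiment <- function(config, n_experiments = 1L,
                                              substrate = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  tcs <- list()
  k <- 0L
  for (e in seq_len(n_experiments)) {
    for (direction in c("A2B", "B2A")) {
      for (r in seq_len(config$replicates)) {
        for (cond in c("cells", "blank")) {
          k <- k + 1L
          tc <- simulate_assay(config, direction, cond,
                               experiment = paste0("exp", e),
                               replicate = paste0("r", r),
                               seed = (config$seed + 1009L * k) %% 2147483647L)
          tc$substrate <- substrate
          tcs[[k]] <- tc
        }
      }
    }
  }
  structure(list(
    timecourses = structure(tcs, class = "timecourse_set",
                            geometry = config$geometry),
    truth = true_permeability(config)),
    class = "simulated_experiment")
}

#' Simulate a transferrin-style competition assay
#'
#' Labeled-ligand transport with and without an unlabeled competitor.
#' With `rmt_mode = "on"` the receptor-mediated component follows the
#' occupancy law `capacity * L / (kd + L + U)` (L labeled dose, U
#' competitor dose), so an equimolar competitor reduces it by the factor
#' `(kd + L) / (kd + 2L)` exactly in the noise-free case; a passive leak
#' `rmt_passive_leak * L` is common to both arms. With `rmt_mode = "off"`
#' the arms differ only by noise.
#'
#' @param config a [simulation_config()]; `rmt_capacity` and `rmt_kd` are
#'   required when `rmt_mode = "on"`.
#' @param n_replicates replicates per arm (default `config$replicates`).
#' @return List of class `competition_assay`: `alone`,
#'   `with_competitor` (transported-amount replicates), `labeled_dose`,
#'   `competitor_dose`, `rmt_mode`.
#' @export
simulate_competition <- function(config, n_replicates = config$replicates) {
  stopifnot(inherits(config, "simulation_config"))
  l <- config$rmt_labeled_dose
  u <- config$rmt_competitor_dose
  leak <- config$rmt_passive_leak * l
  receptor_alone <- 0
  receptor_comp <- 0
  if (config$rmt_mode == "on") {
    receptor_alone <- config$rmt_capacity * l / (config$rmt_kd + l)
    receptor_comp <- config$rmt_capacity * l / (config$rmt_kd + l + u)
  }
  set.seed(config$seed)
  alone <- (receptor_alone + leak) *
    .noise_factor(n_replicates, config$noise_cv)
  with_competitor <- (receptor_comp + leak) *
    .noise_factor(n_replicates, config$noise_cv)
  structure(
    list(alone = alone, with_competitor = with_competitor,
         labeled_dose = l, competitor_dose = u, rmt_mode = config$rmt_mode),
    class = "competition_assay"
  )
}
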