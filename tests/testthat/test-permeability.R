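test_that("cleared volume is receiver amount referenced to donor conc", {
  expect_equal(cleared_volume(0, 600, 10), 0)
  expect_equal(cleared_volume(1, 600, 10), 60)
  expect_equal(cleared_volume(0.05, 900, 5), 9)  # 0.05 * 900 / 5
  expect_error(cleared_volume(1, 600, 0), "donor_conc")
  expect_error(cleared_volume(-1, 600, 10), "receiver_conc")
})

test_that("fit_ps recovers an exact line and flags degenerate slopes", {
  f <- fit_ps(c(15, 30, 45, 60), c(15, 30, 45, 60))
  expect_equal(f$value, 1)
  expect_equal(f$fit_r2, 1)
  expect_true(f$usable)

  z <- fit_ps(c(15, 30, 45, 60), c(0, 0, 0, 0))
  expect_equal(z$value, 0)
  expect_false(z$usable)
  expect_true("nonpositive_slope" %in% z$flags)

  expect_error(fit_ps(15, 10), "at least 2")
  expect_error(fit_ps(c(15, 15), c(1, 2)), "distinct")
})

test_that("fit_ps matches the normal-equations oracle", {
  t4 <- c(15, 30, 45, 60)
  v4 <- c(10, 22, 29, 41)
  expect_equal(fit_ps(t4, v4)$value, ne_slope(t4, v4), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- sort(runif(n, 1, 120))
    y <- 0.5 * x + rnorm(n, 0, 3)
    expect_equal(fit_ps(x, y)$value, ne_slope(x, y), tolerance = 1e-10)
  }
})

test_that("membrane correction follows the series-barrier identity", {
  ps <- function(v, cond = "total") {
    structure(list(value = v, condition = cond, intercept = 0, fit_r2 = 1,
                   n_points = 4, usable = TRUE, flags = character()),
              class = "ps_fit")
  }
  expect_equal(correct_for_membrane(ps(2), ps(4, "membrane"))$value, 4)
  lim <- correct_for_membrane(ps(1), ps(1e6, "membrane"))$value
  expect_equal(lim, 1, tolerance = 1e-4)
  expect_error(correct_for_membrane(ps(4), ps(4, "membrane")),
               "inconsistent")
  expect_error(correct_for_membrane(ps(2, "membrane"), ps(4, "membrane")),
               "condition")

  # corrected value always exceeds PS_total and approaches it as the blank
  # becomes infinitely permeable
  set.seed(3)
  for (i in 1:20) {
    tot <- runif(1, 0.1, 5)
    mem <- tot * runif(1, 1.01, 50)
    corr <- correct_for_membrane(ps(tot), ps(mem, "membrane"))$value
    expect_gt(corr, tot)
    far <- correct_for_membrane(ps(tot), ps(mem * 1e6, "membrane"))$value
    expect_equal(far, tot, tolerance = 1e-4)
  }
})

test_that("pe_from_ps applies the (uL/min)/cm^2 -> 1e-6 cm/s unit chain", {
  ps <- function(v) structure(
    list(value = v, condition = "corrected", intercept = NA, fit_r2 = NA,
         n_points = 4, usable = TRUE, flags = character()), class = "ps_fit")
  g033 <- insert_geometry(0.33, 200, 600)
  expect_equal(pe_from_ps(ps(4), g033)$pe, 202.0, tolerance = 0.1 / 202)
  g1 <- insert_geometry(1, 200, 600)
  expect_equal(pe_from_ps(ps(0.6), g1)$pe, 10.0, tolerance = 1e-12)
  g2 <- insert_geometry(2, 200, 600)
  expect_equal(pe_from_ps(ps(0.6), g2)$pe,
               pe_from_ps(ps(0.6), g1)$pe / 2, tolerance = 1e-12)
})

test_that("TEER is net resistance times area", {
  expect_equal(teer(100, 20, 0.33), 26.4)
  expect_equal(teer(50, 50, 0.33), 0)
  expect_error(teer(10, 20, 0.33), "negative net resistance")
})

test_that("compute_pe recovers a known Pe from noise-free simulation", {
  # true Pe 20 x 1e-6 cm/s, very permeable blank
  cfg <- sim_config_for_pe(20, 20, blank_factor = 50,
                           noise_cv = 0, replicates = 1)
  sim <- simulate_bidirectional_experiment(cfg)
  tc <- Filter(function(t) t$direction == "A2B" &&
                 t$insert_condition == "cells", sim$timecourses)[[1]]
  bl <- Filter(function(t) t$direction == "A2B" &&
                 t$insert_condition == "blank", sim$timecourses)[[1]]
  pe <- compute_pe(tc, bl, cfg$geometry)
  expect_equal(pe$pe, 20, tolerance = 0.02)
  expect_true(pe$corrected)
})

test_that("compute_pe reports the failing stage for degenerate input", {
  tc <- timecourse("x", "A2B", "e1", "r1", "cells",
                   c(15, 30, 45, 60), rep(0, 4), donor_initial = 10)
  bl <- timecourse("x", "A2B", "e1", "r1", "blank",
                   c(15, 30, 45, 60), c(1, 2, 3, 4) / 10, donor_initial = 10)
  expect_error(compute_pe(tc, bl, insert_geometry()), "fit_ps\\(total\\)")
  expect_error(compute_pe(bl, bl, insert_geometry()), "cell-bearing")
})

test_that("Pe agrees between measured and nominal donor under sink", {
  cfg <- sim_config_for_pe(10, 10, noise_cv = 0, replicates = 1)
  sim <- simulate_bidirectional_experiment(cfg)
  tab_m <- analyze_permeability(sim$timecourses, donor_mode = "measured")
  tab_n <- analyze_permeability(sim$timecourses, donor_mode = "nominal")
  expect_equal(tab_m$pe_1e6_cm_s, tab_n$pe_1e6_cm_s, tolerance = 0.1)
})

test_that("Pe is invariant to rescaling all concentrations", {
  cfg <- sim_config_for_pe(15, 30, noise_cv = 0.05, replicates = 1, seed = 5)
  sim <- simulate_bidirectional_experiment(cfg)
  scaled <- lapply(sim$timecourses, function(tc) {
    tc$samples$receiver_conc <- tc$samples$receiver_conc * 37.5
    tc$samples$donor_conc <- tc$samples$donor_conc * 37.5
    tc$donor_initial <- tc$donor_initial * 37.5
    tc
  })
  attr(scaled, "geometry") <- cfg$geometry
  t1 <- analyze_permeability(sim$timecourses)
  t2 <- analyze_permeability(scaled)
  expect_equal(t1$pe_1e6_cm_s, t2$pe_1e6_cm_s, tolerance = 1e-10)
})

test_that("replicates with PS_total >= PS_mem are excluded and flagged", {
  times <- c(15, 30, 45, 60)
  tcs <- list(
    timecourse("x", "A2B", "e1", "r1", "cells", times,
               0.02 * times, donor_initial = 10),
    timecourse("x", "A2B", "e1", "b1", "blank", times,
               0.01 * times, donor_initial = 10))
  attr(tcs, "geometry") <- insert_geometry()
  tab <- analyze_permeability(tcs, donor_mode = "nominal")
  expect_true(is.na(tab$pe_1e6_cm_s[1]))
  expect_match(tab$flags[1], "ps_total_ge_ps_mem")
})
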