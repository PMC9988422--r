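test_that("blank-insert kinetics match the closed-form relaxation oracle", {
  cfg <- simulation_config(ps_passive = 0.4, ps_membrane_blank = 4,
                           noise_cv = 0, replicates = 1)
  tc <- simulate_assay(cfg, "A2B", "blank")
  vd <- 200; vr <- 600; a0 <- 10 * vd
  # first sampling interval starts from a pristine system, so the plain
  # exponential-relaxation solution applies exactly
  ps <- 4
  a <- ps * a0 / vd
  b <- ps / vd + ps / vr
  expect_equal(tc$samples$receiver_conc[1] * vr,
               a / b * (1 - exp(-b * 15)), tolerance = 1e-10)
  # full series against the brute-force Euler renewal oracle
  cum <- euler_renewal_oracle(c(15, 30, 45, 60), ps, ps, 10, vd, vr)
  expect_equal(tc$samples$receiver_conc * vr, cum, tolerance = 1e-3)
})

test_that("cell-insert kinetics match the Euler renewal oracle", {
  cfg <- sim_config_for_pe(20, 40, noise_cv = 0, replicates = 1)
  tc <- simulate_assay(cfg, "B2A", "cells")
  s <- 0.33
  ps_cell_b2a <- 40 * s * 60 / 1000
  ps_cell_a2b <- 20 * s * 60 / 1000
  mem <- cfg$ps_membrane_blank
  fwd <- 1 / (1 / ps_cell_b2a + 1 / mem)
  bwd <- 1 / (1 / ps_cell_a2b + 1 / mem)
  cum <- euler_renewal_oracle(c(15, 30, 45, 60), fwd, bwd, 10,
                              vd = 600, vr = 200)
  expect_equal(tc$samples$receiver_conc * 200, cum, tolerance = 1e-3)
})

test_that("noise-free simulations conserve mass", {
  cfgs <- list(
    simulation_config(noise_cv = 0),
    simulation_config(noise_cv = 0, ps_active = 0.15),
    simulation_config(noise_cv = 0, ps_active = 0.15, km = 5))
  for (cfg in cfgs) {
    for (dir in c("A2B", "B2A")) {
      for (cond in c("cells", "blank")) {
        tc <- simulate_assay(cfg, dir, cond)
        vd <- donor_volume(cfg$geometry, dir)
        vr <- receiver_volume(cfg$geometry, dir)
        total <- tc$samples$donor_conc * vd + tc$samples$receiver_conc * vr
        expect_equal(total, rep(10 * vd, 4), tolerance = 1e-6)
      }
    }
  }
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_assay(cfg, "A2B", "cells")
  b <- simulate_assay(cfg, "A2B", "cells")
  expect_identical(a, b)
  s1 <- simulate_bidirectional_experiment(cfg, n_experiments = 2)
  s2 <- simulate_bidirectional_experiment(cfg, n_experiments = 2)
  expect_identical(s1, s2)
})

test_that("configured efflux asymmetry is recovered through the pipeline", {
  cfg <- sim_config_for_pe(20, 40, noise_cv = 0, replicates = 1)
  expect_equal(true_permeability(cfg)$er, 2, tolerance = 1e-12)
  sim <- simulate_bidirectional_experiment(cfg)
  res <- efflux_from_pe_table(analyze_permeability(sim$timecourses))$sim
  expect_equal(res$er_mean, 2, tolerance = 0.02)

  sym <- simulation_config(ps_passive = 0.4, ps_active = 0, noise_cv = 0,
                           replicates = 1)
  sim0 <- simulate_bidirectional_experiment(sym)
  res0 <- efflux_from_pe_table(analyze_permeability(sim0$timecourses))$sim
  expect_equal(res0$er_mean, 1, tolerance = 0.01)
})

test_that("noisy aggregate ER stays within 3 SE of truth at a fixed seed", {
  cfg <- sim_config_for_pe(20, 40, noise_cv = 0.1, replicates = 3,
                           seed = 2024)
  sim <- simulate_bidirectional_experiment(cfg, n_experiments = 4)
  res <- efflux_from_pe_table(analyze_permeability(sim$timecourses))$sim
  expect_equal(res$n, 4)
  se <- res$er_sd / sqrt(res$n)
  expect_lt(abs(res$er_mean - 2), 3 * se + 1e-9)
})

test_that("membrane correction shifts Pe by the series-barrier factor", {
  cfg <- simulation_config(ps_passive = 0.4, ps_active = 0,
                           ps_membrane_blank = 4, noise_cv = 0,
                           replicates = 1)
  sim <- simulate_bidirectional_experiment(cfg)
  tc <- Filter(function(t) t$direction == "A2B" &&
                 t$insert_condition == "cells", sim$timecourses)[[1]]
  bl <- Filter(function(t) t$direction == "A2B" &&
                 t$insert_condition == "blank", sim$timecourses)[[1]]
  corrected <- compute_pe(tc, bl, cfg$geometry)$pe
  uncorrected <- compute_pe(tc, NULL, cfg$geometry)$pe
  # PS_cell/PS_total = 1 + PS_cell/PS_mem = 1.1 for a 10x blank
  expect_equal(corrected / uncorrected, 1.1, tolerance = 0.01)
})

test_that("competition simulator follows the stated occupancy algebra", {
  off <- simulation_config(rmt_mode = "off", noise_cv = 0)
  ca <- simulate_competition(off)
  expect_equal(ca$alone, ca$with_competitor, tolerance = 1e-12)

  # L = U = kd, no leak: competitor/alone = (kd+L)/(kd+2L) = 2/3
  pure <- simulation_config(rmt_mode = "on", noise_cv = 0,
                            rmt_capacity = 100, rmt_kd = 200,
                            rmt_passive_leak = 0,
                            rmt_labeled_dose = 200, rmt_competitor_dose = 200)
  ca <- simulate_competition(pure)
  expect_equal(mean(ca$with_competitor) / mean(ca$alone), 2 / 3,
               tolerance = 1e-12)

  # passive leak equal to the receptor component at L: ratio (2/3+1)/2 = 5/6
  leak_coef <- (100 * 200 / (200 + 200)) / 200  # leak*L == receptor(L)
  leaky <- simulation_config(rmt_mode = "on", noise_cv = 0,
                             rmt_capacity = 100, rmt_kd = 200,
                             rmt_passive_leak = leak_coef,
                             rmt_labeled_dose = 200,
                             rmt_competitor_dose = 200)
  ca <- simulate_competition(leaky)
  expect_equal(mean(ca$with_competitor) / mean(ca$alone), 5 / 6,
               tolerance = 1e-12)
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(ps_passive = -1), "ps_passive")
  expect_error(simulation_config(noise_cv = -0.1), "noise_cv")
  expect_error(simulation_config(sample_times = c(30, 15)), "sample_times")
  expect_error(simulation_config(ps_passive = 0.3, ps_active = 0.4),
               "ps_active")
})
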