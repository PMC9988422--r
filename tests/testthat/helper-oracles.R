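# Independent oracles and fixture builders shared across tests.

# closed-form least-squares slope via the normal equations; independent of
# the lm() route used by fit_ps()
ne_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# pooled-variance Student t and its two-tailed p, written out from the
# textbook formula rather than via t.test()
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), nx + ny - 2))
}

# simulator config whose ground truth is a prescribed directional Pe pair
sim_config_for_pe <- function(pe_a2b, pe_b2a, geometry = insert_geometry(),
                              blank_factor = 10, ...) {
  s <- geometry$membrane_area_cm2
  ps_a <- pe_a2b * s * 60 / 1000
  ps_b <- pe_b2a * s * 60 / 1000
  simulation_config(geometry = geometry,
                    ps_passive = (ps_a + ps_b) / 2,
                    ps_active = (ps_b - ps_a) / 2,
                    ps_membrane_blank = blank_factor * (ps_a + ps_b) / 2,
                    ...)
}

# brute-force forward model of the receiver-renewal transwell protocol:
# explicit Euler at a small step, receiver reset at every sampling time.
# Independent of the closed-form interval solution in the package.
euler_renewal_oracle <- function(times, ps_fwd, ps_bwd, c0, vd, vr,
                                 dt = 0.001) {
  ad <- c0 * vd
  cum <- numeric(length(times))
  t_prev <- 0
  for (i in seq_along(times)) {
    ar <- 0
    nstep <- round((times[i] - t_prev) / dt)
    for (k in seq_len(nstep)) {
      flux <- ps_fwd * ((ad - ar) / vd) - ps_bwd * (ar / vr)
      ar <- ar + flux * dt
    }
    ad <- ad - ar
    cum[i] <- c0 * vd - ad
    t_prev <- times[i]
  }
  cum
}

# per-experiment Pe pairs of the bundled reference dataset, published
# one-decimal ER summaries to check aggregation against
reference_summaries <- function() {
  data.frame(
    substrate = c("rhodamine123", "hoechst33342", "2-NBDG", "transferrin",
                  "digoxin", "dantrolene", "SASP"),
    er_mean = c(2.2, 3.1, 1.1, 0.7, 1.3, 2.3, 1.4),
    er_sd   = c(2.0, 2.3, 0.4, 0.2, 0.2, 0.9, 0.3),
    n       = c(4L, 4L, 4L, 3L, 4L, 4L, 4L))
}
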