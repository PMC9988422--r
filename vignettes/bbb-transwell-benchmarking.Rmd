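---
title: "Benchmarking transwell BBB models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transwell BBB models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbench)
```

# The measurement model

A transwell assay doses a substrate on one side of a cell-bearing porous
insert (luminal/apical "A" or abluminal/basolateral "B") and samples the
opposite, receiving compartment over time. `bbbench` estimates the
cell-layer permeability coefficient by the cleared-volume method:

1. **Cleared volume.** At each sampling time the receiver content is
   referenced to the donor concentration,
   $V(t) = C_r(t)\,V_R / C_d(t)$ (µL). Only the concentration *ratio*
   enters, so any consistent concentration unit works; one file must use
   one unit.
2. **PS by slope.** Under sink conditions $V(t)$ is linear in $t$ and its
   ordinary-least-squares slope is the permeability–surface-area product
   *PS* (µL/min). The fit keeps a free intercept so an early-time lag
   (mixing, membrane wetting) does not bias the slope; the intercept and
   $r^2$ are retained as diagnostics.
3. **Blank-membrane correction.** Cell layer and insert membrane are
   barriers in series: $1/PS_e = 1/PS_{total} - 1/PS_{mem}$. The formula
   is undefined when $PS_{total} \ge PS_{mem}$; such replicates are
   excluded and flagged (`ps_total_ge_ps_mem`), never clamped, because
   cells cannot make the composite barrier leakier than the bare
   membrane.
4. **Pe.** $P_e = PS_e / S$, converted from (µL/min)/cm² to the
   conventional $10^{-6}$ cm/s via the factor $1000/60$.

Bidirectional assays (dose A, receive B; then dose B, receive A) yield the
efflux ratio $ER = P_e(B{\to}A)/P_e(A{\to}B)$. TEER is net resistance
times area, $(R_{coculture}-R_{blank})\cdot S$ in Ω·cm².

## Donor-concentration handling

Two modes are supported (`donor_mode`):

- `"nominal"` — the sink approximation: $C_d$ is the dosing concentration
  at every timepoint, $V(t)$ is the pointwise ratio above.
- `"measured"` (default when donor samples exist) — the cleared volume is
  accumulated per sampling interval, dividing each interval's receiver
  increment by the interval-mean donor concentration. This is the
  conventional bookkeeping when the donor is sampled at every timepoint,
  and it removes the depletion bias of the pointwise ratio: dividing a
  cumulative amount by an end-of-run donor concentration inflates late
  cleared volumes when the donor has depleted by ~10%.

## Blank matching

A blank (cell-free) insert is fitted per assay to supply $PS_{mem}$.
Which blank corrects which cell insert is genuinely open — published
protocols rarely state a matching rule — so it is a parameter
(`blank_match`). The default pools blank fits within (substrate,
experiment) **across directions**: the bare membrane has no sidedness, so
a single $PS_{mem}$ per experiment is the physically meaningful estimate,
and using the same correction for both directions cancels blank-fit bias
from the efflux ratio, which is the quantity of interest. Per-direction
matching (`"direction"`) and substrate-wide pooling (`"substrate"`) are
available; narrower rules fall back to broader pools when a matching
blank is missing, and a replicate with no blank at all is reported
uncorrected with an explicit flag.

# Statistics

- Directional significance within an experiment uses the two-sample
  equal-variance **Student** *t*-test (two-tailed) on replicate values,
  marked `*` for p < 0.05 and `**` for p < 0.01. The equal-variance form
  is deliberate — it is the test named by the standard operating
  procedures this pipeline targets — and degenerate zero-variance groups
  are handled explicitly (equal means → t = 0, p = 1).
- Per-substrate ER summaries report the arithmetic mean and **sample** SD
  (n−1) over independent experiments; n = 1 leaves the SD absent. Values
  are kept at full precision internally and rounded to one decimal only
  in reports.
- The transporter-function call (`classify_transporter()`) is a decision
  rule, not a test: `efflux_functional` iff mean ER > 1 **and** at least
  half of the experiments individually show $P_e(B{\to}A) > P_e(A{\to}B)$
  with a significance mark. No community consensus ER cutoff exists for
  transwell BBB models, so both thresholds are parameters surfaced in the
  report.
- Facility agreement (`compare_facilities()`) is likewise a convention:
  mean ± SD intervals overlap, plus matching classifications when both
  sides carry per-experiment data. Summary-only records (published
  mean ± SD with no experiment detail) are compared on overlap alone, and
  the applied rule is printed in the `criterion` field.

# Receptor-mediated transcytosis

Two complementary checks:

- `saturation_check()` splits a dose–uptake curve at a breakpoint
  (default 2400 pmol, a parameter) and compares least-squares slopes
  below and at/above it. Verdict `saturable` iff the relative slope drop
  $1 - s_{high}/s_{low}$ exceeds a threshold (default 0.2 — an invented
  but surfaced default; published descriptions of such curves are
  qualitative). No binding model is fitted and no $K_d$ is estimated.
- `competition_test()` compares labeled-ligand transport with and without
  unlabeled competitor. Verdict `rmt_consistent` iff the
  with/without ratio is < 1 **and** the Student *t*-test is significant;
  a ratio ≥ 1 is `not_rmt` regardless of p, since receptor blockade
  cannot increase transport.

# The simulator

`simulation_config()` + `simulate_assay()` implement a mass-conserving
two-compartment exchange,
$\mathrm{d}A_r/\mathrm{d}t = PS_{fwd} C_d - PS_{bwd} C_r$, with:

- a passive cell-layer clearance `ps_passive` (µL/min);
- an apically polarized efflux increment `ps_active`, added to B→A and
  subtracted from A→B cell-layer transport (the minimal lumped mechanism
  that produces ER > 1 under this estimator — no intracellular
  compartment is modeled, because the assay only observes compartment
  concentrations);
- optional saturation of the active component,
  $PS_{act} \cdot k_m/(k_m + C_d)$;
- the insert membrane in series (`ps_membrane_blank`), so that the
  analysis-side correction is exact by construction;
- multiplicative lognormal measurement noise with mean 1 and configured
  CV, applied per sampled concentration, seeded and reproducible.

**Receiver renewal.** The simulation follows the insert-transfer protocol
that the cleared-volume method presumes: at every sampling time the
receiving compartment is renewed (the insert is moved to a fresh well, or
the receiver solution is fully sampled and replaced), so each interval
starts with an empty receiver while the donor depletes over the whole
run; the reported receiver concentration is the cumulative transferred
amount over the receiver volume. This matters: without renewal a blank
insert equilibrates within the hour and its fitted $PS_{mem}$ is tens of
percent low, which no slope-based estimator can repair. Within each
interval the linear case is solved in closed form
($A_r(\Delta t) = \frac{a}{b}(1-e^{-b\Delta t})$ with
$a = PS_{fwd}A_0/V_d$, $b = PS_{fwd}/V_d + PS_{bwd}/V_r$); the saturable
case is integrated with `deSolve::ode` at rtol 1e-9/atol 1e-12. Mass
conservation (donor + cumulative receiver = dose) is exact in the linear
path and held to ~1e-6 relative by the integrator.

The competition simulator uses the receptor-occupancy law
$capacity \cdot L/(k_d + L + U)$ plus a passive leak proportional to the
labeled dose; an equimolar competitor therefore reduces the receptor
component by exactly $(k_d+L)/(k_d+2L)$ in the noise-free case. The
15-min competitor preincubation of the wet protocol is represented by
letting the competitor term act from $t=0$.

## Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| membrane area | 0.33 | cm² | 24-well transwell insert |
| luminal / abluminal volume | 200 / 600 | µL | conventional 24-well working volumes; configurable (insert lines differ) |
| sample times | 15, 30, 45, 60 | min | standard four-point clearance design |
| replicates | 4 | per direction | typical "more than three replicates" practice |
| noise_cv | 0.1 | — | realistic plate-reader / LC-MS CV for these assays |
| ps_membrane_blank | 10 × ps_passive | µL/min | blank membranes are much leakier than a tight cell layer |
| dosing concentration | 10 | amount/µL | arbitrary; the estimator is unit-invariant |
| rmt_kd, labeled & competitor dose | 200, 200, 200 | pmol | equimolar competition at receptor half-occupancy |
| rmt_capacity, rmt_passive_leak | 100, 0.02 | resp. units, fraction | receptor-dominated transport with a small paracellular leak |

## What the simulator does and does not emulate

It reproduces the features the estimator is sensitive to: bidirectional
kinetics with polarized transport, series membrane resistance, donor
depletion, receiver renewal, and multiplicative measurement error. It
does **not** model unstirred water layers (assays on a rocking shaker are
assumed well mixed), intracellular accumulation or metabolism, protein
binding, recovery losses, or well-to-well biological variability beyond
measurement noise. Passing recovery tests therefore demonstrates that the
estimation chain is correct and robust to measurement noise and
depletion — not that any particular laboratory model is well behaved.

# Degenerate inputs and numerical choices

- Fewer than two timepoints: flagged `too_few_timepoints` at read time,
  refused by the fitter — never silently dropped.
- Non-positive clearance slope (no detectable transport): the fit is
  flagged unusable; pipeline stages refuse it by name.
- $PS_{total} \ge PS_{mem}$: replicate excluded with
  `ps_total_ge_ps_mem`.
- Zero-variance *t*-tests: equal means give (t = 0, p = 1), unequal give
  (±∞, 0), avoiding the "data essentially constant" failure.
- All report rounding is one decimal in $10^{-6}$ cm/s (Pe) and ER units;
  internal values keep full precision.

# Problem sizes

The test suite and the reproduction script use desk-scale problems: the
bundled reference dataset (7 substrates × ≤4 experiments), single-
and four-experiment simulations with ≤4 replicates, and Monte-Carlo loops
of 100 seeded runs for the noisy-recovery and competition-agreement
rates. The whole suite runs in well under a minute on one core.

# Known limitations

- The slope estimator assumes the renewal protocol; data collected with a
  continuously accumulating receiver will show downward-biased PS for
  leaky barriers, and no correction for that is attempted here.
- The efflux classification and facility-agreement rules are surfaced
  conventions; different cutoffs may suit other model systems.
- Expression/localization benchmark items are declared evidence, not
  computed: blot or image quantification is out of scope.
- No TEER pass threshold is imposed — TEER enters the scorecard as
  measured evidence only, since defensible thresholds are model- and
  device-specific.
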