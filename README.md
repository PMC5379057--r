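# organflow

Flow pharmacokinetics, design and inference for multi-organ microfluidic
culture platforms.

Perfused "organ-on-chip" platforms link tissue modules — for example an
ovarian follicle module feeding fallopian, uterine, ectocervical and
liver modules — by microfluidic flow, so that hormones secreted upstream
reach downstream tissues at physiologic concentrations. Designing and
interpreting such experiments needs a transport model: what
concentration does a given secretion rate produce, how fast does the
system respond to a change, how far does a downstream module lag behind
its neighbour, and what can daily immunoassay measurements of the
effluent tell you about the secretion rate that produced them?

organflow answers these questions with a well-mixed compartmental mass
balance. For each module $i$ with volume $V_i$, concentration $C_i$
(pg/ml), flows $Q$ (ml/h), zero-order secretion $R_i(t)$ (pg/h) and
first-order elimination $k_i$ (1/h):

$$ V_i \frac{dC_i}{dt} = \sum_{j \to i} Q_{ji} C_j
   - \Big(\sum_{i \to k} Q_{ik}\Big) C_i + R_i(t) - k_i V_i C_i $$

Around that core the package provides:

- **Platform presets** (`make_platform()`): single-tissue (solo,
  40 µl/h), two-tissue (duet) and five-tissue (quintet, 100 µl/h with an
  ectocervix→follicle recirculation loop) topologies, with flow-balance
  validation and through-flow ordering.
- **Simulation and analysis** (`simulate_platform()`, `steady_state()`,
  `step_response_time()`, `intermodule_lag()`): deterministic stiff ODE
  integration, direct steady-state solves, 90% step-response times and
  50%-crossing lags.
- **A synthetic 28-day endocrine cycle** (`make_pituitary_forcing()`,
  `make_cycle_secretion()`, `sample_assay()`): FSH/hCG/prolactin
  "surge-purge" forcing, calibrated E2/P4/inhibin secretion profiles in
  cyclic and pregnancy-like modes, and a daily assay-sampling model with
  lognormal noise at published CVs and left-censoring at functional
  sensitivity.
- **Design search** (`find_flow_config()`, `lag_profile()`): exhaustive
  flow/volume grid evaluation against physiologic-concentration windows
  and response-time bounds.
- **Inference** (`estimate_secretion_rates()`, `per_tissue_rate()`,
  `fold_change()`): secretion-rate recovery from noisy censored effluent
  series by steady-state inversion, per-follicle daily production rates,
  and peak/AUC fold comparisons.
- **Pump QC** (`classify_actuator()`, `reroute_plan()`,
  `daily_flow_rate()`, `normalize_stroke()`): 250–625 µs actuation-time
  classification, fail-safe rerouting over redundant pump pathways, and
  flow/stroke monitoring arithmetic.
- **A reproducible pipeline** (`run_pipeline()`): forcing → secretion →
  simulation → sampling → recovery → comparison, with seed fan-out, CSV
  outputs and a run manifest (thin CLI wrapper in `inst/scripts/`).

## Worked example

Simulate a 28-day cycle on the single-tissue platform, sample the
acceptor daily with realistic E2 assay noise, and recover the secretion
rate:

```r
library(organflow)

solo <- make_platform("solo")
solo
#> <platform_config> solo-MFP
#>   modules: 3 (donor=donor, acceptor=acceptor)
#>   paths:   2 (2 carrying flow)

prof <- make_cycle_secretion("cyclic")
traj <- simulate_platform(solo, cycle_secretion_spec(prof, "tissue"),
                          t_grid = seq(0, 28 * 24, by = 1))
e2 <- sample_assay(traj, "acceptor", "E2", seed = 42)
subset(e2, day >= -2 & day <= 2)
#>    day analyte    value  unit censored
#> 13  -2      E2 199.0686 pg/ml    FALSE
#> 14  -1      E2 232.4990 pg/ml    FALSE
#> 15   0      E2 240.2559 pg/ml    FALSE
#> 16   1      E2 245.7662 pg/ml    FALSE
#> 17   2      E2 217.2036 pg/ml    FALSE
```

The effluent E2 rides around 250 pg/ml (physiologic late-follicular
levels) and peaks at the hCG surge; with this noise draw the argmax
lands on day +1 — with noise disabled (`noise_cv = 0`) it is exactly
day 0. Inverting the steady-state balance over a declared near-peak
window recovers the secretion rate:

```r
estimate_secretion_rates(e2, solo, window = c(-4, 0))
#> <rate_estimate> E2 in tissue: 8.311 pg/h (se 0.611, n = 5)
```

about the 10 pg/h peak secretion rate, attenuated because the
near-peak window averages over the rising and falling flanks. The
system responds well within a day:

```r
step_response_time(solo, "acceptor", fraction = 0.90)
#> [1] 68.07   # hours; the tissue module alone: (V/Q) ln 10 = 40.30 h
```

(68.07 h is above 24 h — the solo platform at 40 µl/h is slow; the
five-tissue design grid is what achieves sub-day response, see below.)

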