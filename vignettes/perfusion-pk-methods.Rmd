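---
title: "Methods: flow pharmacokinetics of multi-organ microfluidic platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow pharmacokinetics of multi-organ microfluidic platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organflow)
```

## The model

organflow treats a perfused multi-organ culture platform as a network of
well-mixed compartments. Each module $i$ (donor reservoir, tissue modules,
acceptor/collection module) holds a constant media volume $V_i$ (ml) and a
single concentration $C_i$ (pg/ml) per analyte. Mass balance gives

$$ V_i \frac{dC_i}{dt} \;=\; \sum_{j \to i} Q_{ji} C_j \;-\;
   \Big(\sum_{i \to k} Q_{ik}\Big) C_i \;+\; R_i(t) \;-\; k_i V_i C_i , $$

where $Q$ are the directed flow rates (ml/h), $R_i(t) \ge 0$ is a
zero-order production (secretion) rate in pg/h, and $k_i \ge 0$ an
optional first-order elimination constant (1/h) representing tissue
consumption. The donor draws fresh media (concentration zero) at its net
outflow rate; the acceptor discharges the media it receives (daily
collection), so all volumes stay constant. Production and elimination are
deliberately split into separate terms: a single signed "production or
elimination rate" is ambiguous about concentration dependence, and
secretion is physically zero-order while consumption scales with the
local concentration.

Three preset topologies ship with the package. The single-tissue (solo)
and two-tissue (duet) platforms are pure cascades at a default
through-flow $Q_D = 0.040$ ml/h; the five-tissue (quintet) platform runs
donor → follicle → fallopian → uterus → ectocervix → liver → acceptor at
$Q_D = 0.100$ ml/h with a recirculation loop returning media from the
ectocervix module to the follicle module at $Q_R$. Segments inside the
loop carry $Q_D + Q_R$ so every intermediate module is flow-balanced.
The five blank spare modules exist in the hardware for future capacity;
they are modelled as unwired (zero-flow) compartments and stay at zero.
No value for $Q_R$ is fixed by the source platform description, so the
preset default is $Q_R = Q_D$ (multiplier 1), with multipliers 0 and 10
spanning the design grid. Intra-module recirculation is subsumed by the
well-mixed assumption — the model has one concentration per module.

Assumptions worth stating: perfect instantaneous mixing within modules,
incompressible steady flow, no spatial gradients, no binding of hormones
to platform materials, no diffusion limitation at the hydrogel
encapsulating the tissue, and no feedback of gonadotropin forcing on
secretion rates (forcing and secretion are independently prescribed, as
in an exogenously clocked culture schedule).

## Units and conventions

Everything internal is ml, ml/h, hours and pg/ml. Hardware-facing
interfaces (platform YAML files, flow QC) speak µl and µl/h and convert
at the boundary, which keeps the steady state of a single secreting
module at the unit-free $C^* = R/Q$ — e.g. 4 pg/h at 0.04 ml/h gives
exactly 100 pg/ml. Mass units were chosen over molar because every
effluent measurement is reported by mass-based immunoassay;
`pg_per_ml_to_nmol_per_l()` converts where molar reasoning is needed.
Time zero is the start of culture (cycle day −14); the ovulatory hCG
surge defines day 0, so the follicular phase spans days −14..0 and the
luteal phase days 0..+14.

## Numerics

The system is linear with (possibly) time-varying forcing. Simulation
uses the stiff-capable `deSolve::lsoda` with an analytic constant
Jacobian, `rtol = 1e-8`, `atol = 1e-12` pg/ml — fixed defaults so
trajectories are deterministic and reproducible to the solver tolerance.
Steady states are obtained by a direct linear solve of the balance
matrix; unwired (zero-row) modules are removed first, and a module with
production but no outflow or elimination is correctly refused as
singular. Tiny negative solver jitter (bounded by −1e-9 pg/ml) is
clamped to zero; anything larger raises an error rather than being
hidden. The test suite checks the integrator against an independent
matrix-exponential closed form on randomized five-module networks to a
relative 1e-6, and checks mass conservation in closed recirculating
loops over 28 simulated days.

"System response time" is not defined operationally by the source
platform description; this package defines it as the time for a module
(by default the acceptor) to reach 90% of its new steady value after a
unit step in donor concentration from a zero state, reported to 0.01 h.
The step response is computed by simulating the donor-forced subsystem
on a coarse expanding horizon, then re-integrating the bracketing
interval on a fine grid and interpolating the crossing. Intermodule lag
is the difference between 50%-of-own-final-value crossing times of two
modules on a monotone step response; non-crossing series raise an
explicit undefined-lag error rather than returning a number.

One empirical nuance: strong recirculation makes the loop modules charge
together as one larger effective compartment. Lags between sequential
modules *on* the loop collapse (the well-mixed limit), but the lag of
the donor→follicle entry hop grows, because the follicle then rises at
the pace of the whole loop. The mixing property is therefore asserted,
and should be interpreted, on sequential loop modules.

## The synthetic endocrine generator

The generator is first-class, tested code; every downstream stage runs
against it without any external data.

**Pituitary forcing ("surge-purge").** Piecewise-constant exogenous
schedules: FSH 10 mIU/ml over days −14..0; an hCG surge of 1.5 IU/ml for
16 h starting at day 0, purged to baseline 0 afterwards (the purge
target is taken as exactly zero); in pregnancy-like mode hCG is instead
sustained at 1.5 IU/ml and prolactin added at 25 ng/ml across days
0..14, emulating conceptus rescue of the corpus luteum. Segments are
half-open $[{\rm from},{\rm to})$.

**Ovarian secretion.** Only effluent *patterns*, not functional forms or
absolute rates, are available for the cycle, so secretion-rate curves
are modelled as smooth lognormal-shaped bumps
$r(d) = r_{\rm peak}\exp\!\big[-\ln^2\!\big(\tfrac{d-d_0}{p-d_0}\big)/2w^2\big]$
for day $d$ past onset $d_0$, peaking at $p$ with log-width $w$ — smooth,
nonnegative, and parameterized by exactly the three quantities a
clinician would describe (peak day, width, peak rate). Defaults:

| analyte   | onset | peak day | width | peak rate (pg/h) |
|-----------|------:|---------:|------:|-----------------:|
| E2        |  −14  |   −1.6   | 0.35  | 10  |
| inhibin A |  −14  |   −1.6   | 0.35  | 4   |
| inhibin B |  −14  |   −3.6   | 0.28  | 6   |
| P4        | −0.5  |    0.5   | 0.90  | 400 (baseline 4) |

The scale anchor is the E2 peak rate of 10 pg/h, which yields a Solo
effluent peak of roughly $R/Q = 250$ pg/ml at 0.04 ml/h —
mid-physiologic for late-follicular oestradiol. P4's 400 pg/h gives an
effluent peak near 7 ng/ml (physiologic luteal range); the inhibins land
at low hundreds of pg/ml. In pregnancy-like mode the P4 rate is held at
its maximum from its peak day through day 14 instead of declining; it
dominates the cyclic rate pointwise over the luteal phase.

**Timing calibration.** The acceptor series lags secretion by the
two-stage washout of the tissue and acceptor modules
($2 \times V/Q = 35$ h for the solo platform), so the timing parameters
were fixed once — by simulating the solo platform and reading the daily
argmax — such that the daily-sampled noiseless acceptor series peaks at
day 0 for E2, day −2 for inhibin B and day +2 for P4, the canonical
pattern of a healthy cycle. P4's peak day of 0.5 was selected over
nearby values because it centres the continuous effluent peak between
the day-2 and day-3 samples with a ~9% margin, rather than <1%. These
calibrated defaults ship with the package and are never re-fit at run
time.

**Assay sampling.** Daily samples are drawn from the trajectory at 24 h
intervals and perturbed by multiplicative lognormal noise with
$\sigma = \sqrt{\ln(1 + {\rm CV}^2)}$ and a mean-one correction, so the
noise is unbiased and the realized coefficient of variation equals the
assay's intra-assay CV. Defaults follow the published assay validation:
E2 CV 6.3%, LOQ 10 pg/ml; P4 CV 4.4%, LOQ 150 pg/ml; inhibin A CV 5.1%,
LOQ 12 pg/ml; inhibin B CV 4.5%, LOQ 14 pg/ml. Values below the
functional sensitivity are left-censored: reported *at* the LOQ with a
flag, never dropped, so estimators retain the censoring information.
Sampling is bit-reproducible for a fixed seed and restores the caller's
RNG state.

**What the generator does and does not emulate.** It reproduces daily
sampling of a flowing system, realistic assay noise and censoring, and
the relative phase structure of the four hormones. It does not model
folliculogenesis, gonadotropin dose–response coupling, day-to-day
biological variability between replicates, inter-assay drift, or tissue
consumption of hormones by downstream modules. Passing tests therefore
demonstrate correctness of the transport model, the sampling model and
the inference machinery — not biological fidelity of absolute hormone
levels, and in particular not the large inter-platform fold decreases
observed in real multi-tissue cultures, which reflect unmodelled
consumption and altered upstream secretion.

## Design search

`find_flow_config()` deliberately uses an exhaustive grid — volumes
ascending, flows ascending, recirculation multipliers ascending — rather
than continuous optimization: the grid is small, the evaluation is the
full 28-day simulation plus a step-response computation, and a
deterministic sweep is auditable. Feasibility requires the peak simulated
concentration of a named module inside a physiologic window; the default
oestradiol window of 30–400 pg/ml (applied to the follicle module) comes
from standard reference ranges for follicular-to-peak serum E2, since no
numeric window is fixed by the source description, and is configurable.
Ties are broken toward smaller total system volume, then smaller
through-flow (less media consumption). All tissue modules share one
volume knob in the default grid. The default grid is 4 volumes × 10
flows × 3 recirculation multipliers = 120 candidates, evaluated on a
2-hourly 28-day grid.

## Inference

Rate recovery inverts the steady-state balance: with production confined
to one module, the measured module's steady concentration is
proportional to the rate, $C = sR$, with the sensitivity $s$ obtained by
solving the balance system at unit production ($s = 1/Q$ on a pure
cascade). The estimate is the least-squares constant fit (the mean) of
the uncensored measurements in a caller-declared steady window, divided
by $s$; the standard error follows from the residual variance. Censored
records are excluded — simple and conservative; a Tobit-style censored
likelihood is explicitly out of scope. The window must be declared by
the caller: the package does not auto-detect stationarity, because a
mis-detected window would silently bias the rate. Under the default E2
noise model (6.3% CV, 14 daily samples) the suite verifies that 95% of
seeded replicates recover the rate within 10% and the median error is
under 3%.

Fold comparisons between platforms use like-for-like statistics — peak
against peak, or trapezoid AUC against AUC over days — computed on
uncensored records only; which statistic underlies any particular
reported fold is a caller choice, since fold magnitudes are not tied to
one definition.

## Quality control

Actuator classification uses the empirical 250–625 µs actuation-time
stability window; both endpoints are treated as inclusive (the source
wording does not state closure, and boundary readings are taken as
evidence of function, not failure). Readings below the window indicate
incomplete valve opening, above it an actuation distance too long for
reliable actuation. Rerouting selects, per flow segment, the first
redundant pump pathway whose actuators are all stable — deterministic
and order-faithful to the pathway list — and flags a segment FAILED only
when no pathway qualifies. Daily realized flow is collected volume over
elapsed time; stroke-volume series are normalized to their first value
(idempotent by construction).

## Problem sizes and determinism

The shipped test and acceptance workloads use: 28-day simulations on 1 h
(cycle runs) or 2 h (design grid) meshes; a 120-candidate design grid;
200 seeded replicates for parameter recovery; and 10,000 draws for the
noise-model check. A single global seed fans out to per-stage child
seeds through a fixed affine map modulo $2^{31}-1$, so every stage is
independently reproducible and all numeric pipeline outputs are
byte-identical across runs with the same config and seed.

## Known limitations

The model is strictly linear: no saturable binding, no
concentration-dependent secretion, no volume changes from sampling
(media withdrawal is idealized as continuous discharge). The donor
forcing is either free (fresh media) or fully prescribed (Dirichlet);
partially mixed donor spikes are not modelled. The recirculation loop
follows the symbol definitions of the source model literally (ectocervix
back to follicle, bypassing the liver); if the physical loop includes
the liver, the preset must be edited accordingly. Absolute secretion
scales are this package's choice, constrained only to produce
physiologic effluent concentrations; inferences about absolute rates in
real cultures require calibrating those scales against measured data.
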