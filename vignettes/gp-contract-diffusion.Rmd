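---
title: "Modelling GP contract-service diffusion in an occupational population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GP contract-service diffusion in an occupational population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdiffuse)
```

## The problem

Young and middle-aged working people sign contracts with general
practitioner (GP) teams at much lower rates than the elderly, even where
contracting is free. `gpdiffuse` implements a system-dynamics model of how
that contract rate evolves over 2015--2030 when policy acts on two fronts:
a tailored GP service package that raises the **demand-side
attractiveness** of contracting (work-related disease prevention, WDP;
health education & counseling, HEC; health-care services, HCS), and
**supply-side incentives** that raise GP teams' motivation (education &
training, ET; job-title promotion, JTP; income incentives, II), including
how contract income is split inside the team (the income distribution
ratio, IDR).

## Model structure

The core is a two-channel innovation-diffusion (Bass) structure with two
population stocks, potential contractors $P$ and contractors $C$, with
$P + C = N$ fixed, plus a GP workforce stock $G$. Adoption flows from
$P$ to $C$ through

$$
\underbrace{\alpha P}_{\text{GP team mobilization}} \; + \;
\underbrace{\beta\,\delta\,\gamma\,\mu\,P\,C/N}_{\text{word of mouth}} ,
$$

and there is no reverse flow: contracts are free and withdrawal data are
essentially nonexistent, so the model deliberately omits withdrawals and
prevalence is non-decreasing. Reported "contract rate" always means the
prevalence $100\,C/N$ (a percentage that can approach 75%), never the
instantaneous adoption flow; both are recorded in every trajectory.

The three word-of-mouth multipliers carry the policy content:

* **Attractiveness** $\beta = \beta_0 + (w_{HCS} hcs + w_{WDP} wdp +
  w_{HEC} hec) \cdot \mathbf{1}(t \ge t_0)$. The package contents are
  additive increments on a strictly positive baseline $\beta_0$; without
  a baseline term the no-intervention scenario could not diffuse at all,
  yet it demonstrably does.
* **Driving force** $\gamma = \gamma_{\min}\,(g_0 + w_{ET} et +
  w_{JTP} jtp + ii \cdot L(\text{income}))\cdot$ with the same step
  gating. $L$ is a monotone piecewise-linear lookup from GP per-capita
  income to the income-incentive impact — the standard system-dynamics
  table-function idiom.
* **Collaborative effect** $\delta(r) = s\,[\,w\sqrt{r} +
  (1-w)\sqrt{1-r}\,]$ of the IDR $r$, discussed below.

The supply side closes a balancing loop: contractors create staffing need
(`gps_needed = max(floor, C / panel_size)`), staffing adjusts first-order
with time constant $\tau$, and a larger workforce dilutes per-capita
income (`base_income + contract_fee * C * idr / G`), which feeds back
through the lookup $L$ into $\gamma$. With the income-incentive switch
off, the workforce block is inert by construction — a property the test
suite checks.

All six switches activate as a step at the intervention start year
(default 2020, when building-based GP services were introduced); before
that, every scenario follows the same no-intervention dynamics, which is
what makes the pre-2020 segment usable as model history.

## The collaborative-effect functional form

A literal reading of the model's variable table would set $\delta = IDR$,
a monotone multiplier. But the reported policy experiment shows an
*interior optimum*: the 2030 contract rate peaks at IDR 0.5, with 0.7
second and 0.3 clearly lower. A monotone $\delta$ cannot produce that, so
the package uses the asymmetric concave composite above: the GP's share
and the team's share both enter through a square-root utility, with
asymmetry weight $w \in (0.5, 1)$ favouring the GP (core member), and the
normalizer $s$ chosen so $\delta = 1$ at the reference IDR (0.5). Hence
scenarios that do not vary the IDR are unaffected by this modelling
choice.

This family has a hard geometric limit worth stating plainly: keeping the
maximizer of $\delta$ between 0.5 and 0.7 (so the grid ranks
$0.5 > 0.7 > 0.3 > 0.1$) bounds the relative gap
$\delta(0.5)/\delta(0.7)$ at about 2%, while per-capita income — and with
it the lookup term of $\gamma$ — necessarily *increases* in the IDR. The
model therefore reproduces the location of the optimum and the large
asymmetry between 0.7 and 0.3, but it cannot stretch the 0.5-versus-0.7
difference to the reported 2 percentage points; the shipped residual
report (`reference_residuals.csv` in `inst/extdata`) shows exactly how
far that single anchor lands from its target, and the calibration is
flagged infeasible rather than smoothed away. We kept the tolerance at
0.5 pp rather than widening it to make the flag go away.

## Parameters, units, conventions

Only products and ratios of the multiplier chain are identifiable from
prevalence data, so three scale conventions are fixed once: $\beta_0 = 1$,
$g_0 = 1$, $\gamma_{\min} = 0.5$. The word-of-mouth coefficient $\mu$
(per year) then carries the overall internal-influence scale; $\mu$ is
treated as a constant contact-rate-times-adoption-fraction coefficient of
the Bass tradition. Structural constants are set to plausible magnitudes
for a large metropolitan occupational population and are absorbed by
calibration wherever their absolute scale matters:

| parameter | default | units | meaning |
|---|---|---|---|
| `N` | 1e7 | persons | young/middle-aged population (constant; no demographic flows) |
| `panel_size` | 2000 | contracts/team | panel served by one GP team |
| `contract_fee` | 100 | currency/contract/yr | per-contract subsidy pooled as team income |
| `base_income` | 150000 | currency/yr | non-contract income per team |
| `gp_adjust_time` | 1 | yr | staffing adjustment time constant |
| `gp_floor` | 100 | teams | minimum staffing |
| `idr_ref` | 0.5 | — | IDR at which delta is normalized to 1 |
| `dt` | 1/12 | yr | integration step |
| `horizon` | 2015--2030 | yr | simulated window |

The remaining parameters — $\alpha$, $\mu$, the initial prevalence
`cr0`, the six switch weights, the lookup ordinates, and the asymmetry
weight `w_delta` — are the calibrated degrees of freedom, mirroring what
a full published parameter table would have pinned down. The lookup
abscissae (120k, 225k, 260k, 400k) bracket the income range the model
actually visits (roughly 150k--350k across IDR 0.1--0.9); its ordinates
are calibrated through a monotone decomposition (`ii_y1` plus
non-negative increments), so any admissible vector keeps the table
non-decreasing.

## Numerical choices

The simulator integrates the two-state system $(C, G)$ with classic
fixed-step fourth-order Runge--Kutta at $dt = 1/12$ year. Explicit Euler
— the habitual choice in system-dynamics tools — was measured against
the closed-form solutions available for frozen multipliers (the pure
mobilization exponential and the two-channel Bass solution) and misses
them by 1--3% relative at this step size, far outside the 0.1% oracle
band the test suite enforces; RK4 meets it with orders of magnitude to
spare, at four derivative evaluations per step. Euler remains available
(`method = "euler"`) as the literal stock-flow update, and
`step_model()` exposes a single such update. The step discontinuity at
the intervention start year falls exactly on a grid point, so no stage
straddles the switch by more than one step. The adoption flow is
truncated whenever a step would overshoot $P = 0$ (only reachable under
extreme parameters); every truncation is logged in the trajectory's
`cap_events` attribute. Halving $dt$ moves the 2030 rate by well under
0.1 pp under the reference calibration — the convergence check in the
test suite.

## Inverse calibration

The exact parameter values behind the reported results are not publicly
available, so the package solves the inverse problem instead:
`gp_calibrate()` minimizes a weighted sum of squared anchor residuals
over a box, by Latin-hypercube screening plus Nelder--Mead refinement in
a logistic transform of the box (derivative-free: the objective is cheap
— one 15-year simulation per scenario — and potentially non-smooth at
the flow cap). The anchor set (`reference_anchors()`) transcribes the
reported 2030 outcomes: levels for the baseline (42.3%), the service
package (57.8%), single-content-with-single-incentive scenarios,
mixed-scenario levels and bands, the differences attributed to specific
interventions (15.4, 10, 33.1 pp), and the IDR grid (peak 75.2% at 0.5,
0.7 exceeding 0.3 by 9 pp, 0.5 exceeding 0.7 by 2 pp). Tolerances are
0.5 pp for exactly printed figures and 1--1.5 pp where the source
wording is itself approximate ("about", "around"); a reported 58--68%
band enters as a range anchor. Two soft structure constraints encode the
reported orderings (WDP ≈ HEC slightly above HCS; II above ET/JTP by
3--5 pp).

The shipped reference vector was produced by a two-stage run of
`gp_calibrate()` — a broad stage and a warm-started refinement, both
with recorded seeds — scripted end-to-end in
`scripts/make_reference_calibration.R` and committed with its residual
report. One vector must satisfy all anchors *simultaneously*; per-anchor
parameter switching is exactly what the joint objective forbids, and the
acceptance test re-evaluates the committed vector against the full
anchor set. A parameter-recovery experiment (free $\alpha$, $\mu$,
$\beta_0$ against anchors generated from known values, recovered within
5%) guards the identifiability of the freed subset before the reference
fit is trusted.

## The synthetic history and what validation shows

No annual historical contract-rate series for this subgroup is published
— only that official statistics exist and that the model tracks them.
`generate_history()` therefore emulates such a series from the model
itself: the historical policy path (no intervention before 2020, service
package from 2020 — which, by step gating, is simply the `gpsp`
trajectory), sampled annually, plus independent Gaussian observation
noise with a 1 pp default standard deviation, truncated to [0, 100]. The
noise default is a judgment call: large enough that the historicity
demonstration is not vacuous, small enough that administrative annual
statistics plausibly scatter that much.

`historicity_test()` compares a simulated trajectory against any such
series by MAPE (pass threshold 5% by default — the source reports
"good agreement" without a number, so the threshold is ours and is
configurable) and RMSE. Two things this does and does not establish: a
zero-noise self-generated series must close the loop with MAPE below
0.01% (a pure software check), and fitting a noisy self-generated series
shows the pipeline behaves sensibly — neither says anything about how
the real series would fit, because the synthetic series inherits every
structural assumption of the model (no withdrawals, constant population,
step intervention in 2020, no reporting artifacts or policy shocks).

Because MAPE is a relative measure, years with low prevalence (the first
simulated years, under the reference calibration) dominate it for any
absolute noise level — a 1 pp error on a 4% rate is already a 25%
relative miss; observed rates of exactly zero are dropped from the MAPE
with a warning, and fits over such early years are better judged by the
RMSE the report also carries. The demonstration below therefore samples
the window where prevalence is well above the noise floor:

```{r history}
ref <- reference_calibration()
h <- generate_history(ref, years = 2018:2023, noise_sd = 0.5, seed = 7)
traj <- gp_simulate(ref, gp_scenario(hcs = 1, wdp = 1, hec = 1))
historicity_test(traj, h)
```

`sensitivity_sweep()` re-runs one scenario while varying a single knob;
the IDR grid sweep reproduces `idr_sweep()` exactly and is the model's
reported sensitivity analysis.

## Worked example

```{r example}
res <- run_catalog(ref)
res[res$scenario %in% c("baseline", "gpsp", "mixed7"), ]
idr_sweep(ref)
```

## Known limitations

* No withdrawal/churn flow and a closed population: prevalence can only
  rise, and saturation behaviour beyond 2030 is untested extrapolation.
* The calibration is under-determined: many parameter vectors fit the
  anchors comparably; the shipped vector is one reproducible
  representative, regularized by bounds and the ordering penalties, not
  a unique estimate. No uncertainty intervals are attached (point
  calibration only).
* The 2 pp IDR 0.5-versus-0.7 margin is structurally out of reach of the
  constrained collaborative-effect family, as discussed above; the
  corresponding anchor is reported red by design. A second, milder
  tension: with the income-incentive magnitude pinned by the
  exactly-reported +10 pp single-incentive gain and the 75.2% IDR peak,
  the all-demand-plus-II scenario lands just above (by under 1 pp) the
  58--68% band reported for that scenario group. The committed residual
  report carries both.
* Simulations are desk-scale (about 180 monthly steps over 2015--2030;
  each run takes a few milliseconds), so every result in the test suite
  and acceptance script is recomputed from scratch at full resolution.
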