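---
title: "Model-based lung elastance and PEEP titration support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based lung elastance and PEEP titration support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventelast)
```

## The problem

Patients with acute lung injury or ARDS are ventilated with a positive
end-expiratory pressure (PEEP) that must balance two risks: too little PEEP
leaves alveoli collapsed and the lung stiff; too much over-distends already
recruited tissue and injures it. Lung *elastance* — pressure per unit volume,
cmH2O/l, the reciprocal of compliance — measures that stiffness directly, and
it can be identified breath by breath from the airway pressure and flow
signals that every modern ventilator already measures. `ventelast` implements
that identification and the PEEP-selection rules built on it.

## The model and its identification

The package uses the single-compartment linear lung model for a sedated,
paralyzed patient (no spontaneous effort, so pleural pressure is taken as
zero and airway pressure stands in for transpulmonary pressure):

$$P_{aw}(t) = E_{lung}\,V(t) + R_{lung}\,Q(t) + P_0,$$

with airway pressure $P_{aw}$ (cmH2O), inflated volume $V$ (l, the integral
of flow, zeroed at inspiration onset), flow $Q$ (l/s), elastance $E_{lung}$
(cmH2O/l), resistance $R_{lung}$ (cmH2O·s/l) and offset pressure $P_0$,
taken as the measured PEEP. Only inspiration is analysed: rising pressure is
what recruits — or damages — lung, so expiration carries no information the
selection rules need.

**Integral-based identification.** Rather than regressing pressure on
$(V, Q)$ sample-wise, `identify_constant()` integrates the model from
inspiration onset $t_0$ to every sample $t_i$:

$$\int_{t_0}^{t_i} P_{aw}\,dt
  = E \int_{t_0}^{t_i} V\,dt + R\,V(t_i) + P_0\,(t_i - t_0),$$

and solves the resulting overdetermined linear system by ordinary least
squares. Integration low-pass-filters the sensor noise, which is what makes
per-breath estimates usable at 100 Hz with ~0.5 cmH2O pressure noise. With
$P_0$ fixed the unknowns are $(E, R)$; $P_0$ can instead be estimated as a
third parameter, but with a square (constant) flow profile the volume
regressor is then collinear with time and the system is singular — the
function detects this and advises fixing $P_0$.

**Dynamic elastance.** A single $E_{lung}$ per breath hides how stiffness
changes *within* the breath as volume is inflated. `identify_dynamic()`
fits the time-variant model

$$P_{aw}(t) = E_{drs}(t)\,V(t) + R_{lung}\,Q(t) + P_0$$

by partitioning the inspiration into consecutive windows (default 0.1 s,
ten samples at 100 Hz) and solving, per window, the scalar integral
least-squares problem
$\int (P_{aw} - R\,Q - P_0)\,dt = E \int V\,dt$ with $R$ and $P_0$ held at
previously identified values. A *windowed* rather than pointwise estimate is
deliberate: pointwise division $(P_{aw} - RQ - P_0)/V$ would fit the data
exactly by construction and report a meaningless zero fitting error, whereas
a finite-dimensional $E_{drs}$ retains a genuine residual. With the window
stretched to the whole inspiration the windowed estimate collapses exactly
to the constant fit (the tests assert this nesting). Windows whose mean
volume is below `v_floor_frac` (default 0.05) of tidal volume are dropped:
elastance is unidentifiable while $V \approx 0$ at inspiration onset.

**Fitting error.** `reconstruct_pressure()` evaluates the identified model
and reports the absolute percentage error
$|P_{model} - P_{meas}|/P_{meas} \times 100$ per inspiration sample,
summarized as median [IQR]. Whether published summaries of this error used
means or medians per breath before pooling is not stated anywhere we could
verify; we report medians with linearly interpolated quartiles throughout.
Because the dynamic model nests the constant one, its error never exceeds
the constant model's on the same breath.

## Derived metrics

* **Dynamic-elastance area**, `edrs_area()`:
  $\int E_{drs}(t)\,dt$ over the inspiration (cmH2O·s/l). Each window's
  value represents that window, so the integral is the midpoint-rectangle
  sum `sum(edrs * width)` — exact for the piecewise-constant series the
  estimator produces, and exact for a linearly varying elastance evaluated
  at window midpoints. (A trapezoid between midpoints would silently drop
  half a window at each end of the inspiration.)
* **Work of breathing**, `wob_decomposition()`: with $P_0 = 0$
  (atmospheric reference, as appropriate for work), $WOB = P_{aw} V$
  decomposes as $E V^2 + R Q V$ — an elastic and a resistive part whose sum
  equals the total *exactly, per sample*, an identity the tests assert at
  1e-12. For the dynamic model, $WOB_E(t)/V(t)^2$ returns $E_{drs}(t)$,
  which is why the area metric is proportional to elastic work.
* **Summaries**: within a PEEP level, the $E_{drs}$ median/IQR pools all
  windows of all breaths; the constant elastance and the area are medians
  over breaths (one value per PEEP is what the selection rules consume).
  Across patients, `cross_patient_median()` uses linearly interpolated
  quartiles and rounds half-away-from-zero to one decimal, the convention
  of printed clinical tables (an exactly-halfway median such as 51.85 must
  round up, not to even).

## PEEP selection

Given a per-PEEP metric table (`titration_summary`):

* `select_minimum()` returns the PEEP with the lowest metric — maximum
  compliance. Ties break toward the **lowest** PEEP: when two levels are
  equally compliant the lower applied pressure is the safer choice, and
  this rule also reproduces the published tie case.
* `select_inflection()` implements the diminishing-returns rule: on the
  descending limb of the metric–PEEP curve it finds where the metric
  crosses 110% and 105% of the minimum, by linear interpolation between
  grid levels, and returns that PEEP interval (lower bound = 110% crossing,
  upper = 105% crossing, so the interval always lies at or below the
  argmin). Linear interpolation is our declared choice — published ranges
  are printed to coarse precision and their interpolation scheme is
  unknowable — so tests assert containment properties and our own
  hand-interpolated endpoints, not printed endpoints. If the minimum sits
  at the first grid level the interval is degenerate there (warning); on a
  non-monotone limb the last downward crossing before the argmin is used.

The PEEP grid is treated as data: titrations stopped early at, say, PEEP 16
or 27 cmH2O keep those levels, and selection operates on the actual grid.

The bundled `study_tables()` provide the printed per-PEEP metrics of a
published ten-patient ALI/ARDS titration study, which is what the
selection-rule tests and the acceptance script recompute from. For the
minimum-area rule, three of the ten patients' printed per-PEEP areas have
argmins that do not match the study's own printed selection (e.g. an argmin
at PEEP 28 against a printed selection of 20); those three are documented
discrepancies and excluded from the reproduction checks rather than
papered over. Similarly, the printed "minimum dynamic elastance" selections
are not always the argmin of the printed per-PEEP medians — the study's
operational definition evidently also used the within-breath trajectory —
so only the unambiguous patient is asserted.

## The simulator: what it emulates and what it does not

`sim_config()`/`simulate_titration()` generate volume-controlled SIMV
breaths over a staircase recruitment manoeuvre matching the study
conditions: tidal volume in the 0.4–0.6 l band (default 0.5 l), square or
decelerating inspiratory flow, 100 Hz sampling, PEEP raised in 5 cmH2O
steps from ZEEP, stopping before any level whose noiseless peak pressure
would exceed 45 cmH2O. Ground truth is

$$E(PEEP, V) = E_{base}(PEEP) + s(PEEP)\,V,$$

the simplest form that produces both a U-shaped elastance–PEEP relation
(default minimum 25 cmH2O/l at PEEP 15, ~52 at ZEEP — the moderate-ARDS
range) and the observed within-breath behaviour: $E_{drs}$ falling during
the breath at low PEEP (recruitment), rising at high PEEP (stretch), via
$s(PEEP) = 1.2\,(PEEP - 15)$ by default. This is a modelling convenience,
not a claim about lungs. Sensor noise is additive Gaussian (defaults
0.5 cmH2O, 0.01 l/s); resistance is constant (8 cmH2O·s/l by default);
expiration is passive first-order decay with time constant $R/E$ — its
fidelity is non-critical since only inspiration is analysed. Flow-shape
discontinuities are aligned with the sampling grid so the trapezoid-
integrated delivered volume equals the configured tidal volume exactly.

What passing simulation tests therefore show: the estimators invert the
model class they assume, at realistic noise, sampling and titration
protocol, and the selection rules recover a known optimum end-to-end. What
they cannot show: robustness to real-lung departures from the model —
nonlinear resistance, viscoelasticity, spontaneous effort, leaks,
cardiogenic oscillations — none of which the simulator emulates.

## Numerical choices

* Trapezoidal (cumulative) integration everywhere, second-order accurate at
  100 Hz; `integrate_flow()` starts at exactly zero.
* Segmentation: inspiration onset = flow rising through +0.02 l/s sustained
  ≥ 0.1 s (both config-exposed); cycle ends at the next onset, or at
  end-of-recording for the final breath provided its expiration was
  captured; candidate cycles without expiratory flow below −0.02 l/s are
  rejected; measured PEEP = mean pressure over the 50 ms before onset;
  partial cycles at the recording edges are discarded. Volume is re-zeroed
  at each onset rather than drift-corrected globally, since all analysis is
  per-breath. Indices are 1-based half-open intervals, R's native
  convention.
* Identification needs ≥ 10 inspiration samples; rank deficiency is
  detected via the QR decomposition rather than left to produce NA
  coefficients.
* Samples with non-positive measured pressure are excluded from the APE
  with a warning (they can occur at ZEEP under noise).
* Problem sizes in the tests and acceptance script: 2–10 breaths per level
  and 3 breaths per level in the 20-run end-to-end recovery study — enough
  that per-level medians are meaningful while keeping the default suite
  fast.

## Limitations

The model omits pleural pressure (valid only under sedation and paralysis),
nonlinear and flow-dependent resistance, and chest-wall mechanics; at high
fitting error the constant-elastance summary can misrepresent a patient, a
situation the dynamic estimate is specifically intended to expose. The
selection rules are decision *support*: they rank candidate PEEP levels on
respiratory mechanics alone and say nothing about oxygenation or
haemodynamics. No optimum elastance value generalises across patients — the
patient is their own reference, which is precisely why the titration is
analysed as a trend.
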