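---
title: "Multi-fidelity personalisation of cardiac active mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-fidelity personalisation of cardiac active mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofit)
```

This vignette is the package's account of the science it implements: the
models, the calibration procedures, the numerical choices, and — equally
important — what the synthetic study conditions do and do not establish
about real data.

## The problem

Active stress generated by cardiomyocytes drives ventricular contraction.
Phenomenological active-stress models (a handful of parameters, driven only
by the activation time) are easy to constrain from clinical pressure data,
but give no access to excitation–contraction coupling. Biophysically
detailed crossbridge models do, at the price of a high-dimensional
parameter vector that cannot be fitted by running an organ-scale model
inside an optimiser loop. The workflow implemented here splits the problem
by fidelity:

* **Step 1** personalises the cheap phenomenological model at the organ
  scale, where only a handful of forward simulations are affordable — a
  fixed-point iteration typically needs 2–4 of them.
* **Step 2** transfers the organ-scale solution to the cell scale as
  *median nodal traces* of stress, calcium and stretch, and personalises
  the detailed model against their biomarkers using a 0D cell model that
  costs milliseconds per evaluation, so a population-based optimiser with
  tens of thousands of evaluations is affordable.

## Models

### Phenomenological active stress (low fidelity)

$$S_a(t_s) = S_{max}\,\tanh^2\!\left(\frac{t_s}{\tau_{SR}}\right)
            \tanh^2\!\left(\frac{t_{CR}-t_s}{\tau_{SD}}\right),
            \qquad 0 \le t_s \le t_{CR},$$

zero outside the transient; $t_s$ is time since electrical activation.
The four parameters map almost one-to-one onto the four pressure
biomarkers, which is what makes the fixed-point calibration work: $S_{max}$
(kPa) sets the peak pressure, $\tau_{SR}$ (ms) the upstroke rate,
$\tau_{SD}$ (ms) the relaxation rate, $t_{CR}$ (ms) the transient — and
hence pressure — duration. Length dependence is neutral by default at the
cell scale; the organ-scale surrogate applies its own length-dependence
factor (below).

### Detailed crossbridge model (high fidelity)

A Land-type human contraction model with six states: troponin calcium
occupancy (`CaTRPN`), the blocked tropomyosin fraction (`TmB`), weak and
strong crossbridge fractions (`XW`, `XS`) and their distortions (`ZetaW`,
`ZetaS`). Calcium sensitivity is length dependent through
$Ca_{50}(\lambda) = Ca_{50,ref}\,(1 + \beta_1(\lambda - 1))$ and tension
through $h(\lambda) = \max(0,\, 1 + \beta_0(\lambda + \min(\lambda, 0.87)
- 1.87))$, with $\lambda$ capped at 1.2 inside the model; active stress is
$S_a = h(\lambda)\,T_{ref}/r_s\,(X_S(\zeta_S + 1) + X_W \zeta_W)$. Kinetic
constants not being fitted use the published reference values of the human
model (`land_params()`); the five fitted parameters default to a
representative personalised set ($n_{TRPN} = 3.22$, $\beta_1 = -1.21$,
$n_{Tm} = 5.47$, $Ca_{50,ref} = 0.501\,\mu M$, $k_{UW} = 0.046$/ms).

### Calcium transient

A double-exponential transient (`rice_params()`) with resting and peak
concentration and rise/decay time constants, normalised so the trace peak
equals $Ca_{max}$ exactly — this makes $Ca_{max}$ an interpretable fitting
bound (fits that want longer stress transients push it to the admissible
edge, which is visible rather than hidden in a shape factor).

### Three-element passive element

$$S_p = a_p\left(e^{b(\lambda-1)} - 1 + k\,(\lambda - 1 - C_d)\right),
\qquad \dot C_d = \frac{k\,(\lambda - 1 - C_d)}{\eta},$$

with $\eta = \eta_l$ when the dashpot lengthens and $\eta_s$ otherwise
($b = 9.1$, $k = 7$, $\eta_l = 200$ ms, $\eta_s = 20$ ms). The single
calibrated scale $a_p$ (kPa) controls the stretch minimum of the 0D model;
it absorbs organ-scale boundary-condition effects and is *not* a
single-cell stiffness. On this model, $\lambda_{min}$ is strictly
increasing in $a_p$: at the default crossbridge/calcium parameters,
$a_p = 42, 63, 87$ kPa produce $\lambda_{min} \approx 0.80, 0.83, 0.86$ —
the range over which stretch-minimum targets from organ-scale median
traces are matched by fitting $a_p$ alone. The exponential parallel branch
matters: with a linear spring in its place the compressive response
saturates and the stretch minimum becomes insensitive to the stress scale,
which is inconsistent with the behaviour the calibration relies on.

## The 0D electromechanics model

The cardiomyocyte stretch trajectory solves the force balance

$$S_a([Ca^{2+}]_i, \lambda, \dot\lambda, t) + S_p(\lambda, t) = 0,
\qquad \lambda(0) = \lambda_0 ,$$

with activation at the start of each cycle. Numerics
(`solve_stretch_equilibrium()`):

* the slow states (crossbridge fractions, troponin, tropomyosin, dashpot
  strain) advance by classical RK4 with the stretch frozen at the previous
  step;
* the distortion states are advanced by implicit Euler *as functions of the
  new stretch* inside the per-step scalar equilibrium solve (safeguarded
  Newton with a bisection fallback, residual tolerance $10^{-6}$ kPa).
  This is the stabilisation that makes the massless force balance well
  posed: a fully lagged stretch rate is unstable precisely where tension
  crosses zero, because the distortion feedback then flips the equilibrium
  between branches. Treating the distortions implicitly lets their kinetics
  act as the physical viscosity of the solve.
* the dashpot strain is initialised so the passive element is stress-free
  at $\lambda_0$, making the balance consistent at $t = 0$;
* output grid $dt = 0.1$ ms by default (0.2 ms inside optimisation loops);
  halving $dt$ moves $\lambda_{min}$ by $\sim 2\times10^{-5}$ relative, two
  orders below the 0.1% self-convergence requirement;
* beats repeat until the state at the cycle boundary changes by less than
  a tolerance in max-norm (steady state is recomputed whenever parameters
  change).

The core is compiled (Rcpp) because the cell-scale calibration and the
sensitivity analysis evaluate it tens of thousands of times; an
independent pure-R integrator (`engine = "r"`) mirrors the scheme and the
test suite checks the two agree to $10^{-7}$ in stretch.

## The organ-scale surrogate

`simulate_beat()` implements a lumped ventricle: a thin-walled
incompressible spherical shell with $\lambda = (V/V_0)^{1/3}$ and the
Laplace map $P = \tfrac{2V_w}{3V}(S_a + S_p)$ (converted kPa → mmHg),
diode valves with finite forward and backward resistances (backward
defaults 1000 mmHg·ms/mL, so closed valves leak slightly rather than
sealing perfectly), a three-element Windkessel afterload, and
constant-pressure atrial filling without an atrial kick. Two deliberate
physiological ingredients:

* **Length dependence at the organ scale.** The Tanh stress is multiplied
  by $\max(0, 1 + ld\,(\lambda - 1))$ (default $ld = 4$). A lumped sphere
  driven by a length-independent sustained stress ejects without bound —
  nothing terminates ejection — so some Frank–Starling-type dependence is a
  structural necessity of the surrogate, not a tuning knob. The cell-scale
  Tanh model stays neutral.
* **Asymmetric wall elasticity.** Exponential stiffening in extension
  (sets a finite end-diastolic volume under constant preload), linear in
  compression (ejection is terminated by afterload and length dependence,
  not by a wall).

Default configuration (chosen once as a physiologically plausible adult
ventricle at a 1000 ms cycle, before any calibration experiments):
$V_0 = 70$ mL, $V_w = 80$ mL, $P_{la} = 14$ mmHg, $a_{p,lv} = 10$ kPa,
$b = 10$, $R_1 = 40$, $R_2 = 1100$ mmHg·ms/mL, $C = 1.0$ mL/mmHg,
$R_{AVf} = 60$, $R_{MVf} = 40$ mmHg·ms/mL, true Tanh parameters
$S_{max} = 38$ kPa, $\tau_{SR} = 110$, $\tau_{SD} = 45$, $t_{CR} = 500$ ms.
This produces $P_{max} \approx 107$ mmHg, $dP/dt \approx +1.1/-0.9$
mmHg/ms, $PTD_{90} \approx 447$ ms, $SV \approx 75$ mL, EDV $\approx 110$
mL, $\lambda \in [0.79, 1.17]$ — within the clinical ranges of the target
biomarkers. On this configuration all six parameter→biomarker couplings
used by the fixed point are monotone with log-sensitivities between
roughly 0.2 and 1.5 in magnitude, which is what makes the multiplicative
updates contract.

One biomarker convention follows from lumped-model physics: `dPdt_min` is
extracted from the segment *after* the pressure peak (the isovolumetric
relaxation rate, which is also its clinical meaning). The global minimum
of $dP/dt$ on a lumped-model trace sits in a valve-switching transient
during early ejection and is insensitive to $\tau_{SD}$, which would break
the fixed-point update for that parameter; on smooth clinical-like beats
the two definitions coincide. Similarly, `PTD90` uses the pressure at the
activation time as its baseline — stated as a convention because duration
baselines differ between laboratories.

## Step 1: fixed-point calibration

`calibrate_step1()` loops simulate → extract biomarkers → cost →
multiplicative update, with unit weights and threshold 0.1. A fixed point
of the update map is exactly a biomarker match. There is no global
convergence proof; on the surrogate, self-consistency experiments
(synthetic targets from known parameters, initial guesses drawn ±50% by
Latin hypercube) converge in 2–4 iterations across seeds. An optional
per-iteration clip of the update factors to $[0.2, 5]$ (off by default) is
available to damp oscillations on extreme ratios. A forward-model failure
mid-loop returns the best iterate seen, flagged `aborted` — failures are
an expected mode, not an exception.

## Step 2: penalty method + differential evolution

`calibrate_step2()` computes target biomarkers from the median traces and
minimises the weighted relative least-squares cost (weights
$w_{Sa} = (5, 1, 5, 1, 1)$ for $S_{a,max}, dS_a/dt|_{max}, STD_{30},
STD_{50}, STD_{90}$ and $w_\lambda = 100$) plus $\mu \sum_i v_i^2$ over the
constraint violations $v_i$. The penalty schedule is $\mu = 10^3$ growing
tenfold over three stages, each stage warm-starting the next population —
chosen for robustness; the optimum of a feasible synthetic problem ends
with an all-zero violation report. Two modes exist: the calcium transient
model co-fitted (10 parameters, calcium-duration constraints active) or a
median calcium trace as fixed input (6 parameters).

The inner solver is best1bin differential evolution: Latin hypercube
initial population (15 per dimension), dithered mutation factor in
$[0.5, 1]$, binomial crossover 0.7, greedy selection (the incumbent cost
is non-increasing), convergence when the population cost spread falls
below 1% of its mean. DE is the right tool here because parameter
combinations inside the admissible box can make the 0D simulation fail;
failures map to a large finite sentinel cost and the optimiser simply
moves around them. Fitted-parameter bounds default to ±50% around the
defaults.

Two numerical points deserve emphasis:

* **The resting-stress constraint is relative.** "Resting stress is zero"
  is enforced as $|S_a(0)| \le 2\%$ of the peak. On a limit-cycle beat the
  cycle-start stress equals the end-of-cycle carry-over, which cannot
  vanish when the transient duration approaches the cycle length — and the
  admissible calcium durations ($CTD_{90}$ up to 785 ms at a 1000 ms
  cycle) explicitly allow such transients. An absolute near-zero tolerance
  makes the representative published parameter set infeasible and lets the
  penalty dominate the fit. Two percent sits a factor five below the 10%
  relaxation used by the sensitivity analysis.
* **Parameters are not claimed unique.** The acceptance surface is
  *biomarker* recovery (all five stress biomarkers and $\lambda_{min}$
  within 2% on synthetic self-consistency problems); different parameter
  vectors can produce the same biomarkers.

## Sobol sensitivity analysis

`saltelli_sample()` builds the (A, B, AB$_i$) radial design — $N(D+2)$
model runs for first-order and total-effect indices; `sobol_indices()`
uses the Saltelli-2010 estimator for $S1$ and the Jansen estimator for
$ST$, with bootstrap confidence half-widths over the $N$ design rows.
`evaluate_samples()` runs the 0D model per sample at the analysis setup
($\lambda_0 = 1.1$, $a_p = 42$ kPa, 1000 ms cycle) over the nine fitted
crossbridge/calcium parameters, excludes non-physiological stress traces
(the step-2 trace constraints with the resting stress relaxed to 10% of
the peak; biomarker-extraction failures count as non-physiological), and
substitutes excluded rows by the means over the physiological rows so the
estimator blocks stay aligned. `rank_parameters()` orders parameters by
their total effect summed over biomarkers, ties broken by input order. The
machinery is validated against the closed-form indices of an additive
linear function and of the Ishigami function at $N = 1024$.

At the analysis setup with mid-range (default) parameters the 0D model
produces $\lambda_{min} \approx 0.80$ — at the edge of the organ-scale
range 0.82–0.86 that fitted stiffnesses of 47–87 kPa produce, which is
consistent: 42 kPa sits just below the smallest fitted stiffness.

## Robustness protocols

`run_uncertainty_study()` perturbs the clinical biomarker targets ±10%
(coordinate-wise Latin hypercube, default n = 10) and reruns the
personalisation per sample; `run_initial_guess_study()` perturbs the
initial guesses ±50% (default n = 5) against fixed targets, reporting
differences relative to the default-initial-guess result. Failed samples
are recorded and excluded from summaries rather than aborting the study.
Summaries (`summarise_rel_diffs()`) report mean, SD, min and max of the
relative differences in percent, with the **population** SD (divisor $n$)
— the convention that reproduces the published cohort summary pairs from
their per-case values; table entries below the 0.1% reporting resolution
are treated as 0.

## What the synthetic conditions do and do not show

The generators emulate one-beat pressure/volume traces with the clinical
biomarker structure and heterogeneous nodal ensembles (activation-time
jitter, lognormal amplitude scaling with median one, additive stretch
offsets). They do not emulate measurement noise correlations, beat-to-beat
variability, atrial kick, 3D spatial stress gradients, or pre-processing
artefacts of catheter data. Passing self-consistency tests therefore
demonstrates that the estimators and optimisers recover what the models
can represent, under the stated noise models — not that a particular
patient's absolute pressures and volumes would be reproduced. Problem
sizes in the tests (ensembles of 25–101 nodes, DE populations of 150,
Sobol base samples of 1024 on benchmarks and 128 on the 0D model) were
chosen as the smallest sizes at which the statistical checks are stable.

## Known limitations

* The fixed-point updates have no global convergence guarantee; the clip
  guard exists for extreme ratios but is off by default.
* $a_p$ and the organ-scale surrogate parameters are effective quantities;
  no physiological interpretation at the single-cell or tissue level is
  claimed.
* Mechano-electrical feedback and membrane-potential dynamics are out of
  scope; calcium is prescribed or phenomenological.
* Estimated parameter vectors are not unique; only biomarker-level
  recovery is asserted.
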