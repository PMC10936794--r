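---
title: "Modelling and design notes for ventilab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and design notes for ventilab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventilab)
```

## The plant model

`ventilab` treats the ventilator–patient system as a single-compartment
lumped circuit: the lung is a compliance `Cc` (ml/cm H2O) behind the airway
resistance, fed through a load-reservoir branch with compliance `C2` and
resistance `R2c`. Eliminating the internal node gives a
first-order-plus-dead-time transfer function from commanded volume rate to
delivered flow,

$$G(s) = \frac{b_0}{a_1 s + a_0}\, e^{-\theta s},
\qquad b_0 = C_c,\; a_1 = C_c C_2 R_{2c},\; a_0 = C_c + C_2,$$

with transport delay $\theta = 0.45\,T_{resp}$. Units are fixed
package-wide: pressure in cm H2O, volume in ml, flow in ml/s, time in s.

Two assemblies coexist deliberately. The *symbolic* mode composes the
coefficients from physical parameters and is intended for parameter
studies (its homogeneity in the compliances is tested: scaling `Cc` and
`C2` together scales `a0` proportionally and leaves the DC gain
unchanged). The *canonical* mode returns the fixed reference set
`b0 = 0.07425, a1 = 0.022, a0 = 0.54`. At the reference parameter values
the two assemblies agree on `a0 = 0.54` but **not** on `b0`
(0.075 vs 0.07425) or `a1` (0.01315 vs 0.022). The origin of the canonical
numerator and lag cannot be derived from the tabulated physical
parameters, so the package refuses to guess: canonical mode uses the set
verbatim and logs a warning describing the mismatch. `R2c` and the valve
resistance sometimes written `Rv2c` are treated as the same quantity.

### Discretization

Simulation uses the exact zero-order-hold update
$y_{k+1} = \varphi y_k + (1-\varphi) K u_{k-d}$ with
$\varphi = e^{-a_0 \Delta t / a_1}$, which is exact at the sample instants
for piecewise-constant input — a delay-free step response matches the
analytic first-order solution to machine precision, and a smoothly varying
input converges at first order in $\Delta t$ (both tested). The transport
delay is an integer-sample ring buffer; the rounding, when inexact, is
logged. A guard rejects $\Delta t \ge a_1/a_0$ (the lag time constant),
not because the exact update would be unstable but because such sampling
cannot resolve the dynamics being studied. The default $\Delta t$ is
2 ms against a lag of ~41 ms.

## Reference waveforms

The volume-controlled flow reference is the gated constant: flow
$\gamma$ while $\gamma t < V_T$ **and** $0 < t < t_{insp}$ (strict
inequalities, honoured exactly: flow is zero at the cycle boundary), zero
otherwise, with within-cycle time $t \in [0, T_{resp})$.

No waveform equations exist in the literature this package draws on for
its CPAP and PAV modes, so both are package conventions chosen to give the
modes distinguishable signatures rather than clinical fidelity: CPAP is
the constant set pressure; PAV is PEEP plus the assist gain times a
half-sine patient-effort surrogate over the inspiratory window (whether a
measured or surrogate effort drives PAV in practice is
implementation-specific; the surrogate keeps the generator
self-contained). Defaults: breath period 4 s (normal adult
~15 breaths/min) split 1.6 s inspiration / 2.4 s expiration (I:E = 1:1.5),
set pressures 20 and 40 cm H2O as the two study levels.

## PID and its tuning

The PID is discretized with backward-Euler integral and derivative, the
derivative acting on the error (the continuous law differentiates the
error signal, so the discrete one does too). Actuation is clamped and the
integrator frozen while clamped (anti-windup); the clamp floor defaults to
0 in scenarios because the delivery valve is one-way — the ventilator
cannot draw flow back out of the patient.

No published gains exist for this loop, so defaults come from
internal-model (IMC) tuning: $K_p = \tau / (K(\lambda + \theta))$,
$K_i = K_p/\tau$, $K_d = 0$, with the closed-loop time constant
$\lambda = \max(\tau, \theta)$. On the delay-free canonical plant this is
the "closed-loop time constant equals the plant lag" rule
($K_p = 1/K \approx 7.27$, $K_i \approx 178.5\ \mathrm{s^{-1}}$); on
delay-dominant plants it backs off to the dead time, the usual robustness
guideline. All shipped results state their gains via the scenario object.

## The ILC-PID controller

The learning update is
$u_{i+1} = Q[u_i + L e_i] + C e_{i+1}$. The operator form that folds the
feedback term through $(1-Q)^{-1}$ is not realizable causally
sample-by-sample, so the package implements the scheme in the iteration
(lifted) domain: whole stored cycles are filtered offline between breaths,
while the $C$ term — the PID law applied to the current cycle's error —
runs online inside the breath. This is precisely the "current cycle
feedback" structure: feedforward learned from repetition plus within-cycle
feedback.

Realizations:

* **Q** is a zero-phase (forward–backward) first-order low-pass with
  cutoff defaulting to the plant cutoff $a_0/a_1 \approx 24.5$ rad/s.
  Zero-phase filtering introduces no steady-state lag (a constant series
  passes through unchanged); finite cycles are reflection-padded at the
  edges to suppress transients (pad length ~3 filter time constants,
  configurable).
* **L** is the scalar `l_gain / dc_gain` (default `l_gain = 0.8`), so the
  first-order contraction factor at DC is $|1 - l| = 0.2$. The learning
  signal is additionally *advanced* by the plant's transport delay in
  samples before filtering — standard serial delay compensation, placing
  each correction where the error it addresses was caused. Because the
  shift cancels the delay phase in the lifted domain, the reported
  contraction estimate $\sup_\omega |Q(j\omega)(1 - L G(j\omega))|$ uses
  the delay-free frequency response; an estimate $\ge 1$ warns rather than
  errors, since the bound is sufficient, not necessary.
* Iteration memory is explicit (`iteration_memory`), reset per scenario;
  nothing leaks across scenarios.

## Scenario design

Four default scenarios ship with the package. They are deliberately
labelled *paper-style*: published endpoint values for this loop (an
uncontrolled pressure excursion, specific tidal-volume maxima) depend on
excitation, gains and filters that are nowhere stated, so the package
asserts *orderings and saturation behaviour* — uncontrolled error
$\ge$ PID error $\ge$ ILC-PID final-cycle error — rather than endpoint
numbers.

* `cpap20`, `pav20`, `volume_tracking` use the delay-free canonical plant.
  The full stated delay, $0.45 \times 4\,\mathrm{s} = 1.8$ s, exceeds the
  1.6 s inspiratory window — with it, no within-breath controller can act
  on the breath that caused the error, which is one reason the published
  trajectories are not reproducible either way; the delay is therefore
  configurable, including 0. On these feasible-reference scenarios the
  per-cycle RMS error is monotonically non-increasing over ten learning
  iterations (tested with a 1e-9 jitter allowance).
* `volume_increasing` keeps a 0.2 s transport delay and commands a flow
  (300 ml/s) beyond what the clamped actuation can deliver. This is the
  regime where learning visibly pays off in delivered volume: the
  reactive PID ramps up only after the error appears each breath, while
  the learned feedforward saturates the valve from the start of
  inspiration, so ILC-PID delivers the larger tidal volume. On an
  easily-reachable reference the comparison inverts for an uninteresting
  reason — an overshooting controller "delivers" more volume — which is
  why the volume comparison is asserted on this scenario.

One unit oddity is kept as documented: tidal volumes of a few ml appear in
the source material for this loop's volume scenario, which is
physiologically implausible (adult tidal volumes are hundreds of ml); the
package keeps ml throughout and treats those endpoint values as
non-reproducible.

## The synthetic breath-record generator

The generator emulates per-recording tables of roughly 6000–8000 rows with
28 features per breath — ventilator waveform summaries (tidal volume, I:E
ratio, pressures, PEEP, flows, compliance/resistance estimates),
vital-sign and demographic fields (age, gender, urine output, laboratory
values) — plus a binary mode label (0 = volume, 1 = pressure). The actual
feature distributions of the emulated recordings are nowhere documented,
so the packaged `feature_spec` fixes physiologically plausible ranges
(VT 300–600 ml, I:E around 1:1.5–1:3, PEEP 4–10 cm H2O, and so on) and
shifts the ten pressure-linked features by 0.3–1.0 SD in pressure-mode
rows. A single `effect_size` knob scales all shifts: the default 1 gives
overlapping but learnable classes (a nearest-centroid baseline exceeds
70% test accuracy, the package's learnability floor), 3 gives
near-separable classes, 0 removes the signal entirely.

What the generator does **not** emulate: within-recording autocorrelation
(rows are i.i.d.), missingness, label noise, multi-class mode structure,
and any real covariance between clinical variables beyond the shared mode
shift. Passing benchmarks on this data therefore demonstrates that the
harness measures what it should — signal when present, chance when
absent — not that any classifier family would reach a particular accuracy
on hospital data.

Preprocessing follows the fitted-parameter pattern: `zscore()` (sample
SD, divisor $n-1$ — the divisor is stated because conventions differ)
and `one_hot()` return their fitted statistics/registries so held-out data
is transformed with training-set parameters only; tests assert this by
construction. `split_table()` is stratified 70/30 by default with the
total train size `round(n * fraction)`.

## The benchmark harness

Six classifier families map to standard algorithms: `DT` a Gini decision
tree (rpart), `OBT` the same learner under a wider hyperparameter search
(depth, minimum split, complexity — the "optimizable" variant), `NBT`
Gaussian naive Bayes (e1071), `NeNT` Euclidean k-nearest-neighbours
(class, on standardized one-hot expanded features), `ET` a boosted
tree ensemble (xgboost), and `NNT` a single-hidden-layer feed-forward
network (nnet, softmax output). The harness — stratified split, seeded
contiguous-fold CV plan, grid search, metric layer, ROC — is the package's
own; the individual learners are deliberately off-the-shelf.

Two conventions are fixed to match the field's reporting style: accuracy
is a percentage to one decimal; the proportion metrics are reported to
four decimals. Training time is recorded but excluded from every
assertion — it is hardware-dependent and meaningless across machines.
Published metric tables for this kind of benchmark are not always
internally consistent with their own confusion matrices; the package's
worked examples use only count sets whose recomputed metrics match the
values quoted alongside them, and no "corrected" values are invented.

The k-fold plan is a seeded shuffle followed by contiguous slicing — fold
sizes differ by at most one, each index validates exactly once. ROC is a
threshold sweep over the unique scores with trapezoid AUC, checked in
tests against an independent reference implementation (pROC) and for
invariance under monotone score transforms.

### The rule network

The rule-based neural classifier is a fixed-topology network stated as
explicit IF/THEN rules over seven binary inputs, three hidden nodes with
discrete activation sets and two output nodes. The stated rule list is
incomplete — no input rule ever assigns `H1`, and many input vectors fire
no classification rule — so the evaluator makes the gap explicit: the two
classification rules are checked in order (first match wins, since their
antecedents can overlap), and anything unmatched receives a configurable
default class together with an `unmatched` flag rather than a silent
answer.

## Problem sizes and numerical tolerances

Test and acceptance runs use: 10-cycle scenarios at 2 ms sampling
(2000 samples per breath); 600-row tables for the high-separability
benchmark and 2000 rows for the permuted-label null (sized so the ±0.05
accuracy band is several sampling standard deviations wide); 1000 fuzz
cases for the metric-recount oracle; 10 000 scores for the ROC null. The
step-response oracle tolerance is 1e-6 at 0.1 ms sampling; monotone
learning allows 1e-9 numerical jitter; z-score round-trips are checked to
1e-10.

## Known limitations

* The plant is linear and single-compartment: no nonlinear lung
  mechanics, leaks, humidifier dynamics, or switching-valve detail.
* PAV uses an effort surrogate, not estimated patient effort.
* The ILC analysis is nominal; no robust synthesis against plant
  mismatch is attempted (the contraction estimate is a design aid).
* The benchmark measures harness correctness on synthetic tables; it
  makes no claim about classifier rankings on real clinical data.
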