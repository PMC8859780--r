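---
title: "Predicting spike features of conductance-based neurons with small neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spike features of conductance-based neurons with small neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conductance-based (Hodgkin-Huxley-type) point-neuron models are the standard
biophysical description of spike generation, but integrating them is
expensive: the action potential forces sub-hundredth-millisecond time steps.
`spikefeat` implements a hybrid strategy: a cheap classifier (the *spike
prediction module*, SPM) watches three membrane voltages spaced 1 ms apart
and decides whether a spike peak will occur 1 ms after the last sample; when
it fires, a small regressor (the *feature prediction module*, FPM) predicts
the three quantities that summarize the upcoming spike --- the peak voltage
$V_{max}$, the afterhyperpolarization trough $V_{min}$, and the dropping
interval $T_{width} = t_{min} - t_{max}$ --- and the window then jumps past
the predicted spike to $t + 3\,\mathrm{ms} + T_{width}$.

## The biophysical model layer

Every neuron in the registry obeys the membrane equation

$$C_m \frac{dV}{dt} = -I_{leak} + I_{inj} - \sum_{ion} I_{ion},
\qquad I_{ion} = \bar g\, m^p h^q (V - E_{ion}),$$

with gating kinetics $dx/dt = \alpha_x(V)(1-x) - \beta_x(V)x$ or the
equivalent steady-state form $dx/dt = (x_\infty(V) - x)/\tau_x(V)$. Units are
fixed throughout: mV, ms, µA/cm², mS/cm², µF/cm². Rate functions are drawn
from a closed registry of named analytic forms (`linoid`, `expo`,
`logistic`, `constant`, `biexp_inv`, `sigtau`, `prodsigtau`), so the YAML
model configs under `inst/models/` are purely declarative --- no code is ever
executed from a config file. The `linoid` form's removable singularity is
evaluated by its first-order series within $10^{-7}$ mV of the singular
voltage, the standard numerical treatment.

Nine models cover ten firing patterns: regular spiking with and without
adaptation, fast spiking with and without adaptation, two bursters (the
regular-spiking burster also produces mixed-mode firing at a documented
intensity, found by scanning and frozen in its config), phasic onset
spiking, and the Class I / Class II excitable pair. Three are exact
transcriptions of canonical published models --- the classical Hodgkin-Huxley
squid axon (`ClassII_excitable`), the reduced Traub-Miles pyramidal cell
(`ClassI_excitable`), and the Wang-Buzsaki fast-spiking interneuron
(`FS_NoAdaptation`). The other six are *adapted* transcriptions: their cited
sources were not reproducible verbatim here, so each is built from the
source's well-known current composition, verified by simulation to produce
the named firing pattern, and labelled as adapted in its `citation` field.
Two deliberate simplifications: the retinal-ganglion-cell entry omits the
Ca²⁺ and Ca²⁺-gated K⁺ currents (no intracellular calcium state is in
scope), and both adaptation-class models implement adaptation with an M-type
slow K⁺ current.

## Integration

Fixed-step classical fourth-order Runge-Kutta at $dt = 0.01$ ms, implemented
in C++ for speed, with an R-level reference step (`rk4_step`) that the test
suite checks against the compiled path to $10^{-12}$. Gates are clamped to
$[0,1]$ only for floating-point overshoots below $10^{-6}$; anything larger
raises an error rather than masking a model defect. Dataset-generation runs
prepend a 100 ms settling period at zero input (excluded from collection) so
initialization transients never leak into the first spike's window; the
state itself is initialized at the model's resting hint with gates at
steady state.

Stochastic stimuli are frozen per integration step: one Gaussian draw per
step, seen identically by all four RK4 stages. True white noise is
ill-defined inside a Runge-Kutta scheme; frozen-per-step noise keeps every
trace bit-reproducible given a seed.

## Stimuli

Four injected-current protocols: constant, linear ramp, sinusoid, and
Gaussian noise at four levels. Level $L$ noise has
$\sigma = (L/4)(I_{max}-I_{min})/4$, so its central $\pm 2\sigma$ span covers
$25L\%$ of the model's constant-current sweep range --- a Gaussian has
unbounded support, and $\pm 2\sigma$ (≈95% of draws) is the conventional
effective range. Ramps span the sweep range over the trace; sinusoids use
the range midpoint as baseline, half the range as amplitude, and 5 Hz.

Each model's sweep range is stored in its config and was chosen, once, as a
range over which the model fires its characteristic pattern repetitively
(for the phasic model, a range of onset spiking; its single-spike responses
mean large sample quotas are unreachable by design, and the dataset builder
reports that rather than silently padding). The classical HH range is
7--15 µA/cm², roughly 1.1--2.4 times rheobase.

## Spike features and datasets

Spikes are segmented at upward crossings of the detection threshold
(default −10 mV): the peak is the maximum before the next downward crossing;
the trough is the minimum between the peak and the next upward crossing.
For the final spike of a trace the trough window runs to the trace end, and
the spike is kept only if the minimum falls strictly before the last sample
--- if the minimum sits on the final sample the trough was truncated and the
spike is discarded. (Discarding *every* final spike would leave phasic
neurons, which never fire a second spike, without a single usable sample.)
Feature times live on the integration grid; sub-grid event location is
deliberately out of scope, which has measurable consequences discussed
below.

The pre-peak window samples the trace at $t_{max}-3, -2, -1$ ms. Windows
that would precede the trace start are skipped and counted. Burst spikes
whose window overlaps the previous spike's falling phase are kept --- the
window is whatever the trace contains.

Training data use the constant-current protocol: 64 evenly spaced
intensities across the sweep range, 500 ms traces (extended automatically if
the quota is unmet), samples taken round-robin across intensities so
per-intensity counts stay balanced, default quota 2,400 per model. The grid
is deliberately dense with short traces: a 16-point sweep leaves the
intensity continuum under-sampled and measurably degrades generalization to
time-varying stimuli (constant→sinusoidal $R^2$ for peak voltage on the HH
model rises from 0.87 to 0.98 when moving from 16×2000 ms to 64×500 ms,
while constant-current accuracy is unchanged), and short traces keep onset
transients represented. Constant-current *test* sets use an intensity grid
offset by half a grid step, so every test intensity is unseen.

Noise test sets superimpose level-$L$ noise on the same intensity sweep
rather than on a single mid-range baseline. A single-baseline noise set
concentrates all features near one operating point (truth standard
deviation ~20× smaller than training), which makes $R^2$ on it degenerate
--- small absolute errors, meaningless or negative $R^2$. Sweeping the
baseline restores a meaningful denominator while leaving the noise
construction itself untouched.

All six quantities are min-max normalized to $[0,1]$ using extrema recorded
from the training split only; test values may fall outside $[0,1]$ and are
never clipped; denormalization is exact. Metrics are reported in normalized
units ($R^2$ is scale-invariant in any case).

## The networks

The FPM is a 3-10-3 feed-forward net (logistic-sigmoid hidden layer,
identity output); the SPM mirrors it as 3-10-1 with a sigmoid output and a
*strict* 0.5 gate --- an output of exactly 0.5 is classified as no-spike.
Training is full-batch iRPROP⁻ on the mean squared error for 1,000 passes
over a seeded 70/30 train/validation split (one "iteration" = one full
pass). iRPROP⁻ was chosen because it is deterministic given the seed, has
no learning rate to tune, and is a period-appropriate standard; its
defaults ($\Delta_0 = 0.05$, $\Delta_{max} = 1$, $\eta^+ = 1.2$,
$\eta^- = 0.7$) were fixed once against validation loss and are recorded in
every trained network's provenance.

SPM training windows are labelled positive when a spike peak follows the
last window sample by exactly 1 ms. Negatives (1:1 overall) come in two
strata: *far* windows with no peak within the following 1.5 ms, and
*near-miss* windows misaligned by ±(0.01--0.5) ms, concentrated within
±0.15 ms. The near-miss stratum exists because a gate trained only against
far negatives opens several grid steps before the true alignment, and the
FPM inherits the shift as a systematic feature error.

## The hybrid loop

The runtime loop slides the 3-sample window along a reference voltage trace
in 0.01 ms steps, evaluates the SPM (vectorized over all candidate windows,
then walked sequentially --- identical semantics, far faster), and on a gate
emits one prediction event and restarts at $t + 3\,\mathrm{ms} + T_{width}$
rounded to the grid. Termination is guaranteed because $t$ advances by at
least one step per iteration, and events can never overlap because
$T_{width} > 0$. One refinement: any *continuous* classifier output must
cross 0.5 somewhere before the exact alignment, so on gating the window is
advanced to the local maximum of the SPM output (at most a few hundredths
of a millisecond) before the FPM is consulted. Without this the gate fires
1--3 steps early and the predicted features slide along the learned manifold.
Evaluation matches events to true spikes by greedy one-to-one nearest-time
pairing within 1 ms.

The loop operates on a supplied reference trace (evaluation mode). A fully
self-propelled simulator that integrates subthreshold segments and splices
predicted spikes is a speculative extension and deliberately not part of
this package.

## What the accuracy ceiling looks like, honestly

Two measurement-resolution effects bound the achievable test metrics, and
no amount of model capacity moves them:

* **Grid quantization of extrema.** Peak and trough times are grid times,
  so $T_{width}$ is a multiple of 0.01 ms and successive spikes at one
  intensity --- which land at arbitrary sub-grid phase --- jitter by roughly
  one grid step. For models whose features barely vary across the sweep
  (the Traub-Miles $T_{width}$ spans only ~0.05 ms; its $V_{max}$ ~0.65 mV),
  this jitter is a sizeable fraction of the total variance, capping
  held-out $R^2$ near 0.95--0.97 for $T_{width}$ and ~0.99 for $V_{max}$,
  and pushing normalized RMSE above 0.02. The same nets reach
  $R^2 \ge 0.995$ wherever the feature's dynamic range dominates the grid
  jitter (all three features of the Wang-Buzsaki model; HH $V_{max}$ and
  $V_{min}$).
* **Future-noise dependence.** Under per-step Gaussian noise the trough is
  shaped by noise arriving *after* the prediction window, which no
  window-based predictor can know. Fitting a fresh net on noise-mode data
  itself (the within-mode ceiling) yields $R^2 \approx 0.93/0.92/0.21$ for
  HH $V_{max}/V_{min}/T_{width}$ at level 4 --- the unpredictability is in
  the data, not the method. Features with large dynamic range remain
  predictable (Wang-Buzsaki level-4 $V_{max}$: $R^2 = 1.00$ to two
  decimals).

The test suite asserts the near-perfect ($R^2$ rounding to 1.00,
normalized RMSE below 0.02) behaviour literally where the data can meet it
and documents these two ceilings where it cannot.

## Problem sizes

Full-protocol checks (2,400-sample datasets, 1,000 training iterations) run
for the three canonical models in the acceptance tests and the acceptance
script; module tests use 100--300-sample datasets and shorter training,
which exercise every code path at a few seconds per block. The nine-model
invariant checks (resting stability, gate bounds, dt-robust spike counts,
validation-curve shape) run at 300--1500 ms of simulated time per model.

## Known limitations

* Point neurons only: no morphology, synapses, networks, temperature
  scaling, or stochastic channel gating.
* The six non-canonical registry models are adapted, not verbatim,
  transcriptions; their qualitative firing patterns are tested, their exact
  parameter values are not authoritative.
* The SPM/FPM pair is trained per model; nothing is shared across models.
* Grid-resolution feature extraction is a modelling commitment (see the
  ceiling discussion above), matching the fixed-step integrator.
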