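---
title: "Temporal-difference models of dopamine and interval timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-difference models of dopamine and interval timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtd)
```

`microtd` simulates a single reinforcement-learning system that produces
both dopamine-like reward-prediction errors and interval-timing behavior.
This vignette explains the model, the representational assumptions that do
the scientific work, the parameters that matter, and the limits of what the
simulations show.

## The model

At each discrete time step `t` (20 steps per second by default) the agent
occupies a state described by a feature vector `x_t` and receives reward
`r_t`. A linear critic estimates the value (expected discounted return)

    V(t) = sum_d w(d) x_t(d)

and learns by temporal-difference (TD) updating: the prediction error

    delta_t = r_t + gamma * V(t+1) - V(t)

drives the weight update `w <- w + alpha * delta * e`, with eligibility
traces `e <- gamma * lambda * e + x_t` defining the plasticity window.
`delta_t` is the modeled correlate of phasic dopamine. For instrumental
tasks a softmax actor keeps per-action preferences `u(a, d)` over the same
features; action probabilities are `softmax_a(sum_d u(a,d) x_t(d))` and only
the taken action is updated, by `eta * delta * (1 - p(a)) * x_t`. This is
the tabular preference rule generalized to linear function approximation;
for one-hot features it reduces exactly to the tabular form.

All of these updates run online, within the step loop, using the current
weights for both `V(t)` and `V(t+1)`. Weights start at zero, eligibility
traces are reset at trial start, and `V` beyond the final step of a trial
is 0. One convention deserves emphasis: the successor value `V(t+1)` is
computed from what is actually *observed* at `t+1`, so on Pavlovian trials
it includes the reward-elicited features when the reward lands at `t+1`.
Without this, the reward-onset features behave as an unpredictable bonus
and learned values converge to a fraction of the analytic discounted value;
with it, the complete-serial-compound model reproduces `gamma^(T-t) * r`
essentially to machine precision (see the test suite). On instrumental
trials the next step's reward depends on an action not yet sampled, so the
successor value there cannot include it.

## Time as a feature vector

Two representations of elapsed time are implemented.

**Complete serial compound (CSC).** One indicator feature per post-onset
step: a perfect clock. It learns the exact discounted value function, and
exactly because of that it fails to match two dopamine findings: omission
of an expected reward produces one large negative error at the scheduled
step, and an early reward produces a large negative error at the usual
time — neither of which is observed in dopamine recordings.

**Microstimuli.** Each stimulus (cue *and* reward — rewards elicit their
own features) leaves a memory trace `y_t` set to 1 at onset and decaying by
`rho` per step. A bank of `D` Gaussian receptive fields with centers
`d/D` (d = 1..D) and width `sigma` reads the trace:

    x_t(d) = y_t * dnorm((y_t - d/D) / sigma)

The printed form of this equation in the antecedent literature is
typographically ambiguous about the normalizing prefactor; we use the
standard normal density of the standardized distance, with no `1/sigma`
prefactor, since any constant scale is absorbed by the learning rate.
Because the trace starts at 1, fields with centers near 1 fire *early*
after onset and centers near 0 fire *late*; late fields have broader
temporal tuning (the trace moves more slowly through them), so temporal
precision degrades with elapsed time. That asymmetry is the engine behind
every timing phenomenon in the package: rising reward-prediction errors
with longer cue-reward intervals, small and temporally smeared omission
responses, near-zero errors at the usual time after an early reward
(positive late-cue weights cancel against negative early-reward weights),
and response curves whose spread grows with the timed interval.

## Trial structure conventions

Each trial carries one blank step before cue onset (cue at step 1). The
phasic "cue response" is the prediction error of the transition *into* the
cue state; with no pre-cue step that transition would not exist, and the
recorded cue-onset error would tend to zero with training instead of
`gamma^T * r`. Because the pre-cue step has all-zero features, its
eligibility is zero and the cue response is never trained away — cues
really are unpredictable. The inter-trial interval (500 steps by default)
carries no stimuli or rewards; with per-trial trace resets every ITI step
has `delta = 0` and updates nothing, so the runner skips those steps
outright. Reported `reward_step - cue_onset` always equals the programmed
interval.

## Choosing the trace decay

`rho` is the timescale knob of the representation. The resolution with
which the basis can localize elapsed time `t` is proportional to
`|dy/dt| = y(t) * log(1/rho)`: deep traces move too slowly, shallow ones
have not yet separated. For a task whose difficulty concentrates at one
criterion duration `L` — the fixed interval of a peak procedure, the long
anchor of a bisection — the resolution at `L` is maximized by
`log(1/rho) = 1/L`, i.e. the trace reaches `1/e` at the criterion time.
`trace_decay_for_interval()` implements this rule and the behavioral
recipes use it by default. Two consequences are worth noting. First, the
rule is scale-invariant, so simulations at different intervals are
time-rescaled copies of each other; the spread of timed responding then
grows in proportion to the interval, which is the scalar property of
animal timing, and fitted peak times land on the trained interval at any
FI. Second, the package default `rho = 0.985` at 20 steps/s is the same
rule anchored at 3.3 s — the middle of the 1–16 s cue-reward range used
for the Pavlovian prediction-error simulations, which therefore run on the
default basis unchanged.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | – | critic learning rate (standard microstimulus parameterization) |
| `gamma` | 0.98 | per step | discounting; 0.98^20 ≈ 0.67 per second |
| `lambda` | 0.95 | per step | eligibility decay / plasticity window |
| `D` | 50 | – | microstimuli per stimulus |
| `sigma` | 0.08 | trace units | receptive-field width |
| `rho` | 0.985 | per step | trace decay (see above) |
| `steps_per_second` | 20 | – | 50-ms time step |
| `eta` | 0.1 (peak), 0.3 (bisection) | – | actor learning rate |

The actor rate is not constrained by prior literature; it was fixed once
per task family at design time. Bisection uses the larger value (and 4000
trials, 20% probes) because choice states are visited for only a few steps
per trial and ~160 probe presentations per duration are needed for a
stable psychometric function. The CSC convergence demonstration uses
`alpha = 0.1`, the conventionally larger step size for a tabular one-hot
code. Behavioral read-outs (response curves, psychometric functions) use
the probe trials of the second half of training, i.e. post-acquisition
responding.

## Tasks and analyses

* **Pavlovian conditioning** (`make_pavlovian_task()`): cue then reward at
  a fixed delay, with probe derivations (`make_probe_trial()`) for early
  reward, omission, and extended unrewarded trials.
* **Peak procedure** (`make_peak_task()`): reinforced trials reward the
  first "respond" at or after the FI; 25% of trials are unrewarded probes
  lasting three FIs. Responding is summarized by a four-parameter Gaussian
  fit (baseline + bump) of the probe response curve; the baseline absorbs
  the softmax indifference level far from the trained time, where features
  have decayed to zero and the policy necessarily returns to chance. The
  fitted mean is the peak time, the fitted SD the spread; a smoothed
  argmax is the fallback if the fit fails, flagged in `fit_quality`.
* **Bisection** (`make_bisection_task()`): anchor-duration cues are
  followed by a 2-s choice window at cue offset (actions short/long/
  withhold; no actions during the cue, as when response levers extend only
  at offset). The decaying cue trace at the window is what encodes the
  elapsed duration. Probes at five geometrically spaced intermediate
  durations are never reinforced. The indifference point interpolates
  p(long) against log duration at 0.5 — consistent with the
  geometric-mean regularity — and is reported as absent rather than
  extrapolated when 0.5 is never crossed.
* **Dopamine manipulations** (`run_dopamine_manipulation_experiment()`):
  the early/late microstimulus split models the hypothesis that the
  striatum carries the early channel. The drug experiment places the
  boundary at the trace strength reached at the *trained* interval, so the
  manipulated channel is exactly the one generating pre-reward
  predictions; attenuation (`gain_early < 1`, D2 antagonism or
  Parkinsonian depletion) then biases predictions and responding later,
  enhancement (`> 1`, agonists) earlier. Manipulations are applied as
  acute challenges: training is drug-free, evaluation runs with gains
  applied and learning frozen. Gains multiply the shared feature stream
  seen by critic and actor alike, since striatal output feeds both.
* **Rectified scalar-noise prediction errors** (`sample_pe()`,
  `rectify()`, `interval_scaling_experiment()`): the semi-Markov account
  is implemented at the level of its prediction-error distribution —
  zero-mean Gaussian noise with SD `k * T^p` (defaults `k = 0.15`, a
  typical Weber fraction, and `p = 1`, strictly scalar), rectified at a
  floor of −0.1 reward units ("slightly below zero"). The closed form
  `E[max(X, c)] = c * Phi(c/sd) + sd * phi(c/sd)` provides an analytic
  check on the Monte-Carlo means. The exponent is exposed so that
  near-linear scaling in the interval versus in its logarithm can both be
  explored; only monotonicity is asserted.

## Numerical choices and degenerate inputs

Softmax probabilities are computed with max-subtraction (overflow-safe);
categorical draws and task interleaving use R's RNG, so a single
`set.seed`/`seed =` argument reproduces entire sessions bit-for-bit. The
compiled session engine is cross-checked step-for-step (tolerance 1e-12)
against an independently coded reference session built from the exported
R primitives, for both bases and for `lambda` of 0 and 0.95. Parameter
validation happens in the constructors (`sigma > 0`, `rho` strictly inside
(0,1), probabilities in [0,1], gains nonnegative); all-zero response
curves, empty tasks, never-crossing psychometric functions and k-last
read-outs longer than the session are rejected with explicit errors rather
than silently extrapolated. Pavlovian sessions are fully deterministic;
`seed` arguments there exist only for interface symmetry.

## Problem sizes

The shipped experiment recipes use 100 trials per interval for the
Pavlovian prediction-error pattern, 500 trials for probe and convergence
demonstrations, 2000 trials for each peak-procedure simulation, and 4000
for bisection; the semi-Markov experiment draws 1e5 samples per interval.
These sizes were chosen so that every demonstrated pattern is stable
across seeds.

## What the simulations do and do not show

The task generators emulate idealized laboratory procedures: perfectly
timed stimuli, unit rewards, stationary contingencies, a subject that
never disengages. They do not emulate motivational drift, motor
constraints on response rates, inter-subject variability, or the partial
reinforcement of real sessions. Passing simulations therefore show that
the model *mechanisms* produce the qualitative phenomena under clean
conditions — not that the model quantitatively fits any particular
animal's data. Known limitations: the fitted response curves sit on a 0.5
softmax baseline rather than the near-zero baselines of well-trained
animals (a two-action softmax with zero features cannot do otherwise);
bisection probes undergo mild extinction, which slightly depresses
long-probe choice late in training; rectification is imposed on the
prediction-error distribution rather than derived from a full
belief-state model, and compromises TD convergence by design — it is a
description of the dopamine signal, not a normative algorithm.
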