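# microtd

Temporal-difference models of dopamine and interval timing in the basal
ganglia.

Phasic dopamine famously tracks the reward-prediction error of
temporal-difference (TD) learning, and the basal ganglia are equally
implicated in interval timing — the perception of durations in the
seconds-to-hours range. `microtd` is a simulator for the hypothesis that
one computational system does both: a TD(λ) critic and softmax actor
operating over a *microstimulus* representation of time, in which each
stimulus leaves a decaying memory trace read out by a bank of Gaussian
temporal receptive fields. Early post-stimulus time is encoded precisely,
later time coarsely, and that one asymmetry yields dopamine-like
prediction-error phenomena and timed behavior (peak-procedure response
curves, temporal bisection psychometric functions, scalar variability, and
the directional effects of dopaminergic drugs) from the same learner.

The package is aimed at computational-neuroscience researchers and
students who want reproducible, scriptable versions of these simulations.

## The model in brief

Value is a linear function of time-indexed features,
`V(t) = Σ_d w(d) x_t(d)`, trained by the TD update

```
δ_t = r_t + γ V(t+1) − V(t)
e   ← γλ e + x_t
w   ← w + α δ_t e
```

with `δ_t` the modeled dopamine signal. Two feature codes are provided:
the complete serial compound (CSC; one indicator per elapsed step — a
perfect clock) and microstimuli
`x_t(d) = y_t · φ((y_t − d/D)/σ)`, where `y_t` is the stimulus trace
(1 at onset, decaying by ρ per 50-ms step) and φ is the standard normal
density. For instrumental tasks, a softmax actor over the same features
learns action preferences from `η δ_t (1 − p)` updates. A separate module
implements the rectified scalar-noise account of semi-Markov prediction
errors: `PE ~ Normal(0, (k·T)²)` clipped at a floor slightly below zero,
whose mean therefore grows with the interval `T`.

## Worked example

Prediction errors at cue and reward as a function of the cue-reward
interval (100 Pavlovian trials per interval, standard parameters α = 0.01,
γ = 0.98, λ = 0.95, D = 50, σ = 0.08, 20 steps/s):

```r
library(microtd)
run_interval_pe_experiment()
#>   interval_s cue_delta reward_delta n_trials
#> 1          1  0.486991        0.915      100
#> 2          2  0.353486        0.922      100
#> 3          4  0.132598        0.944      100
#> 4          8  0.010576        0.984      100
#> 5         16  0.000229        0.994      100
```

The cue response falls with the interval (temporal discounting) while the
reward response rises (long-delay predictions are temporally imprecise, so
more of the reward arrives unpredicted) — the signature interval
dependence of dopamine firing in classical conditioning.

Peak procedure: train the actor-critic on a 20-s fixed interval (2000
trials, 25% unrewarded 60-s probes) and summarize probe responding:

```r
pk <- run_peak_experiment(fi_s = 20, n_trials = 2000, seed = 1)
pk$stats
#> <peak_stats> peak = 20.08 s, spread (SD) = 6.76 s [gaussian, R2 = 0.969]
```

Responding peaks at the trained interval; at FI-40 the peak moves to ~40 s
and the spread doubles (scalar timing). Acute dopamine manipulations of
the early (striatal) microstimulus channel shift the peak directionally,
antagonist-like attenuation rightward and agonist-like enhancement
leftward:

```r
run_dopamine_manipulation_experiment(fi_s = 20, seed = 1)
#>   gain_early peak_time_s spread_s fit_quality
#> 1        0.5       21.17    6.679      0.9736
#> 2        1.0       20.17    6.909      0.9646
#> 3        2.0       19.55    7.330      0.9560
```

Temporal bisection with 2-s and 8-s anchors produces a monotone
psychometric function whose indifference point sits near the geometric
mean (4 s):

```r
run_bisection_experiment(2, 8, seed = 1)
#> <bisection_experiment> anchors 2/8 s
#> <psychometric_result> indifference point: 4.23 s
#>   duration_s     p_long  n
#> 1   2.519842 0.00000000 75
#> 2   3.174802 0.01176471 85
#> 3   4.000000 0.41176471 85
#> 4   5.039684 0.77011494 87
#> 5   6.349604 0.97500000 80
```

And the rectified scalar-noise model: unrectified prediction errors
average to zero at every interval, rectified ones grow with it, matching
the closed form `c·Φ(c/σ) + σ·φ(c/σ)`:

```r
interval_scaling_experiment(c(1, 4, 16), rectified_pe_config(), seed = 1)
#>   interval_s   sd  mean_raw mean_rectified mean_analytic
#> 1          1 0.15 -0.000337         0.0227        0.0227
#> 2          4 0.60  0.000618         0.1933        0.1927
#> 3         16 2.40 -0.000118         0.9058        0.9083
```

A thin command-line wrapper is installed at `inst/cli/microtd`
(subcommands `interval_pe`, `pavlovian`, `peak`, `bisection`,
`interval_scaling`, with `--config`, `--seed`, `--out`, `--trials`,
`--interval` flags); experiment configurations are plain YAML or JSON
handled by `load_config()` / `run_experiment()`.

See the vignette (`vignettes/microstimulus-td.Rmd`) for the model's
assumptions, the trace-decay rule behind the scalar property, and known
limitations.

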