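# ocupharm

Active-inference simulation of oculomotor pharmacology.

Eye movements are an unusually clean read-out of brain function, and many
drugs — benzodiazepines, anticholinergics, dopaminergic and noradrenergic
agents — change them in characteristic ways. `ocupharm` is for computational
neuroscientists and psychopharmacologists who want a mechanistic simulator
of those changes: it models a delayed (memory-guided) saccade task as a
discrete Markov-decision-process agent that plans by minimising expected
free energy, coupled to a continuous attractor model of the saccade
generator, and exposes four precision (synaptic-gain) parameters as
synthetic neuromodulators:

- **ζ (`zeta`)** — likelihood precision, `softmax(ζ · log A)`: acetylcholine.
- **ω (`omega`)** — transition precision, `softmax(ω · log B)`: noradrenaline.
- **γ (`gamma = 1/β`)** — policy precision in `π = softmax(−γG − F)`: dopamine.
- **Π (`pi_motor`)** — precision of the motor fixation prior in the saccade
  generator (`k_eff = k·p_t/(p_t+Π)`, `λ_eff = λ₀ + c_λ·Π`): GABAergic
  nigro-collicular gain.

Sweeping each parameter reproduces the qualitative drug signatures: an
inverse dose–response of saccadic peak velocity with GABAergic gain
(overshoot when depleted, slow hypometric "broken" saccades when high),
saturating cholinergic speeding (hypometria and inappropriate saccades when
depleted), dopaminergic randomisation of saccadic choice with simulated
dopamine traces, and noradrenergic control of delay-period "neuronal"
persistence with behaviour left intact. The agent's state inference is a
structured variational scheme (exact forward–backward smoothing within each
hidden-state factor, mean-field across factors); policies are temporally
deep (all action sequences over the remaining trial).

## Worked example

```r
library(ocupharm)
model <- build_model()                       # the delayed saccade task
trial <- run_trial(model, precisions(), true_target = "up", seed = 1)
print(trial)
#> <ocu_trial> target = up | actions: fixation -> fixation -> up | correct
#>   peak velocity 667.6 deg/s, amplitude 7.78 deg, 1 saccade(s), endpoint error 0.03 deg
```

The agent holds fixation through the cue and delay steps, saccades on the
go signal, and lands 0.03° from the 8°-eccentric target with a single
~670 deg/s saccade — correct task performance. `glance(trial)` adds the
delay-period persistence index (0.986: the posterior probability still
assigned to the true target at the final represented time just before
feedback), and `autoplot(trial$trajectory)` draws the displacement and
velocity traces with the 250 ms step boundaries.

A dose–response sweep returns one row per grid value:

```r
sweep <- sweep_gaba(pi_grid = c(0.25, 1, 8), n_trials = 4, seed = 1)
sweep[, c("pi_motor", "peak_velocity", "amplitude", "overshoot_rate", "saccades_to_arrival")]
#>   pi_motor peak_velocity amplitude overshoot_rate saccades_to_arrival
#> 1     0.25    1695.81563 7.7478722              1                   1
#> 2     1.00     667.58590 7.7761549              0                   1
#> 3     8.00      30.87242 0.3665901              0                   2
```

Low GABAergic gain: fast, overshooting saccades. High gain: peak velocity
collapses to ~31 deg/s and arrival takes two movements — a broken saccade.
`sweep_ach()`, `sweep_dopamine()`, `sweep_noradrenaline()`,
`interaction_grid()` (the noradrenaline × dopamine experiment) and
`recovery_experiment()` (grid-search maximum-likelihood recovery of γ from
simulated choices via `fit_gamma()`) follow the same pattern, and
`chance_level()` gives the uniform-policy accuracy oracle.

A thin command-line wrapper is installed at `inst/exec/ocupharm`
(`run-trial`, `sweep`, `interaction`, `recover`, `plot` subcommands); it
writes CSV/JSON outputs plus the resolved configuration and seed for
provenance. Configuration is YAML or JSON (see `default_config()`).

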