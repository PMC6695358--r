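---
title: "Simulating oculomotor pharmacology with precision-controlled active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating oculomotor pharmacology with precision-controlled active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

ocupharm simulates a delayed (memory-guided) saccade task with a hybrid
generative model and asks what happens to eye movements when the *confidence*
of different parts of that model is turned up or down. The premise is that
neuromodulators set synaptic gain, and synaptic gain implements the precision
(inverse variance) of probabilistic beliefs. Four precisions are exposed:

| parameter  | acts on                              | neuromodulator analogue | default |
|------------|--------------------------------------|-------------------------|---------|
| `zeta`     | outcome likelihoods (`A`)            | acetylcholine           | 2       |
| `omega`    | state transitions (`B`)              | noradrenaline           | 2       |
| `gamma = 1/beta` | confidence in plans (policies) | dopamine                | 2 (`beta = 0.5`) |
| `pi_motor` | the motor fixation prior             | GABA (nigro-collicular) | 1       |

All four are dimensionless gains: `zeta` and `omega` exponentiate and
renormalise probability columns (`softmax(precision * log p)`), `gamma` is the
inverse temperature of the policy softmax, and `pi_motor` weighs a
stationarity prior against the descending target prior in the saccade
generator.

## The task

One trial has four discrete steps of 250 ms each (cue, delay, go, feedback),
consistent with the natural frequency of saccadic sampling; longer delays can
be configured with `n_delay_steps`. Hidden states factorise into the fixation
location (5 states: the central cross and four targets at 8 degrees
eccentricity; the only controllable factor — a saccade can move fixation to
any location), the target location (4 states; static in reality), and the
trial stage (advancing deterministically). Outcomes are the target cue
(visible only while the stage is "cue"), the cross colour (red only during
the delay), feedback, and proprioception (an identity map from the fixation
location). Feedback is informative as soon as it logically can be: leaving
the cross during the delay or before the go signal has acted emits
`incorrect` immediately, and at the final stage `correct` requires fixation
to match the target. Preferences assign +4/-4 nats to `correct`/`incorrect`
(`c_pref`, configurable); the magnitude is large enough that default-precision
behaviour is reliably correct while premature saccades still carry a finite
(~3.6 nats per violated step) rather than infinite penalty.

```{r}
library(ocupharm)
model <- build_model()
trial <- run_trial(model, precisions(), true_target = "up", seed = 1)
glance(trial)
autoplot(trial$trajectory)
```

## Perception, planning, movement

**Perception.** Under each candidate policy, hidden states are inferred by a
fixed-point variational scheme with a structured posterior: each factor keeps
its full Markov-chain posterior, smoothed exactly by scaled forward-backward
recursions given the other factors' current marginals, and factors iterate to
convergence (maximum 16 sweeps, convergence when no marginal moves by more
than `1e-4`). The coupling across factors is mean-field, through the expected
log-likelihood of the observed outcomes; unobserved future outcomes
marginalise away, so beliefs about the future are prior predictions under the
policy. For a single-factor model the scheme is exact, which is what the
enumeration-oracle tests exploit; we chose it over naive per-slice mean
field, whose fixed points lock onto first-impression evidence when
transitions are near-deterministic. The structured free energy has the
closed form `F = (n_factors - 1) * E[ln A] - sum_f ln Z_f` and is
non-increasing over updates (a property test asserts this).

**Planning.** Policies are deep: all control sequences over the remaining
transitions, enumerated in full (125 at the first step of a four-step trial;
`policy_cap` can truncate the horizon for longer tasks). Each policy is
scored by its expected free energy `G` — risk, the KL divergence from
predicted outcomes to the preference target `softmax(C)`, plus ambiguity, the
expected conditional outcome entropy. The policy prior is
`softmax(-gamma * G)`; the posterior adds the evidence, `softmax(-gamma * G - F)`.
Expected precision is itself updated: `beta` takes damped Newton steps
towards `beta_prior + (pi_posterior - pi_prior) . G`, clipped at 1/64, and the
iterates of `gamma = 1/beta` form the simulated dopamine trace. With per-step
re-enumeration of remaining policies, `F` differs little across candidates,
so the trace sits near its prior whenever policy evaluation is unambiguous
and moves only at intermediate `gamma`; the burst/dip phenomenology of the
update rule itself is exercised directly in the unit tests.

**Movement.** One action is sampled from the policy posterior's marginal over
next saccades. The descending message to the saccade generator is the
posterior-predictive distribution over the *next proprioceptive outcome*,
model-averaged over the policies consistent with the sampled action, and
converted to a single attracting point as the probability-weighted mean of
location coordinates. This Bayesian model average is the route by which
categorical imprecision reaches continuous kinematics: a flat predictive
pulls the attracting point towards the centre of the display, shortening and
slowing the saccade, even though the plant itself is untouched.

The plant integrates believed position `mu` as a second-order attractor,

```
mu_ddot = k_eff * (eta - mu) - lambda_eff * mu_dot
k_eff      = k * p_t / (p_t + pi_motor)
lambda_eff = lambda0 + c_lambda * pi_motor
```

with the true eye following `mu` through a first-order reflex (rate `rho`),
semi-implicit Euler at `dt = 1` ms (an explicit stability guard rejects
`k_eff * dt^2 >= 1`). `pi_motor` is the precision of a competing
stationarity (fixation) prior — nigro-collicular inhibition: it both shunts
the pull towards the target and stiffens the damping, so beliefs about
moving become harder to update. Defaults (`k = 3.2e5 s^-2`, `lambda0 = 250
s^-1`, `c_lambda = 1080 s^-1`, `rho = 800 s^-1`) were calibrated
analytically so that `pi_motor = 1` is near-critically damped with a peak
velocity of order 700-1000 deg/s for an 8-degree saccade, `pi_motor = 0.25`
is underdamped (a hypermetric overshoot that is subsequently corrected, at
higher peak velocity), and `pi_motor = 8` is so overdamped that arrival
spans multiple 250 ms segments — a broken saccade. Only the monotonicity
and shape of these curves carry meaning; the absolute velocity scale is
arbitrary. Believed velocity is re-anchored at segment boundaries (the
discrete re-sampling of the visual scene), which is what gives broken
saccades their multiple distinct pulses.

## Why likelihoods have finite base fidelity

A 0/1 probability column is invariant under any precision exponent, so if
the agent's likelihoods and the target's stability were exactly
deterministic, `zeta` and `omega` would do nothing until they hit zero and
then everything at once. The agent's generative model therefore assigns base
fidelity 0.9 to every likelihood column (`likelihood_fidelity`) and 0.9
per-step stability to the remembered target (`target_stability`), while the
generative *process* — the experimental apparatus — stays veridical: cues
are exact, the target never actually moves, and proprioception is read off
the plant endpoint through a sharp (4 deg^-2) softmax over locations, which
recovers the identity mapping whenever saccades land on target. At the
default `zeta = 2` the agent's effective likelihoods are sharper than 0.996,
so defaults behave like the ideal observer.

## The four experiments

`sweep_gaba()`, `sweep_ach()`, `sweep_dopamine()` and
`sweep_noradrenaline()` run seeded trial batches along one precision grid
with everything else at defaults, returning a tidy `dose_response` table
(`autoplot()` draws the panels).

* **GABA** (`pi_motor` in 0.25-8): peak velocity falls strictly with the
  dose; the lowest dose overshoots; the highest produces broken saccades.
  The `saccades_to_arrival` metric counts suprathreshold events before the
  eye first comes within 1 degree of the target, using a 10 deg/s
  segmentation threshold: the corrective components of broken saccades are
  slow, and for a linear overdamped plant a second pulse can be shown to
  never exceed ~12 deg/s on this geometry, so the conventional 30 deg/s
  criterion (the `detect_saccades()` default, used for every other metric)
  would be blind to them by construction.
* **ACh** (`zeta` in 0-4): peak velocity rises with a clear saturation —
  the predictive distribution over locations sharpens asymptotically — while
  depletion shortens saccades (the attracting point slides towards the
  centre mixture) and makes mistimed saccades common. At `zeta = 0` the
  predictive is uniform and, by the symmetry of the location map, the
  attracting point is the fixation cross itself: the saccade vanishes.
* **Dopamine** (`gamma` in 1/64-4): accuracy climbs from chance to ceiling.
  Chance is computed by an empirical oracle (`chance_level()`: the same
  simulation with a forced-uniform policy posterior) rather than assumed
  1/4, because a random agent also mistimes saccades — measured chance is
  about 1-2%, close to the combinatorial (1/5)^3. At the highest `gamma`
  the simulated dopamine trace is flat to within 5%.
* **Noradrenaline** (`omega` in 0.75-5): the persistence index — the
  policy-averaged posterior probability of the true target at the final
  represented time, read at the last pre-feedback epoch, since feedback
  would reveal the answer and contaminate a memory measure — rises strictly
  from ~0.55 towards 1, and the belief rasters (`trial_raster()`) gain
  structure in their late rows, while accuracy is statistically unchanged
  across the grid: deep policies make behaviour robust to degraded memories.

The `omega` grid deliberately starts at 0.75 rather than lower: below
roughly 0.6-0.7 the flattening of the agent's own forward predictions eats
into the expected-free-energy contrast between saccade destinations and
behaviour genuinely degrades, which is the regime `interaction_grid()`
exploits. That experiment crosses a memory-degrading blockade
(`omega = 0.6`) with mild dopamine depletion (`gamma` 2 to 1) at 500 trials
per cell and measures the difference-in-differences in accuracy: depletion
costs roughly twice as much under blockade (+0.15 to +0.2), the directional
interaction predicted by the redundancy argument — if the plan is inferred
while the cue is fresh, either precise memories or precise plans suffice.
Strong depletion (`gamma = 0.25`) is deliberately avoided there because it
collapses saccade *timing*, which is omega-independent and masks the
interaction.

## Parameter recovery

`fit_gamma()` estimates the policy precision from observed choices by
grid-search maximum likelihood: each trial stores its per-step `(F, G)`
evaluations, so candidate precisions re-form the policy posterior and score
the observed actions through the same marginal used for sampling —
generation and fitting share one likelihood. `recovery_experiment()` checks
calibration: with 200 trials generated mid-grid (`gamma = 1/4`), at least
90% of 20 replications recover the generating value exactly or one grid
step away. Fitting real eye-tracking data is out of scope; the machinery
exists to demonstrate that the parameterisation is identifiable from
behaviour alone.

## Numerical choices and degenerate inputs

* Probabilities are floored at `1e-16` and renormalised before logarithms.
* Ties (argmax of one-hot limits, equidistant endpoints) resolve to the
  lowest index.
* `beta` updates are damped by 1/2 and clipped at 1/64.
* CSV floats are written at 9 significant digits, making identical
  config+seed runs byte-identical.
* Randomness enters only through action sampling (and optional future
  noise hooks): a master seed yields a per-trial seed stream whose first
  `k` entries are invariant to the batch size, so batches can grow without
  perturbing earlier trials.
* Degenerate requests fail loudly: negative precisions, non-tiling
  integration steps, unstable `dt`, unknown config keys, empty data for
  `fit_gamma()`.

## Problem sizes

The shipped test suite runs the correct-trial check at 100 trials, the
dopamine and noradrenaline sweeps at 200 trials per grid point, the
interaction at 500 per cell, and recovery over 20 replications of 200
trials; `scripts/acceptance.R` reports the same quantities at 100 trials
per point (250 per interaction cell, 10 recovery replications). These sizes
put two-standard-error bands of a few percentage points on every rate.

## What the generator does and does not emulate

The synthetic trials capture the qualitative pharmacology: inverse
dose-response of velocity with GABAergic gain, saturating cholinergic
speeding with hypometria and inappropriate saccades under depletion,
dopaminergic randomisation of saccadic choice, and noradrenergic control of
delay-period persistence without behavioural cost. They do not emulate
receptor subtypes, pharmacokinetics, or multi-site drug action; neuronal
dynamics are rate-coded posterior probabilities indexed by update epoch,
not spiking; the plant is a point-mass filter without muscle-pair
biomechanics; dopaminergic effects on saccade *speed* are absent by
construction, since `gamma` touches only the discrete level. Passing tests
therefore certify the internal logic of the precision-to-behaviour
mappings, not quantitative agreement with any empirical dose-response
curve.
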