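---
title: "Methods: TD learning with value decay in self-paced tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TD learning with value decay in self-paced tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forgetfulRL)
```

## The model

`forgetfulRL` simulates a subject performing a self-paced goal-reaching
task, modeled as a chain of discrete states in which, at every time step,
the subject chooses between advancing (`Go`) and staying put (`Stay`).
Learning is temporal-difference (TD(0)) reinforcement learning on action
values $Q(A)$, with one addition that is the package's entire reason to
exist: every learned value decays multiplicatively at every time step,
modeling forgetting (e.g. decay of plastic synaptic changes).

Per time step $t$, with the subject arriving in state $S(t)$ and obtaining
reward $R(S(t))$:

1. **RPE.** Under Q-learning,
   $\delta(t) = R(S(t)) + \gamma \max_{A_{cand}(t)} Q(A_{cand}(t)) - Q(A(t-1))$.
   Under SARSA the max is replaced by $Q(A(t))$, the value of the action
   actually selected at $t$ (so SARSA selects its action *before* the RPE is
   computed). Two boundary conventions apply: at the goal no action
   candidates exist and the future-value term is replaced by 0, and at the
   first step of a trial there is no previous action and $Q(A(t-1))$ is
   replaced by 0, so the start of a trial is not predicted.
2. **Update.** $Q(A(t-1)) \leftarrow Q(A(t-1)) + \alpha\, f\, \delta(t)$,
   where $f \in [0,1]$ is the blockade factor (below); only the previous
   action's entry changes.
3. **Decay.** $Q(A) \leftarrow (1-\varphi) Q(A)$ for *every* action $A$,
   selected or not.
4. **Selection and transition.** Softmax with inverse temperature $\beta$
   over the candidate values,
   $P(A_i) = e^{\beta Q(A_i)} / \sum_j e^{\beta Q(A_j)}$, computed
   shift-invariantly (max subtracted) so that large $\beta$ sweeps do not
   overflow. The chosen transition is executed deterministically.

A trial ends on the step in which the goal is occupied; the return to the
start is automatic, consumes no counted time step, and triggers no extra
decay. Trial length therefore counts one step per occupied state,
including the start and the goal: the minimum on the 7-state track is 7,
and the chance level under unbiased choice is 13
(`chance_level_steps(7)`).

### Ordering choices

The within-step order — update, then decay, once per counted step — is a
substantive commitment, fixed by two analytic anchors the simulator must
respect:

* Persistent staying at a state paying 0.1 per step (with $\alpha = 0.5$,
  $\varphi = 0.01$, $\gamma = 1$) must converge to the fixed point of
  $V \leftarrow (1-0.01)(V + 0.5 \times 0.1)$, i.e. $V = 4.95$
  (`persistent_stay_value()`); decay-then-update would converge elsewhere.
* Over a minimal 7-step trial, an untouched value must shrink by exactly
  $(1-\varphi)^7 \approx 0.932$ at $\varphi = 0.01$; this pins "decay once
  per counted step", including the goal-occupancy step. (Whether the goal
  step itself decays is not analytically forced — the bound is a lower
  bound — so we chose the uniform rule: every counted step decays.)

Q-learning selects its action *after* the update and decay of that step
(selection is part of the transition); SARSA selects before the RPE, as its
RPE definition requires. Ties in the Q-learning max need no tie-breaking
because only the maximum value, not an argmax action, enters the RPE.

### Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $\alpha$ | learning rate | 0.5 | in $[0,1]$ |
| $\beta$ | inverse temperature | 5 | $\beta=0$ uniform, large $\beta$ greedy |
| $\gamma$ | time discount factor | 1 | 1 = no discounting |
| $\varphi$ | decay rate per time step | 0 | experiments sweep 0–0.02 by 0.002 |
| $r$ | goal reward | 1 | 0.5–1.5 in the reward-amount experiment |
| $x$ | mid-track reward at `S4` | 0 | paid on *every* occupancy step |

All values start at 0. These defaults are the standard conditions of every
built-in experiment; they are not tuned per run.

### Simulated dopamine blockade

Dopamine is identified with the RPE. Blockade/depletion is modeled by
scaling the RPE-dependent increment inside the update (step 2) by a factor
$f$ (0: complete blockade; 0.25: partial) from a given trial onward
(`da_manipulation(factor, onset_trial)`). The *logged* $\delta$ — the
simulated dopamine signal — is always the raw RPE; only the plasticity
pathway is scaled. In the tasks simulated here $\delta$ is non-negative
under Q-learning, so scaling $\delta$ and scaling the increment coincide.

## Environments

**Linear track** (`linear_track()`): states $S_1 \dots S_n$ (default
$n=7$), `Stay`/`Go` everywhere before the goal. Action indices follow the
odd = `Stay`, even = `Go` convention so that value profiles and logs line
up with the usual plotting layout. Options: `mid_reward` ($x$ at `S4`,
every occupancy step), `allow_back` (a `Back` action at interior states,
three-way softmax), `n_states` (4 and 10 in the architecture experiment).

**T-maze** (`tmaze()`): nine states; stem `1-2-3`, junction `4` with three
candidates (`GoArm1`, `GoArm2`, `Stay`), arms `4-5-7` and `4-6-8`, and a
trial-end state `9` with no candidates from which the subject is returned
to the start. Arm rewards are delivered on the first arrival within a
trial only. Both cost conditions share this graph; only the reward
placement differs: with high cost the large reward sits at state 7, behind
the extra state 5, while without high cost it sits at state 5, one `Go`
from the junction (small reward at state 6 in both). We encoded the two
conditions as one fixed graph with movable rewards rather than two
different graphs: it is the minimal structure consistent with the task
description, and it keeps the action set identical across conditions.
`Stay` is available at all arm states (5–8), junction latency is counted
from the trial start through the first junction occupancy inclusive
(minimum 4).

## State-value variant

`run_session_state()` replaces action values with state values $V(S)$:
$\delta(t) = R(S(t)) + \gamma V(S(t+1)) - V(S(t))$ (future term 0 at the
goal), the same update-then-decay ordering, and `Go` chosen at $S_i$ with
probability $e^{\beta V(S_{i+1})} / (e^{\beta V(S_i)} + e^{\beta V(S_{i+1})})$.
Selection at $S_1$ uses the same rule as the interior states. This variant
isolates the *gradient* mechanism: there are no `Go`/`Stay` values, hence
no value contrast, yet forgetting still speeds goal-reaching via the
gradient of state values.

## Reduced two-variable model

To understand the steady state at the pre-goal state, the package includes
the reduced continuous-time system for $q(A_{11})$ (`Stay`) and
$q(A_{12})$ (`Go`):

$$\frac{dq(A_{11})}{dt} = y\, \alpha\, (\gamma\, q(A_{12}) - q(A_{11})) - \psi\, q(A_{11}),
\qquad
\frac{dq(A_{12})}{dt} = \alpha\, (r - q(A_{12})) - \psi\, q(A_{12}),$$

with $y = e^{\beta (q(A_{11}) - q(A_{12}))}$ the expected number of
consecutive `Stay` choices per trial, analyzed in the region
$q(A_{11}) \le q(A_{12})$ where the max in the `Stay` RPE resolves to
$q(A_{12})$. $\psi$ is the decay degree *per trial* — roughly the per-step
rate $\varphi$ times the trial length — and both parameters are exposed
separately; no automatic conversion is performed, since the correspondence
is approximate (the reduced model is a continuous-time, per-trial batch
approximation of the online algorithm).

Numerics (`find_equilibria()`): damped Newton iteration (steps capped at
$0.25\,r$, the exponent of $y$ clamped at 50) from a $20\times20$ grid of
starts over $[0, r]^2$ in the region; residual tolerance $10^{-10}$;
duplicates merged within $10^{-6}$; stability from the eigenvalues of a
central-difference Jacobian (step $10^{-7}$, real parts within $10^{-9}$
of zero treated as marginal). Because the `Go` equation is linear and
independent of $q(A_{11})$, its equilibrium
$q(A_{12})^* = \alpha r / (\alpha + \psi)$ is unique; the test suite
exploits this for an independent one-dimensional nullcline-scan oracle.
`bifurcation_sweep()` tabulates equilibria over a $\psi$ grid (default
step $2\times10^{-4}$, refined where the branch count changes) and
`find_saddle_node_upper()` bisects on the 3-to-1 equilibrium-count
transition to $10^{-5}$. At the standard parameters the bistable window is
roughly $\psi \in (0.045, 0.056)$ and the upper saddle-node sits at
$\psi^* \approx 0.0559$; the default bisection bracket $(0.05, 0.09)$ was
chosen to start inside that window. The lower fold is reported by the
sweep but has no printed reference value, so it is not asserted anywhere.

## Kinematic (elaborated) T-maze

`elaborated_tmaze()` decouples physical location from internal state: the
stem spans positions $[0, L]$ ($L = 3$) with unit-length half-open bins
(state $i \leftrightarrow [i-1, i)$), the junction is the point $L$, and
each arm runs from the junction to its reward location. `Stay` is replaced
by `Slow` away from physical constraints: `Go` displaces by 1, `Slow` by
half the previous step's displacement (so a `Slow` after a standstill
stays put — the only self-consistent reading of halving a zero
displacement), and movement clips at the junction and reward locations.
State transitions can therefore occur under `Slow`, and the internal state
can repeat while the body still moves — which is exactly what the velocity
profiles (`velocity_profile()`) quantify: complete stops only at the
start, junction and trial end.

The maze geometry is configurable because no reference segment lengths
exist; the defaults make the high-cost condition's large-reward arm two
units long (one pre-reward internal state — cost as extra distance/state)
and every other arm one unit. The reward location hosts a consummatory
action: one time step, no learned value and no choice, routing to the end
state. `Slow` carries its own learned value wherever it is available, as a
distinct action from `Stay`. The phenomena checked against this model
(preference reversal under depletion only with high cost, slowdown in both
conditions, the velocity-profile shape) are qualitative, and hold across
reasonable geometry choices.

## Experiments, seeding and problem sizes

`run_experiment()` drives the standard conditions: 20 independently seeded
sessions ("subjects") of 500 trials (1000 for the T-maze experiments,
depletion factor 0.25 after 500), block sizes of 5 trials on the track and
10 in the T-maze, and a cumulative cap of 35000 steps per session in the
mid-track-reward experiment. Session seeds are `base_seed + i - 1`, stored
in each result, and every experiment is byte-reproducible from its JSON
manifest. The `scale` argument shrinks sessions and trials proportionally,
which changes only sampling noise.

The test suite runs the cheap invariants at full study size (20 sessions
of 500 trials take well under a second each) and uses 4–10 sessions for
the most expensive qualitative checks (the elaborated maze and the
long bistability trace), sizes at which every asserted effect is far from
its decision boundary.

## What the simulations do and do not show

The environments are the data-generating process: there is no external
data, and all "subjects" are draws of the same seeded stochastic agent.
Passing tests therefore demonstrate internal consistency of the model
family — the decay-induced value gradient and Go/Stay contrast, their
bifurcation structure, the blockade phenomenology — not that real subjects
learn this way. Known limitations, deliberately out of scope: no
eligibility traces (the learner is TD(0) by construction), no adaptive
gain of the reward response, no modulation of response thresholds by
dopamine (only the plasticity pathway is manipulated), no recovery of
latency after depletion (the model sustains the slowdown), and no model of
reward consumption (the consummatory step is a single forced action).
One quantitative caveat: the completion percentage at mid-track reward
$x = 0.04$ is a genuinely stochastic quantity with a per-session settling
probability of roughly 5%, so individual 20-session draws report 90–100%.
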