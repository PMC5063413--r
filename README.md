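# forgetfulRL

Temporal-difference learning with forgetting, for computational
neuroscientists studying the link between sustained dopamine signals and
motivation.

Self-paced tasks — where nothing forces the subject to act *now* — pose a
puzzle for standard reinforcement learning: once action values converge,
the reward-prediction error (RPE, the quantity dopamine is thought to
report) collapses to zero except at trial starts, `Stay` becomes as
valuable as `Go`, and blocking dopamine should barely matter. Real
dopamine depletion, however, produces pronounced slowing and a reluctance
to work for costly rewards. `forgetfulRL` simulates a TD(0) agent with one
twist that resolves this: every learned value decays multiplicatively at
every time step.

The agent, at each step in state $S(t)$ with reward $R(S(t))$:

$$\delta(t) = R(S(t)) + \gamma \max_{A_{cand}} Q(A_{cand}) - Q(A(t-1))
\qquad \text{(Q-learning; SARSA uses } \gamma Q(A(t)) \text{)}$$

$$Q(A(t-1)) \leftarrow Q(A(t-1)) + \alpha\,\delta(t), \qquad
Q(A) \leftarrow (1-\varphi)\,Q(A) \ \ \forall A,$$

with softmax action selection at inverse temperature $\beta$. With decay
rate $\varphi > 0$, updates and forgetting balance at a steady state with
*sustained positive RPE*, a gradient of `Go` values toward the goal, and a
contrast between `Go` and `Stay` values — so the agent keeps moving, and
scaling the RPE-dependent update (simulated dopamine blockade) now
degrades behavior.

The package provides:

* the core agent (Q-learning / SARSA RPE, softmax, decay, blockade) with
  seeded trial/session loops and per-step logs;
* environments: a linear track (optional `Back` action, mid-track reward
  trap), a cost-benefit T-maze, and a kinematic T-maze with continuous
  position loosely coupled to internal states;
* a state-value model variant (selection by state values, no action
  values);
* a reduced two-variable dynamical system for the pre-goal `Go`/`Stay`
  values: equilibria, stability, nullclines, bifurcation sweeps, and
  saddle-node localization;
* analytic helpers (chance-level trial length from absorption analysis,
  persistent-stay fixed points, break-even mid-track reward) and a
  config-driven experiment runner (`run_experiment()`, CLI in
  `inst/cli/forgetful-rl`).

## Worked example

Twenty simulated subjects, 500 trials each, on the 7-state track:

```r
library(forgetfulRL)

env <- linear_track()                      # S1 ... S7, reward 1 at the goal
sessions <- lapply(1:20, function(s)
  run_session(env, agent_params(phi = 0.01), n_trials = 500, seed = s))
summarize_sessions(sessions)
#> <session_summary> 20 sessions: mean steps/trial 9.209 (SE 0.036),
#>                   mean RPE/step 0.1427 (SE 0.0004)
```

With forgetting (`phi = 0.01`) the agent needs ~9.2 steps per trial —
well below both the chance level `chance_level_steps(7)` = 13 (unbiased
`Go`/`Stay` choice) and the no-forgetting agent (`phi = 0` gives 11.4
steps and a mean RPE of 0.09, concentrated at trial starts). The mean RPE
of 0.14 *per step* is the sustained dopamine-like signal. The learned
values show the two mechanisms at work:

```r
round(sessions[[1]]$values, 3)
#> Stay@S1   Go@S1 Stay@S2   Go@S2 Stay@S3   Go@S3 Stay@S4   Go@S4
#>   0.308   0.352   0.093   0.417   0.313   0.493   0.348   0.586
#> Stay@S5   Go@S5 Stay@S6   Go@S6
#>   0.530   0.718   0.000   0.893
```

`Go` values rise monotonically toward the goal (0.35 → 0.89, the value
gradient) and exceed `Stay` everywhere (the value contrast). The reduced
model explains the contrast's stability: past a critical decay degree a
unique strongly-contrasted equilibrium remains,

```r
find_saddle_node_upper(reduced_params())   # alpha 0.5, beta 5, gamma 1, r 1
#> [1] 0.05583
find_equilibria(reduced_params(psi = 0.08))
#>         q11      q12        p11 stability  psi
#> 1 0.1090083 0.862069 0.02263631    stable 0.08
```

i.e. beyond the saddle-node at $\psi^* \approx 0.0559$ the agent stays
with probability only ~0.02 per step. Simulated dopamine depletion is a
`da_manipulation(factor = 0.25, onset_trial = 500)` passed to
`run_session()`; on the T-maze (`tmaze(high_cost = TRUE)`) it reverses
the preference for the high-cost/large-reward arm, while sparing it when
neither arm is costly (`tmaze_metrics()` tabulates both).

Ready-made experiment recipes (decay-rate sweeps, blockade, reward-amount
and architecture dependence, the mid-track reward trap, the kinematic
maze, the bifurcation diagram) run via
`run_experiment("decay_sweep", scale = 1, seed = 1, out_dir = "results")`,
which writes CSV tables plus a JSON manifest.

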