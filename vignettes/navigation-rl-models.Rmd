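---
title: "Modelling wayfinding as reinforcement learning: models, fitting and cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wayfinding as reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navrl)
```

# The task and its state space

The package models goal-directed navigation in a grid of rooms — by default
6 × 6, so 36 states. From each room the navigator can move `up`, `down`,
`left` or `right` into the adjacent room; rooms on the boundary have fewer
exits (2 in corners, 3 on edges) and there are no interior walls. Rooms are
addressed `c(row, col)`, 0-based, row 0 at the top, and `"up"` decreases the
row index; any consistent convention is observationally equivalent, this one
is simply fixed once. Orientation is excluded from the state space: the
choice data being modelled are room-to-room transitions, and facing
direction only matters for first-person rendering, which is outside this
package's scope.

Three goal rooms hold hidden goal objects. A trial is one goal-seeking
episode: the navigator starts somewhere, moves from room to room, and the
trial ends the moment it enters the current goal's room, which delivers
reward `reward_magnitude` (default 1; any positive constant only rescales
values against the inverse temperature, so 1 is canonical). Only the
current trial's goal rewards — the other two goal rooms are ordinary rooms
for that trial, and passing through them has no consequence. Value learning
is kept per goal in three independent tables: finding the apple teaches you
nothing about the banana.

Two phases follow each other:

* **Fixed phase** (9 trials): every trial starts from the same start room,
  and the goals cycle in a fixed order (G1, G2, G3, repeated). This regime
  favours route learning.
* **Random phase** (72 trials): each trial starts from a uniformly random
  non-goal room, and within every consecutive block of three trials the
  three goals appear in a random order, each exactly once. This regime
  favours map-based planning.

The default goal rooms are (1,4), (4,1), (4,4) with start (0,0). The
exact goal coordinates of the emulated experiment are not public; the
analyses depend on path lengths rather than on particular rooms, and the
defaults keep the goals away from the start and from each other. All
geometry is configurable through `nav_task()`.

# The five choice models

All models choose actions by a softmax over action values with inverse
temperature $\theta \in [1, 15]$:

$$p(a \mid s) = \frac{e^{\theta Q(s, a)}}{\sum_{a'} e^{\theta Q(s, a')}}$$

computed with a max-shift (and, for likelihoods, in log space), so it is
invariant to constant shifts of $Q$ and never over- or underflows. High
$\theta$ is exploitative and consistent; $\theta$ near 1 is exploratory.
The bounds $[1, 15]$ are the fitting convention for this task family and
keep the likelihood away from the degenerate fully-deterministic limit.

**Model-free (TD) learners.** The model-free value of the pair
$(s_t, a_t)$ is updated after each transition by the SARSA-style error

$$\delta_t = r_{t+1} + Q(s_{t+1}, a_{t+1}) - Q(s_t, a_t),$$

where $a_{t+1}$ is the action actually taken at $s_{t+1}$ and the bootstrap
term is 0 on the terminal, goal-entering step (without that convention
goal-entering values could not converge to the reward). The target is
deliberately undiscounted: reward is terminal and the TD models fit no
discount parameter. Values start at 0 at the beginning of the experiment
and are carried across trials and phases.

* **TD(0)** updates the current pair only: $Q \mathrel{+}= \alpha\delta$.
* **TD(λ)** keeps an eligibility trace per pair, reset at each trial start,
  updated as $e \leftarrow \lambda e$ for all pairs followed by
  $e(s_t, a_t) \mathrel{+}= 1$; then every pair receives
  $Q \mathrel{+}= \alpha \delta e$. Frequent recent visits earn larger
  shares of each error.
* **TD(1)** implements the idea that every visited location keeps full
  relevance for the rest of the trial: a *replacing*, non-decaying trace
  (set to 1 on visit, held at 1). The literal λ = 1 accumulating trace
  — which counts revisits instead — is available behind
  `td1_accumulating = TRUE`; the replacing form is the default because
  "same updating regardless of visitation frequency" is the property that
  defines this model.

A note on bounds: each TD(0) update is a convex step toward a target in
$[0, r]$, so TD(0) values stay in $[0, r]$ exactly. Trace-based variants
can transiently overshoot $r$ when $\alpha$ times an accumulated trace
exceeds 1; this is a real property of eligibility traces, not a defect,
and the likelihood remains well defined throughout (the replay guards the
log-softmax numerically).

**Model-based values.** `mb_values()` runs a deterministic value-iteration
sweep per goal, terminating at the goal, until the largest change falls
below `tol` (default $10^{-4}$) with discount $\gamma = 0.8$. On this
deterministic grid the converged values have the closed form
$Q_{MB}(s, a) = r\,\gamma^{d(s')}$ with $d(s')$ the room distance from the
landing room to the goal — a decaying value field over the map. The test
suite verifies the sweep against this closed form on every legal entry.
These values represent a perfect cognitive map: identical for every
participant and never updated.

**Hybrid.** Effective values are the entrywise mixture

$$Q_{hybrid} = (1 - \omega) Q_{MF} + \omega Q_{MB}, \qquad \omega \in [0, 1],$$

with the model-free component learned online by TD(λ) (updates use the
model-free table only; $\omega$ mixes at choice time). $\omega$ is the
continuous measure of navigation strategy: 0 is a pure route follower, 1 a
pure cognitive mapper. No rescaling is applied before mixing — both tables
live in $[0, r]$ by construction.

Free parameters per model: TD(0) and TD(1) fit $(\alpha, \theta)$; TD(λ)
adds $\lambda$; the model-based model fits $\theta$ alone; the hybrid fits
all four.

# Likelihood, fitting and model comparison

`trajectory_nll()` replays a participant's recorded choices
deterministically: at each step the softmax probability of the observed
action is scored from the model's current effective values, then the
learning update for the *previous* step is applied — precisely the
choose-then-update order of the generative agent, which chooses its next
action before the pending SARSA update (the update needs that action). The
generator and the replay share one C++ code path, so the fitted model
class contains the generator by construction — the precondition for
parameter recovery to be meaningful.

Phases are fit separately, but model-free values carry across phases. The
package reconciles this by warm-starting Random-phase likelihoods: the
Fixed phase is replayed under the candidate parameters without
contributing to the NLL, and scoring starts at the Random phase
(`warm_start = FALSE` instead starts the Random phase from zero values;
both conventions are defensible for phase-wise fitting, so both are
exposed, with warm start as the documented default because it is the only
one consistent with values genuinely carrying across phases).

`fit_mle()` minimises the NLL with L-BFGS-B inside the parameter box, from
10 seeded uniform-random starting points; the best restart wins, and the
reported optimum is never worse than any restart's starting value. The
restarts guard against the mild multimodality of the TD(λ) and hybrid
likelihoods. At extreme corners (α, λ near 1) the model-free values can
grow explosively on long trials; the objective maps non-finite likelihoods
to a large finite penalty so the search simply leaves such corners.

Models are compared per participant and phase by
$\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}$ (natural log). `n` counts
*trials* in the fitted phase (9 or 72) by default, treating the trial as
the sampling unit; `bic_n = "choices"` switches to counting individual room
choices, which changes only the penalty scale, not within-phase rankings
between models of equal `k`. Winners are minimum-BIC with ties broken
toward fewer parameters, then lexicographically.

# The synthetic cohort

The human data behind the original study are not publicly deposited, so
the package ships a generative stand-in with known ground truth:
`simulate_cohort()` draws per-agent parameters and runs softmax RL agents
through the exact two-phase protocol. Trials are capped at
`max_steps = 2000` and flagged truncated if the goal is never entered —
humans always found the goal eventually, but a near-random agent may not;
truncated trials are excluded from likelihoods and from excessive distance
by default.

Cohort defaults are the package's emulation of the study conditions:
114 agents (the study's final sample size), hybrid generative model, and
marginals

* $\alpha \sim \mathrm{TN}(0.35, 0.15)$ on $[0,1]$,
  $\lambda \sim \mathrm{TN}(0.5, 0.25)$ on $[0,1]$ (shared across phases);
* $\theta_{fixed} \sim \mathrm{TN}(9, 2)$,
  $\theta_{random} \sim \mathrm{TN}(7.5, 1.2)$ on $[1,15]$;
* $\omega_{fixed} \sim \mathrm{TN}(0.35, 0.25)$,
  $\omega_{random} \sim \mathrm{TN}(0.55, 0.3)$ on $[0,1]$,

with TN a normal truncated to the parameter bounds. The orderings encode
the study's qualitative findings — navigators are more consistent
($\theta$ higher) in the Fixed phase and more map-guided ($\omega$ higher)
in the Random phase. The $\theta$ ranges deliberately exclude near-random
navigators: a $\theta \approx 1$ agent needs hundreds of steps per trial,
which is inconsistent with humans completing 81 trials within a session,
and a wide $\theta$ spread would make choice noise — rather than strategy —
dominate wayfinding efficiency, contradicting the study's regime in which
the model-based weight correlates strongly negatively with excessive
distance in both phases. Under the frozen defaults the simulated
$\omega$–ED correlation is negative in both phases across seeds, as it
must be for a faithful stand-in.

The study's signature individual-difference structure — the correlation
between $\omega$ and $\theta$, positive in the Fixed phase (+0.25) and
negative in the Random phase (−0.35) — is planted by a Gaussian copula on
the two parameters within each phase (other parameters independent; the
latent normal correlation is $2\sin(\pi\rho_s/6)$ for a Spearman target
$\rho_s$). Everything is a pure function of the cohort specification and a
master seed.

What the generator does *not* emulate: reaction times, head direction,
within-room behaviour, perceptual noise beyond softmax stochasticity, or
any generative account of how human parameters are actually distributed
(none is published). Passing tests therefore demonstrate that the
*pipeline* is correct and identifiable in-model — they cannot certify
numerical agreement with human results, which is why cohort-level checks
are stated as sign and ordering properties rather than as point targets.

# Downstream statistics

* **Excessive distance**: `(actual − optimal) / optimal` in rooms, the
  standard wayfinding-efficiency index; 0 is perfect, 1 means twice the
  optimal length. Optimal distances are room distances (Manhattan on this
  open grid, equal to BFS on the room graph).
* **Paired t** with Cohen's $d = \bar{d}/s_d$; **one-way repeated-measures
  ANOVA** with classical
  $\eta^2 = SS_{cond}/(SS_{cond}+SS_{subj}+SS_{err})$ (partial $\eta^2$
  also reported) — the definitions common stats GUIs use for this design.
* **Dependent non-overlapping correlation comparison**: the two
  $\omega$–$\theta$ correlations come from the same sample but share no
  variable; the default test combines the Pearson–Filon covariance with
  Fisher-z stabilisation, with the classical raw-correlation statistic as
  an alternative (`variant = "pearson1898"`). The exact variant used in the
  original toolkit is not stated, so the choice is exposed.
* **Sensitivity power analysis**: the smallest detectable correlation at
  given $n$, $\alpha$, power, via the inverse Fisher z transform — 0.26 at
  $n = 114$.
* **Recovery reports**: per-parameter correlation/bias/RMSE of fitted
  against true parameters, and the generating-vs-selected confusion matrix
  for model recovery.

All tests are two-sided and uncorrected, matching the analysis being
emulated; Holm correction can be applied by users downstream if desired.

# Numerical and design notes

* Likelihood replay is exactly deterministic; simulation is a pure
  function of (specification, seed); explicit seeds are required
  everywhere — nothing silently seeds from the clock.
* Degenerate inputs: paired data with identically zero differences return
  $t = 0$ (rather than 0/0); a repeated-measures table with no condition
  variance returns $F = 0$; a trial starting in its goal room (optimal
  distance 0) is an error; truncated trials are an explicit flag, not an
  error.
* Estimation noise couples $\hat\omega$ and $\hat\theta$ within a phase,
  especially in the 9-trial Fixed phase, where the fitted correlation can
  differ substantially from the planted one. Cohort-level structure should
  therefore be read from the Random phase (72 trials) or from
  whole-experiment fits; the package's own validation requires only that a
  strongly planted correlation survive refitting in sign.
* Problem sizes used by the packaged validation: parameter recovery with
  50 hybrid agents × 81 trials; model recovery with 30 agents per
  generating model at $\theta = 8$; cohort-level pattern checks on the
  114-agent default cohort. These sizes give stable signs and orderings
  across seeds while keeping a full validation run in the minutes range on
  one core.

# Workflow

The `analysis/` scripts chain the pipeline end to end and write their
tables under `results/`: `01_simulate_cohort.R` (trajectories and true
parameters), `02_fit_models.R` (all five models, both phases, per agent),
`03_model_comparison.R` (BIC tables, ANOVAs, paired contrasts),
`04_individual_differences.R` ($\omega$/$\theta$ contrasts, correlation
matrix, dependent-correlation test, $\omega$–ED, power), and
`05_recovery.R` (parameter and model recovery). Each is a thin driver over
the functions documented above.
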