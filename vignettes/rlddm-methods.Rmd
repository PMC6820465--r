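---
title: "Models and methods: learning diffusion models for value-based choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: learning diffusion models for value-based choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddm)
```

## The problem

In reward-guided learning tasks, people repeatedly choose between options
whose values they only know from past feedback. Choice probabilities alone
hide part of the process: response times carry independent information about
how evidence is weighed on each trial. This package models both at once. Its
core is a family of *reinforcement learning diffusion decision models*
(RLDDMs): a delta-rule learner estimates option values from feedback, and a
diffusion decision process turns the current value estimates into a choice
and a response time on every trial.

The experimental paradigm the generator emulates is a four-armed bandit:
options A--D pay approximately normally distributed rewards (means 36, 40,
50 and 54 points, SD 5), presented as fixed pairs AB, AC, BD and CD over
three blocks of 80 trials (20 presentations per pair per block, never more
than three of the same pair in a row). Both presented options' rewards are
revealed after each choice (full feedback). The pair structure separates two
value effects: *difficulty* (pairs AC/BD differ by 14 points, AB/CD by 4)
and *magnitude* (pair mean values 38, 43, 47, 52). Accumulated points
convert to a monetary bonus at 1400 points per franc. Responses faster than
150 ms or slower than 3000 ms are flagged and excluded from all likelihoods,
and subjects whose overall accuracy is consistent with coin-flipping under
an exact binomial test (56% of 240 trials at the 5% level) are listed for
exclusion.

## Learning model

Subjective values follow the delta rule. For each presented option with
feedback $f_t$,

$$Q_t = Q_{t-1} + \eta\,(f_t - Q_{t-1}),$$

with either one learning rate $\eta \in [0,1]$ or two
($\eta^+$ for positive and $\eta^-$ for negative prediction errors; exact
ties are routed to $\eta^+$, a measure-zero event for continuous values).
Under full feedback *both* presented options are updated every trial, so the
value trajectory depends only on the feedback stream, not on the simulated
choices — a fact the posterior predictive machinery exploits.

Block 1 starts every option at 27.5 points (the average value advertised in
task instructions). Later blocks present new stimuli, so values restart; the
phrase "initialized at the mean values learned in the previous blocks" is
ambiguous between a grand-mean and a per-option carry-over, and both are
implemented behind `init_rule`. The grand mean is the default: new stimuli
cannot inherit option-specific values, but the learned overall reward level
plausibly transfers.

Pure RL variants map values to choices with the soft-max rule
$p(\mathrm{cor}) = 1/(1 + e^{-\theta (Q_\mathrm{cor} - Q_\mathrm{inc})})$,
with $\theta$ either fixed or growing as a power of experience,
$\theta_t = (n/b)^c$. When the two presented options' presentation counts
disagree mid-block, $n$ is their mean — symmetric in the pair and equal to
the shared count whenever counts agree.

## Decision model

Within a trial, evidence $x$ accumulates as
$x_{i+1} = x_i + \mathcal{N}(v\,dt, \sqrt{dt})$ from $x_0 = a/2$ until it
reaches $a$ (the higher-mean option; accuracy coding) or 0. Response time is
first-passage time plus a non-decision time $t_{er}$. The diffusion
coefficient is fixed at 1, which fixes the scale of $v$ and $a$. There is no
starting-point bias (left/right positions are randomized) and no
across-trial variability parameters.

The likelihood uses the first-passage density of this process, evaluated by
the standard pair of series expansions of the standardized density (one
accurate at small times, one at large times), switching to whichever needs
fewer terms for a truncation error below `tol` (default 1e-10).
Upper-boundary densities come from the lower-boundary form by drift
reflection. The closed forms
$P(\mathrm{upper}) = 1/(1+e^{-va})$ and
$E[T] = (a/2v)\tanh(va/2)$ for the unbiased process serve as oracles in the
tests, and numerical integration of the density reproduces the absorption
probabilities to 1e-4.

The forward simulator uses the Euler scheme above (default `dt` 0.001 s,
response window 5 s) with one refinement: a Brownian-bridge correction draws
within-step boundary crossings that the discrete skeleton misses. Naive
Euler crossing detection has a bias of order $\sqrt{dt}$ in absorption
probabilities (about 0.006 at `dt` = 0.001), large enough to be visible
against Monte-Carlo error at $10^5$ runs; with the correction the simulator
matches the closed forms within sampling error.

## The model space

Nineteen variants are constructible via `model_spec()`:

- **RL 1--4**: soft-max choice models — one or two learning rates crossed
  with fixed or power-increasing sensitivity. Choices only.
- **DDM 1--3**: static diffusion models ignoring feedback — drift per
  difficulty class (1, 2) or per pair (3); single threshold (1) or one per
  pair (2, 3); one non-decision time.
- **RLDDM 1--8**: the learning diffusion models — one or two learning
  rates, drift linear in the value difference
  ($v_t = v_\mathrm{mod}(Q_\mathrm{cor} - Q_\mathrm{inc})$) or S-shaped
  ($v_t = S(v_\mathrm{mod}\,\Delta Q)$ with
  $S(z) = 2v_{\max}/(1+e^{-z}) - v_{\max}$), and a threshold either fixed or
  modulated by the mean value of the presented pair,
  $a_t = \exp(a_\mathrm{fix} + a_\mathrm{mod}\,\bar Q_\mathrm{pres})$.
  A negative $a_\mathrm{mod}$ lowers the threshold for attractive pairs —
  faster choices with nearly unchanged accuracy, the magnitude effect.
- **Pedersen-style RLDDM 1--4**: power-decay variants in which the
  threshold falls as $a_t = a_\mathrm{base}\,t^{-d_a}$ with the within-block
  trial number and (in variants 2 and 4) the drift scaling grows as
  $m_t = v_\mathrm{mod}\,t^{d_m}$. The source describes these forms only
  verbally; the parameterization here (bases at $t = 1$, exponents
  $\ge 0$) is this package's reconstruction.

Values entering trial $t$ are those updated through trial $t-1$: feedback
arrives after the response, so it cannot inform the same trial's drift.

Two numerical notes on nesting. The dual-rate and value-modulated variants
reduce *bit-exactly* to their simpler parents at $\eta^+ = \eta^-$ and
$a_\mathrm{mod} = 0$. The sigmoid drift approaches the linear one as
$v_{\max}$ grows only after curvature rescaling: near zero
$S(z) \approx v_{\max} z / 2$, so the sigmoid model with scaling
$2 v_\mathrm{mod}/v_{\max}$ matches the linear model with scaling
$v_\mathrm{mod}$.

## Hierarchical estimation

Each parameter is sampled on an unconstrained scale through a link: logit
for learning rates, log for positive parameters (thresholds, sensitivities,
$v_{\max}$, power exponents), identity for unbounded ones, and a scaled
logit with a fixed 1-second upper bound for the non-decision time. The
bound is a link choice, not a data-dependent constraint: proposals with
$t_{er}$ at or above a subject's fastest retained response are rejected
through a $-\infty$ likelihood instead. Keeping the link free of the data
makes simulation-based recovery studies symmetric between generation and
fitting.

Subject-level parameters are normal around group means on that scale; group
means carry wide normal priors (SD 2) and group SDs half-normal priors
(scale 1) — weakly informative on every support.

Sampling is Metropolis-within-Gibbs:

1. per subject, a joint random-walk proposal whose covariance adapts (during
   warm-up only) to the running covariance of that subject's draws;
2. conjugate draws of the group means;
3. log-scale random-walk steps on the group SDs;
4. an interleaved *non-centered* move: holding each subject's standardized
   offset fixed, a joint proposal of one parameter's (mean, SD) rescales all
   subjects at once. This ancillarity-sufficiency interleaving breaks the
   group-scale funnel that makes purely centered samplers crawl for weakly
   identified parameters (the learning rate, in practice).

Four chains run by default; the first half of each is warm-up. If any
group-level split R-hat exceeds 1.01 the iteration budget doubles and
sampling restarts, up to a cap; a fit that still fails is returned flagged
`converged = FALSE`, never as an exception. Pointwise log predictive
densities of all retained trials are stored (thinned to at most
`pointwise_draws` draws) for WAIC, `compute_waic()` applying the
variance-based penalty
$\mathrm{WAIC} = 2(-\mathrm{lppd} + p_\mathrm{WAIC})$, and
`compare_models()` reporting the elpd difference with its pointwise
standard error $\sqrt{n\,\mathrm{var}(d_i)}$.

## Evaluation tools

**Posterior predictive checks** draw parameter sets from the joint
posterior (500 by default), simulate one full dataset per draw along each
subject's own feedback stream, and summarize accuracy and response time per
pair and per within-block trial bin (eight bins of ten trials under the
default design), with 95% predictive intervals next to the observed means.
Binning uses the within-block trial index, so each pair contributes its
trials falling in each bin; a within-pair presentation index would be the
alternative reading, and the index convention is an argument away.

**Behavioral regressions** are hierarchical Bayesian models fit with the
same engine: a logistic regression of accuracy and a linear regression of
log response times on standardized pair magnitude, difficulty coded +1
(easy) / -1 (difficult), and their interaction — trial number deliberately
excluded. An effect is declared when the 95% credible interval of the group
coefficient excludes zero. On null data (no learning, fixed threshold) the
intervals straddle zero at their nominal rate; data generated with a
negative threshold modulation produce a negative magnitude coefficient on
response times, the signature dissociation of the magnitude effect.

**Parameter recovery** draws subject parameters from generating group
distributions on the unconstrained scale, simulates, refits, and reports
interval coverage of the group means plus Spearman correlations between
generating and recovered subject-level values (flagged undefined when the
generating SD is zero).

## Study conditions and problem sizes

The synthetic generator's defaults are the paradigm's: 4 options with means
36/40/50/54 and SD 5, 3 x 80 trials, pairs AB/AC/BD/CD at 20 presentations
per block, run-length cap 3, RT window 0.150--3.000 s, 1400 points per
franc. Where the task description fixes no value, generating parameters for
simulation studies were chosen once to give realistic behavior — accuracies
around .75 rising with learning and mean response times near one second:
group means $\eta = 0.12$, $v_\mathrm{mod} = 0.08$, $a = 1.8$,
$t_{er} = 0.35$ s with modest between-subject spread. The shipped recovery
study uses 12 subjects x 240 trials and 5 replications with a reduced
sampler budget (4 chains x 1500 iterations, no doubling), which keeps the
full test suite to minutes while leaving group-mean interval coverage at or
above the 80% bar; doubling the budget tightens the intervals but does not
change the qualitative result.

What passing these tests shows — and what it does not: the synthetic
generator emulates the payoff structure, schedule constraints and feedback
regime of the task, with responses generated *by the model being tested*.
Real data add contaminants the generator omits: attention lapses, fast
guesses inside the retained window, motor-time variability, sequential
effects beyond the delta rule. Green tests therefore certify internal
consistency (simulation, likelihood and estimation agree) and directional
reproduction of the published effects, not that any single model is the
true account of human data.

## Known limitations

- Two-alternative tasks only; multi-alternative paradigms need a different
  accumulator.
- No across-trial variability in drift, start point or non-decision time;
  no starting-point bias; no collapsing bounds.
- The random-walk sampler needs more iterations than a gradient-based
  sampler would for strongly correlated posteriors; the convergence loop
  and diagnostics make this visible rather than hiding it.
- Excluded-RT trials keep feeding the learner in both simulation and
  fitting. In the real task a discarded trial showed a reminder screen
  instead of feedback; retaining the update is an idealization that
  preserves the designed feedback stream.
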