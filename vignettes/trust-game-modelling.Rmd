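---
title: "Modelling trust-game behaviour: the generative model, estimation, and the longitudinal stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trust-game behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustmrt)
```

## The task and its mechanics

In the multi-round trust game an investor starts each of 10 rounds with a
fresh endowment of 20 coins and transfers some amount `a_i` to a trustee.
The transfer is tripled in transit; the trustee repays `a_t`, leaving round
payoffs

```
chi_i = (20 - a_i) + a_t        (investor)
chi_t = 3 a_i - a_t             (trustee)
```

For tractability the investor's choice is discretized into five bins
([0,2], [3,7], [8,12], [13,17], [18,20]) with representatives 0, 5, 10, 15,
20, and the trustee repays one of the fractions 0, 1/6, 1/3, 1/2, 2/3 of the
tripled investment.  A zero investment leaves the trustee a single forced
action (repay 0).  Non-integer repayments (e.g. 2.5 coins for `a_i = 5`,
fraction 1/6) are carried exactly through all utility and likelihood
computations; rounding to whole coins happens only at display time, because
rounding inside utilities would silently reorder argmaxes.

## The generative agent model

Behaviour is modelled as an interactive partially observable Markov decision
process (I-POMDP): each agent carries beliefs about the partner's latent
characteristics, a model of the partner's reasoning, and a finite planning
horizon.  Seven parameters, all on discrete grids, govern an agent:

| parameter | grid | meaning |
|---|---|---|
| `alpha` | 0, 0.4, 1 | inequality aversion (Fehr–Schmidt style penalty on advantageous inequality) |
| `omega` | 0.4–1.8 by 0.2 | social risk aversion: multiplier on coins kept vs. coins returned |
| `k` | 0–4 | theory-of-mind level: depth of recursive partner modelling |
| `P` (`plan`) | 1–4 | planning horizon in future rounds |
| `zeta` | 0, 0.25, 0.5, 0.75, 1 | irritability: additive shift toward a retaliatory policy |
| `q(zeta)` | 0–4 | irritation awareness: prior belief about the partner's irritability |
| `beta` | 1/4, 1/3, 1/2, 1 | inverse temperature of the softmax choice rule |

**Utilities.** An investor values an action pair as
`omega * (20 - a_i) + a_t - alpha * max(chi_i - chi_t, 0)`; a trustee as
`chi_t - alpha * max(chi_t - chi_i, 0)`.  An `alpha = 1` trustee maximizes
utility at the payoff-equalizing repayment (fraction 1/2), which is what
makes inequality aversion the latent "trustworthiness" type an investor
wants to learn.

**Beliefs.** Agents hold Dirichlet pseudo-counts over the partner's
inequality-aversion type (uniform prior (1, 1, 1)) and over the partner's
irritability level, updated by the approximate rule
`A_alpha <- A_alpha + p(o | alpha)`, where `p(o | alpha)` is the probability
of the observed partner action under each type's policy (marginalizing over
the other type dimension with the current belief).  Because an investment of
5 equalizes payoffs regardless of the response, investors do not update
inequality-aversion beliefs from responses to investments of 5 or less.  The
irritability belief uses the same additive rule.  Two gating decisions were
open and are fixed as follows: the inequality gate applies only to the
inequality belief (a response to `a_i = 5` still reveals irritation, so the
irritability belief updates whenever the trustee had a real choice), and
forced moves (responses to zero investments) update nothing.

**Irritation awareness priors.** The five `q` settings are verbal labels
("ignorant" through "certain"); their numeric priors are a package choice,
overridable via `options(trustmrt.irritation_priors = ...)`: `q = 0` is a
point mass on zero irritability with updating disabled, `q = 1` tilts
toward low irritability (counts 3, 0.5, 0.5, 0.5, 0.5), `q = 2` is uniform,
`q = 3` mirrors `q = 1` toward high irritability, and `q = 4` places no
mass on zero irritability.

**Irritability.** Each agent tracks a mixture weight `w` in [0, 1].  After a
partner action strictly below the agent's expectation — the belief-weighted
expected monetary value of the partner's action under the partner models —
the weight shifts up additively by `zeta` (clamped at 1); after an action
strictly above expectation it shifts back down by the same amount (floored
at 0).  Ties do not move the weight: "below expectation" is read strictly.
The choice distribution is the mixture

```
P[a] = (1 - w) * softmax_beta(Q_nonirritated) + w * softmax_beta(Q_irritated)
```

where the irritated policy plans zero steps ahead, has `alpha = 0`, models
the partner at level −1, raises risk aversion to `max(omega, 1)`, and keeps
`beta` unchanged.  For an investor this irritated policy concentrates on
keeping the endowment (retaliation by withholding); for a trustee it
concentrates on repaying nothing.

**Theory of mind and planning.** A level-k agent predicts its partner with a
mixture of level-(k−1) partner models, one per partner type, weighted by its
beliefs.  Level −1 is a static, non-learning policy: softmax over immediate
utility; a static investor's immediate utility is taken in expectation over
the uniform-prior mixture of the three static trustee type policies, whose
prior-weighted expected repayment fraction lies below 1/3 — this is what
makes the irritated policy (inequality aversion 0, risk aversion at least
1) withhold investment rather than sit on a knife-edge of indifference.  Action values back up expected
utility over the next `min(P, 10 - round)` rounds through a soft (softmax-
weighted), undiscounted Bellman recursion in which beliefs and irritation
states evolve along every considered continuation exactly as they would in
play.

## Computational design choices

Everything the engine computes is a deterministic function of (agent
specification, half-move history), memoized in an `agent_context()`.  The
caching contract is that it never changes a probability: identical keys map
to identical deterministic computations, and the test suite compares the
engine against an independent enumerative implementation to 1e−9.

Three simplifications of a fully nested I-POMDP keep exhaustive grid search
tractable in R; all three are deliberate model definitions, applied
identically in simulation, likelihood and the test oracle:

1. *Rollout policy.* Inside planning rollouts, future own behaviour is
   evaluated under the non-irritated softmax policy; the irritation mixture
   applies at choice time.  This makes action values independent of
   irritability, so the 15 partner-type policies share three planning trees
   (one per inequality-aversion type).
2. *Nested planning horizon.* Partner models plan one round ahead.  Deep
   planning inside partner models multiplies the rollout tree at every
   theory-of-mind level; one-step planning keeps the models forward looking
   at tractable cost.
3. *Nested risk aversion.* A trustee equips its direct investor models with
   its assumed investor risk aversion `b^T(omega)`; all deeper nested
   trustee models assume a risk-neutral investor (`omega = 1`).  An
   investor's partner-model computations are then independent of the
   investor's own `omega`, which lets the whole risk-aversion grid share
   one set of partner-model caches.

With these choices a reduced-grid fit of one subject (theory of mind ≤ 1,
one-step planning) costs a few seconds for the first likelihood evaluation
and ~0.05 s per further grid point; higher levels and horizons remain
available but cost minutes per 10-round evaluation, which is why the
shipped default trustee is the `alpha = 0.4`, `k = 1`, `P = 1`,
`zeta = 0.25`, `beta = 1/3` agent rather than a deeper one, and why the
desk-scale analyses in the tests and the acceptance script restrict
planning to one step at full game length (two steps are exercised on
truncated 3-round games, where the horizon bounds the tree).

## Estimation and model comparison

Subject parameters are estimated by exhaustive search over the parameter
grid (the full Cartesian product has 24,000 points), minimizing the
negative log likelihood (nats) of the observed trajectory.  The default
likelihood scope scores all 20 actions of a game: the 10 investments under
the subject model and the 10 repayments under the subject's belief-weighted
partner-model mixture.  This scope is the one consistent with the
uniform-random reference model's average BIC of 32.19 = 20·ln 5; an
investor-only scope is available behind a flag.  A trustee's forced response
to a zero investment contributes log 1 = 0, which makes the random model's
likelihood trajectory-dependent when zero investments occur; this is
documented rather than hidden.  Ties in the grid search (common at high
stochasticity) are broken by ascending lexicographic order over
(alpha, omega, k, P, zeta, q, beta) and counted in the fit result.

Model variants are compared with a Draper Bayesian information criterion,

```
BIC = NLL + (p / 2) * (log(10) - log(2 * pi))
```

with natural logarithms and `p` free parameters: M1 the full model (p = 7),
M2 fixes irritability and irritation awareness to 0 (p = 5), M3 additionally
fixes risk aversion to 1 and the softmax to 1/3 (p = 3), M4 additionally
fixes theory of mind to 0 (p = 2), and M5 is the uniform-random policy
(p = 0).  The penalty's `log(10)` counts 10 per-role actions while the
likelihood scores 20; the two constants are kept exactly as written, since
the criterion is used only to rank models and the reference value 32.19
pins the convention.

## Behavioural indices

Per trajectory the package computes: a-priori (unconditional) trust, the
round-1 investment; mean trust, the mean investment over the 10 rounds;
reciprocity, by default the OLS slope of the round-to-round investment
change on the preceding change in repayment fraction (rounds with undefined
fractions dropped; missing if fewer than two usable pairs or a constant
predictor); a retaliation index, the mean next-round investment change
after an unfair repayment, where "unfair" defaults to a repayment fraction
strictly below 1/3 (less returned than invested) and is overridable; and
total winnings, the sum of investor payoffs over the ten independent
20-coin rounds.  Reciprocity and the retaliation marker are verbal
definitions in the source literature; the formulas used here are explicit
and configurable, and the chosen variants are recorded in the metrics
output.

## The synthetic cohort generator

`generate_cohort()` emulates the longitudinal study design the analysis
stages assume: baseline ages uniform on 14–25 years; a second visit after
an interval drawn from Normal(1.48, 0.29) years (truncated at 0.5); a
standard-normal family-adversity factor; investor irritability drawn from a
softmax over the zeta grid whose logits shift linearly with adversity
(positive link: more adversity, more irritability); latent risk aversion
declining with cross-sectional age (−0.05 per year) and within person over
the inter-visit interval (−0.1 per year), snapped to the omega grid; one
simulated game per visit against a configurable trustee (default above, or
a replay schedule of canned repayment fractions); and three waves of
friendship-questionnaire scores generated as a linear function of wave,
baseline round-1 investment, adversity and the adversity-by-trust
interaction plus noise.  Slope magnitudes were chosen once as plausible
settings for this design; they are inputs to recovery checks, not targets.

What the generator does *not* emulate: the real cohort's age distribution
(unknown beyond its range), attrition and missingness beyond simple
subsetting, measurement error in questionnaires, or the empirical trustee
algorithm (unpublished; the default trustee is a model agent, and replay
mode exists precisely so analyses can be pinned to fixed trustee
behaviour).  Passing tests on synthetic cohorts therefore demonstrates
internal consistency of estimator and generator — parameter recovery, effect
directions, coverage — not external validity on human data.

## Statistical stages

Ages are decomposed into a between-person component (participant mean age,
centred on the sample mean of participant means) and a within-person
component (visit age minus participant mean), an exact decomposition
verified to reconstruct `age = sample mean + cross-sectional +
longitudinal`.  The family-adversity factor is the first principal
component of standardized questionnaire subscale totals, oriented so that
adversity-coded subscales load positively (scores are sign-fixed; an
affine rescaling of any subscale leaves them unchanged).  Longitudinal
models are linear mixed models with subject random intercepts fit by REML
(`lmerTest`), Satterthwaite approximate degrees of freedom, continuous
predictors centred, and effect-coded categorical contrasts.  Random slopes
are available via the `random` argument; intercept-only is the default
because the displayed model formula of the study design uses it.  Quadratic
age terms are off by default and available via `quadratic_age = TRUE`.
Exact numerical agreement with any particular statistics package's
degrees-of-freedom approximation is a non-goal; the stage is validated by
coverage and recovery on the package's own generator (95% CI coverage of a
known longitudinal slope over 200 simulated cohorts of 200 subjects in the
test suite).

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use desk-scale study conditions:
oracle equivalence on 3-round games over the corner grid (alpha in {0, 1},
omega in {0.4, 1.8}, k ≤ 1, P ≤ 2, zeta in {0, 0.5}); recovery with 50
simulated agents at `beta = 1` on a 64-point reduced grid (all 8 omega
values, k ≤ 1, one-step planning) against a fixed replay trustee; model
comparison on 8 irritable full-model agents over a 216-point grid
containing every value the nested variants fix; and 150–200 replicate
cohorts for the mixed-model stage.  These sizes are the package's choices
for reproducible desk-scale validation; all of them scale up by passing
larger grids or cohort sizes.

## Known limitations

* Exhaustive search over the full 24,000-point grid with deep theory of
  mind and planning is computationally out of reach in plain R; the
  reduced grids above are the supported operating point, and the engine's
  cost grows roughly as 5^(2P) per round and multiplicatively in k.
* The level −1 policy, the irritation-awareness priors, and the nested-
  model conventions are explicit package choices where the source
  literature gives only verbal descriptions; all are documented above and
  overridable where a numeric choice is involved.
* The irritation trigger compares single observed actions to expectations;
  it does not model cumulative grievance or forgiveness beyond the
  additive weight dynamics.
* Model comparison uses average BIC with a fixed penalty; no
  subject-level random-effects model selection is attempted.
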