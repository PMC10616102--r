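# trustmrt

Generative modelling and longitudinal analysis of behaviour in the
10-round investor–trustee trust game.

In the task, an investor starts each round with 20 coins and transfers an
amount `a_i` to a trustee; the transfer is tripled and the trustee repays
`a_t`, giving round payoffs `chi_i = (20 - a_i) + a_t` and
`chi_t = 3*a_i - a_t`. Investments are discretized to representatives
{0, 5, 10, 15, 20} and repayments to fractions {0, 1/6, 1/3, 1/2, 2/3} of
the tripled investment. The package is aimed at researchers in
computational psychiatry and developmental decision science who want to
fit, simulate and stress-test this family of models on trial-level choice
data or on synthetic cohorts.

Its core is an interactive POMDP agent with seven discrete parameters
Θ = (α, ω, k, P, ζ, q(ζ), β):

* Fehr–Schmidt-style inequality aversion α, with utilities
  `u_I = ω(20 − a_i) + a_t − α·max(chi_i − chi_t, 0)` and
  `u_T = chi_t − α·max(chi_t − chi_i, 0)`;
* social risk aversion ω (a trustee instead carries b^T(ω), its static
  assumption about the investor's ω);
* level-k theory of mind: a level-k agent predicts its partner with a
  belief-weighted mixture of level-(k−1) partner models, with Dirichlet
  pseudo-count learning `A_α ← A_α + p(o|α)` over partner inequality
  aversion and irritability;
* a planning horizon P with soft, undiscounted Bellman backups over
  `min(P, 10 − round)` future rounds;
* irritability ζ: after a below-expectation partner action the policy
  shifts additively (weight `w ← min(w + ζ, 1)`) toward a retaliatory
  policy with no planning, no inequality aversion, level −1 partner
  modelling and ω raised to at least 1, mixed as
  `P[a] = (1 − w)·softmax_β(Q) + w·softmax_β(Q_irr)`;
* irritation awareness q(ζ) setting the prior over the partner's ζ;
* softmax inverse temperature β.

Subjects are fit by exhaustive grid search over the discrete parameter
space (negative log likelihood of all 20 observed actions per game), and
model variants M1 (full, p = 7) through M5 (uniform random, p = 0) are
compared with a Draper BIC, `BIC = NLL + (p/2)(log 10 − log 2π)`; M5's
analytic average BIC for positive-investment games is 20·ln 5 ≈ 32.19.
Around the model sit the study's behavioural indices (a-priori trust,
mean trust, reciprocity, retaliation, total winnings), a synthetic
longitudinal cohort generator, and the statistical stages:
within/between-person age decomposition, a PCA family-adversity factor,
and linear mixed models with Satterthwaite degrees of freedom.

## Worked example

```r
library(trustmrt)

# an irritable, risk-tolerant adolescent-like investor...
inv <- agent_params("investor", alpha = 0.4, omega = 0.6, k = 1, plan = 1,
                    zeta = 0.5, q = 2, beta = 1)
# ...playing a trustee that replays fixed repayment fractions
sched <- c(1/2, 1/2, 1/6, 1/2, 0, 1/2, 1/2, 1/6, 1/2, 1/2)
game <- simulate_game(inv, sched, seed = 7)
game
#> <game_trajectory> subject s1 timepoint T1 - 10 rounds
#>  investments: 10 20 20 0 0 20 20 20 20 20
#>  repayments:  15 30 10 0 0 30 30 10 30 30

trust_indices(game)[, c("a_priori_trust", "mean_trust", "total_winnings")]
#>   a_priori_trust mean_trust total_winnings
#> 1             10         15            235

# refit the investor on a reduced grid
grid <- parameter_grid(alpha = c(0, 0.4, 1), omega = c(0.6, 1, 1.4),
                       k = 0:1, plan = 1L, zeta = c(0, 0.5),
                       q = c(0L, 2L), beta = c(1/3, 1))
fit <- fit_subject(game, model_spec("M1"), grid = grid)
fit
#> <fit_result> M1 NLL = 18.919 BIC = 20.545 p = 7 ( 1 tie(s) over 144 grid points )
#> <agent_params> investor alpha=1 omega=0.6 k=1 P=1 zeta=0.5 q=0 beta=0.333333
```

The round-1 investment (a-priori trust) is made before any feedback; mean
trust averages all ten investments; total winnings sum the ten independent
round payoffs. The fit result reports the negative log likelihood in nats,
the Draper BIC, and how many grid points tied with the winner (ties are
broken lexicographically). From this single game the search recovers the
generating risk aversion, theory-of-mind level and irritability exactly;
inequality aversion, irritation awareness and the softmax temperature are
only weakly identified by ten rounds, which is exactly what the seeded
recovery experiment (`recovery_experiment()`) quantifies at cohort scale.

On a cohort, `generate_cohort()` simulates subjects with ages 14–25, a
~1.5-year follow-up, an adversity-linked irritability distribution and
age-linked risk aversion; `decompose_age()`, `adversity_factor()` and
`fit_longitudinal_model()` reproduce the longitudinal analysis stages; and
`run_pipeline()` chains generation, behavioural metrics, fitting, model
comparison and the mixed models into a reproducible artifact directory
with a JSON manifest.

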