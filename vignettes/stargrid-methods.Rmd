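---
title: "Models and methods: social learning in the star-harvest game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social learning in the star-harvest game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

`stargrid` studies how people form and update beliefs about ingroup and
outgroup members from trial-by-trial experience in a competitive setting.
The environment is the *star-harvest game*: five players move around a
10 x 10 grid collecting stars that appear stochastically. Instead of moving,
a player may *zap* in one of the four directions; every player caught in the
ray is sent to a time-out zone for three turns. Four of the players are bots
of two scripted kinds. Both kinds seek stars; they differ only under
competition (another player strictly closer to the bot's nearest star):
*zappers* zap the competitor when it shares their row or column, *avoiders*
turn to a star they can win or move away. Group identity is induced by a
minimal-group manipulation: in the `groups` condition two bots share the
participant's avatar colour (ingroup) and two wear the other colour
(outgroup); colours never affect bot behaviour.

## The decision and learning model

The participant's per-target decision to zap is modelled, for every
(turn, target) pair in which the participant shares a row or column with the
target ("zap opportunity"), as a Bernoulli draw with

p(zap) = logit^-1( bias + prior_rel + w_star * StarDist
                   + w_target * TargetDist + w_zap * TargetZap )

where `prior_rel` is `prior_in` for ingroup targets, `prior_out` for
outgroup targets and 0 for neutral ones; `StarDist` and `TargetDist` are
Manhattan distances from the decider to the nearest star and to the target;
and `TargetZap` is the current belief, in [0, 1], that the target zaps.

Beliefs start at 0 (priors are carried by the decision rule, not by the
initial belief) and are updated by a prediction-error rule after every
observed action of another player. A *zap* is observed when a player's ray
hits someone. An *avoidance* is a move made while the mover (a) shared a row
or column with an active player and (b) was not the unique closest player to
any star — mirroring the bots' own competition trigger, so that plain
star-seeking moves teach nothing. Observations classified this way update
the actor's belief at the relation-specific learning rate (`lr_zap_*`
towards 1, `lr_avoid_*` towards 0). Under the full model the update also
propagates to the actor's same-team partner at the *attribution* rates
(`at_zap_*`, `at_avoid_*`): attribution 0 means no group-level inference,
attribution equal to the learning rate means the teammate is treated as if
they had acted themselves.

Three nested variants are compared: `P` (priors only; all rates forced to
0), `PL` (priors + individual learning; attribution forced to 0), and `PLA`
(priors + learning + attribution). The nesting is exact and is verified by
the test suite.

## Parameters, units, defaults

* Linear-scale parameters (`bias`, `prior_in`, `prior_out`, `w_star`,
  `w_target`, `w_zap`): additive logit-scale terms, unbounded.
* Rates (`lr_*`, `at_*`): probability-scale step sizes in [0, 1].
* Distances are divided by `distance_divisor` (default 10, the grid side)
  before entering the decision rule, so the weights refer to
  tenths-of-the-grid. With that scaling, plausible fitted values are of
  order 0.3 for `w_star` and -1.8 for `w_target`; the corresponding
  raw-distance weights would be ten times smaller.
* The synthetic-population defaults (`default_group_params()`) encode a
  reluctant zapper whose outgroup prior exceeds the ingroup prior, who
  learns far faster from zaps than from avoidances, and whose attribution
  of avoidances to outgroup teammates is near zero. Between-participant
  heterogeneity (`default_group_sd()`) is 0.5 on the sampling scale for
  every parameter — a moderate spread for this model class.

## The game engine and its conventions

The engine is deterministic given `(config, policies, seed)`; a single
seeded generator drives every draw in a fixed order (within-round policy
draws in turn order, then star spawn, star expiry, and time-out re-entry).
Design choices the game rules leave open were fixed once:

* All distances, movement and "closest" judgements use the Manhattan (L1)
  metric — movement is 4-directional, so L1 is the path metric.
* A zap ray affects every active player on the line (a first-hit-only mode
  sits behind `zap_ray = "first"`).
* After each round one star may spawn (probability 0.75) on a cell free of
  players and stars; stars present before the spawn expire independently
  with probability `star_expire_prob`. The expiry probability is not fixed
  by the game description; the default is 0.05 per star per round and is
  exposed in the configuration.
* Blocked moves (edge or occupied cell) are no-ops; bot policies try the
  alternative distance-reducing axis before accepting a no-op. Tie-breaks
  (nearest star, competing player, movement axis) are deterministic:
  lowest index, row before column.
* A zapped player misses exactly `timeout_turns` full rounds and re-enters
  at a uniformly random cell free of players and stars.
* Games start with one star on the board and players at random distinct
  cells.

## Event extraction

`build_event_stream()` interleaves, in game order, *observations* (every
other player's classified zap/avoid action — the learner watches bot-vs-bot
behaviour too) and *decisions* (the participant's zap opportunities with
covariates from the pre-move state). Within a turn the acting player's
behaviour updates beliefs before any later decision is evaluated, matching
the sequential game. When a participant's ray hits a target, that
(turn, target) pair is scored as a zap; same-turn candidates not in the ray
count as non-zaps. The zap-rate denominator counts (turn, target)
opportunity pairs — the unit of the model likelihood; a turns-based
denominator is available as an option.

## Hierarchical fitting

Participants' 14 parameters (6 linear, 8 rates on the logit scale) are
modelled as draws from independent normal group distributions with weakly
informative priors: group means ~ N(0, 2.5), group sds ~ half-N(0, 1).
Participants who never zapped are excluded before fitting (their likelihood
carries almost no information about the zap parameters).

Because no Hamiltonian Monte Carlo engine is part of this package's
dependency set, the reference sampler is written here as an adaptive
Metropolis-within-Gibbs scheme with three move types per iteration:

1. componentwise random-walk updates of each participant's parameters
   (proposal scales adapted to ~44% acceptance during warmup);
2. a *joint shift* of one group mean together with every participant's
   value of that parameter — the group-prior terms cancel, so acceptance is
   governed by the aggregated likelihood tilt. This move is what identifies
   group means for parameters that are weakly informed at the individual
   level (most learning and attribution rates);
3. a *joint rescale* of one group sd together with every participant's
   deviation (the funnel direction), plus conjugate Gibbs draws of the
   group means and slice-sampling updates of the group sds.

One further move exploits the model's only structural non-identifiability:
`bias` enters every decision together with one of the two group priors, so
only the sums `bias + prior_in` and `bias + prior_out` are data-identified.
A likelihood-invariant translation along the null direction (bias up, both
priors down) samples that direction from the priors directly; the reported
split between bias and priors is therefore the symmetric one the N(0, 2.5)
priors imply. Convergence is monitored with rank-normalised split-Rhat;
values above 1.05 trigger a warning. The centered parameterisation with
Gibbs/slice group updates replaces the non-centered Cholesky trick used
with gradient-based samplers, which has no analogue in a random-walk
scheme; group-level correlations between parameters are not modelled.

A fast empirical-Bayes fitter (`method = "map"`) shares the same model: EM
sweeps alternate per-participant penalised optimisation with closed-form
group-mean/sd updates, and the posterior is represented by Laplace draws
around each participant's mode. It is useful for quick smoke runs and
pipelines, but it has two known distortions: for weakly identified rate
parameters the point estimates shrink heavily towards the group
initialisation, and the Laplace draws misstate the pointwise
log-likelihood variance that WAIC's complexity penalty is built from.
Group-level inference and model comparison therefore use the MCMC sampler;
the MAP fitter is the convenience method.

Model comparison uses WAIC computed from the per-draw pointwise
log-likelihood matrix (`-2 * (lppd - pWAIC)`), with the standard error of
pairwise differences computed from the pointwise contributions, and Akaike
weights over the compared variants. Posterior intervals are 89%
highest-density intervals.

## Synthetic data: what it emulates, what it does not

`simulate_study()` samples per-participant parameters from the group
distributions, then plays closed-loop games in which the participant slot
is driven by the model itself: it observes and learns online, and on its
own turn evaluates each shared-line candidate in random order, drawing a
Bernoulli decision per candidate at the model probability; the first
success becomes a zap, otherwise the agent moves by the avoider policy.
This keeps the generative process aligned with the per-opportunity
Bernoulli likelihood up to one deliberate simplification: a real turn emits
at most one zap, so when several candidates are available the later ones
are slightly censored relative to independent Bernoulli draws.

`replay_predict()` is the complementary open-loop tool: it discards the
logged participant's choices and runs the model against the recorded bot
behaviour and star locations only, yielding expected zapping behaviour and
belief trajectories. Bot-only logs for replays are produced by the engine
itself with the participant slot following the avoider placeholder (its
positions make the distance covariates well-defined); the original study
seeded such simulations with pilot human sessions, so regime comparisons
on engine-generated logs are qualitative orderings, not curve matches.

Synthetic data inherit the scripted bots' regularities; they do not emulate
human variability in movement style, attention lapses, or condition
dropout. Passing recovery tests therefore demonstrates the estimator works
when the model is true, not that the model captures every feature of real
play.

## Simulation regimes

Three regime pairs demonstrate that the design separates the mechanisms
(`regime_params()`): priors low/high (-0.9 / -0.1) with learning and
attribution off; zap learning rate low/high (0.2 / 0.9) with avoidance
rate 0.25 and attribution off; zap attribution low/high (0.2 / 0.5) with
zap learning rate 0.8, avoidance rate 0.25 and avoidance attribution 0.
All regimes share `w_star` 0.26, `w_target` -1.84, `w_zap` 0.89 and zero
bias; the regime definitions fix the varied values, and the shared
situational weights are the population defaults. Expected orderings —
higher prior, more zapping; higher zap learning rate, faster zapper-belief
growth and a wider zapper/avoider gap; higher zap attribution, rising
avoider beliefs and a narrower gap — are asserted by sign tests across 100
seeded replays in the test suite.

## Numerical choices and degenerate inputs

* Decision probabilities are clamped to [1e-12, 1 - 1e-12] before taking
  logs.
* With no star on the board, the nearest-star distance is defined as the
  grid diameter 2 (grid_size - 1) — maximally far.
* The shortest-interval HDI uses the sorted-draws sliding window.
* `to_sampling()` clamps rates to [1e-6, 1 - 1e-6] before the logit, so a
  generating rate of exactly 0 (e.g. the PL variant's attribution) maps to
  a finite but extreme logit.
* Laplace covariance matrices are projected to the nearest positive
  definite matrix (eigenvalue floor 1e-8) before Cholesky.
* Group sds are floored at 0.05 (MAP) / 1e-3 (MCMC) to avoid degenerate
  collapse.

## Problem sizes used by the test suite

The suite exercises the full chain at sizes a reviewer can rerun at a desk:
oracle equivalence on 50 random streams; regime orderings over 100 seeded
replays; parameter recovery on one 60-participant, 100-turn cohort fitted
with 2 chains of 1500 kept iterations; model recovery on 10 + 10 cohorts
of 30 participants fitted with 2 chains of 400 kept iterations. The
acceptance script repeats the same computations at a 30-participant,
40-replay scale. Larger cohorts
and longer chains tighten the same quantities but do not change the
qualitative conclusions.

## Known limitations

* Group-level correlations between parameters are not estimated.
* The random-walk sampler needs many iterations for near-flat directions;
  split-Rhat for some group sds can stay above 1.05 at desk-scale run
  lengths.
* Several rate parameters (avoidance learning, attribution) are only
  weakly identified by 100-turn games: their marginal posteriors remain
  broad and prior-influenced at realistic cohort sizes, a property of the
  design rather than of the estimator (the original study's broad
  logit-scale posteriors for the same parameters point the same way).
* At the default generating parameters the attribution mechanism adds only
  a few nats of predictive gain per 30-participant cohort, so WAIC-based
  selection between PL and PLA at that scale operates near its noise
  floor: PL data reliably select PL (parsimony), while PLA data select PLA
  only in about half of replicates.
* The neutral condition shares a single learning/attribution rate pair
  (the in/out mean) since no two bots share a team there; only the
  mixed-group condition is fitted by default.
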