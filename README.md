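# stargrid

Simulation and modelling tools for studying **intergroup bias in social
learning** with the multiplayer *star-harvest* grid game. Five players move
around a 10 × 10 grid collecting stars; instead of moving, a player can
*zap* in one of four directions, sending every player caught in the ray to a
time-out zone for three turns. Four players are scripted bots — *zappers*
zap competitors that share their row or column, *avoiders* never zap — and a
minimal-group manipulation makes two bots ingroup and two outgroup (or all
four neutral). The question the package serves: when a participant decides
whether to zap a specific player, how much of that decision is driven by
group-identity priors, by what they have learned about that individual, and
by generalisation from the individual's teammates?

## The model

For every (turn, target) pair where the decider shares a row or column with
the target (a *zap opportunity*), the probability of zapping is

```
p(Zap) = logit⁻¹( Bias + Prior_in/out
                  + w_StarDist · StarDist + w_TargetDist · TargetDist
                  + w_TargetZap · TargetZap )
```

where `TargetZap ∈ [0, 1]` is the learned belief that the target zaps.
Beliefs start at 0 and follow a prediction-error rule after each observed
action (zap = 1, avoid = 0):

```
PlayerZap(t+1) = PlayerZap(t) + LR_Zap/Avoid^In/Out · (outcome − PlayerZap(t))
```

and, with group-level attribution, the same observation also moves the
belief about the actor's *teammate* at the attribution rates `At_*`:

```
OthersZap(t+1) = OthersZap(t) + At_Zap/Avoid^In/Out · (outcome − OthersZap(t))
```

Three nested variants are compared: **P** (priors only), **PL** (priors +
learning), **PLA** (priors + learning + attribution). Fitting is
hierarchical (normal group distributions over per-participant parameters;
rates on the logit scale) with an adaptive Metropolis-within-Gibbs sampler
or a fast MAP/Laplace empirical-Bayes fitter, and variants are compared by
WAIC with Akaike weights. Posterior intervals are 89% HDIs.

## A worked example

Simulate a bot-only game, then a game whose participant slot is driven by
the learning model with known parameters, and compare zap rates:

```r
library(stargrid)

cfg <- game_config(seed = 42)            # groups condition, mixed bots
log <- run_game(cfg)                     # placeholder participant: never zaps
p   <- params_from_vector(default_group_params())
sim <- simulate_participant(cfg, p, variant = "PLA", seed = 7)
zap_rate(sim)
#> # A tibble: 4 × 5
#>   relation behavior n_zaps n_opportunities  rate
#> 1 ingroup  avoider       2               8  0.25
#> 2 ingroup  zapper        2              10  0.2
#> 3 outgroup avoider       1               4  0.25
#> 4 outgroup zapper        0              11  0
```

Each row is a group-identity × bot-behaviour cell; `rate` is zaps divided by
zap opportunities (shared-row/column turns). Replaying a log through the
model exposes the internal quantities — the belief that each target zaps and
the per-opportunity zap probability:

```r
rp <- replay_predict(sim, p, "PLA", seed = 1)
head(rp$decisions, 4)
#>    turn target relation star_dist target_dist belief p_zap behavior sim_zap
#> 1     1      4 outgroup       0.6         0.5  0     0.131 zapper         0
#> 2     5      2 ingroup        0.2         0.2  0     0.100 zapper         0
#> 3    20      4 outgroup       0.3         0.5  0.951 0.245 zapper         0
#> 4    21      4 outgroup       0.2         0.3  0.828 0.290 zapper         0
```

By turn 20 the model has watched the outgroup zapper act and its belief has
risen from 0 to 0.95, lifting the zap probability from 0.13 to 0.25 —
exactly the learning signal the fitted parameters are estimated from.
`autoplot(rp)` draws the belief trajectories.

The full chain — simulate a cohort, exclude non-zappers, fit P/PL/PLA,
compare by WAIC, score parameter recovery — is one call:

```r
res <- pipeline_run(n_participants = 20, method = "map", seed = 1,
                    out_dir = "artifacts")
res$comparison    # WAIC table with dWAIC, dSE, pWAIC, Akaike weights
res$recovery      # truth vs estimate, absolute error, 89% HDI coverage
```

`tidy()` and `glance()` methods summarise fitted objects; game logs read
and write a documented JSON-Lines format (`write_game_log()`,
`read_game_log()`).

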