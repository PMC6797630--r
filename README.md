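# ddspill

Delay discounting across commodities under a motivational state:
adaptive measurement, Bayesian per-session estimation, and a six-model
comparison of how the state changes discounting.

## What it is for

In a repeated-measures hunger design, each participant's delay discounting
is measured in a control and a fasted state for three commodities — food
(in-domain: eating corrects hunger), money (indirectly fungible into food)
and music downloads (no route to the state). The question is *which*
commodities show increased discounting when hungry. `ddspill` provides the
complete analysis chain for such studies, plus a synthetic-study generator
so every stage can be validated by simulation, for researchers in
behavioural economics and computational psychiatry.

## The models at its core

Subjective value follows the hyperbolic discount function
`V = R / (1 + kD)` (`k` in days⁻¹; half-life `1/k` days), with
exponential, Myerson–Green and modified-Rachlin forms for robustness.
A choice between an immediate `A` and a delayed `B` follows the
lapse-contaminated probit rule

    P(choose delayed) = ε + (1 − 2ε) · Φ((V_B − V_A) / α),

fitted per session by MCMC under priors `α ~ Exp(0.1)`,
`ε ~ Beta(1.1, 10.9)`, `log k ~ Normal(log(1/50), 2.5)`. Trial designs
are selected adaptively by expected information gain over a fixed-`B`
design space (19 log-spaced delays from 1 hour to 1 year).

Per-participant changes in `log k` (fasted − control) are then modelled as
Cauchy-distributed around group-level per-commodity locations, and six
hypotheses about those locations — trait-only `(0,0,0)`, in-domain
`(a,0,0)`, monetary fungibility `(b,b,0)`, negative spillover `(g,−d,−d)`,
spillover `(e,z,z)` with `e > z`, state-only `(h,h,h)` — are fitted by
maximum likelihood and compared with AIC/BIC and Akaike/Schwarz weights
`w ∝ exp(−½ ΔIC)`.

## Worked example

```r
library(ddspill)
cfg  <- population_config(n_participants = 6, rng_seed = 1)  # spillover generator
sim  <- simulate_study(cfg)            # 6 x 2 x 3 adaptive sessions of 35 trials
fits <- run_fit(sim$trials, quiet = TRUE)
study_report(fits)
```

```
         food money music
control 60.05 46.49 96.11
fasted   6.31 28.50 80.24
 food money music
 2.05  0.60  0.54
median AUC: 0.858
spillover ratio: 22.17 %
```

Half-lives (days, first block) collapse from 60 to 6 days for food when
"fasted" while money and music fall far less; the paired Cohen's *d*
effect sizes (second block) show the same asymmetry; the predictive
AUC-ROC says the fitted choice model predicts ~86% pairwise-correctly; and
the out-of-domain change is ~22% of the in-domain change, near the 25%
this generator encodes.

```r
run_compare(delta_from_summaries(fits))$comparison
```

```
                model n     LL  dAIC   wAIC  dBIC   wBIC
           trait_only 1 -37.91 18.28 0.0001 18.69 0.0000
            in_domain 2 -28.08  0.61 0.3666  0.82 0.3428
 monetary_fungibility 2 -34.14 12.73 0.0009 12.94 0.0008
   negative_spillover 3 -28.08  2.61 0.1349  2.61 0.1400
            spillover 3 -26.77  0.00 0.4972  0.00 0.5160
           state_only 2 -34.81 14.08 0.0004 14.29 0.0004
```

At only 6 simulated participants the spillover model already leads but
cannot dominate; with the default 50 participants its weight approaches 1.
Note the boundary identity visible in the LL column: with a positive
out-of-domain change, negative spillover collapses onto in-domain
(−28.08 for both).

A thin command-line wrapper over the same stages is installed at
`inst/scripts/dd-pipeline.R`
(`simulate` / `fit` / `compare`, with `--config`, `--seed`, `--out`,
`--quiet`).

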