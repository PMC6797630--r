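---
title: "Measuring and modelling state-induced changes in delay discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling state-induced changes in delay discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddspill)
```

## The scientific question

When a motivational state such as hunger sets in, does the devaluation of
delayed rewards rise only for the commodity that can correct the state
(food), or does the change spill over to commodities that cannot (money,
music downloads)? `ddspill` implements the full analysis chain for a
repeated-measures design answering that question: each participant's delay
discounting is measured in a control and a deprived (fasted) state, for
three commodities, and six competing models of the per-commodity change in
discounting are compared formally.

## Discounting and the choice model

Subjective value is modelled with the hyperbolic discount function
$V = R / (1 + kD)$, with the rate $k$ in days$^{-1}$; the half-life $1/k$
is the delay at which a reward loses half its value. Exponential,
Myerson–Green hyperboloid and modified-Rachlin forms are available for
robustness analyses, and the normalised area under the discounting curve
(`normalized_discount_auc()`) provides a form-agnostic index: trapezoidal
area under $V/R$ against normalised delay, anchored at $(0, 1)$.

A binary choice between an immediate amount $A$ and a delayed amount $B$
at delay $D_B$ is modelled by a lapse-contaminated probit rule,

$$P(\text{choose delayed}) = \epsilon + (1 - 2\epsilon)\,
\Phi\!\left(\frac{V_B - V_A}{\alpha}\right),$$

where $\alpha > 0$ is the comparison acuity (the SD, in commodity units,
of the effective comparison noise) and $\epsilon \in [0, 0.5)$ a lapse
rate capturing value-independent responding at both extremes. The value
difference is taken in raw commodity units, with no normalisation: $\alpha$
absorbs the scale, and the rule is exactly invariant under joint rescaling
of values and acuity (a property the test suite checks). Note that the
Greek letters $\alpha$ and $\epsilon$ are re-used by the hypothesis-model
layer below with entirely different meanings; in code the two namespaces
never mix (`choice_params()` vs `hypothesis_model()`).

## Per-session inference

Each participant × condition × commodity session is fitted separately and
independently. Priors are
$\alpha \sim \text{Exponential}(0.1)$,
$\epsilon \sim \text{Beta}(1.1, 10.9)$, and
$\log k \sim \text{Normal}(\log(1/50),\, 2.5)$ — centred on a 50-day
half-life, weak enough that 35 informative trials dominate. Sampling uses
JAGS with 4 chains, 500 adaptation iterations and 1000 retained draws per
chain; these are exposed as configuration because the contract is on the
diagnostics, not the sampler settings. Convergence is summarised by
split-chain $\hat R$ (threshold 1.05) and effective sample size, and
non-convergence is flagged, never silently dropped. The point estimate of
a session is the posterior median of $\log k$.

The Beta lapse prior technically has support $(0,1)$, but $\epsilon > 0.5$
makes the choice rule non-monotone; its prior mass there is below 0.4%.
Draws at or above 0.5 are therefore removed from the stored posterior, and
if they exceeded 1% of the mass the fit carries a warning flag.

Model fit quality is assessed with the area under the ROC curve of the
posterior-predictive choice probabilities against the observed responses
(Mann–Whitney construction, ties at 0.5); 1 is perfect prediction, 0.5 is
chance. The AUC is undefined (and returned as flagged `NA`) when a session
contains a single response class.

## The adaptive measurement protocol

The emulated protocol fixes the delayed reward per commodity (20 for money
and music, 10 for food, under the exchange rate 20 money units = 20 songs
= 10 food units) and adapts the immediate amount $A$ and delay $D_B$ per
trial. Delays live on a 19-point geometric grid from 1 hour to 1 year —
"approximately logarithmic spacing" is realised as exact geometric spacing
between those stated endpoints. Candidate immediate amounts are the 99
percent steps $B/100, \dots, 99B/100$; percent granularity is the
package's own choice, as is the selection criterion itself: the original
protocol's algorithm is external to this package, so `select_next_trial()`
uses a myopic expected-information-gain stand-in. Concretely, the current
posterior over $(\log k, \alpha, \epsilon)$ is represented by (weighted)
draws; for each candidate design the expected post-response Shannon
entropy of the binned (30 bins) marginal posterior over $\log k$ is
computed in closed form from the draws, and the candidate minimising it is
chosen. Ties — e.g. under an atomic posterior, which no observation can
sharpen — fall back to the candidate whose predictive choice probability
is closest to 0.5, then to grid order, keeping selection deterministic.

During a simulated session the interim posterior is a particle
approximation (500 draws from the prior, likelihood-reweighted per trial,
systematic resampling plus two Metropolis rejuvenation steps against the
full session history whenever the effective sample size halves) rather
than a full MCMC refit per trial; the inferential contract applies to the
final JAGS fit only. Sessions start from the prior with no warm-start
trial. In matched-seed simulations the adaptive chooser roughly halves to
quarters the posterior SD of $\log k$ relative to random designs drawn
from the same space — the property the test suite asserts over 20 seeds.

## Six models of the change in discounting

The analysis object is the table $\Delta_{p,c}$ of per-participant changes
in $\log k$ (fasted minus control) for commodities (food, money, music).
Participant scatter around the group-level change is modelled as Cauchy
with a shared scale — heavy tails make the group locations robust to the
occasional extreme participant. Each candidate model maps free parameters
(all constrained positive) to per-commodity locations:

| model | locations (food, money, music) | parameters incl. scale |
|---|---|---|
| trait only | $(0, 0, 0)$ | 1 |
| in-domain | $(a, 0, 0)$ | 2 |
| monetary fungibility | $(b, b, 0)$ | 2 |
| negative spillover | $(g, -d, -d)$ | 3 |
| spillover | $(e, z, z)$, $e > z$ | 3 |
| state only | $(h, h, h)$ | 2 |

Two conventions deserve note. First, the negative-spillover model's
out-of-domain *change* is negative while its free parameter $d$ is
positive, consistent with the all-positive constraint. Second, the
spillover model's ordering constraint $e > z$ is enforced by
reparameterising the in-domain change as the out-of-domain change plus a
positive excess; without it, spillover would be exchangeable with a
relabelled variant and the comparison ill-posed.

Fitting maximises the summed Cauchy log-density by Nelder–Mead on
log-transformed parameters, from 8 random starts (locations in $[0,3]$,
scale in $[0.05, 2]$) plus deterministic near-boundary starts
($\log$-parameter $= -30$), because nested-model structure makes boundary
optima routine: when the out-of-domain mean change is positive, the
negative-spillover fit drives $d$ to its boundary and collapses onto the
in-domain fit — an equality the comparison table should display, and which
the tests assert to $10^{-6}$ log-likelihood units. The best endpoint
wins; ties go to the smaller parameter norm. The scale is floored at
$10^{-6}$ to avoid density singularities on degenerate tables. A refined
grid-search oracle in the test suite confirms the optimiser to $10^{-4}$
log-likelihood units on small tables.

Models are compared with $AIC = 2n - 2LL$ and $BIC = n\ln N - 2LL$ and
converted to weights $w_m \propto \exp(-\tfrac12 \Delta IC_m)$. The BIC
sample size is the number of participants (50 in the emulated design),
not the number of $\Delta$ cells: recomputing the published comparison
table's $\Delta BIC$ column from its LL and $n$ columns reproduces it with
$\ln 50$ and fails with $\ln 150$, and the package's consistency test
encodes that check. Parameter counts $n$ include the scale parameter.

Descriptive outputs accompany the formal comparison: per-commodity paired
Cohen's $d$ of the change in $\log k$ (zero-variance differences are
rejected as undefined rather than reported as 0), percentile bootstrap
CIs of mean changes (2000 resamples by default), and the spillover ratio —
the mean out-of-domain change as a percentage of the mean in-domain
change.

## The synthetic-study generator

`population_config()` defaults encode the emulated study conditions: 50
participants, 2 conditions × 3 commodities, 35 trials per session, fixed
delayed rewards, the 19-delay grid. Baseline $\log k$ is drawn per
participant × commodity from Normal($\log(1/50)$, 1.0) with correlation
0.5 across commodities — discount rates for different commodities
correlate in real populations, and the exchangeable-correlation value is a
free, documented default, not an empirical claim. Condition effects are
drawn from the configured generative hypothesis model with Cauchy scatter
(default scale 0.5; default model spillover with in-domain shift 2.4 and
out-of-domain shift 0.6, magnitudes in line with a strong fasting
manipulation and a 25% spillover). Raw Cauchy tails occasionally produce
absurd changes (a $|\Delta\log k| > 10$ is a half-life change of five
orders of magnitude), so generated deltas beyond $\pm 10$ are resampled;
this truncation is a property of the *generator* only — the analysis
modules never truncate data. Simulated responders default to acuity 2 and
lapse 0.01, attentive but imperfect.

What the generator does **not** emulate: session-order effects, within-
participant correlation of lapse/acuity across sessions, questionnaire or
physiological covariates, and any model misspecification (simulated
choices truly come from the hyperbolic probit model). Passing recovery
tests therefore demonstrates the estimation and comparison machinery is
correct and well-calibrated under the assumed model, not that the model is
true of human data.

## Validation sizes and numerical choices

The test suite exercises: parameter recovery over 50 simulated adaptive
sessions with true $\log k \in [-5, 0]$, acuity in $[0.1, 2]$ and lapse up
to 0.05 (at least 90% of posterior medians within $\pm 0.5$, posterior SD
below the prior SD in every run); model recovery over 100 replicate
$P = 50$ tables per generating model (the generator must win the AIC
weight in a majority for every model); 20 matched adaptive-vs-random
seeds; and 20 replicate tables for the spillover-ratio property (mean
estimate within $[15\%, 35\%]$ when the true out/in ratio is 25%). These
sizes were chosen as the smallest that make the stochastic assertions
stable across seeds.

Other numerical details: per-session seeds are derived arithmetically from
the study seed so every stage is reproducible end to end and parallel
structures (sessions, replicates) never share streams; all CSV artifacts
carry `#`-prefixed metadata headers (package version, seed, config hash)
and round-trip through the package readers.

## Known limitations

* The adaptive chooser is a documented stand-in, not a reimplementation of
  the external protocol; recovery-based comparisons with it are
  like-for-like within this package only.
* Sessions are fitted independently; there is no hierarchical pooling
  across participants or conditions, matching the emulated analysis.
* The curvature parameter of the hyperboloid families is not fitted by the
  pipeline; those families are provided for value-function evaluation and
  the AUC robustness metric.
* Cauchy group-level locations are compared by maximum likelihood with
  IC weights; fully Bayesian model comparison (marginal likelihoods) is
  deliberately out of scope, avoiding priors over effect sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- population_config(n_participants = 6, rng_seed = 1)
sim <- simulate_study(cfg)
fits <- run_fit(sim$trials, quiet = TRUE)
study_report(fits)
res <- run_compare(delta_from_summaries(fits))
res$comparison
```

With the default spillover generator, the comparison assigns the spillover
model the highest AIC weight once enough participants are simulated, and
`study_report()` returns the headline descriptives: median half-lives per
condition and commodity, paired effect sizes, the median predictive
AUC-ROC and the spillover ratio.
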