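---
title: "Models and methods: drift-diffusion and mixed-model analysis of SRET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: drift-diffusion and mixed-model analysis of SRET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sretddm)
```

# The scientific problem

In the self-referential encoding task (SRET) a participant decides, word by
word, whether positive and negative adjectives describe them. The interesting
quantities are not just the endorsement and rejection rates but the latent
decision process behind them: how quickly evidence accumulates toward "yes"
or "no", whether there is an a-priori response bias, and how those quantities
shift with an experimental manipulation — here, exposure to blue-enriched
versus blue-depleted light in a within-subject, two-session, counterbalanced
design. `sretddm` implements the full analysis chain for such data: a
synthetic-data generator matching the design, hierarchical Bayesian
estimation of drift-diffusion model (DDM) variants, posterior-overlap
inference, posterior-predictive checks, trial-level random-intercept
logistic models, and descriptive summaries.

Because raw data from studies of this kind are often not deposited, the
generator is a first-class, tested component: every stage of the analysis
can be exercised, and its calibration verified, on data whose ground truth
is known.

# The diffusion model

A decision on one trial is modelled as a Wiener process with unit diffusion
coefficient accumulating noisy evidence from a starting point $z a$ (with
relative bias $z \in (0,1)$) between absorbing boundaries $0$ and $a$, at
mean rate $v$ (the drift). The observed reaction time is the first-passage
time plus a non-decision time $t_0$ covering encoding and motor execution.
The upper boundary is the "no, this does not describe me" (rejection)
response, coded 1; positive drift therefore favours rejection.

The likelihood uses the exact first-passage density. Writing
$\tau = (rt - t_0)/a^2$ and $w$ for the relative start point of the
reflected process, the density is evaluated with the standard small-time and
large-time series expansions, the branch chosen per evaluation by comparing
the number of terms each needs at truncation tolerance $10^{-7}$ (the two
branches agree to well below $10^{-6}$ where both are usable; this is
tested). The lower-boundary density follows from the reflection
$v \to -v$, $z \to 1 - z$. The probability of absorption at the upper
boundary has the closed form

$$P(\text{upper}) = \frac{1 - e^{-2 v a z}}{1 - e^{-2 v a}}, \qquad
P(\text{upper}) = z \text{ when } v = 0,$$

which serves as an independent oracle for the simulator.

## Simulation

Trials are simulated by Euler–Maruyama with default step `dt = 1e-3` s. A
naive discrete walk misses boundary crossings that occur *within* a step,
which inflates reaction times and biases the choice fraction by
$O(\sqrt{dt})$ — at the default group parameters and `dt` the
choice-probability bias of the uncorrected walk would exceed Monte-Carlo
error at the sample sizes we use. Each step therefore also applies the Brownian-bridge
crossing probabilities $\exp(-2(a - x_0)(a - x_1)/dt)$ and
$\exp(-2 x_0 x_1 / dt)$, which removes the leading-order bias; the residual
$O(dt)$ error is checked by a step-halving test and against the closed-form
absorption probability.

# The synthetic-data generator

The generator reproduces the design the analyses assume: 33 analysed
participants, two sessions two weeks apart with the two light conditions
counterbalanced (the enriched-first/depleted-first split differs by at most
one participant), and per session 26 positive plus 26 negative adjectives in
each of three blocks — 156 trials per session, 10,296 trials in total,
5,148 per valence. Adjectives come from a packaged lexicon; word identity
carries no effect (only valence does), so the specific tokens are
interchangeable.

Group-level truth defaults to the reported best-fit posterior means: drift
$-0.73$ and $-0.71$ for positive words under depleted and enriched light,
$1.13$ and $1.36$ for negative words, with shared $a = 1.42$, $z = 0.49$,
$t_0 = 0.46$ s. Participant-level parameters are drawn from normal
hierarchies around these means, truncated **by resampling** (not clipping,
which would put probability atoms on the bounds) to $a > 0$,
$z \in (0.05, 0.95)$, $t_0 \in (0.1, 1.0)$ s. Between-participant SDs are
not reported for this design; the defaults ($0.25$ for each drift cell,
$0.20$ for $a$, $0.04$ for $z$, $0.05$ s for $t_0$) are plausible magnitudes
relative to the group means and are configurable — they are assumptions, and
conclusions that depend on them should be checked across settings. A
per-participant hue-awareness flag is Bernoulli at rate 0.26, and sex is
assigned proportionally to a 22:13 female:male ratio (21:12 at $n = 33$).

What the generator deliberately does **not** emulate: inter-trial intervals,
fixation and light-adaptation periods, practice effects, word-level
psycholinguistic covariates, and inter-trial variability parameters
(`sv`, `st`, `sz`) of extended DDM formulations. Passing recovery tests on
these data therefore show that the estimation machinery is calibrated for
the stated generative family — not that real SRET data satisfy that family.

A second generator produces trial-level binary responses from a
random-intercept logistic truth,
$\operatorname{logit} P(\text{reject}) = \beta_0 + b_i +
\beta_c \mathbb{1}[\text{enriched}] + \beta_{rt} \cdot rt$ with
$b_i \sim N(0, \tau_{00})$, reaction times drawn from a lognormal matched to
the observed task moments (mean 0.85 s, SD 0.45 s). Its defaults are the
reported negative-word estimates: $\beta_0 = \log 12.07$,
$\beta_c = \log 1.24$, $\beta_{rt} = \log 0.68$, $\tau_{00} = 1.88$.

# Hierarchical estimation

## Model variants

Variants are defined by which of $\{v, z, t\}$ vary across the four
condition-by-valence cells under cell-means coding with no intercept
(`parameter ~ 0 + condition:valence`); the null variant shares everything.
Boundary separation never varies by cell — such variants are known not to
converge for this design and the spec constructor rejects them with an
explicit error. The hierarchy places participant-level additive offsets on
$a$, $z$ and $t_0$ (half-normal SD hyperpriors), while drift is estimated at
the group (cell) level only, matching how the posterior-predictive check is
defined (participant-level $a, t, z$; group-level $v$).

## Priors

Group drift cells $N(0, 2^2)$; group $a \sim N(1.5, 0.75^2)$ truncated to
$(0.3, 4)$; group $z$ logit-normal $N(0, 0.5^2)$; group
$t_0 \sim N(0.4, 0.3^2)$ truncated below at $0.05$ s. The *upper* truncation
of the group $t_0$ deserves a note: each participant's effective
non-decision time (group mean plus offset) is capped just below that
participant's own minimum RT, which is what keeps the likelihood finite.
Truncating the group mean at the *global* minimum RT — the smallest RT of
the fastest participant — would clamp the group mean below its true value
whenever participants genuinely differ in $t_0$, since the global minimum
tracks the fastest participant's $t_0$ rather than the group's. The group bound is
therefore the largest per-participant minimum RT, with validity enforced at
the participant level. Hierarchical SDs have Half-Normal(0.3) priors — weak
on the scale of all three parameters.

## Sampler

Sampling is adaptive Metropolis-within-Gibbs: scalar Gaussian random-walk
updates for every group coefficient and participant offset (proposal scales
adapted toward 44% acceptance during burn-in only, then frozen), log-scale
walks for the hierarchical SDs (these touch no likelihood), and — important
for convergence diagnostics — an interweaving *recentering* move per family
that proposes shifting a group mean by $\varepsilon$ while shifting every
offset by $-\varepsilon$. That move leaves all participant-level values, and
hence the likelihood, unchanged, and is accepted on the prior ratio alone;
without it the group-mean/offset ridge mixes too slowly for split-chain
R-hat to reach 1.01. Drift cells are initialized by inverting the
closed-form choice probability at each cell's empirical rejection rate.

The reference protocol retains every 10th of 25,000 post-burn-in draws from
30,000 per chain; the desk-scale profile used throughout the examples,
tests, and the acceptance script is 3 chains of 6,000 draws, burn-in 1,000,
thin 5 (1,000 retained per chain). The full-design fit at the desk profile
runs in minutes; retained-draw arithmetic, seeded reproducibility, and
agreement between the sampler's internal likelihood and the exported
`hddm_log_likelihood()` are all tested.

## Convergence and model comparison

`gelman_rubin()` implements the split-chain potential scale reduction
factor; `mcmc_autocorrelation()` the normalized within-chain lag profiles.
Model comparison uses `DIC = \bar D + p_D` with
`p_D = \bar D - D(\hat\theta)` evaluated at the posterior means
(Spiegelhalter's definition); deviance is tracked at every retained draw.
Lower DIC is better; `select_best_model()` reports the ranking and each
variant's DIC difference from the null. (Displays elsewhere sometimes plot a
transformed difference where taller bars mean better fit; the package
reports untransformed DIC and $\Delta$DIC only.)

## Inference by posterior overlap

A condition contrast is deemed significant when less than 5% of posterior
probability mass overlaps between the two distributions. "Overlap" is
operationalized as the overlap coefficient
$\mathrm{OVL} = \int \min(\hat f_a, \hat f_b)$ computed from Gaussian KDEs
(Silverman bandwidth) on a shared 512-point grid; for equal-variance normal
pairs this equals $2\Phi(-|\Delta\mu|/2\sigma)$, which the tests use as a
closed-form oracle. Because "overlap" could also be read as a tail
probability of the difference distribution, the auxiliary directional
probability $P(a - b > 0)$ is always reported alongside; the significance
flag is driven by OVL.

## Posterior-predictive check

For each participant-by-condition-by-valence cell, RTs are simulated at the
participant's posterior-mean $a$, $z$, $t_0$ and the group posterior-mean
cell drift, and the 10th/30th/50th/70th/90th percentile pairs of observed
versus simulated RTs are reported per response boundary. Observed RTs are
first trimmed at 3.29 SD from the cell mean — the trimming applies to
observed data only. Cells with fewer than five retained trials at a boundary
are flagged and excluded from summaries. Using posterior means rather than
full posterior-predictive draws matches how the check is defined for this
analysis; it understates predictive uncertainty and is meant as a
calibration display, not an inferential test.

# Trial-level logistic models

The odds of positive self-evaluation (rejecting a negative word; endorsing a
positive one) are modelled per valence with `condition`, `rt`, and
optionally `sex` and `hue` as fixed effects and a participant random
intercept. Estimation is maximum likelihood with the random effect
integrated out by adaptive Gauss–Hermite quadrature (15 nodes by default;
estimates are stable to `1e-5` against 25 nodes) via `lme4::glmer` with the
BOBYQA optimizer — the same estimation stack the original analysis used.
The package computes the derived quantities itself: Wald 95% CIs
$\exp(\beta \pm 1.96\,\mathrm{SE})$ and two-sided z p-values, the
latent-scale ICC $\tau_{00}/(\tau_{00} + \pi^2/3)$, and Nakagawa marginal /
conditional $R^2$ on the same latent scale. Note the printed residual
variance $\pi^2/3 \approx 3.29$ is a property of the logistic link, not an
estimated intercept variance; $\tau_{00}$ is the estimated quantity.

Candidate fixed-effect structures (main effects, two-way, and three-way
interactions with sex and hue) are ranked by BIC. "BIC corrected for small
samples" is ambiguous for clustered binary data: the table therefore reports
standard BIC (penalty $\log n_{\text{obs}}$, which drives the ranking) and a
cluster-based variant with penalty $\log n_{\text{participants}}$, since the
effective information for between-participant terms scales with clusters.

Standardized coefficients come from refitting on a dataset with continuous
predictors z-scored — a pure reparameterization, verified by identical
log-likelihoods.

# Descriptive summaries

`proportion_table()` reproduces the response-type table: counts,
percentages rounded half-up to one decimal (base R's `round()` rounds half
to even, which would not reproduce printed tables), and RT mean (SD) per
condition-by-valence-by-response cell. Aggregate condition comparisons use
one-tailed paired t-tests on per-participant proportions, expecting larger
positive-self-evaluation proportions under enriched light. Identical paired
vectors have zero-variance differences, so the t statistic is undefined
there; the function raises an explicit error rather than returning 0/0.

# Numerical choices and degenerate inputs

* WFPT series tolerance $10^{-7}$; density is exactly $-\infty$ for
  $rt \le t_0$.
* Simulator `dt = 1e-3` s with bridge correction; paths are censored at 20 s
  (effectively unreachable at sane parameters).
* Truncation everywhere by resampling or support rejection, never clipping.
* Degenerate posteriors: constant draws give `pD = 0` and
  `DIC = deviance`; constant draw sets make the overlap coefficient
  undefined and raise an error.
* Quantiles use type-7 interpolation; a single sample yields that value at
  every probability.
* GLMM fits that fail outright raise a diagnostic error; singular
  (boundary) variance fits are reported with a warning and reduce to plain
  logistic regression, which is itself a tested oracle case.

# Problem sizes used by the tests and acceptance script

Recovery checks run the full 33-participant, two-session design (10,296
trials) at the desk-scale MCMC profile. The DIC model-selection property
uses ten replicates of a 6-participant, one-block design with short chains —
the valence contrast in drift is so large that ranking is insensitive to
chain length. Logistic-model recovery uses ten seeds of the full 5,148-trial
negative-word design. Oracle tests use $10^5$-draw Monte Carlo samples.

# Known limitations

* Drift heterogeneity across participants is present in the generator but
  not in the estimation model (drift is group-level by design); at the
  default between-participant SDs this mismatch leaves group drift-cell
  recovery within tolerance, but larger heterogeneity would bias cell
  means toward the sample average of participant drifts.
* The sampler is random-walk based; posteriors with strong correlations
  between group drift cells and the starting point would mix better under
  gradient-based samplers, which are out of scope.
* No WAIC/LOO; DIC only, as the comparison statistic for this analysis.
* The overlap rule is a decision threshold, not a calibrated error rate; its
  behaviour under the null is exercised in tests but no frequentist
  guarantee is implied.
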