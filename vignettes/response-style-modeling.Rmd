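---
title: "Modeling strategy shifts in test-taking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling strategy shifts in test-taking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respshift)
```

# The measurement problem

Two examinees with the same number-correct score need not have produced that
score by the same process. Some solve every item with the intended strategy;
others switch strategy midway, fatigue, or fall into rapid guessing for the
tail of the test. When that happens, a single ability estimate per person
mixes construct-driven and construct-irrelevant behavior, and the score's
correlation with external criteria (its validity coefficient) is attenuated.

`respshift` implements two complementary ways of detecting and correcting
for this:

* **between-person** strategy differences, with a mixture Rasch model whose
  latent classes have their own item-difficulty profiles;
* **within-person** strategy shifts, with a joint model of item accuracy and
  response time in which each response belongs to one of two latent states —
  *construct-driven* or *erratic* — and the state sequence follows either a
  lag-1 Markov chain or a single per-person change point. Erratic responses
  are then trimmed and examinees rescored, and the gain in criterion
  validity is quantified.

# Models

## Mixture Rasch model (between-person)

The Rasch model gives the probability of a correct response as
$p(X_{ij}=1 \mid \theta_j, \beta_i) = \mathrm{logistic}(\theta_j - \beta_i)$.
The mixture extension assigns each person to one of $G$ latent classes, each
with its own difficulty vector $\beta_{ig}$ (mean zero within class) and
weight $\pi_g$.

Within a class the responses enter through the *conditional* likelihood
given raw scores (`fit_rasch_cml()`), which eliminates the person parameters
via the elementary symmetric functions of the item easiness values and makes
item estimation independent of the ability distribution (specific
objectivity). Each class additionally carries a raw-score distribution
smoothed by a two-parameter log-linear model (a location and a dispersion
parameter on the score scale). The free-parameter count is therefore
$G(I-1) + (G-1) + 2G$: 31 parameters for one class of a 30-item test and 32
more per added class. A free multinomial score distribution would add ~30
parameters per class instead; the two-moment smoothing keeps the score
model honest while preserving the parameter-count structure that model
comparison tables rely on.

EM details that matter:

* **Initialization.** `n_starts` random soft partitions drawn from a
  symmetric Dirichlet; the best solution by log-likelihood is kept. Mixture
  likelihoods are multimodal; 5–20 starts are typical.
* **M-step.** Weighted CML per class by BFGS on an anchored
  parameterization (last item fixed at 0 during optimization, solution
  centered afterwards). Beyond $|\beta| = 25$ the objective switches to a
  clamped value plus a quadratic penalty so that a nearly separated weighted
  subsample cannot push `exp(-beta)` out of floating-point range.
* **Degeneracy.** A start whose class weight collapses below $10^{-5}$ is
  discarded and does not count as a solution.
* **Abilities.** Warm's weighted (bias-corrected) likelihood estimate
  within the assigned class; it is finite at extreme raw scores, so no
  score adjustment is needed (a plain ML variant with the conventional
  0.3-score-point adjustment is available via `ability_method = "ml"`).
* **Person fit.** The standardized log-likelihood index ($l_z$): the
  person's response log-likelihood Z-scored against its model-implied mean
  and variance.
* **Likelihood variants.** The conditional-likelihood mixture is the
  default; `likelihood = "mml"` switches to marginal maximum likelihood
  with a class-specific normal ability distribution (mean and SD estimated,
  Gauss-Hermite integration), which has the same per-class parameter count.
* **Model comparison.** `likelihood_ratio_test()` referred to chi-square.
  The regularity conditions fail on a mixture boundary, so the p-value
  carries an explicit `approximate` flag; AIC is reported alongside.

`profile_classes()` reproduces the descriptive layer: per-class trait,
log-RT and criterion summaries, within-class correlations, and item-level
regressions of class difficulty and item mean log RT on cognitive-complexity
covariates (memory load, unique elements), with serial position added and an
R-change F test.

## Lognormal response-time model

Log response times are modelled as
$\ln RT_{ij} \sim N(\tau_j - \gamma_i,\ \sigma^2)$ with person speed
$\tau_j$ and item time intensity $\gamma_i$. The model is identified by
$\mathrm{mean}(\gamma) = 0$, which makes $\tau_j$ the person's expected log
response time — under this sign convention *higher $\tau$ means slower
responding*, and the printed mean log RT of a group of examinees is directly
comparable to $\tau$. (The classical formulation writes the mean as item
intensity minus person speed; the convention used here follows the equation
as we state it, and only the interpretation of $\tau$'s sign differs.)

Estimation is least squares / Gaussian ML on the observed cells by
alternating projections; missing cells are simply excluded. The residuals
$e_{ij} = \ln RT_{ij} - (\tau_j - \gamma_i)$ are the central diagnostic:
large magnitudes in *either* direction — uncharacteristically fast or
uncharacteristically slow — flag responses produced by a different process
than the person's usual one (rapid guessing, lapses, warm-up search).

## Joint two-state model

Accuracy and response time are modelled jointly with a latent state
$\xi_{ji} \in \{1, 2\}$ per response:

* accuracy: $X_{ji} \sim \mathrm{Bernoulli}(\mathrm{logistic}(\theta_{js} -
  \beta_{is}))$, with state-specific abilities;
* response time: $\ln RT_{ji} \sim N(\tau_j - \gamma_i,\ \sigma^2_s)$, the
  states being defined by the size of the residual variance
  ($\sigma^2_1 < \sigma^2_2$); a speed-shift variant
  ($\tau_{js}$ state-specific, single $\sigma^2$) is available to check
  whether a simple pace change could explain the data instead.

State dynamics are either a time-homogeneous lag-1 Markov chain (initial
probabilities and a 2×2 transition matrix, both with Dirichlet(1,1) priors)
or a per-person change point $k_j$: construct-driven through item $k_j$,
erratic afterwards, $k_j = I$ meaning no transition.

Estimation is Gibbs sampling (`gibbs_fit_markov()`,
`gibbs_fit_changepoint()`), implemented in compiled code: forward filtering
/ backward sampling for Markov state sequences, enumeration of the discrete
full conditional for change points, slice sampling for the logistic-scale
parameters (no tuning required), and conjugate updates for speeds,
intensities, residual precisions and transition probabilities. Two chains
with 10,000 burn-in and 10,000 kept draws mirror the long-run protocol;
1,000/1,000 is adequate for simulation work and is what the test suite
uses. Split-chain potential scale reduction, effective sample size, and
lag-1 autocorrelation are computed per parameter
(`convergence_diagnostics()`); a fit with any $\hat R > 1.1$ is returned
with `converged = FALSE` rather than an error.

### Identification: what the data cannot decide by themselves

A two-state model in which the second state has free per-person abilities,
free item difficulties, and a residual variance that may sit anywhere above
the first state's is weakly identified in ways that matter at realistic
sample sizes. We found three distinct degeneracies in simulation, and the
package's defaults close each of them:

1. **Boundary mimicry.** A state with $\sigma^2_2$ just above $\sigma^2_1$
   fits ordinary responses essentially as well as the construct state, so
   the assignment entropy of thousands of cells can outweigh a per-cell
   likelihood cost near zero: on data with *no* erratic state, 20–50% of
   cells drift into a barely separated second state. The package therefore
   enforces a minimum separation $\sigma^2_2 \ge \rho_0 \sigma^2_1$
   (`min_variance_ratio`, default 4) on every draw, via order-constrained
   precision draws; an *empty* erratic state is re-born from its prior only
   at $\ge 25 \sigma^2_1$. The motivating application has a ~9× separation,
   so the floor is far from any realistic posterior; data whose states
   genuinely differ by less are reported as indistinct
   (`characterize_states()`).
2. **Accuracy memorization.** Free per-person erratic abilities can absorb
   chance runs of incorrect answers, and with a flat change-point prior a
   transition costs nothing, so high-residual construct cells leak into the
   erratic state and dilute $\sigma^2_2$. Two defaults address this:
   erratic abilities are hierarchically centered,
   $\theta_{j2} \sim N(\mu_2, 0.25)$ with the common erratic level $\mu_2$
   estimated (erratic responding — guessing, lapses — is modelled as a
   person-invariant success level); and under the change-point structures
   the item difficulties are shared between states by default
   (`share_beta`), since the switching penalty that protects the Markov
   structure (its learned, small transition probability) has no analogue
   under a flat prior on $k$.
3. **The flat change-point prior.** For the same reason, the default prior
   on $k_j$ is spike-and-slab: no transition with estimated population
   probability $\omega \sim \mathrm{Beta}(1,1)$, otherwise uniform over
   positions. This is the exact hierarchical analogue of the Markov model
   learning its small switch rate, and it is consistent with the
   substantive finding that most examinees never transition. A strictly
   flat prior is available (`k_prior = "uniform"`) and reproduces the
   dilution described above.

Two sampler-robustness devices are also defaults: a warm-up phase (first
half of burn-in, capped at 500 sweeps) during which all responses are held
construct-driven so $\theta, \beta, \tau, \gamma, \sigma^2_1$ are well fit
before state sampling is released; and, under the change-point structures,
a partially collapsed update of $k_j$ (the erratic precision integrated out
against its truncated prior, then redrawn immediately) seeded by a
per-person variance change-point scan. Priors are
$N(0, 4)$ for abilities and difficulties (weakly informative on the logit
scale; a variance of 100 produces prior draws of ±10 logits, which is not
weak for a probability model), $N(0, 100)$ for $\tau$ and $\gamma$ (log-
seconds scale), and Gamma(0.001, 0.001) for the residual precisions. All
are `joint_config()` options.

Identification of location is by recentring each sweep:
$\mathrm{mean}(\beta_{\cdot s}) = 0$ with the compensating shift applied to
$\theta_{\cdot s}$, and $\mathrm{mean}(\gamma) = 0$ with the shift applied
to $\tau$ — both transformations leave the likelihood invariant.

### Interpreting the states

A large residual variance means *unexpected* response times, not
necessarily disengagement. `characterize_states()` reports, per state, the
EAP residual variance and the empirical proportion correct over the cells
classified into it, and flags the high-variance state as disengaged only
when its accuracy is also lower. If the high-variance state has the
*higher* accuracy — e.g., an examinee engaged only for the first few, slow
items and guessing at a typical pace thereafter — the function attaches an
alternative-interpretation note instead. The
`early_engagement_inversion` simulation scenario generates exactly this
counter-example (for a fraction of examinees; if every examinee showed the
pattern on the same items, the item time-intensities would absorb the shift
and no residual signal would remain).

## Trimming, rescoring, and validity

State classifications (or residual thresholds) become trim masks
(`mask_from_states()`, `mask_from_residual_threshold()`); trimmed responses
are treated as not observed. Rescoring is EAP under a standard normal prior
by 61-node Gauss–Hermite quadrature with the item parameters fixed
(`eap_abilities()`), which is deterministic and finite for every response
pattern. Persons left with fewer than 3 retained responses are excluded
from validity correlations and counted.

The validity pipeline (`validity_table()`) reports, per trim rule, the raw
criterion correlation, the post-trim empirical reliability
$\mathrm{var}(\widehat\theta) / (\mathrm{var}(\widehat\theta) +
\overline{\mathrm{PSD}^2})$, the disattenuated correlation
$r / \sqrt{\rho}$, and the variance explained. Trimming shortens the test,
so the raw correlation moves for two reasons — less construct-irrelevant
contamination (up) and less reliability (down); disattenuation puts the
trims on a common footing. The disattenuation and the bootstrap below are
*reconstructed* procedures (the original appendix describing them is not
available): the correction is single-sided (test side only), and the
bootstrap null re-trims at random with each person's trim count held fixed,
`p` being the fraction of null gains at least as large as the observed
gain. Both are deliberately simple and are isolated behind their own
functions so they can be swapped.

Residual-threshold trims are standardized by the construct-driven state's
residual SD when a two-state fit is available (thresholds should reference
engaged behavior), else by the homoscedastic SD.

# The synthetic-data generator

`simulate_joint()` / `simulate_mixture_rasch()` generate data whose truth is
known, under conditions emulating a 301-examinee, 30-item, 8-option
matrix-reasoning test:

* abilities $N(0,1)$; difficulties built from generated cognitive
  covariates (memory load, unique elements) plus noise, so class/item
  profiling has signal to find;
* speeds $N(3.2, 0.45^2)$ (about 25 s per item), intensities linked weakly
  to memory load;
* construct-driven residual variance 0.187; erratic variance 1.647 (~9×);
* erratic accuracy fixed at 0.25 by default (0.26 in the `paper_like_*`
  presets, matching the post-transition proportion correct the method is
  meant to detect; pure 8-option guessing would be 0.125);
* change points drawn uniformly from the last third of the test
  (`k_range = 21:30`, `k = 30` meaning no transition); the Markov preset
  uses initial distribution (.948, .052) and a slow-mixing transition
  matrix, $P \approx [[.9907, .0093], [.0216, .9784]]$, reconstructed to
  have stationary distribution (.70, .30) and ~20% erratic occupancy by
  item 30 — the published summaries constrain the matrix only up to this
  reconstruction;
* a person-level criterion on an AFQT-like scale (mean 215, SD 16) with
  correlation 0.63 with true ability — the disattenuated post-trim validity
  the analysis is designed to recover.

Generation is bit-exact given (config, seed); configs round-trip through
YAML. What the generator does *not* emulate: option-level distractor
behavior, multidimensional abilities, speed–accuracy tradeoff within the
construct state, or item-position drift in difficulty. Passing recovery
tests on these data therefore show that the estimation machinery is
correct under the model's own assumptions, not that real test data satisfy
those assumptions.

# Numerical choices

* Elementary symmetric functions by the stable summation recursion; their
  item-deleted versions by deflation (exact for the ≤60-item range this
  package targets).
* CML convergence: successive optimizer passes must agree to $10^{-6}$ in
  every coordinate.
* EAP quadrature: 61 Gauss–Hermite nodes agree with a 10,001-point grid to
  $10^{-4}$ over random 30-item patterns (tested).
* Residual variances are clamped to $[10^{-8}, 10^{8}]$; truncated gamma
  draws fall back to the nearest interior point when the truncation region
  carries no numerical mass.
* Ties in hard class assignment break toward the first (largest-weight)
  class; classes are relabelled by decreasing weight, states by increasing
  residual variance.
* Reduced problem sizes used by the test suite: 301×30 with 1,000 burn-in +
  1,000 kept draws for the recovery checks (2 chains), 400 + 400 (1 chain)
  for the 20-replicate validity study, and 300-person mixtures with 5 EM
  starts. These are the package's desk-scale defaults for simulation work;
  empirical analyses should use the long-run protocol.

# Known limitations

* Exactly two response states; no higher-order Markov lags; transition
  probabilities are time-homogeneous. A per-position transition model would
  need a different identification argument.
* The change-point structure allows one transition, construct → erratic.
* Under the variance-separation floor, genuinely mild heteroscedasticity
  (ratio < 4) is reported as a single state rather than estimated.
* The mixture module is dichotomous-only, and the conditional-likelihood
  mixture cannot separate classes that differ only in their score
  distributions.
* Bit-for-bit replication of other software's mixture output is a
  non-goal; parameter-count conventions follow the two-moment score model
  described above.
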