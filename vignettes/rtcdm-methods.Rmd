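---
title: "Joint cognitive diagnosis with response times and rapid guessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint cognitive diagnosis with response times and rapid guessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcdm)
```

## The problem

Cognitive diagnostic models (CDMs) classify test-takers on a set of
fine-grained binary skills ("attributes") from their item responses, via
a $J \times K$ Q-matrix that records which attributes each item
requires.  On computer-based tests a fraction of responses are *rapid
guesses*: answers given too quickly for any real solution attempt.
Rapid guesses carry no information about the attributes, and they
distort both the item parameters (a rapid guess by a skilled test-taker
looks like a "slip") and the response-time parameters (rapid guesses
are much faster than solution attempts).  `rtcdm` implements a family
of joint models for responses and response times in which a latent
per-person-per-item indicator $\xi_{ij}$ separates the two behaviours,
so that rapid guesses are identified from the data rather than screened
out by ad-hoc time thresholds.

## The model

**Response times.** Under a solution attempt ($\xi_{ij} = 1$) the
log response time is normal,
$\log RT_{ij} \sim N(\beta_j - \tau_i,\; 1/\kappa_j^2)$, with item time
intensity $\beta_j$ (mean log-seconds for the population), person speed
$\tau_i$, and time discrimination $\kappa_j$ (the log-RT standard
deviation is $1/\kappa_j$).  Under a rapid guess ($\xi_{ij} = 0$) the
log response time is $N(\beta_0,\; 1/\kappa_0^2)$, common to all
persons and items: rapid-guess time does not depend on who is guessing
or on the item's difficulty.

**Responses.** The base response process is a CDM on the attribute
profile $\alpha_i \in \{0,1\}^K$.  The package evaluates the saturated
G-DINA form (intercept, main effects, and interactions over each item's
required attributes, identity link) and its two classical special
cases, which are the estimable forms:

* DINA (non-compensatory): success probability $1 - s_j$ when *all*
  required attributes are mastered, $g_j$ otherwise;
* DINO (compensatory): success probability $1 - s'_j$ when *at least
  one* required attribute is mastered, $g'_j$ otherwise.

Under a rapid guess the mastery terms drop out and the success
probability is the baseline $\delta^*_j$, tied by default to the
guessing parameter ($\delta^*_j = \delta_{j0}$): guessing rapidly
succeeds at the same rate as guessing without the required skills.  A
`delta_star` hook exists on the forward model for an untied baseline,
but it is not estimated — with a single binary response per cell there
is no obvious information to separate $\delta^*_j$ from $g_j$, so the
sampler keeps the tie.

**Behaviour.** $\xi_{ij} \sim \mathrm{Bernoulli}(\pi_j)$, where
$\pi_j$ is the item's solution-attempt probability; $1 - \pi_j$ is its
rapid-guessing rate.  Setting $\xi \equiv 1$ recovers the plain joint
models (RT-DINA, RT-DINO); the mixtures are RT-DINA-RG and RT-DINO-RG.

## Estimation

`fit_rtcdm()` runs a Metropolis-within-Gibbs sampler (Rcpp core).  The
update cycle per iteration:

1. **Attribute profiles**: each person's profile is drawn *exactly*
   from its full conditional over all $2^K$ latent classes (classes in
   binary-counting order, attribute 1 the least-significant bit), under
   a saturated Dirichlet prior on the class probabilities.  The
   saturated class prior absorbs whatever dependence structure the
   attributes have without imposing a higher-order trait.  Response
   times never enter this step: given $\xi$, RT carries no attribute
   information.  Exact enumeration is refused for $K > 10$.
2. **Behaviour indicators**: per-cell Bernoulli draws with posterior
   odds combining the prior odds $\pi_j : 1-\pi_j$, the response
   likelihood ratio and the response-time density ratio (the
   observed-scale $1/rt$ terms cancel).
3. **Guessing/slipping**: conjugate Beta draws from the cell counts,
   with the draw of $(g_j, 1-s_j)$ truncated to the monotone region
   $g_j < 1-s_j$ (a positive item discrimination index is required for
   identifiability, and the generating designs respect it).
4. **Speeds, intensities, precisions**: normal–normal draws for each
   $\tau_i$ (over that person's solution cells) and $\beta_j$;
   Gamma draws for $\kappa_j^2$ from squared residuals; the same for
   $\beta_0, \kappa_0^2$ over rapid-guess cells.  An item or person
   with no solution cells in a sweep falls back to its prior draw.
5. **Solution-attempt probabilities**: conjugate Beta from the $\xi$
   counts.
6. **Speed scale** $\sigma_\tau$: random-walk Metropolis on
   $\log \sigma_\tau$ (proposal sd 0.1) under a half-normal(1) prior —
   the one non-conjugate block.

**Priors** (defaults, all overridable via `rtcdm_priors()` or the YAML
config): $g_j, \pi_j \sim \mathrm{Beta}(1,1)$;
$1-s_j \sim \mathrm{Beta}(1,1)$ truncated to $1-s_j > g_j$;
$\beta_j, \beta_0 \sim N(3, 10^2)$;
$\kappa_j^2, \kappa_0^2 \sim \mathrm{Gamma}(0.01, 0.01)$;
class probabilities $\sim$ Dirichlet(1); $\sigma_\tau$ half-normal(1).
These are weakly informative and conjugate where possible.

**Identification.** The speed location is fixed by the
$\tau_i \sim N(0, \sigma_\tau^2)$ hierarchy (no post-hoc centering).
Label switching between the "fast guessing" and "slow solution" states
is prevented by initializing $\beta_0$ at the 10th percentile of pooled
log RT and, by default, constraining $\beta_0 \le \min_j \beta_j$
(`chain_config(constrain_beta0 = )`); rapid guesses are faster than
solution attempts by construction of the state.

**Initialization.** Attribute profiles from a per-attribute
correct-rate split, $\xi = 1$ everywhere, item parameters at neutral
values; chains beyond the first jitter their starting points.

**Defaults.** `chain_config()` is 2 chains of 6,000 iterations with
3,000 burn-in.  Split-$\hat R$ is reported per item parameter and the
$\sigma_\tau$ Metropolis acceptance rate is logged.

## Model comparison

`dic()` reports $DIC = \bar D + p_D$ with
$p_D = \bar D - D(\hat\theta)$.  Both the per-draw deviance and the
plug-in marginalize the discrete latents — $\alpha_i$ over the $2^K$
classes and $\xi_{ij}$ over $\mathrm{Bernoulli}(\pi_j)$ — so that
$\bar D$ and $D(\hat\theta)$ are computed on the same measure; plug-in
deviances at discrete modes are unstable for mixtures.  All deviances
use the *observed-scale* response-time density (lognormal, including
the $1/rt$ Jacobian).  The scale convention shifts all DICs by the same
data-dependent constant, so orderings — the quantity of interest — are
unaffected.

## The synthetic-data generator

`simulate_dataset()` draws a complete dataset with its truth block; the
canonical designs are `study1_design()` (DINA) and `study2_design()`
(DINO).  The generating conditions:

| quantity | law | default |
|---|---|---|
| guessing $g_j$ | $U(0.05, 0.3)$ | IDI support $(0.5, 0.9)$ |
| slipping $s_j$ | $U(0.05, 0.2)$ | |
| time intensity $\beta_j$ | $U(2, 4)$ | log-seconds |
| time discrimination $\kappa_j$ | $U(0.15, 2)$ | |
| RG state | fixed | $\beta_0 = 2$, $\kappa_0 = 1.6$ |
| speed $\tau_i$ | $N(0, 0.3^2)$ | |
| attributes | equicorrelated MVN, mean 0.5, $\rho = 0.5$, cutoff $0.253$ | $\approx 60\%$ mastery |
| persons | | $I = 1000$ |

The 30-item, 5-attribute Q-matrix (`sim_qmatrix()`) has ten single-,
ten two- and ten three-attribute items in a balanced rotation.  In the
rapid-guessing condition the solution-attempt probabilities follow the
design table's blocked pattern — $\pi_j = 0.9$ for items 1–5, 11–15,
21–25 and $0.8$ for the rest — i.e. RG rates of 0.1 and 0.2 coexist
across items within the test.  `rg_level = "0.2"` shifts the pattern
down by 0.1; a homogeneous-$\pi$ switch is available because the
blocked and homogeneous readings of a "two-level" RG manipulation are
both defensible.  Item parameters are redrawn independently each
replication.

What the generator does **not** emulate about real data: item-position
effects and speededness (rapid guessing concentrated late in a timed
test), within-person dependence of $\xi$ across items beyond the
item-level rates, missing responses (rejected, not imputed), and any
correlation between person speed and attribute mastery.  Passing
recovery tests therefore show that the estimator inverts its own
generative model at realistic sizes — not that real tests satisfy these
assumptions.

## Recovery metrics

`run_recovery()` aggregates, per model: item-parameter bias
$\sum_r (\hat\nu_r - \nu)/r$ and RMSE
$\sqrt{\sum_r (\hat\nu_r - \nu)^2/r}$ (per item, then averaged per
family; per-item tables are also emitted), attribute classification
accuracy (posterior mastery probability thresholded at 0.5, ties to
mastery; cell-wise agreement averaged over persons and attributes,
with whole-pattern accuracy as a secondary column), and speed
reliability $\mathrm{cor}(\hat\tau, \tau)^2$ using posterior-mean
$\hat\tau$.  `cohens_kappa()` gives chance-corrected agreement between
two binary classifications, for comparing the mastery calls of two
fitted models.

## Numerical choices

* Truncated Beta and normal draws use inverse-CDF sampling, with
  midpoint fallbacks when the truncation region's probability mass
  underflows.
* Class-conditional response log-likelihoods are computed once per item
  as mastery/non-mastery contrasts, so the $2^K$-class scan costs
  $O(\sum_c |\text{mastered}_c|)$ per person rather than
  $O(2^K J)$.
* Probabilities are clamped away from 0/1 by $10^{-12}$ where logs are
  taken of sampled values.
* G-DINA delta vectors are validated eagerly at construction: every
  reduced profile's success probability must lie in $[0,1]$.

## Scale of the shipped recovery studies

The package's recovery harness and acceptance script run each condition
at the full design size ($I = 1000$, 30 items) with 10 replications and
2 chains $\times$ 1,500 iterations (500 burn-in).  These lengths are a
deliberate compute choice for a routinely re-runnable check: the
blocked conjugate sampler with exact class draws reaches its stationary
distribution within a few hundred iterations on these designs.  At the
harness lengths the slowest-mixing parameters (the $\pi_j$–$s_j$ pairs
of weakly discriminating items, which trade off against each other)
show split-$\hat R$ up to $\approx 1.15$, while condition-level
accuracy and reliability means agree to about three decimals with runs
four times longer; at the package default of 2 × 6,000 iterations
every item parameter reaches split-$\hat R < 1.05$.  Monte-Carlo error on the
reported condition means at 10 replications is about 0.002 for
accuracy and 0.01–0.02 for reliability.

## Known limitations

* Only DINA and DINO variants are estimated; the saturated G-DINA-RG
  is available as a forward model (`p_correct_gdina()`,
  `delta_dina()`/`delta_dino()` embeddings) but has no sampler.
* Q-matrix identifiability is not checked algorithmically; users should
  verify completeness/identifiability externally before trusting
  attribute classifications.
* The rapid-guess success rate is tied to the guessing parameter; free
  $\delta^*_j$ is not estimated.
* A single global RG time state $(\beta_0, \kappa_0)$ is assumed;
  per-item RG time parameters are not considered.
* Exact class enumeration limits $K \le 10$ in estimation.
* Alternative RT laws (gamma, linear-transformation) and links other
  than identity are out of scope.

## A worked example

```{r example, eval = FALSE}
design <- study1_design("0.1")          # DINA, blocked RG rates 0.1/0.2
dat <- simulate_dataset(design, seed = 42)
fit <- fit_rtcdm(dat, rg = TRUE, seed = 7)
summary(fit)[1:5, ]
classification_accuracy(classify_attributes(fit$alpha_prob),
                        dat$truth$alpha)
reliability(fit$tau_mean, dat$truth$tau)
dic(fit)
```
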