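# rtcdm

Cognitive diagnostic modelling of item responses **and** response
times, with a latent per-person-per-item indicator that separates
effortful solution attempts from rapid guesses.

## Why

Cognitive diagnostic models (CDMs) classify test-takers on K binary
skills ("attributes") through a J×K Q-matrix. On computer-based tests,
some responses are *rapid guesses* — too fast to be real solution
attempts. Treating them as ordinary responses inflates slipping
parameters, deflates time-intensity and guessing estimates, and
degrades both attribute classification and person-speed measurement.
`rtcdm` estimates the joint mixture model in which each cell (person i,
item j) carries a latent behaviour indicator ξᵢⱼ:

* **Response time**: log RTᵢⱼ ~ N(βⱼ − τᵢ, 1/κⱼ²) under a solution
  attempt (ξᵢⱼ = 1), and log RTᵢⱼ ~ N(β₀, 1/κ₀²) under a rapid guess
  (ξᵢⱼ = 0).
* **Response**: a DINA model (success probability 1−sⱼ iff *all*
  required attributes are mastered, else gⱼ) or DINO model (1−s′ⱼ iff
  *at least one* is mastered, else g′ⱼ) under a solution attempt; the
  bare guessing rate under a rapid guess. The saturated G-DINA form
  (identity link) is provided as a forward model.
* **Behaviour**: ξᵢⱼ ~ Bernoulli(πⱼ), with πⱼ the item's
  solution-attempt probability.

The four estimable models are RT-DINA, RT-DINO and their mixture
extensions RT-DINA-RG and RT-DINO-RG, fitted by a Metropolis-within-
Gibbs sampler (Rcpp) with exact attribute-class draws over all 2^K
latent classes. DIC compares the fitted models; recovery metrics
(bias, RMSE, classification accuracy, speed reliability
cor(τ̂, τ)², Cohen's κ) evaluate them. See
`vignettes/rtcdm-methods.Rmd` for the model, priors, identification
strategy and limitations.

Intended users: psychometricians and measurement researchers working
with low-stakes computer-based assessments where rapid guessing is a
plausible concern.

## A worked example

Simulate the standard 30-item, 5-attribute DINA recovery design with
blocked rapid-guessing rates of 0.1/0.2 across items, fit the
RT-DINA-RG model, and evaluate against the simulation truth:

```r
library(rtcdm)

design <- study1_design("0.1")     # I = 1000; pi_j in {0.9, 0.8}
dat    <- simulate_dataset(design, seed = 42)
fit    <- fit_rtcdm(dat, rg = TRUE, seed = 7,
                    chain = chain_config(n_chains = 2, n_iter = 1500,
                                         n_burnin = 500))
fit
#> rtcdm_fit: RT-DINA-RG, 1000 persons x 30 items, K = 5
#>   2 chains x 1500 iterations (500 burn-in), 2000 kept draws
#>   max split-Rhat (item params): 1.149
#>   DIC: 285955.8

classification_accuracy(classify_attributes(fit$alpha_prob),
                        dat$truth$alpha)
#> [1] 0.935
reliability(fit$tau_mean, dat$truth$tau)
#> [1] 0.7680113
mean(coef(fit)$s - dat$truth$s)      # slipping bias, correctly specified
#> [1] 0.005283794

# the same data ignoring rapid guessing: slipping inflates
base <- fit_rtcdm(dat, rg = FALSE, seed = 7,
                  chain = chain_config(n_chains = 2, n_iter = 1500,
                                       n_burnin = 500))
mean(coef(base)$s - dat$truth$s)
#> [1] 0.1043852
dic(base)$dic - dic(fit)$dic         # DIC prefers the RG model
#> [1] 2016.123
```

93.5% of the 5,000 person-attribute cells are classified correctly by
the RG model; the misspecified RT-DINA overestimates slipping by ~0.10
on average and is decisively rejected by DIC.  (The short chains used
here leave split-Rhat ≈ 1.15 on the slowest-mixing π/s pair; the
package default `chain_config()` of 2 × 6000 iterations brings every
item parameter below 1.04 with the same posterior means.)
`run_recovery()` wraps this loop over replications and both models and
aggregates bias/RMSE per parameter family.

## Command line

A thin wrapper over the same functions
(`system.file("cli", "rtcdm.R", package = "rtcdm")`):

```sh
Rscript rtcdm.R simulate --design study1 --rg 0.1 --reps 2 --seed 7 --out sims
Rscript rtcdm.R fit --model dina --rg --responses sims/rep001/Y.csv \
    --rt sims/rep001/RT.csv --q sims/rep001/Q.csv --seed 2 --out fit1
Rscript rtcdm.R evaluate --alpha-posterior fit1/alpha_posterior.csv \
    --tau-posterior fit1/tau_posterior.csv \
    --truth-persons sims/rep001/truth_persons.csv --out eval1
Rscript rtcdm.R recover --design study1 --rg 0.1 --models rg,base \
    --reps 10 --seed 1 --out rec1
```

Q-matrices travel as headerless 0/1 CSV/TSV; responses and response
times as CSV with one header row of item labels (times in seconds).
Priors and chain settings come from a YAML config (`--config`).

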