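#' Full conditional distributions of the discrete latents
#'
#' Exact single-sweep conditionals used by the Gibbs sampler, exposed
#' for inspection and verification.  `alpha_full_conditional()` returns
#' the posterior probability mass over all \eqn{2^K} attribute classes
#' for one person given that person's responses, behaviour indicators
#' and the item parameters (response times carry no information about
#' the attribute profile, so they do not enter).
#' `xi_full_conditional()` returns the posterior probability of a
#' solution attempt (\eqn{\xi = 1}) for one person-item cell, combining
#' the prior odds \eqn{\pi_j : 1 - \pi_j} with the response and
#' observed-scale response-time likelihood ratios.
#'
#' @param y binary response vector (length J) for the person.
#' @param xi binary behaviour indicator vector (length J).
#' @param g,s guessing and slipping vectors (length J).
#' @param qmatrix a [validate_qmatrix()] object.
#' @param model `"DINA"` or `"DINO"`.
#' @param class_prior probability vector over the \eqn{2^K} classes in
#'   [latent_classes()] order.
#' @return `alpha_full_conditional`: numeric vector of length
#'   \eqn{2^K} summing to one.
#' @export
alpha_full_conditional <- function(y, xi, g, s, qmatrix,
                                   model = c("DINA", "DINO"),
                                   class_prior = NULL) {
  model <- match.arg(model)
  Q <- validate_qmatrix(qmatrix)
  K <- ncol(Q)
  M <- mastery_matrix(Q, model)
  if (is.null(class_prior)) class_prior <- rep(1 / 2^K, 2^K)
  stopifnot(length(y) == nrow(Q), length(xi) == nrow(Q),
            length(class_prior) == 2^K)
  ll <- log(class_prior)
  for (c in seq_len(2^K)) {
    p <- ifelse(xi == 1,
                ifelse(M[c, ] == 1, 1 - s, g),
                g)
    ll[c] <- ll[c] + sum(stats::dbinom(y, 1, p, log = TRUE))
  }
  w <- exp(ll - max(ll))
  w / sum(w)
}

#' @rdname alpha_full_conditional
#' @param y_cell,rt binary response and response time (seconds) of the
#'   cell.
#' @param p1,p0 success probabilities under solution attempt and rapid
#'   guess (scalars; `p0` defaults to the guessing parameter tied to
#'   the rapid-guess success rate).
#' @param pi_j solution-attempt probability of the item.
#' @param tau,beta,kappa person speed and the item's time
#'   intensity/discrimination.
#' @param beta0,kappa0 rapid-guessing state time parameters.
#' @return `xi_full_conditional`: scalar probability of \eqn{\xi = 1}.
#' @export
xi_full_conditional <- function(y_cell, rt, pi_j, p1, p0, tau, beta, kappa,
                                beta0, kappa0) {
  stopifnot(rt > 0, pi_j >= 0, pi_j <= 1)
  if (pi_j == 1) return(1)
  if (pi_j == 0) return(0)
  l1 <- log(pi_j) + stats::dbinom(y_cell, 1, p1, log = TRUE) +
    logdensity_rt(rt, tau, beta, kappa, xi = 1)
  l0 <- log(1 - pi_j) + stats::dbinom(y_cell, 1, p0, log = TRUE) +
    logdensity_rt(rt, tau, beta, kappa, xi = 0,
                  beta0 = beta0, kappa0 = kappa0)
  1 / (1 + exp(l0 - l1))
}

#' Conjugate conditional updates (closed forms)
#'
#' Closed-form posterior parameters for the conjugate blocks of the
#' sampler, exposed for verification.  `beta_binomial_posterior()`
#' returns the Beta posterior after `successes`/`failures` Bernoulli
#' observations; `normal_normal_posterior()` the posterior mean and
#' standard deviation of a normal mean with known per-observation
#' precisions and a normal prior.
#'
#' @param a,b Beta prior shapes.
#' @param successes,failures Bernoulli counts.
#' @return `beta_binomial_posterior`: list `(a, b, mean)`.
#' @export
beta_binomial_posterior <- function(a, b, successes, failures) {
  a2 <- a + successes
  b2 <- b + failures
  list(a = a2, b = b2, mean = a2 / (a2 + b2))
}

#' @rdname beta_binomial_posterior
#' @param prior_mean,prior_sd normal prior on the mean.
#' @param obs observations.
#' @param obs_prec per-observation precisions (scalar or vector).
#' @return `normal_normal_posterior`: list `(mean, sd)`.
#' @export
normal_normal_posterior <- function(prior_mean, prior_sd, obs, obs_prec) {
  obs_prec <- rep_len(obs_prec, length(obs))
  prec <- 1 / prior_sd^2 + sum(obs_prec)
  m <- (prior_mean / prior_sd^2 + sum(obs_prec * obs)) / prec
  list(mean = m, sd = sqrt(1 / prec))
}
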