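# exact full-conditional checks against brute-force enumeration

test_that("attribute conditional matches two-term Bayes on one item", {
  # single DINA item, uniform prior over {(0), (1)}, Y = 1, xi = 1:
  # P(alpha = 1 | Y) = 0.9 / (0.9 + 0.2)
  Q <- validate_qmatrix(matrix(1, 1, 1))
  pmf <- alpha_full_conditional(y = 1, xi = 1, g = 0.2, s = 0.1,
                                qmatrix = Q, model = "DINA")
  expect_equal(pmf[2], 0.9 / 1.1, tolerance = 1e-10)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
})

test_that("attribute conditional reduces to the prior when all xi = 0", {
  Q <- tiny_qmatrix()
  prior <- runif(8); prior <- prior / sum(prior)
  pmf <- alpha_full_conditional(y = rep(1, 6), xi = rep(0, 6),
                                g = rep(0.2, 6), s = rep(0.1, 6),
                                qmatrix = Q, class_prior = prior)
  expect_equal(pmf, prior, tolerance = 1e-12)
})

test_that("attribute conditional equals brute-force enumeration (K = 2)", {
  Q <- validate_qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  g <- c(0.2, 0.25, 0.15); s <- c(0.1, 0.12, 0.08)
  y <- c(1, 0, 1); xi <- c(1, 1, 0)
  prior <- c(0.1, 0.2, 0.3, 0.4)
  for (model in c("DINA", "DINO")) {
    # oracle: multiply likelihood terms explicitly for each of 4 classes
    cls <- latent_classes(2)
    post <- numeric(4)
    for (c in 1:4) {
      lik <- prior[c]
      for (j in 1:3) {
        p <- if (xi[j] == 0) g[j] else {
          req <- which(unclass(Q)[j, ] == 1)
          mast <- if (model == "DINA") all(cls[c, req] == 1)
                  else any(cls[c, req] == 1)
          if (mast) 1 - s[j] else g[j]
        }
        lik <- lik * (if (y[j] == 1) p else 1 - p)
      }
      post[c] <- lik
    }
    post <- post / sum(post)
    expect_equal(
      alpha_full_conditional(y, xi, g, s, Q, model, prior), post,
      tolerance = 1e-10)
  }
})

test_that("behaviour-indicator conditional matches two-term Bayes", {
  expect_equal(xi_full_conditional(1, rt = 3, pi_j = 1, p1 = 0.9, p0 = 0.2,
                                   tau = 0, beta = 1, kappa = 1,
                                   beta0 = 0, kappa0 = 1), 1)
  # identical likelihoods under both branches: posterior = prior
  expect_equal(xi_full_conditional(1, rt = exp(1), pi_j = 0.7, p1 = 0.4,
                                   p0 = 0.4, tau = 0, beta = 1, kappa = 1,
                                   beta0 = 1, kappa0 = 1), 0.7,
               tolerance = 1e-12)
  # worked cell: response ratio (0.9 : 0.2), RT density ratio 2 by placing
  # log RT at the solution mean and sqrt(2 log 2) from the RG mean
  p <- xi_full_conditional(1, rt = exp(1), pi_j = 0.9, p1 = 0.9, p0 = 0.2,
                           tau = 0, beta = 1, kappa = 1,
                           beta0 = 1 - sqrt(2 * log(2)), kappa0 = 1)
  expect_equal(p, 1.62 / 1.64, tolerance = 1e-10)
})

test_that("conjugate closed forms match hand arithmetic", {
  # Beta(1,1) prior, 30 successes / 70 failures
  post <- beta_binomial_posterior(1, 1, 30, 70)
  expect_equal(post$a, 31)
  expect_equal(post$b, 71)
  expect_equal(post$mean, 31 / 102, tolerance = 1e-12)
  # no data: posterior = prior
  expect_equal(beta_binomial_posterior(2, 5, 0, 0)$mean, 2 / 7)
  # solution-attempt probability updates: 800 of 1000 cells
  expect_equal(beta_binomial_posterior(1, 1, 800, 200)$mean, 801 / 1002,
               tolerance = 1e-10)
  expect_equal(beta_binomial_posterior(1, 1, 1000, 0)$mean, 1001 / 1002,
               tolerance = 1e-10)

  # single observation, near-flat prior: posterior mean -> the observation
  nn <- normal_normal_posterior(0, 1e6, obs = 2.7, obs_prec = 1)
  expect_equal(nn$mean, 2.7, tolerance = 1e-6)
  # 3-cell speed update: precision 1/sigma^2 + sum kappa_j^2, weighted mean
  kap2 <- c(1.2, 0.5, 2.5)^2
  obs <- c(0.4, -0.1, 0.6)  # beta_j - log RT_ij
  st <- 0.3
  prec <- 1 / st^2 + sum(kap2)
  expect_equal(normal_normal_posterior(0, st, obs, kap2)$mean,
               sum(kap2 * obs) / prec, tolerance = 1e-12)
  expect_equal(normal_normal_posterior(0, st, obs, kap2)$sd,
               sqrt(1 / prec), tolerance = 1e-12)
})

test_that("DIC arithmetic: plug-in formula on constructed deviances", {
  # degenerate posterior: all draws identical => p_D = 0
  d0 <- .dic_from_deviance(123.4, 123.4)
  expect_equal(d0$p_d, 0)
  expect_equal(d0$dic, 123.4)
  # single Bernoulli observation y = 1, all draws p = 0.5
  dev <- -2 * log(0.5)
  d1 <- .dic_from_deviance(dev, dev)
  expect_equal(d1$dic, 1.3863, tolerance = 1e-4)
})
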