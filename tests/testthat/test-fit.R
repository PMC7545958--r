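test_that("sampler returns coherent posterior structures and is seeded", {
  d <- tiny_design(pi_j = 0.85, I = 200L)
  dat <- simulate_dataset(d, seed = 19)
  fit <- fit_rtcdm(dat, rg = TRUE, chain = quick_chain(), seed = 3)
  expect_s3_class(fit, "rtcdm_fit")
  expect_equal(dim(fit$alpha_prob), c(200L, 3L))
  expect_equal(dim(fit$xi_prob), c(200L, 6L))
  expect_true(all(fit$alpha_prob >= 0 & fit$alpha_prob <= 1))
  expect_true(all(fit$xi_prob >= 0 & fit$xi_prob <= 1))
  expect_equal(ncol(fit$draws$g), 6L)
  expect_equal(nrow(fit$draws$g), 200L)  # (400 - 200) kept x 1 chain
  expect_true(all(is.finite(unlist(fit$rhat))))
  expect_true(all(fit$draws$g > 0 & fit$draws$g < 1))
  expect_true(all(fit$draws$g < 1 - fit$draws$s))  # support constraint
  expect_true(all(fit$draws$kappa > 0))
  expect_true(all(rowSums(fit$draws$lambda) - 1 < 1e-12))

  # summary table covers item and global parameters
  sm <- summary(fit)
  expect_true(all(c("g[1]", "pi[6]", "beta0", "sigma_tau") %in% sm$parameter))
  expect_true(all(sm$q2.5 <= sm$mean & sm$mean <= sm$q97.5))

  # full determinism given the seed
  fit2 <- fit_rtcdm(dat, rg = TRUE, chain = quick_chain(), seed = 3)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$alpha_prob, fit2$alpha_prob)
})

test_that("disabling the RG mixture removes pi, beta0 and kappa0", {
  d <- tiny_design(pi_j = 1, I = 150L)
  dat <- simulate_dataset(d, seed = 23)
  fit <- fit_rtcdm(dat, rg = FALSE, chain = quick_chain(), seed = 4)
  expect_null(fit$draws$pi)
  expect_null(fit$draws$beta0)
  expect_null(fit$draws$kappa0)
  expect_true(all(fit$xi_prob == 1))
})

test_that("fitting the RG model to RG-free data drives pi towards one", {
  dat <- simulate_dataset(study1_design("none"), seed = 47)
  fit <- fit_rtcdm(dat, rg = TRUE,
                   chain = chain_config(n_chains = 1, n_iter = 600,
                                        n_burnin = 300,
                                        store_deviance = FALSE),
                   seed = 5)
  expect_true(all(colMeans(fit$draws$pi) >= 0.95))
})

test_that("invalid inputs fail fast", {
  d <- tiny_design(I = 50L)
  dat <- simulate_dataset(d, seed = 1)
  bad <- dat
  bad$RT[2, 3] <- -1
  expect_error(fit_rtcdm(bad, chain = quick_chain()), "positive")
  wide <- validate_qmatrix(diag(11))
  datw <- list(Y = matrix(0L, 5, 11), RT = matrix(1, 5, 11),
               qmatrix = wide, model = "DINA")
  class(datw) <- "rtcdm_data"
  expect_error(fit_rtcdm(datw, chain = quick_chain()), "K > 10")
  expect_error(dic(fit_rtcdm(dat, chain = quick_chain(), seed = 1)),
               "store_deviance")
})

test_that("posterior means recover a well-determined tiny model", {
  # larger information per parameter: 500 persons, 6 items, light RG,
  # time discriminations kept high so speeds are well determined
  d <- sim_design(tiny_qmatrix(), n_persons = 500L, pi_j = 0.9,
                  kappa_range = c(1, 2))
  dat <- simulate_dataset(d, seed = 61)
  fit <- fit_rtcdm(dat, rg = TRUE,
                   chain = chain_config(n_chains = 2, n_iter = 2000,
                                        n_burnin = 700,
                                        store_deviance = FALSE), seed = 6)
  est <- coef(fit)
  expect_lt(mean(abs(est$beta - dat$truth$beta)), 0.1)
  expect_lt(mean(abs(est$pi - dat$truth$pi_j)), 0.07)
  expect_lt(abs(est$beta0 - dat$truth$beta0), 0.1)
  acc <- classification_accuracy(classify_attributes(fit$alpha_prob),
                                 dat$truth$alpha)
  expect_gt(acc, 0.8)
  expect_gt(cor(fit$tau_mean, dat$truth$tau), 0.55)
  # chains agree
  expect_lt(max(unlist(fit$rhat)), 1.1)
})
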