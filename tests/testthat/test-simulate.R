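test_that("attribute generator hits the designed mastery rate and correlation", {
  set.seed(100)
  a <- simulate_attributes(10000, 5, mu = 0.5, rho = 0.5, cutoff = 0.253)
  expect_true(all(abs(colMeans(a) - 0.60) < 0.02))

  # extreme cutoff: everyone masters everything
  a1 <- simulate_attributes(50, 3, cutoff = -Inf)
  expect_true(all(a1 == 1L))

  # rho = 0: attributes pairwise uncorrelated
  a0 <- simulate_attributes(10000, 4, rho = 0)
  phi <- cor(a0)
  expect_true(all(abs(phi[upper.tri(phi)]) < 0.05))
})

test_that("datasets are bit-reproducible from the seed", {
  d <- study1_design("0.1", n_persons = 100L)
  x1 <- simulate_dataset(d, seed = 77)
  x2 <- simulate_dataset(d, seed = 77)
  expect_identical(x1, x2)
  x3 <- simulate_dataset(d, seed = 78)
  expect_false(identical(x1$Y, x3$Y))
})

test_that("behaviour indicators follow Bernoulli(pi_j)", {
  d <- sim_design(tiny_qmatrix(), n_persons = 5000L, pi_j = 0.8)
  x <- simulate_dataset(d, seed = 5)
  expect_true(mean(x$truth$xi) > 0.78 && mean(x$truth$xi) < 0.82)

  d_none <- sim_design(tiny_qmatrix(), n_persons = 200L, pi_j = 1)
  x_none <- simulate_dataset(d_none, seed = 5)
  expect_true(all(x_none$truth$xi == 1L))
  expect_false(d_none$rg_enabled)
})

test_that("a noiseless DINA generator reproduces the mastery indicator", {
  d <- sim_design(tiny_qmatrix(), n_persons = 400L, model = "DINA",
                  pi_j = 0.85, g_range = c(1e-9, 2e-9),
                  s_range = c(1e-9, 2e-9))
  x <- simulate_dataset(d, seed = 31)
  Q <- unclass(x$qmatrix)
  # independent oracle: per-cell mastery from alpha and the Q-matrix
  for (i in sample.int(400, 40)) {
    for (j in seq_len(nrow(Q))) {
      if (x$truth$xi[i, j] == 1) {
        mast <- all(x$truth$alpha[i, which(Q[j, ] == 1)] == 1)
        expect_identical(x$Y[i, j] == 1L, mast)
      } else {
        expect_identical(x$Y[i, j], 0L)  # rapid guess with g ~ 0 never succeeds
      }
    }
  }
})

test_that("generated response times match their two-state moments", {
  d <- study1_design("0.2", n_persons = 10000L)
  x <- simulate_dataset(d, seed = 12)
  rg_cells <- x$truth$xi == 0
  lrt <- log(x$RT)
  n_rg <- sum(rg_cells)
  # RG cells: mean ~ beta0 = 2, sd ~ 1/kappa0 = 1/1.6, +-3 MC se
  expect_lt(abs(mean(lrt[rg_cells]) - 2), 3 * (1 / 1.6) / sqrt(n_rg))
  expect_lt(abs(sd(lrt[rg_cells]) - 1 / 1.6), 0.01)
  # solution cells of one item: mean ~ beta_j (tau averages out), allowing
  # for the tau and sampling spread
  j <- 7L
  sol <- x$truth$xi[, j] == 1
  expect_lt(abs(mean(lrt[sol, j] + x$truth$tau[sol]) - x$truth$beta[j]),
            3 * (1 / x$truth$kappa[j]) / sqrt(sum(sol)))
  # correct rate among solution attempts with full mastery ~ 1 - s_j
  M <- mastery_from_alpha(x$truth$alpha, x$qmatrix, "DINA")
  cells <- x$truth$xi == 1 & M == 1
  p_hat <- sum(x$Y[cells]) / sum(cells)
  expect_lt(abs(p_hat - mean(1 - x$truth$s)), 0.02)
})

test_that("study designs encode the blocked pi pattern and variants", {
  pattern <- rep(rep(c(0.9, 0.8), each = 5), times = 3)
  expect_equal(study1_design("0.1")$pi_j, pattern)
  expect_equal(study1_design("0.2")$pi_j, pattern - 0.1)
  expect_equal(study1_design("none")$pi_j, rep(1, 30))
  expect_false(study1_design("none")$rg_enabled)
  expect_equal(study1_design("0.1", pi_pattern = "homogeneous")$pi_j,
               rep(0.9, 30))
  expect_equal(study1_design("0.1")$model, "DINA")
  expect_equal(study2_design("0.1")$model, "DINO")
  expect_error(study1_design("0.3"))

  d <- study1_design("0.1")
  expect_equal(d$n_persons, 1000L)
  expect_equal(d$beta0, 2)
  expect_equal(d$kappa0, 1.6)
  expect_equal(d$sigma_tau, 0.3)
  # IDI support implied by the g/s generating bounds
  expect_equal(1 - d$s_range[2] - d$g_range[2], 0.5)
  expect_equal(1 - d$s_range[1] - d$g_range[1], 0.9)
})

test_that("observed-data container validates shapes and support", {
  Q <- tiny_qmatrix()
  Y <- matrix(rbinom(60, 1, 0.5), 10, 6)
  RT <- matrix(rlnorm(60), 10, 6)
  dat <- rtcdm_data(Y, RT, Q)
  expect_s3_class(dat, "rtcdm_data")
  expect_null(dat$truth)
  expect_error(rtcdm_data(Y, RT[, -1], Q), "dimension mismatch")
  expect_error(rtcdm_data(Y[, -1], RT[, -1], Q), "dimension mismatch")
  expect_error(rtcdm_data(Y, -RT, Q), "positive")
  Yna <- Y; Yna[1, 1] <- NA
  expect_error(rtcdm_data(Yna, RT, Q), "missing")
})
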