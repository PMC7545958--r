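test_that("G-DINA success probability is the subset sum of delta terms", {
  # worked example: K* = 2
  delta <- c(0.1, 0.3, 0.2, 0.3)
  expect_equal(p_correct_gdina(c(1, 1), delta), 0.9)
  expect_equal(p_correct_gdina(c(0, 0), delta), 0.1)
  expect_equal(p_correct_gdina(c(1, 0), delta), 0.4)

  # any profile without the required attributes gets the intercept
  expect_equal(p_correct_gdina(c(0, 0, 0), delta = c(0.15, rep(0.1, 7))),
               0.15)

  # K* = 3 random valid deltas vs brute-force subset enumeration
  set.seed(4)
  for (rep in 1:5) {
    raw <- runif(8)
    delta <- raw / sum(raw) * runif(1, 0.5, 1)  # sums to <= 1, all >= 0
    for (r in seq_len(8)) {
      a <- latent_classes(3)[r, ]
      expect_equal(p_correct_gdina(a, delta), brute_gdina(a, delta),
                   tolerance = 1e-12)
    }
  }

  expect_error(p_correct_gdina(c(1, 1), delta = c(0.5, 0.4, 0.4, 0.4)),
               "outside")
  expect_error(validate_delta(c(0.5, 0.6)), "outside")
})

test_that("DINA gives 1-s on full mastery of the required set, g otherwise", {
  qrow <- c(1, 1, 0)
  expect_equal(p_correct_dina(c(1, 1, 0), g = 0.2, s = 0.1, qrow = qrow), 0.9)
  expect_equal(p_correct_dina(c(1, 1, 1), g = 0.2, s = 0.1, qrow = qrow), 0.9)
  expect_equal(p_correct_dina(c(1, 0, 1), g = 0.2, s = 0.1, qrow = qrow), 0.2)
  expect_error(p_correct_dina(c(1, 1), g = 0, s = 0.1), "\\(0, 1\\)")
  expect_error(p_correct_dina(c(1, 1), g = 0.6, s = 0.5), "monotonicity")
})

test_that("DINA equals G-DINA constrained to intercept + top interaction", {
  g <- 0.22; s <- 0.13
  delta <- delta_dina(g, s, Kstar = 3)
  expect_equal(delta[1], g)
  expect_equal(delta[8], 1 - s - g)
  cls <- latent_classes(3)
  for (r in seq_len(8)) {
    expect_equal(p_correct_dina(cls[r, ], g, s, qrow = c(1, 1, 1)),
                 p_correct_gdina(cls[r, ], delta), tolerance = 1e-12)
  }
})

test_that("DINO gives 1-s' with any required attribute, g' otherwise", {
  qrow <- c(1, 1)
  expect_equal(p_correct_dino(c(1, 0), g = 0.25, s = 0.15, qrow = qrow), 0.85)
  expect_equal(p_correct_dino(c(0, 0), g = 0.25, s = 0.15, qrow = qrow), 0.25)

  # alternating-sign delta construction reproduces the two-branch form
  g <- 0.25; s <- 0.15
  delta <- delta_dino(g, s, Kstar = 3)
  d <- 1 - s - g
  expect_equal(delta, c(g, d, d, -d, d, -d, -d, d))
  cls <- latent_classes(3)
  for (r in seq_len(8)) {
    expect_equal(p_correct_dino(cls[r, ], g, s, qrow = c(1, 1, 1)),
                 p_correct_gdina(cls[r, ], delta), tolerance = 1e-12)
  }
})

test_that("rapid-guess form reduces to the base model when xi = 1 and to the
           baseline when xi = 0", {
  qrow <- c(1, 1, 0)
  cls <- latent_classes(3)
  for (r in seq_len(8)) {
    a <- cls[r, ]
    expect_equal(
      p_correct_rg(a, xi = 1, model = "DINA", g = 0.2, s = 0.1, qrow = qrow),
      p_correct_dina(a, 0.2, 0.1, qrow))
    # xi = 0: constant in the profile
    expect_equal(
      p_correct_rg(a, xi = 0, model = "DINA", g = 0.2, s = 0.1, qrow = qrow),
      0.2)
    expect_equal(
      p_correct_rg(a, xi = 0, model = "DINO", g = 0.25, s = 0.15,
                   qrow = qrow), 0.25)
  }
  # free delta_star overrides the tie to the intercept
  expect_equal(p_correct_rg(c(1, 1, 1), xi = 0, model = "DINA", g = 0.2,
                            s = 0.1, qrow = qrow, delta_star = 0.3), 0.3)
})

test_that("monotonicity and the IDI span hold over all profiles", {
  qrow <- c(1, 1, 1)
  g <- 0.2; s <- 0.1
  cls <- latent_classes(3)
  for (fn in list(p_correct_dina, p_correct_dino)) {
    p <- apply(cls, 1, fn, g = g, s = s, qrow = qrow)
    expect_equal(max(p) - min(p), idi(g, s))
    # adding one mastered attribute never decreases the probability
    for (r in seq_len(8)) {
      for (k in which(cls[r, ] == 0)) {
        up <- cls[r, ]; up[k] <- 1
        expect_gte(fn(up, g = g, s = s, qrow = qrow),
                   fn(cls[r, ], g = g, s = s, qrow = qrow))
      }
    }
  }
})

test_that("IDI arithmetic and the generating support", {
  expect_equal(idi(0.05, 0.05), 0.90)
  expect_equal(idi(0.30, 0.20), 0.50)
  set.seed(9)
  v <- idi(runif(500, 0.05, 0.3), runif(500, 0.05, 0.2))
  expect_true(all(v > 0.5 & v < 0.9))
})
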