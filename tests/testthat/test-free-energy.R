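test_that("exact Gaussian free energy attains the evidence bound at the posterior", {
  m <- gauss_model(prior_mean = 0, prior_var = 1, obs_var = 1)
  r <- free_energy_gaussian(m, s = 1)  # q defaults to the exact posterior
  expect_equal(r$divergence, 0, tolerance = 1e-12)
  expect_equal(r$F, -r$log_evidence, tolerance = 1e-12)
  # closed-form evidence: s ~ N(0, prior_var + obs_var)
  expect_equal(r$F, -log(dnorm(1, 0, sqrt(2))), tolerance = 1e-12)
})

test_that("all three decompositions agree on random tractable instances", {
  set.seed(7)
  for (i in 1:50) {
    m <- gauss_model(rnorm(1), runif(1, 0.2, 3), runif(1, 0.2, 3))
    s <- rnorm(1, 0, 2)
    q <- gauss_beliefs(rnorm(1), runif(1, -1, 2))
    r <- free_energy_gaussian(m, s, q)
    expect_equal(r$F, r$energy - r$entropy, tolerance = 1e-9)
    expect_equal(r$F, r$complexity - r$accuracy, tolerance = 1e-9)
    expect_equal(r$F, r$divergence - r$log_evidence, tolerance = 1e-9)
    expect_gte(r$divergence, 0)
  }
})

test_that("free energy upper-bounds negative log evidence for any beliefs", {
  set.seed(11)
  m <- gauss_model(0.3, 1.5, 0.8)
  s <- 1.1
  lev <- free_energy_gaussian(m, s)$log_evidence
  for (i in 1:200) {
    q <- gauss_beliefs(rnorm(1, 0, 3), runif(1, -2, 3))
    expect_gte(free_energy_gaussian(m, s, q)$F, -lev - 1e-10)
  }
})

test_that("surprisal quadrature matches the closed form and scales quadratically", {
  m <- gauss_model(0.5, 1.2, 0.7)
  s <- 0.9
  closed <- surprisal(m, s)
  generic <- list(log_joint = function(psi, s_) {
    dnorm(s_, psi, sqrt(0.7), log = TRUE) + dnorm(psi, 0.5, sqrt(1.2), log = TRUE)
  })
  expect_equal(surprisal(generic, s), closed, tolerance = 1e-8)

  # the evidence mode minimizes surprisal; 5 SD out costs ~12.5 nats more
  sd_ev <- sqrt(1.2 + 0.7)
  expect_lt(surprisal(m, 0.5), surprisal(m, 0.5 + 0.5 * sd_ev))
  expect_equal(surprisal(m, 0.5 + 5 * sd_ev) - surprisal(m, 0.5), 12.5,
               tolerance = 1e-10)
})

test_that("Laplace free energy is the declared sum of precision-weighted terms", {
  # zero errors, unit precisions: only the normalization constant remains
  r0 <- laplace_free_energy(list(z = c(0, 0), w = rep(0, 3)),
                            list(z = 0, w = 0))
  expect_equal(r0$F, 0.5 * 5 * log(2 * pi), tolerance = 1e-12)

  # doubling one scalar error with precision pi raises F by (3/2) pi eps^2
  lp <- 1.3
  e <- 0.8
  f1 <- laplace_free_energy(list(z = e), list(z = lp))$F
  f2 <- laplace_free_energy(list(z = 2 * e), list(z = lp))$F
  expect_equal(f2 - f1, 1.5 * exp(lp) * e^2, tolerance = 1e-12)

  # random instance equals the independent sum-of-terms evaluator
  set.seed(3)
  errs <- list(z = matrix(rnorm(10), 2), w1 = matrix(rnorm(12), 3),
               v = rnorm(3), w2 = matrix(rnorm(12), 3))
  lps <- list(z = 1.2, w1 = 2.5, v = 0.4, w2 = 2.5)
  r <- laplace_free_energy(errs, lps, param_deviation = 0.3,
                           param_log_precision = 2)
  expect_equal(r$F, naive_laplace_F(errs, lps, 0.3, 2), tolerance = 1e-12)
  # complexity - accuracy identity holds by construction
  expect_equal(r$F, r$complexity - r$accuracy, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(gauss_model(0, -1, 1), "positive")
  expect_error(laplace_free_energy(list(z = 1), list(w = 1)), "share names")
  expect_error(laplace_free_energy(list(z = 1), list(z = Inf)), "finite")
})
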