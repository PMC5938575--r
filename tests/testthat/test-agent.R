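test_that("perception recovers the conjugate Gaussian posterior", {
  m <- gauss_model(prior_mean = -0.5, prior_var = 2, obs_var = 0.5)
  s <- 1.3
  post <- gauss_posterior(m, s)
  ag <- ns_agent(m, init_mean = 0)
  Fs <- numeric(200)
  for (i in 1:200) {
    ag <- perception_step(ag, s, dt = 0.05)
    Fs[i] <- attr(ag, "F")
  }
  expect_equal(ag$expectations$mu, post$mean, tolerance = 1e-4)
  # descent: free energy non-increasing along the flow
  expect_true(all(diff(Fs) <= 1e-8))
})

test_that("pure prior prediction is the zero-error limit of perception", {
  # with sensory equal to its own voiced prediction and flow-consistent
  # expectations, the update must follow the model flow (order-0 motion
  # equals the generalized velocity to first order)
  m <- birdsong_model()
  ag <- ns_agent(m, init_x1 = c(2, 3, 22), init_x2 = c(1, -1, 26))
  y <- agent_emission <- nichesync:::agent_emission(ag)
  ag2 <- perception_step(ag, gen_state(y), dt = 1 / 256)
  v1 <- ag$expectations$x1$values
  v2 <- ag2$expectations$x1$values
  # motion of the order-0 fast states ~ dt * x^(1) (scaled: rate * Z_1)
  # first-order prediction; curvature over the tick contributes O((rate*dt)^2)
  pred_step <- (1 / 256) * m$rate1 * v1[, 2]
  expect_lt(max(abs((v2[, 1] - v1[, 1]) - pred_step)),
            0.3 * max(abs(pred_step)))
})

test_that("action voices the current predictions", {
  m <- birdsong_model()
  ag <- ns_agent(m, role = "silent")
  out <- action_step(ag)
  expect_equal(out[["amplitude"]], 0)

  ag$role <- "singing"
  expect_equal(action_step(ag),
               song_observation(ag$expectations$x1$values[, 1], m))

  # two agents with identical expectations emit identical samples
  ag2 <- ns_agent(m, role = "singing", id = "B")
  ag2$expectations <- ag$expectations
  expect_identical(action_step(ag), action_step(ag2))

  ag$role <- "listening"
  expect_error(action_step(ag), "listening")
})

test_that("an infinitely precise prior cannot move under learning", {
  m <- birdsong_model(theta_prior_log_precision = 32)
  ag <- ns_agent(m)
  tr <- list(gtheta = rep(5000, 100), htheta = rep(100, 100),
             epoch_seconds = 2)
  ag2 <- learning_step(ag, tr)
  expect_lt(abs(ag2$theta_mean - ag$theta_mean), 1e-6)
  expect_error(learning_step(ag, list(gtheta = numeric(0))), "empty")
})

test_that("repeated learning converges to the precision-weighted compromise", {
  # quadratic F(theta) = pi_d/2 (theta - theta*)^2 with a finite prior:
  # the stationary point balances data and prior pulls
  m <- birdsong_model(theta_prior_mean = 20, theta_prior_log_precision = 0,
                      gamma_v = 0)  # accrual scale exp(-gamma_v) = 1
  ag <- ns_agent(m)
  pi_d <- 2
  theta_star <- 26
  for (i in 1:300) {
    g <- pi_d * (ag$theta_mean - theta_star)
    ag <- learning_step(ag, list(gtheta = rep(g, 10),
                                 htheta = rep(pi_d, 10),
                                 epoch_seconds = 2))
  }
  target <- (pi_d * theta_star + 1 * 20) / (pi_d + 1)
  expect_equal(ag$theta_mean, target, tolerance = 2e-3)
  # posterior precision never decreases
  expect_gte(ag$theta_log_precision, m$theta_prior_log_precision)
})

test_that("confidence intervals follow the Gaussian quantiles", {
  m <- birdsong_model()
  ag <- ns_agent(m)
  ag$theta_mean <- 5
  ag$theta_log_precision <- 0
  ci <- confidence_interval(ag, 0.90)
  expect_equal(unname(ci), 5 + c(-1, 1) * qnorm(0.95), tolerance = 1e-4)

  ag$theta_log_precision <- 20
  ci_tight <- confidence_interval(ag, 0.90)
  expect_lt(ci_tight[["high"]] - ci_tight[["low"]], 1e-3)

  w90 <- diff(confidence_interval(ag, 0.90))
  w50 <- diff(confidence_interval(ag, 0.50))
  expect_equal(unname(w90 / w50), qnorm(0.95) / qnorm(0.75), tolerance = 1e-6)
  expect_error(confidence_interval(ag, 1.2), "level")
})
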