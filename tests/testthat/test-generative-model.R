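test_that("the Lorenz flow matches hand-evaluated values and fixed points", {
  expect_equal(lorenz_flow(c(0, 0, 0), 10, 28, 8 / 3), c(0, 0, 0))
  expect_equal(lorenz_flow(c(1, 1, 1), 10, 28, 8 / 3, tau = 1),
               c(0, 26, -5 / 3))
  # nontrivial analytic fixed point (c, c, rho - 1), c = sqrt(beta (rho-1))
  rho <- 28; beta <- 8 / 3
  cc <- sqrt(beta * (rho - 1))
  expect_equal(lorenz_flow(c(cc, cc, rho - 1), 10, rho, beta), c(0, 0, 0),
               tolerance = 1e-12)
  # time-constant scaling: doubling tau halves the flow pointwise
  expect_equal(lorenz_flow(c(2, -1, 5), 10, 28, 8 / 3, tau = 2),
               lorenz_flow(c(2, -1, 5), 10, 28, 8 / 3, tau = 1) / 2)
  expect_error(lorenz_flow(c(1, NA, 1)), "finite")
})

test_that("the hierarchical flow decouples when the output map is zero", {
  m0 <- birdsong_model(output_map = c(0, 0, 0))
  h <- list(x1 = c(1, 2, 3), x2 = c(4, 5, 6))
  f <- model_flow(m0, h)
  # v = 0, so level 1 runs at its default (theta) rho
  p1 <- m0$levels[[1]]$flow_params
  expect_equal(f$x1, lorenz_flow(h$x1, p1$sigma, m0$theta_prior_mean,
                                 p1$beta, p1$tau))
  expect_equal(f$v, 0)
})

test_that("freezing the slow level reproduces a single-level chaotic run", {
  # slow level pinned at a fixed point implies a constant cause, hence a
  # constant effective rho; the fast trajectory must match a plain Lorenz
  # run with that rho
  m <- birdsong_model()
  rho2 <- m$rho2; b2 <- m$levels[[2]]$flow_params$beta
  x2_fix <- c(sqrt(b2 * (rho2 - 1)), sqrt(b2 * (rho2 - 1)), rho2 - 1)
  v_fix <- sum(m$levels[[2]]$output_map * x2_fix)
  rho_eff <- m$theta_prior_mean + m$rho_mod_cap * tanh(v_fix / m$rho_mod_cap)

  p1 <- m$levels[[1]]$flow_params
  f_two <- function(x) model_flow(m, list(x1 = x, x2 = x2_fix))$x1
  f_one <- function(x) lorenz_flow(x, p1$sigma, rho_eff, p1$beta, p1$tau)
  x <- c(2, 3, 20)
  for (i in 1:50) {
    expect_equal(f_two(x), f_one(x), tolerance = 1e-12)
    x <- integrate_flow(f_one, x, 1 / 256)
  }
})

test_that("song samples live in the audible band", {
  m <- birdsong_model()
  # map midpoint: x3 at f_ref gives exactly f_mid
  expect_equal(song_observation(c(0, 0, m$f_ref), m)[["frequency"]], m$f_mid)
  # silence limit: amplitude falls to zero as the y-state goes very negative
  expect_lt(song_observation(c(0, -60, 25), m)[["amplitude"]], 1e-6)
  # a generated trajectory stays inside the clipped band at every sample
  sim <- tiny_duet(n_epochs = 2, seed = 3)
  expect_true(all(sim$song$frequency >= m$freq_range[1]))
  expect_true(all(sim$song$frequency <= m$freq_range[2]))
  expect_true(all(sim$song$amplitude >= 0))
})

test_that("noise-free self-simulation yields vanishing prediction errors", {
  m <- birdsong_model()
  ex <- flow_consistent_expectations(m, c(2, 3, 22), c(1, -1, 26))
  # sensory equal to the agent's own voiced prediction
  y <- song_pred <- rbind(ex$x1$values[2, ],
                          ex$x1$values[3, ] - c(m$f_ref, rep(0, 4)))
  errs <- prediction_errors(m, ex, gen_state(y))
  for (b in errs) expect_lt(max(abs(b)), 1e-9)
})

test_that("sensory offsets perturb only the corresponding error entries", {
  m <- birdsong_model()
  ex <- flow_consistent_expectations(m, c(2, 3, 22), c(1, -1, 26))
  y0 <- rbind(ex$x1$values[2, ], ex$x1$values[3, ] - c(m$f_ref, rep(0, 4)))
  delta <- 0.37
  y1 <- y0; y1[1, 1] <- y1[1, 1] + delta
  e0 <- prediction_errors(m, ex, gen_state(y0))
  e1 <- prediction_errors(m, ex, gen_state(y1))
  expect_equal(unname(e1$z[1, 1] - e0$z[1, 1]), delta)
  e1$z[1, 1] <- e0$z[1, 1]
  expect_equal(e1, e0, ignore_attr = TRUE)
})

test_that("prediction errors match an independent evaluator and the compiled core", {
  m <- birdsong_model()
  for (seed in 1:5) {
    inst <- random_instance(m, seed)
    errs <- prediction_errors(m, inst$ex, inst$sens)
    ref <- naive_errors(m, inst$ex, inst$sens, m$theta_prior_mean)
    for (b in names(errs)) {
      expect_equal(unname(as.vector(errs[[b]])), unname(as.vector(ref[[b]])),
                   tolerance = 1e-10)
    }
    # compiled core agrees with the R surface
    ag <- ns_agent(m); ag$expectations <- inst$ex
    eps_cpp <- nichesync:::.errors_core(
      nichesync:::agent_mu(ag), as.vector(inst$sens$values),
      m$theta_prior_mean, nichesync:::core_pars(ag)
    )
    eps_r <- c(as.vector(errs$z), as.vector(errs$w1),
               as.vector(errs$v), as.vector(errs$w2))
    expect_equal(as.vector(eps_cpp), eps_r, tolerance = 1e-10)
    # and the Laplace F assembled from them matches the naive evaluator
    r <- birdsong_free_energy(m, inst$ex, inst$sens)
    expect_equal(r$F, naive_laplace_F(errs, model_log_precisions(m), 0,
                                      m$theta_prior_log_precision),
                 tolerance = 1e-9)
  }
})

test_that("generated songs are chaotic: adjacent starts diverge within 4 s", {
  sys <- couple(ns_agent(birdsong_model(), id = "A"),
                ns_agent(birdsong_model(), id = "B"),
                mode = "uncoupled", schedule = epoch_schedule(n_epochs = 3))
  sim <- simulate_duet(sys, seed = 5, init = "perturb")
  A <- expectation_trajectory(sim, "A", level = 1)
  B <- expectation_trajectory(sim, "B", level = 1)
  d0 <- sqrt(sum((A[1, ] - B[1, ])^2))
  expect_lt(d0, 1e-3)
  dmax <- max(sqrt(rowSums((A - B)^2)))
  expect_gt(dmax, 1)
})
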